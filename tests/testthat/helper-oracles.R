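## Independent oracles, deliberately naive: exhaustive enumeration only.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

## exhaustive global alignment score with affine gaps costing
## open + len * ext (the Biostrings convention); pure recursion over all
## alignments, no dynamic programming
brute_align_score <- function(a, b, open = 11, ext = 1, mat = blosum62) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, prev) {
    if (i == length(av) && j == length(bv)) return(0)
    best <- -Inf
    if (i < length(av) && j < length(bv)) {
      best <- max(best,
                  mat[av[i + 1L], bv[j + 1L]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i < length(av)) {  ## gap in b
      pen <- ext + if (prev == "GA") 0 else open
      best <- max(best, -pen + rec(i + 1L, j, "GA"))
    }
    if (j < length(bv)) {  ## gap in a
      pen <- ext + if (prev == "GB") 0 else open
      best <- max(best, -pen + rec(i, j + 1L, "GB"))
    }
    best
  }
  rec(0L, 0L, "M")
}

## minimum parsimony cost over all internal labelings (root state free)
exhaustive_parsimony_cost <- function(tree, states, gain = 2, loss = 1) {
  ntip <- length(tree$tip.label)
  k <- tree$Nnode
  states <- as.logical(states[tree$tip.label])
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  full <- cbind(matrix(rep(states, each = nrow(combos)), nrow = nrow(combos)),
                combos)
  p <- full[, tree$edge[, 1L], drop = FALSE]
  c_ <- full[, tree$edge[, 2L], drop = FALSE]
  cost <- rowSums((!p & c_) * gain + (p & !c_) * loss)
  min(cost)
}

random_rooted_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = TRUE)
  tr$node.label <- paste0("i", seq_len(tr$Nnode))
  tr
}

random_pattern <- function(tree, seed) {
  set.seed(seed)
  setNames(stats::runif(length(tree$tip.label)) < 0.5, tree$tip.label)
}
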