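#' Parse a rooted newick tree
#'
#' Reads a newick string into an [ape::phylo] object, preserving internal
#' node labels and branch lengths. Input is validated before parsing:
#' unbalanced parentheses and duplicated leaf labels raise errors that name
#' the offending position or label.
#'
#' @param text A single newick string (terminating `;` optional).
#' @return A rooted `phylo` object.
#' @seealso [write_newick()]
#' @export
#' @examples
#' tr <- parse_newick("((A,B)n1,C)root;")
#' tr$tip.label
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) stop("parse error: empty newick string")
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("parse error: unmatched ')' at position ", i)
    }
  }
  if (depth != 0L) {
    stop("parse error: ", depth, " unclosed '(' (string ends at position ",
         length(chars), ")")
  }
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("parse error: ", conditionMessage(e))
  )
  if (is.null(tree)) stop("parse error: newick string could not be parsed")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("parse error: duplicate leaf label(s): ",
         paste(unique(dup), collapse = ", "))
  }
  nl <- tree$node.label
  if (!is.null(nl)) {
    nl <- nl[nzchar(nl)]
    if (anyDuplicated(nl)) {
      stop("parse error: duplicate internal node label(s): ",
           paste(unique(nl[duplicated(nl)]), collapse = ", "))
    }
  }
  tree
}

#' Write a tree as a canonical newick string
#'
#' Inverse of [parse_newick()]; `parse_newick(write_newick(tree))` is stable.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written to disk.
#' @return The newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

## --- internal tree helpers -------------------------------------------------

## labels for every node id: tips 1..Ntip, then internals
node_labels <- function(tree) {
  nl <- tree$node.label
  if (is.null(nl)) nl <- paste0("node", seq_len(tree$Nnode))
  nl[!nzchar(nl)] <- paste0("node", which(!nzchar(nl)))
  c(tree$tip.label, nl)
}

label_to_node <- function(tree) {
  labs <- node_labels(tree)
  setNames(seq_along(labs), labs)
}

root_node <- function(tree) length(tree$tip.label) + 1L

## children list indexed by node id
children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n)
  by_parent <- split(tree$edge[, 2L], tree$edge[, 1L])
  ## preserve the input (left-to-right) child order
  for (p in names(by_parent)) ch[[as.integer(p)]] <- by_parent[[p]]
  ch
}

parent_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  par <- rep(NA_integer_, n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

## node ids in preorder (root first, left-to-right in input order)
preorder_nodes <- function(tree) {
  ch <- children_list(tree)
  out <- integer(0)
  stack <- root_node(tree)
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(ch[[v]], stack)
  }
  out
}

postorder_nodes <- function(tree) rev(preorder_nodes(tree))

## logical matrix-free: for each node, tips below it (list of tip ids)
tips_below <- function(tree) {
  ch <- children_list(tree)
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) below[[v]] <- v
    else below[[v]] <- unlist(lapply(ch[[v]], function(c) below[[c]]))
  }
  below
}

## branch length of the edge above each node (NA for root)
edge_length_above <- function(tree, default = 1) {
  n <- length(tree$tip.label) + tree$Nnode
  len <- rep(NA_real_, n)
  if (is.null(tree$edge.length)) {
    len[tree$edge[, 2L]] <- default
  } else {
    len[tree$edge[, 2L]] <- tree$edge.length
  }
  len
}

## MRCA of a set of node ids (>= 1); for a single node returns it
mrca_node <- function(tree, nodes) {
  stopifnot(length(nodes) >= 1L)
  if (length(nodes) == 1L) return(nodes)
  par <- parent_vec(tree)
  anc <- function(v) {
    out <- v
    while (!is.na(par[v])) {
      v <- par[v]
      out <- c(out, v)
    }
    out
  }
  common <- Reduce(intersect, lapply(nodes, anc))
  common[1L]  ## anc() lists bottom-up, intersect preserves first arg's order
}
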