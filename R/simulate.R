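## evaluate code under a fixed RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Parameters for gene-content simulation
#'
#' Rates are per unit branch length per active (functional) gene copy.
#'
#' @param loss_rate,duplication_rate,transfer_rate,pseudogenization_rate
#'   Nonnegative event rates.
#' @param root_copies Number of functional copies at the root (default 1).
#' @param seed Integer seed; fully determines the simulation.
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(loss_rate = 0.1, duplication_rate = 0,
                              transfer_rate = 0, pseudogenization_rate = 0,
                              root_copies = 1L, seed = 1L) {
  rates <- c(loss_rate, duplication_rate, transfer_rate,
             pseudogenization_rate)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("parameter error: rates must be finite and nonnegative")
  }
  stopifnot(root_copies >= 0L)
  structure(list(loss_rate = loss_rate, duplication_rate = duplication_rate,
                 transfer_rate = transfer_rate,
                 pseudogenization_rate = pseudogenization_rate,
                 root_copies = as.integer(root_copies),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

## edges eligible as transfer recipients for a donor at node v:
## neither ancestral nor descendant to the donor edge (no branch dates are
## modelled; overlap in time is approximated by phylogenetic unrelatedness)
eligible_recipients <- function(tree, v, par, below) {
  anc <- integer(0)
  u <- v
  while (!is.na(par[u])) { u <- par[u]; anc <- c(anc, u) }
  n <- length(par)
  setdiff(which(!is.na(par)), c(v, anc, below[[v]]))
}

#' Simulate gene-content evolution along a species tree
#'
#' Each functional copy evolves independently down the tree; losses,
#' duplications, pseudogenizations and transfer emissions are competing
#' Poisson processes per copy per branch. A transferred copy is inserted at
#' the top of a uniformly chosen recipient branch that is neither ancestral
#' nor descendant to the donor branch, and does not itself re-transfer.
#' Pseudogenized copies stop evolving and are inherited as pseudogenes by
#' all descendant leaves. Branch lengths default to 1 where absent.
#'
#' @param tree Rooted `phylo`.
#' @param params A [simulation_params()].
#' @param family Family identifier for the emitted matrix and event log.
#' @param origin Node label where the family originates (default: the
#'   root). The founding copies start at the top of that node's stem edge;
#'   leaves outside its subtree stay absent unless a transfer reaches them.
#' @param plant_transfer_to Optional node label: after the vertical
#'   simulation, exactly one transferred copy is planted at the top of this
#'   node's stem edge (recorded as a transfer event with the origin as
#'   donor) and evolves down its subtree. Used to build ground truth for
#'   transfer-recovery experiments.
#' @return A `simulation_run`: list with `params`, `true_events` (data frame
#'   `type`, `edge`, `family`, `donor`), `leaf_matrix` (a
#'   [phyletic_matrix()] restricted to the family), and `tree`.
#' @export
simulate_gene_content <- function(tree, params = simulation_params(),
                                  family = "sim", origin = NULL,
                                  plant_transfer_to = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "simulation_params"))
  labs <- node_labels(tree)
  par <- parent_vec(tree)
  ch <- children_list(tree)
  below <- tips_below(tree)
  len <- edge_length_above(tree, default = 1)
  ntip <- length(tree$tip.label)
  root <- root_node(tree)

  env <- new.env()
  env$events <- list()
  env$fun <- integer(ntip)   ## functional copies per leaf
  env$pse <- integer(ntip)   ## pseudogene copies per leaf
  env$emissions <- list()    ## pending transfers: list(donor_node)

  record <- function(type, node, donor = NA_character_) {
    env$events[[length(env$events) + 1L]] <-
      list(type = type, edge = labs[node], donor = donor)
  }

  rates <- c(loss = params$loss_rate, dup = params$duplication_rate,
             pseudo = params$pseudogenization_rate,
             transfer = params$transfer_rate)

  ## simulate one functional copy from `offset` along the edge above `v`;
  ## can_transfer is FALSE for already-transferred copies
  sim_copy <- function(v, offset, can_transfer) {
    if (v != root) {
      L <- len[v]
      t <- offset
      total <- sum(rates)
      while (total > 0) {
        t <- t + stats::rexp(1L, total)
        if (t >= L) break
        type <- sample(names(rates), 1L, prob = rates)
        if (type == "loss") {
          record("loss", v)
          return(invisible(NULL))
        } else if (type == "dup") {
          record("duplication", v)
          sim_copy(v, t, can_transfer)
        } else if (type == "pseudo") {
          record("pseudogenization", v)
          for (tip in below[[v]]) env$pse[tip] <- env$pse[tip] + 1L
          return(invisible(NULL))
        } else if (type == "transfer" && can_transfer) {
          env$emissions[[length(env$emissions) + 1L]] <- v
        }
      }
    }
    if (v <= ntip) {
      env$fun[v] <- env$fun[v] + 1L
    } else {
      for (c in ch[[v]]) sim_copy(c, 0, can_transfer)
    }
    invisible(NULL)
  }

  lab2node <- label_to_node(tree)
  origin_node <- root
  if (!is.null(origin)) {
    if (!origin %in% names(lab2node)) stop("unknown origin label: ", origin)
    origin_node <- lab2node[[origin]]
  }
  with_seed(params$seed, {
    for (i in seq_len(params$root_copies)) sim_copy(origin_node, 0, TRUE)
    if (!is.null(plant_transfer_to)) {
      if (!plant_transfer_to %in% names(lab2node)) {
        stop("unknown recipient label: ", plant_transfer_to)
      }
      recip <- lab2node[[plant_transfer_to]]
      record("transfer", recip, donor = labs[origin_node])
      sim_copy(recip, 0, FALSE)
    }
    ## resolve transfer emissions (transferred copies do not re-transfer)
    while (length(env$emissions)) {
      donor <- env$emissions[[1L]]
      env$emissions <- env$emissions[-1L]
      elig <- eligible_recipients(tree, donor, par, below)
      if (!length(elig)) next
      recip <- elig[sample.int(length(elig), 1L)]
      record("transfer", recip, donor = labs[donor])
      sim_copy(recip, 0, FALSE)
    }
  })

  ev <- if (length(env$events)) {
    data.frame(type = vapply(env$events, `[[`, "", "type"),
               edge = vapply(env$events, `[[`, "", "edge"),
               family = family,
               donor = vapply(env$events, `[[`, "", "donor"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(type = character(0), edge = character(0),
               family = character(0), donor = character(0),
               stringsAsFactors = FALSE)
  }
  status <- ifelse(env$fun > 0L & env$pse > 0L, "mixed",
                   ifelse(env$fun > 0L, "functional",
                          ifelse(env$pse > 0L, "pseudogene", "absent")))
  mat <- phyletic_matrix(data.frame(
    species = tree$tip.label, family = family,
    copy_count = env$fun + env$pse, status = status,
    member_ids = "", provenance = "simulated",
    stringsAsFactors = FALSE))
  structure(list(params = params, true_events = ev, leaf_matrix = mat,
                 tree = tree),
            class = "simulation_run")
}

CODON_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

#' Simulate a TrmFO-related protein with planted diagnostic features
#'
#' Generates a query sequence from the packaged reference template: the
#' diagnostic positions (catalytic 51/223, FAD motif, folate triad 308-310,
#' flavin stack 343) are set according to the requested subfamily (C/C for
#' TrmFO and RlmFO, Y/Y for TrmFO-like) and are never mutated; every other
#' position diverges from the template with probability `divergence`
#' (baseline homolog divergence) and additionally with probability `noise`.
#' TrmFO-like sequences carry a 20-residue deletion downstream of the
#' diagnostic positions, mirroring their shorter length.
#'
#' @param subfamily `"TrmFO"`, `"RlmFO"` or `"TrmFO_like"`.
#' @param length Target length (>= 350 so that position 343 exists).
#' @param noise Extra substitution probability away from diagnostic
#'   positions, in `[0, 1)`.
#' @param seed Integer seed.
#' @param divergence Baseline per-position divergence from the template.
#' @param cds If `TRUE`, also emit a CDS (uniform synonymous codons).
#' @param pseudogene If `TRUE` (with `cds`), plant a premature stop at 50%
#'   of the coding length.
#' @param annotation Reference annotation (defaults to the packaged one).
#' @return List with `protein`, `cds` (or `NULL`), `subfamily`.
#' @export
simulate_protein <- function(subfamily = c("TrmFO", "RlmFO", "TrmFO_like"),
                             length = NULL, noise = 0, seed = 1L,
                             divergence = 0.25, cds = FALSE,
                             pseudogene = FALSE, annotation = NULL) {
  subfamily <- match.arg(subfamily)
  if (noise < 0 || noise >= 1) stop("noise must be in [0, 1)")
  if (is.null(annotation)) annotation <- load_reference_annotation()
  template <- strsplit(annotation$reference_sequence, "")[[1]]
  if (is.null(length)) length <- base::length(template)
  if (length < 350L) stop("length too short: need >= 350 to host position 343")
  tlen <- base::length(template)
  motif_start <- scan_fad_motif(annotation$reference_sequence)[1L]
  protected <- c(annotation$catalytic_positions,
                 annotation$folate_triad_positions,
                 annotation$flavin_stack_position,
                 seq(motif_start, motif_start + 8L))
  with_seed(seed, {
    seq <- template
    if (length <= tlen) {
      seq <- seq[seq_len(length)]
    } else {
      seq <- c(seq, sample(AA20, length - tlen, replace = TRUE))
    }
    cat_res <- if (subfamily == "TrmFO_like") "Y" else "C"
    seq[annotation$catalytic_positions] <- cat_res
    mutate <- function(seq, p) {
      free <- setdiff(seq_along(seq), protected)
      hit <- free[stats::runif(base::length(free)) < p]
      seq[hit] <- vapply(seq[hit], function(a) sample(setdiff(AA20, a), 1L),
                         character(1))
      seq
    }
    seq <- mutate(seq, divergence)
    if (noise > 0) seq <- mutate(seq, noise)
    if (subfamily == "TrmFO_like" && base::length(seq) >= 370L) {
      seq <- seq[-(350:369)]  ## 20-aa deletion past all diagnostics
    }
    protein <- paste(seq, collapse = "")
    cds_seq <- NULL
    if (cds) {
      codons <- vapply(seq, function(a) {
        opts <- CODON_BY_AA[[a]]
        opts[sample.int(base::length(opts), 1L)]
      }, character(1))
      codons <- c(codons, "TAA")
      if (pseudogene) {
        codons[floor(base::length(codons) / 2L)] <- "TAA"
      }
      cds_seq <- paste(codons, collapse = "")
    }
    list(protein = protein, cds = cds_seq, subfamily = subfamily)
  })
}
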