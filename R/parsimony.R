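#' Cost model for gene-content parsimony
#'
#' Defaults encode the reductive-evolution prior for mollicutes: losses are
#' cheap (1), novel acquisitions and horizontal transfers rare (2).
#'
#' @param gain_cost,loss_cost,transfer_cost Positive event costs.
#' @param mode `"wagner"` (free gains/losses, Sankoff dynamic programming),
#'   `"dollo"` (at most one origin per family), or `"dollo_with_transfers"`
#'   (one primary origin plus transfer re-origins).
#' @return A `cost_model` list.
#' @export
cost_model <- function(gain_cost = 2, loss_cost = 1, transfer_cost = 2,
                       mode = c("dollo", "wagner", "dollo_with_transfers")) {
  mode <- match.arg(mode)
  for (x in c(gain_cost, loss_cost, transfer_cost)) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop("costs must be positive finite numbers")
    }
  }
  structure(list(gain_cost = gain_cost, loss_cost = loss_cost,
                 transfer_cost = transfer_cost, mode = mode),
            class = "cost_model")
}

check_leaf_states <- function(tree, leaf_states) {
  if (is.numeric(leaf_states)) leaf_states <- leaf_states > 0
  if (is.null(names(leaf_states))) stop("leaf_states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(leaf_states))
  if (length(miss)) {
    stop("leaf missing from states: ", paste(head(miss, 3L), collapse = ", "))
  }
  extra <- setdiff(names(leaf_states), tree$tip.label)
  if (length(extra)) {
    stop("state given for unknown leaf: ", paste(head(extra, 3L), collapse = ", "))
  }
  leaf_states[tree$tip.label]
}

new_scenario <- function(family, costs, total_cost, events, node_states,
                         origin = NA_character_) {
  if (is.null(events) || !nrow(events)) {
    events <- data.frame(type = character(0), edge = character(0),
                         family = character(0), donor = character(0),
                         stringsAsFactors = FALSE)
  }
  structure(list(family = family, cost_model = costs,
                 total_cost = total_cost, events = events,
                 node_states = node_states, origin = origin),
            class = "event_scenario")
}

event_df <- function(type, edge, family, donor = NA_character_) {
  data.frame(type = type, edge = edge, family = family, donor = donor,
             stringsAsFactors = FALSE)
}

## presence/absence info shared by the dollo routines
dollo_geometry <- function(tree, states) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  ch <- children_list(tree)
  has_present <- logical(n)  ## >=1 present tip at/below node
  all_present <- logical(n)
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) {
      has_present[v] <- states[v]
      all_present[v] <- states[v]
    } else {
      has_present[v] <- any(has_present[ch[[v]]])
      all_present[v] <- all(all_present[ch[[v]]])
    }
  }
  list(has_present = has_present, all_present = all_present, children = ch,
       ntip = ntip)
}

## minimal-loss region below an origin: returns loss child-node ids
dollo_losses_below <- function(tree, geom, origin) {
  losses <- integer(0)
  stack <- origin
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    for (c in geom$children[[v]]) {
      if (geom$has_present[c]) stack <- c(stack, c)
      else losses <- c(losses, c)
    }
  }
  losses
}

## nodes in the presence region below an origin
dollo_region_below <- function(tree, geom, origin) {
  region <- integer(0)
  stack <- origin
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    region <- c(region, v)
    for (c in geom$children[[v]]) {
      if (geom$has_present[c]) stack <- c(stack, c)
    }
  }
  region
}

dollo_reconstruct <- function(tree, states, costs, family) {
  labs <- node_labels(tree)
  n <- length(labs)
  if (!any(states)) {
    return(new_scenario(family, costs, 0,
                        NULL, setNames(rep(FALSE, n), labs)))
  }
  geom <- dollo_geometry(tree, states)
  origin <- mrca_node(tree, which(seq_len(geom$ntip) %in% which(states)))
  region <- dollo_region_below(tree, geom, origin)
  losses <- dollo_losses_below(tree, geom, origin)
  node_states <- setNames(rep(FALSE, n), labs)
  node_states[region] <- TRUE
  events <- rbind(
    event_df("gain", labs[origin], family),
    if (length(losses)) event_df("loss", labs[losses], family)
  )
  total <- costs$gain_cost + costs$loss_cost * length(losses)
  new_scenario(family, costs, total, events, node_states,
               origin = labs[origin])
}

wagner_dp <- function(tree, states, costs) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  ch <- children_list(tree)
  cost <- matrix(Inf, nrow = n, ncol = 2L)  ## columns: absent, present
  w <- function(s, t) {
    if (s == t) 0 else if (s == 0L) costs$gain_cost else costs$loss_cost
  }
  for (v in postorder_nodes(tree)) {
    if (v <= ntip) {
      cost[v, if (states[v]) 2L else 1L] <- 0
    } else {
      for (s in 0:1) {
        tot <- 0
        for (c in ch[[v]]) {
          tot <- tot + min(cost[c, 1L] + w(s, 0L), cost[c, 2L] + w(s, 1L))
        }
        cost[v, s + 1L] <- tot
      }
    }
  }
  list(cost = cost, children = ch, ntip = ntip, w = w)
}

wagner_reconstruct <- function(tree, states, costs, family) {
  dp <- wagner_dp(tree, states, costs)
  labs <- node_labels(tree)
  root <- root_node(tree)
  best <- min(dp$cost[root, ])
  ## tie-break: prefer presence at the root, then no event on each edge,
  ## which keeps forced events as close to the root as possible
  root_state <- if (dp$cost[root, 2L] <= dp$cost[root, 1L]) 1L else 0L
  par <- parent_vec(tree)
  assign <- integer(length(labs))
  assign[root] <- root_state
  events <- NULL
  for (v in preorder_nodes(tree)) {
    if (v == root) next
    p <- par[v]
    s <- assign[p]
    v0 <- dp$cost[v, 1L] + dp$w(s, 0L)
    v1 <- dp$cost[v, 2L] + dp$w(s, 1L)
    t <- if (v1 < v0) 1L else if (v0 < v1) 0L else s
    assign[v] <- t
    if (t != s) {
      events <- rbind(events,
                      event_df(if (t == 1L) "gain" else "loss", labs[v], family))
    }
  }
  node_states <- setNames(assign == 1L, labs)
  new_scenario(family, costs, best, events, node_states)
}

#' Most-parsimonious ancestral reconstruction of a binary gene family
#'
#' Reconstructs ancestral presence/absence and the implied event scenario
#' for one gene family on a rooted species tree. In `wagner` mode this is
#' Sankoff dynamic programming under asymmetric gain/loss costs with a free
#' root state. In `dollo` mode the family originates exactly once: the
#' origin is the MRCA of the carrier leaves (charged `gain_cost` on its stem
#' edge, the root's own label when the origin is the root) and losses are
#' placed on the maximal carrier-free subtrees below it, which is the unique
#' minimum-loss Dollo reconstruction.
#'
#' Events are annotated on edges identified by their child-node label
#' ("loss at node 2" means the branch whose child is node 2).
#'
#' @param tree Rooted `phylo` with unique tip labels.
#' @param leaf_states Named logical (or 0/1) vector over all tips; `TRUE` =
#'   family present (pseudogenes count as present, see
#'   [family_leaf_states()]).
#' @param costs A [cost_model()].
#' @param family Family identifier recorded on the events.
#' @return An `event_scenario`: list with `family`, `cost_model`,
#'   `total_cost`, `events` (data frame type/edge/family/donor),
#'   `node_states` (named by node label), and `origin`.
#' @export
#' @examples
#' tr <- parse_newick("((A,B)x,(C,D)y)r;")
#' sc <- sankoff_reconstruct(tr, c(A = 1, B = 1, C = 0, D = 0),
#'                           cost_model(mode = "wagner"))
#' sc$events
sankoff_reconstruct <- function(tree, leaf_states, costs = cost_model(),
                                family = "family") {
  stopifnot(inherits(tree, "phylo"), inherits(costs, "cost_model"))
  states <- check_leaf_states(tree, leaf_states)
  switch(costs$mode,
         wagner = wagner_reconstruct(tree, states, costs, family),
         dollo = dollo_reconstruct(tree, states, costs, family),
         dollo_with_transfers = dollo_with_transfers(tree, states, costs,
                                                     family))
}

#' Enumerate all most-parsimonious reconstructions
#'
#' In `wagner` mode, enumerates every internal labeling achieving the
#' minimum Sankoff cost (the canonical scenario of
#' [sankoff_reconstruct()] is always a member). In `dollo` mode the
#' minimum-loss reconstruction is unique (see [sankoff_reconstruct()]), so a
#' single scenario is returned.
#'
#' @inheritParams sankoff_reconstruct
#' @param max_scenarios Guard against state-space explosion; exceeding it
#'   raises an error.
#' @return List of `event_scenario` objects.
#' @export
enumerate_mprs <- function(tree, leaf_states, costs = cost_model(),
                           family = "family", max_scenarios = 10000L) {
  stopifnot(inherits(tree, "phylo"), inherits(costs, "cost_model"))
  states <- check_leaf_states(tree, leaf_states)
  if (costs$mode != "wagner") {
    return(list(sankoff_reconstruct(tree, states, costs, family)))
  }
  dp <- wagner_dp(tree, states, costs)
  labs <- node_labels(tree)
  root <- root_node(tree)
  par <- parent_vec(tree)
  best <- min(dp$cost[root, ])
  pre <- preorder_nodes(tree)
  assigns <- list()
  for (s in 0:1) {
    if (dp$cost[root, s + 1L] == best) {
      a <- integer(length(labs)); a[root] <- s
      assigns <- c(assigns, list(a))
    }
  }
  for (v in pre) {
    if (v == root) next
    nxt <- list()
    for (a in assigns) {
      s <- a[par[v]]
      v0 <- dp$cost[v, 1L] + dp$w(s, 0L)
      v1 <- dp$cost[v, 2L] + dp$w(s, 1L)
      for (t in 0:1) {
        if ((if (t == 0L) v0 else v1) == min(v0, v1)) {
          b <- a; b[v] <- t
          nxt <- c(nxt, list(b))
        }
      }
      if (length(nxt) > max_scenarios) {
        stop("MPR enumeration exceeds max_scenarios = ", max_scenarios)
      }
    }
    assigns <- nxt
  }
  lapply(assigns, function(a) {
    events <- NULL
    for (v in pre) {
      if (v == root) next
      if (a[v] != a[par[v]]) {
        events <- rbind(events, event_df(if (a[v] == 1L) "gain" else "loss",
                                         labs[v], family))
      }
    }
    cost <- if (is.null(events)) 0 else
      sum(ifelse(events$type == "gain", costs$gain_cost, costs$loss_cost))
    new_scenario(family, costs, cost, events, setNames(a == 1L, labs))
  })
}

#' Dollo parsimony with horizontal-transfer re-origins
#'
#' Exact search for the cheapest scenario in which the family has one
#' primary origin (charged `gain_cost`) plus any number of transfer
#' re-origins (each charged `transfer_cost`), with losses at `loss_cost`.
#' The search space is organised around the maximal carrier-only subtrees
#' ("blocks"); an exact set-cover dynamic program over blocks chooses the
#' origin edges. The primary origin is the preorder-first origin; transfer
#' donors are recorded as the primary origin's edge label. The result never
#' costs more than the plain Dollo scenario on the same input.
#'
#' @inheritParams sankoff_reconstruct
#' @param max_blocks Explosion guard on the number of carrier blocks.
#' @return An `event_scenario` (with `transfer` events when beneficial).
#' @export
dollo_with_transfers <- function(tree, leaf_states, costs = cost_model(
                                   mode = "dollo_with_transfers"),
                                 family = "family", max_blocks = 20L) {
  stopifnot(inherits(tree, "phylo"), inherits(costs, "cost_model"))
  states <- check_leaf_states(tree, leaf_states)
  labs <- node_labels(tree)
  if (!any(states)) {
    return(new_scenario(family, costs, 0, NULL,
                        setNames(rep(FALSE, length(labs)), labs)))
  }
  geom <- dollo_geometry(tree, states)
  par <- parent_vec(tree)
  root <- root_node(tree)
  ## blocks: maximal subtrees whose leaves are all carriers
  blocks <- which(vapply(seq_along(labs), function(v) {
    geom$all_present[v] && (is.na(par[v]) || !geom$all_present[par[v]])
  }, logical(1)))
  B <- length(blocks)
  if (B > max_blocks) {
    stop("transfer search guard: ", B, " carrier blocks exceed max_blocks = ",
         max_blocks)
  }
  pre <- preorder_nodes(tree)
  pre_rank <- match(seq_along(labs), pre)
  ## candidate origins: nodes with at least one carrier below, in preorder
  cand <- pre[geom$has_present[pre]]
  anc_of <- function(v) {
    out <- v
    while (!is.na(par[v])) { v <- par[v]; out <- c(out, v) }
    out
  }
  block_anc <- lapply(blocks, anc_of)
  covered <- vapply(cand, function(o) {
    m <- 0
    for (b in seq_len(B)) if (o %in% block_anc[[b]]) m <- m + bitwShiftL(1L, b - 1L)
    as.integer(m)
  }, integer(1))
  loss_n <- vapply(cand, function(o) length(dollo_losses_below(tree, geom, o)),
                   integer(1))
  cost_o <- costs$loss_cost * loss_n + costs$transfer_cost
  full <- bitwShiftL(1L, B) - 1L
  ## candidates able to cover each block (its ancestors-or-self)
  cand_by_block <- lapply(seq_len(B), function(b) {
    which(bitwAnd(covered, bitwShiftL(1L, b - 1L)) != 0L)
  })
  dp <- rep(Inf, full + 1L)
  dp_n <- rep(0L, full + 1L)       ## number of origins (tie-break: fewer)
  choice <- rep(NA_integer_, full + 1L)
  dp[1L] <- 0  ## mask 0 stored at index 1
  for (mask in seq_len(full)) {
    lb <- bitwAnd(mask, -mask)  ## lowest set bit
    bidx <- as.integer(round(log2(lb))) + 1L
    bestc <- Inf; bestn <- 0L; bestk <- NA_integer_
    for (k in cand_by_block[[bidx]]) {
      rest <- bitwAnd(mask, bitwNot(covered[k]))
      rest <- bitwAnd(rest, full)
      cc <- dp[rest + 1L] + cost_o[k]
      nn <- dp_n[rest + 1L] + 1L
      if (cc < bestc - 1e-9 || (abs(cc - bestc) < 1e-9 && nn < bestn)) {
        bestc <- cc; bestn <- nn; bestk <- k
      }
    }
    dp[mask + 1L] <- bestc
    dp_n[mask + 1L] <- bestn
    choice[mask + 1L] <- bestk
  }
  ## reconstruct chosen origin set
  origins <- integer(0)
  mask <- full
  while (mask != 0L) {
    k <- choice[mask + 1L]
    origins <- c(origins, cand[k])
    mask <- bitwAnd(mask, bitwNot(covered[k]))
    mask <- bitwAnd(mask, full)
  }
  origins <- origins[order(pre_rank[origins])]
  primary <- origins[1L]
  losses <- unlist(lapply(origins, function(o)
    dollo_losses_below(tree, geom, o)))
  region <- unlist(lapply(origins, function(o)
    dollo_region_below(tree, geom, o)))
  node_states <- setNames(rep(FALSE, length(labs)), labs)
  node_states[region] <- TRUE
  events <- event_df("gain", labs[primary], family)
  if (length(origins) > 1L) {
    events <- rbind(events,
                    event_df("transfer", labs[origins[-1L]], family,
                             donor = labs[primary]))
  }
  if (length(losses)) events <- rbind(events, event_df("loss", labs[losses], family))
  total <- costs$gain_cost +
    costs$transfer_cost * (length(origins) - 1L) +
    costs$loss_cost * length(losses)
  new_scenario(family, costs, total, events, node_states,
               origin = labs[primary])
}

#' Replay a scenario's events down the tree
#'
#' Applies the scenario's gain/transfer/loss events from the root downward
#' and returns the implied leaf presence states. Used to assert the replay
#' invariant: every scenario reproduces its input leaf states exactly.
#'
#' @param tree Rooted `phylo`.
#' @param scenario An `event_scenario`.
#' @return Named logical vector over tips.
#' @export
replay_scenario <- function(tree, scenario) {
  labs <- node_labels(tree)
  root <- root_node(tree)
  par <- parent_vec(tree)
  ev <- scenario$events
  ev <- ev[ev$type %in% c("gain", "loss", "transfer"), , drop = FALSE]
  by_edge <- split(ev$type, ev$edge)
  state <- logical(length(labs))
  root_state <- isTRUE(scenario$node_states[[labs[root]]])
  for (v in preorder_nodes(tree)) {
    s <- if (v == root) root_state else state[par[v]]
    e <- by_edge[[labs[v]]]
    if (!is.null(e)) {
      if (any(e %in% c("gain", "transfer"))) s <- TRUE
      if (any(e == "loss")) s <- FALSE
    }
    state[v] <- s
  }
  setNames(state[seq_along(tree$tip.label)], tree$tip.label)
}

#' Re-type events across related subfamilies
#'
#' A gain of one subfamily on a lineage that already carries a sister
#' subfamily is re-typed as a duplication (with the sister recorded; when
#' several sisters are present the sister is `"ambiguous"`, as for the
#' ruminant-clade duplication where the copied template cannot be decided).
#' Transfers keep their type. Pseudogene leaf states append terminal-edge
#' pseudogenization events.
#'
#' @param scenarios Named list of `event_scenario` objects on the same tree,
#'   one per subfamily.
#' @param relations List of character vectors grouping related subfamilies;
#'   default groups the COG1206 subfamilies.
#' @param matrix Optional [phyletic_matrix()] supplying pseudogene leaf
#'   states.
#' @return Data frame of annotated events: `family`, `type`, `edge`,
#'   `donor`, `sister`.
#' @export
type_events <- function(scenarios,
                        relations = list(c("trmFO", "rlmFO", "trmFO_like")),
                        matrix = NULL) {
  stopifnot(is.list(scenarios), !is.null(names(scenarios)))
  out <- NULL
  for (fam in names(scenarios)) {
    sc <- scenarios[[fam]]
    ev <- sc$events
    if (nrow(ev)) {
      ev$sister <- NA_character_
      group <- NULL
      for (g in relations) if (fam %in% g) group <- g
      sisters <- setdiff(intersect(group, names(scenarios)), fam)
      for (i in which(ev$type == "gain")) {
        lab <- ev$edge[i]
        carriers <- sisters[vapply(sisters, function(s) {
          isTRUE(scenarios[[s]]$node_states[[lab]])
        }, logical(1))]
        if (length(carriers) == 1L) {
          ev$type[i] <- "duplication"
          ev$sister[i] <- carriers
        } else if (length(carriers) > 1L) {
          ev$type[i] <- "duplication"
          ev$sister[i] <- "ambiguous"
        }
      }
      out <- rbind(out, ev)
    }
    if (!is.null(matrix) && fam %in% matrix$family) {
      sub <- matrix[matrix$family == fam &
                      matrix$status %in% c("pseudogene", "mixed"), ]
      if (nrow(sub)) {
        ps <- event_df("pseudogenization", sub$species, fam)
        ps$sister <- NA_character_
        out <- rbind(out, ps)
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(type = character(0), edge = character(0),
                      family = character(0), donor = character(0),
                      sister = character(0), stringsAsFactors = FALSE)
  }
  out[, c("family", "type", "edge", "donor", "sister")]
}

#' Genotype-to-phenotype consistency report
#'
#' Checks each empirically assayed RNA-modification site against the gene
#' content: m5U54 in tRNA requires a functional trmFO; m5U1939 in 23S rRNA
#' requires a functional rlmD or rlmFO; m3U1915 requires a functional rlmH.
#' Species on the `rlmh_exceptions` list where rlmH is predicted but the
#' site is unmodified are flagged `documented_exception` rather than
#' `inconsistent` (the paper documents these cases; low expression or
#' point mutations are the suspected causes). Pseudogenes count as
#' non-functional.
#'
#' @param matrix A [phyletic_matrix()].
#' @param phenotypes Data frame with columns `species`, `site`, `state`
#'   (`present`/`absent`/`not_determined`).
#' @param rlmh_exceptions Species with documented rlmH prediction/assay
#'   disagreement.
#' @return Data frame: `species`, `site`, `predicted`, `observed`,
#'   `verdict` (`consistent`, `inconsistent`, `documented_exception`).
#' @export
genotype_phenotype_check <- function(matrix, phenotypes,
                                     rlmh_exceptions = c("Mesoplasma_florum",
                                                         "Spiroplasma_citri",
                                                         "Mycoplasma_agalactiae")) {
  rules <- list(m5U54_tRNA = "trmFO",
                m5U1939_23S = c("rlmD", "rlmFO"),
                m3U1915_23S = "rlmH")
  rows <- NULL
  for (i in seq_len(nrow(phenotypes))) {
    site <- phenotypes$site[i]
    if (!site %in% names(rules)) next
    if (phenotypes$state[i] == "not_determined") next
    sp <- phenotypes$species[i]
    fams <- rules[[site]]
    predicted <- any(vapply(fams, function(f) {
      st <- pm_cell(matrix, sp, f)$status
      st %in% c("functional", "mixed")
    }, logical(1)))
    observed <- phenotypes$state[i] == "present"
    verdict <- if (predicted == observed) {
      "consistent"
    } else if (site == "m3U1915_23S" && predicted && !observed &&
               sp %in% rlmh_exceptions) {
      "documented_exception"
    } else {
      "inconsistent"
    }
    rows <- rbind(rows, data.frame(species = sp, site = site,
                                   predicted = predicted, observed = observed,
                                   verdict = verdict,
                                   stringsAsFactors = FALSE))
  }
  rows
}

#' Read an RNA-modification phenotype table
#' @param path TSV with columns `species`, `site`, `state`.
#' @return Data frame.
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  required <- c("species", "site", "state")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("format error: missing column(s) ",
                         paste(miss, collapse = ", "))
  ok <- df$state %in% c("present", "absent", "not_determined")
  if (!all(ok)) stop("format error: bad state token at row ",
                     which(!ok)[1L] + 1L)
  if (anyDuplicated(paste(df$species, df$site))) {
    stop("format error: duplicate (species, site) record")
  }
  df
}
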