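ref <- load_reference_dataset()

test_that("wagner reconstruction handles the textbook cases", {
  tr <- parse_newick("((A,B)x,(C,D)y)r;")
  all_on <- c(A = 1, B = 1, C = 1, D = 1)
  sc <- sankoff_reconstruct(tr, all_on, cost_model(mode = "wagner"))
  expect_equal(nrow(sc$events), 0L)
  expect_equal(sc$total_cost, 0)
  expect_true(sc$node_states[["r"]])

  sc2 <- sankoff_reconstruct(tr, c(A = 1, B = 1, C = 0, D = 0),
                             cost_model(gain_cost = 2, loss_cost = 1,
                                        mode = "wagner"))
  expect_equal(sc2$events$type, "loss")
  expect_equal(sc2$events$edge, "y")
  expect_equal(sc2$total_cost, 1)
  ## matches the exhaustive enumeration over all 8 internal labelings
  expect_equal(sc2$total_cost,
               exhaustive_parsimony_cost(tr, c(A = 1, B = 1, C = 0, D = 0)))

  expect_error(sankoff_reconstruct(tr, c(A = 1, B = 1, C = 0), cost_model()),
               "leaf missing|missing from states")
})

test_that("sankoff cost equals the exhaustive oracle on random instances", {
  ## small sample here; the full 1000-instance sweep runs in the
  ## acceptance suite
  for (i in 1:60) {
    n <- 4L + (i %% 5L)
    tr <- random_rooted_tree(n, seed = 1000 + i)
    pat <- random_pattern(tr, seed = 2000 + i)
    g <- 1 + (i %% 3); l <- 1 + ((i + 1) %% 2)
    sc <- sankoff_reconstruct(tr, pat, cost_model(gain_cost = g,
                                                  loss_cost = l,
                                                  mode = "wagner"))
    expect_equal(sc$total_cost, exhaustive_parsimony_cost(tr, pat, g, l),
                 info = paste("instance", i))
    ## replay invariant: events applied from the root state reproduce the
    ## leaf pattern exactly
    expect_identical(unname(replay_scenario(tr, sc)),
                     unname(as.logical(pat[tr$tip.label])))
  }
})

test_that("MPR enumeration finds all co-optimal scenarios", {
  tr <- parse_newick("(A,B)r;")
  mprs <- enumerate_mprs(tr, c(A = 1, B = 0),
                         cost_model(gain_cost = 1, loss_cost = 1,
                                    mode = "wagner"))
  expect_length(mprs, 2L)
  types <- sort(vapply(mprs, function(s) s$events$type[1L], ""))
  expect_identical(types, c("gain", "loss"))
  ## the canonical scenario is a member
  canon <- sankoff_reconstruct(tr, c(A = 1, B = 0),
                               cost_model(gain_cost = 1, loss_cost = 1,
                                          mode = "wagner"))
  costs <- vapply(mprs, `[[`, numeric(1), "total_cost")
  expect_true(all(costs == canon$total_cost))

  tr2 <- parse_newick("((A,B)x,(C,D)y)r;")
  one <- enumerate_mprs(tr2, c(A = 1, B = 1, C = 1, D = 1),
                        cost_model(mode = "wagner"))
  expect_length(one, 1L)
  expect_equal(nrow(one[[1L]]$events), 0L)

  expect_error(enumerate_mprs(tr2, c(A = 1, B = 0, C = 1, D = 0),
                              cost_model(gain_cost = 1, loss_cost = 1,
                                         mode = "wagner"),
                              max_scenarios = 1L),
               "max_scenarios")
})

test_that("dollo reconstruction reproduces the published trmFO scenario", {
  sc <- sankoff_reconstruct(ref$tree, family_leaf_states(ref$matrix, "trmFO"),
                            cost_model(mode = "dollo"), "trmFO")
  losses <- sc$events$edge[sc$events$type == "loss"]
  expect_true(all(c("2", "28", "33") %in% losses))
  expect_identical(sc$origin, "38")  ## present in the mollicute ancestor
  expect_identical(replay_scenario(ref$tree, sc),
                   family_leaf_states(ref$matrix, "trmFO"))
})

test_that("dollo reconstruction reproduces the published rlmD scenario", {
  sc <- sankoff_reconstruct(ref$tree, family_leaf_states(ref$matrix, "rlmD"),
                            cost_model(mode = "dollo"), "rlmD")
  losses <- sc$events$edge[sc$events$type == "loss"]
  expect_true(all(c("36", "12", "19") %in% losses))
  expect_true("Mycoplasma_pulmonis" %in% losses)
  expect_true(sc$node_states[["27"]])  ## kept in the Hominis ancestor
})

test_that("rlmFO originates at the Spiroplasma-group ancestor", {
  sc <- sankoff_reconstruct(ref$tree, family_leaf_states(ref$matrix, "rlmFO"),
                            cost_model(mode = "dollo"), "rlmFO")
  expect_identical(sc$origin, "36")
  expect_identical(replay_scenario(ref$tree, sc),
                   family_leaf_states(ref$matrix, "rlmFO"))
})

test_that("transfer-augmented dollo recovers the trmFO-like HGT", {
  states <- family_leaf_states(ref$matrix, "trmFO_like")
  cm <- cost_model(mode = "dollo_with_transfers")
  sc <- dollo_with_transfers(ref$tree, states, cm, "trmFO_like")
  expect_identical(sc$origin, "34")
  tr_ev <- sc$events[sc$events$type == "transfer", ]
  expect_equal(nrow(tr_ev), 1L)
  expect_identical(tr_ev$edge, "n51")  ## M. agalactiae / M. bovis ancestor
  expect_identical(tr_ev$donor, "34")
  expect_identical(replay_scenario(ref$tree, sc), states)

  ## prohibitive transfer cost: vertical-only scenario wins
  cm100 <- cost_model(transfer_cost = 100, mode = "dollo_with_transfers")
  sc2 <- dollo_with_transfers(ref$tree, states, cm100, "trmFO_like")
  expect_equal(sum(sc2$events$type == "transfer"), 0L)
  expect_identical(sc2$origin, "37")
  expect_identical(replay_scenario(ref$tree, sc2), states)
  ## brute-force check on the two candidate scenario costs
  dollo_sc <- sankoff_reconstruct(ref$tree, states,
                                  cost_model(mode = "dollo"), "trmFO_like")
  expect_equal(sc2$total_cost, dollo_sc$total_cost)
  expect_lt(sc$total_cost, dollo_sc$total_cost)
})

test_that("a clade-confined pattern needs no transfers", {
  states <- family_leaf_states(ref$matrix, "rlmFO")
  sc <- dollo_with_transfers(ref$tree, states,
                             cost_model(mode = "dollo_with_transfers"),
                             "rlmFO")
  expect_equal(sum(sc$events$type == "transfer"), 0L)
  dollo_sc <- sankoff_reconstruct(ref$tree, states,
                                  cost_model(mode = "dollo"), "rlmFO")
  expect_equal(sc$total_cost, dollo_sc$total_cost)
  expect_identical(sc$origin, dollo_sc$origin)
})

test_that("transfers never cost more than plain dollo", {
  for (i in 1:25) {
    pat <- random_pattern(ref$tree, seed = 4000 + i)
    if (!any(pat)) next
    d <- sankoff_reconstruct(ref$tree, pat, cost_model(mode = "dollo"))
    t <- dollo_with_transfers(ref$tree, pat,
                              cost_model(mode = "dollo_with_transfers"))
    expect_lte(t$total_cost, d$total_cost)
    expect_identical(replay_scenario(ref$tree, t), pat[ref$tree$tip.label])
  }
})

test_that("event typing recovers duplications, HGT and pseudogenizations", {
  fams <- c("trmFO", "rlmFO", "trmFO_like")
  scs <- lapply(setNames(fams, fams), function(f) {
    cm <- cost_model(mode = if (f == "trmFO_like") "dollo_with_transfers"
                            else "dollo")
    sankoff_reconstruct(ref$tree, family_leaf_states(ref$matrix, f), cm, f)
  })
  ev <- type_events(scs, matrix = ref$matrix)
  dup36 <- ev[ev$family == "rlmFO" & ev$type == "duplication", ]
  expect_identical(dup36$edge, "36")
  expect_identical(dup36$sister, "trmFO")   ## copied from trmFO at node 36
  dup34 <- ev[ev$family == "trmFO_like" & ev$type == "duplication", ]
  expect_identical(dup34$edge, "34")
  expect_identical(dup34$sister, "ambiguous")  ## trmFO or rlmFO template
  expect_true("transfer" %in% ev$type)
  ps <- ev[ev$type == "pseudogenization", ]
  expect_setequal(
    paste(ps$family, ps$edge),
    c("trmFO Spiroplasma_citri", "rlmFO Spiroplasma_citri",
      "rlmFO Mycoplasma_capricolum_subsp_capripneumoniae"))
  ## trmFO's single origin at the root stays a gain (no sister present)
  expect_identical(ev$type[ev$family == "trmFO" & ev$edge == "38"], "gain")
})

test_that("mutual exclusivity and counting queries work", {
  expect_equal(mutual_exclusivity(ref$matrix, "rlmD", "rlmFO")$overlap_count,
               0L)
  expect_equal(mutual_exclusivity(ref$matrix, "trmA", "rlmD")$overlap_count,
               0L)
  toy <- phyletic_matrix(data.frame(
    species = c("s1", "s1", "s2", "s2"),
    family = rep(c("a", "b"), 2),
    copy_count = c(1L, 1L, 1L, 0L),
    status = c("functional", "functional", "pseudogene", "absent")))
  expect_equal(mutual_exclusivity(toy, "a", "b")$overlap_count, 1L)
  expect_identical(mutual_exclusivity(toy, "a", "b")$species, "s1")
  ## pseudogenes count as present only when functional_only = FALSE
  expect_equal(mutual_exclusivity(toy, "a", "b",
                                  functional_only = FALSE)$overlap_count, 1L)
  expect_error(mutual_exclusivity(toy, "a", "zzz"), "unknown family")

  expect_equal(count_species(ref$matrix, c("trmFO", "rlmFO", "trmFO_like")),
               12L)
  expect_equal(count_species(ref$matrix, "thyA"), 16L)
  expect_equal(count_species(toy, "a", status = "functional"), 1L)
  expect_error(count_species(toy, "a", status = "odd"), "malformed")
})

test_that("genotype-phenotype report is consistent with exceptions", {
  gp <- genotype_phenotype_check(ref$matrix, ref$phenotypes)
  expect_false(any(gp$verdict == "inconsistent"))
  exc <- gp[gp$verdict == "documented_exception", ]
  expect_setequal(exc$species, c("Mesoplasma_florum", "Spiroplasma_citri",
                                 "Mycoplasma_agalactiae"))
  expect_true(all(exc$site == "m3U1915_23S"))
  ## M. capricolum subsp. capricolum: no trmFO, no m5U54 -> consistent
  mcc <- gp[gp$species == "Mycoplasma_capricolum_subsp_capricolum" &
              gp$site == "m5U54_tRNA", ]
  expect_identical(mcc$verdict, "consistent")
  expect_false(mcc$predicted)
  ## S. citri: rlmFO pseudogene, m5U1939 absent -> consistent
  sc <- gp[gp$species == "Spiroplasma_citri" & gp$site == "m5U1939_23S", ]
  expect_identical(sc$verdict, "consistent")
})
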