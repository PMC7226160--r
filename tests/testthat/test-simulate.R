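ref <- load_reference_dataset()

test_that("simulation is fully determined by its seed", {
  p <- simulation_params(loss_rate = 0.2, duplication_rate = 0.05,
                         transfer_rate = 0.05,
                         pseudogenization_rate = 0.05, seed = 99L)
  r1 <- simulate_gene_content(ref$tree, p)
  r2 <- simulate_gene_content(ref$tree, p)
  expect_identical(r1$true_events, r2$true_events)
  expect_identical(as.data.frame(r1$leaf_matrix),
                   as.data.frame(r2$leaf_matrix))
  r3 <- simulate_gene_content(ref$tree, simulation_params(loss_rate = 0.2,
                                                          seed = 100L))
  expect_false(identical(r1$true_events, r3$true_events) &&
                 identical(as.data.frame(r1$leaf_matrix),
                           as.data.frame(r3$leaf_matrix)))
})

test_that("all-zero rates copy the root state to every leaf", {
  r <- simulate_gene_content(ref$tree, simulation_params(
    loss_rate = 0, duplication_rate = 0, transfer_rate = 0,
    pseudogenization_rate = 0, seed = 1L))
  expect_equal(nrow(r$true_events), 0L)
  expect_true(all(r$leaf_matrix$status == "functional"))
  expect_true(all(r$leaf_matrix$copy_count == 1L))
  expect_error(simulation_params(loss_rate = -1), "nonnegative")
})

test_that("loss on a star tree matches the Poisson survival expectation", {
  n <- 10000L
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  mu <- 0.3
  r <- simulate_gene_content(star, simulation_params(loss_rate = mu,
                                                     seed = 7L))
  p_hat <- mean(r$leaf_matrix$status == "functional")
  p <- exp(-mu)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("without transfers every run has a single origin", {
  for (s in 1:10) {
    r <- simulate_gene_content(ref$tree, simulation_params(
      loss_rate = 0.3, duplication_rate = 0.1, seed = 500 + s))
    expect_false(any(r$true_events$type == "transfer"))
    ## single-origin (Dollo) property: the dollo scenario replays exactly
    states <- family_leaf_states(r$leaf_matrix, "sim")
    sc <- sankoff_reconstruct(ref$tree, states, cost_model(mode = "dollo"))
    expect_identical(replay_scenario(ref$tree, sc),
                     states[ref$tree$tip.label])
  }
})

test_that("clade origin and planted transfer shape the leaf pattern", {
  r <- simulate_gene_content(ref$tree, simulation_params(loss_rate = 0,
                                                         seed = 3L),
                             origin = "34", plant_transfer_to = "n51")
  states <- family_leaf_states(r$leaf_matrix, "sim")
  in34 <- c("Mycoplasma_auris", "Mycoplasma_yeatsii",
            "Mycoplasma_putrefaciens", "Mycoplasma_mycoides_subsp_mycoides",
            "Mycoplasma_mycoides_subsp_capri",
            "Mycoplasma_capricolum_subsp_capricolum",
            "Mycoplasma_capricolum_subsp_capripneumoniae")
  in51 <- c("Mycoplasma_agalactiae", "Mycoplasma_bovis")
  expect_setequal(names(states)[states], c(in34, in51))
  tr_ev <- r$true_events[r$true_events$type == "transfer", ]
  expect_identical(tr_ev$edge, "n51")
  expect_identical(tr_ev$donor, "34")
})

test_that("pseudogenized copies are inherited as pseudogenes", {
  r <- simulate_gene_content(ref$tree, simulation_params(
    loss_rate = 0, pseudogenization_rate = 0.5, seed = 11L))
  expect_true(any(r$true_events$type == "pseudogenization"))
  expect_true(any(r$leaf_matrix$status %in% c("pseudogene", "mixed")))
})

test_that("simulated proteins carry their planted diagnostics", {
  ann <- ref$annotation
  for (fam in c("TrmFO", "RlmFO", "TrmFO_like")) {
    p <- simulate_protein(fam, noise = 0, seed = 17)
    sig <- extract_signature(
      global_align(p$protein, ann$reference_sequence), ann)
    want <- if (fam == "TrmFO_like") "Y" else "C"
    expect_identical(sig$residue_at_51, want)
    expect_identical(sig$residue_at_223, want)
    expect_true(sig$fad_motif_found)
    expect_true(sig$folate_triad_found)
    expect_true(sig$flavin_stack_Y343)
  }
  ## TrmFO-like proteins are ~20 residues shorter
  expect_equal(nchar(simulate_protein("TrmFO", seed = 1)$protein) -
                 nchar(simulate_protein("TrmFO_like", seed = 1)$protein),
               20L)
  expect_error(simulate_protein("TrmFO", length = 300), "length too short")
  ## determinism
  expect_identical(simulate_protein("RlmFO", noise = 0.1, seed = 4),
                   simulate_protein("RlmFO", noise = 0.1, seed = 4))
  ## planted pseudogene CDS is detected
  broken <- simulate_protein("TrmFO", cds = TRUE, pseudogene = TRUE,
                             seed = 23)
  expect_true(detect_pseudogene(broken$cds, 445)$pseudogene)
})
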