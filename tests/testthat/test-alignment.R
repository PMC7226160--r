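ann <- load_reference_annotation()

test_that("identity alignment has no gaps and the expected score", {
  aln <- global_align("ACDEFG", "ACDEFG")
  expect_false(grepl("-", aln$aligned_query))
  expect_equal(aln$column_map, 1:6)
  expect_equal(aln$score,
               sum(diag(blosum62[c("A", "C", "D", "E", "F", "G"),
                                 c("A", "C", "D", "E", "F", "G")])))
})

test_that("alignment inputs are validated", {
  expect_error(global_align("", "ACD"), "empty")
  expect_error(global_align("ACD", ""), "empty")
  expect_error(global_align("AC1", "ACD"), "illegal character")
})

test_that("ungapping the aligned strings recovers the inputs", {
  aln <- global_align("MKVLWAALLG", "MKKKVLWALG")
  expect_identical(gsub("-", "", aln$aligned_query), aln$query)
  expect_identical(gsub("-", "", aln$aligned_reference), aln$reference)
  cm <- aln$column_map
  expect_true(all(diff(cm[!is.na(cm)]) > 0))  ## monotone over non-gaps
})

test_that("optimal score matches the exhaustive enumeration oracle", {
  ## short sequences over a reduced alphabet; oracle enumerates every
  ## global alignment recursively
  alphabet <- c("A", "C", "D", "E", "G")
  set.seed(11)
  for (i in 1:40) {
    a <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b)$score, brute_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("signature extraction reads the annotated positions", {
  self <- global_align(ann$reference_sequence, ann$reference_sequence)
  sig <- extract_signature(self, ann)
  expect_identical(sig$residue_at_51, "C")
  expect_identical(sig$residue_at_223, "C")
  expect_true(sig$fad_motif_found)
  expect_true(sig$folate_triad_found)
  expect_true(sig$flavin_stack_Y343)

  planted <- simulate_protein("TrmFO_like", noise = 0, seed = 3)
  sig2 <- extract_signature(
    global_align(planted$protein, ann$reference_sequence), ann)
  expect_identical(sig2$residue_at_51, "Y")
  expect_identical(sig2$residue_at_223, "Y")
  expect_true(sig2$fad_motif_found)
  expect_true(sig2$folate_triad_found)
})

test_that("a deletion spanning a catalytic position reads as deleted", {
  q <- ann$reference_sequence
  ## remove residues 45..60 (spans position 51)
  q <- paste0(substr(q, 1, 44), substr(q, 61, nchar(q)))
  sig <- extract_signature(global_align(q, ann$reference_sequence), ann)
  expect_identical(sig$residue_at_51, "deleted")
  expect_identical(sig$residue_at_223, "C")
})

test_that("signature is invariant to padding the query with flanks", {
  p <- simulate_protein("TrmFO", noise = 0, seed = 5)
  base <- extract_signature(
    global_align(p$protein, ann$reference_sequence), ann)
  padded <- paste0("WWWWWWWWWW", p$protein, "WWWWWWWWWW")
  sig <- extract_signature(
    global_align(padded, ann$reference_sequence), ann)
  expect_identical(sig[c("residue_at_51", "residue_at_223",
                         "folate_triad_found", "flavin_stack_Y343")],
                   base[c("residue_at_51", "residue_at_223",
                          "folate_triad_found", "flavin_stack_Y343")])
})

test_that("FAD motif scan finds exactly the degenerate pattern", {
  expect_equal(scan_fad_motif(paste0("KKKKKKKKK", "GAGTAGLEA", "KKK")), 10L)
  expect_length(scan_fad_motif(paste0("KKKKKKKKK", "GAGTTGLEA", "KKK")), 0L)
  expect_length(scan_fad_motif(strrep("K", 50)), 0L)
  ## [A/S] and [A/V] degeneracy
  expect_equal(scan_fad_motif("GAGKSGKEV"), 1L)
})

test_that("pseudogene detection applies the stop/truncation/frame rules", {
  intact <- simulate_protein("TrmFO", cds = TRUE, seed = 2)
  expect_false(detect_pseudogene(intact$cds, 445)$pseudogene)

  broken <- simulate_protein("TrmFO", cds = TRUE, pseudogene = TRUE, seed = 2)
  res <- detect_pseudogene(broken$cds, 445)
  expect_true(res$pseudogene)
  expect_identical(res$reason, "premature_stop")

  ## truncation: half-length CDS (the intact CDS has no internal stops)
  half <- substr(intact$cds, 1, 666)
  res2 <- detect_pseudogene(half, 445)
  expect_true(res2$pseudogene)
  expect_identical(res2$reason, "truncation")

  res3 <- detect_pseudogene("ATGAA", 100)
  expect_true(res3$pseudogene)
  expect_identical(res3$reason, "length_frame")

  expect_error(detect_pseudogene("AT", 100), "length >= 3")
  expect_error(detect_pseudogene("ATGNNN", 100), "illegal nucleotide")
})

test_that("subfamily decision rules fire in order", {
  yy <- structure(list(residue_at_51 = "Y", residue_at_223 = "Y",
                       fad_motif_found = TRUE, folate_triad_found = TRUE,
                       flavin_stack_Y343 = TRUE),
                  class = "residue_signature")
  cc <- yy; cc$residue_at_51 <- "C"; cc$residue_at_223 <- "C"
  cy <- yy; cy$residue_at_51 <- "C"

  expect_identical(classify_subfamily(yy, list(trmfo_context = 0.9,
                                               rlmfo_context = 0.9))$subfamily,
                   "TrmFO_like")
  expect_identical(classify_subfamily(cc, list(trmfo_context = 0.6,
                                               rlmfo_context = 0.1))$subfamily,
                   "TrmFO")
  expect_identical(classify_subfamily(cc, list(trmfo_context = 0.1,
                                               rlmfo_context = 0.6))$subfamily,
                   "RlmFO")
  expect_identical(classify_subfamily(cy)$subfamily, "ambiguous")
  expect_identical(classify_subfamily(cc)$subfamily, "ambiguous")
  expect_identical(classify_subfamily(cc, gene_tree_clade = "RlmFO")$subfamily,
                   "RlmFO")
  expect_error(classify_subfamily(cc, list(trmfo_context = 2,
                                           rlmfo_context = 0)),
               "\\[0, 1\\]")
})
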