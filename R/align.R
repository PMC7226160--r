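AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("input error: ", what, " must be a single string")
  }
  if (!nzchar(seq)) stop("input error: empty ", what)
  bad <- setdiff(strsplit(seq, "")[[1]], AA20)
  if (length(bad)) {
    stop("input error: illegal character(s) in ", what, ": ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(seq)
}

#' Optimal global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`), used to
#' map reference coordinates onto query sequences. The engine is
#' [Biostrings::pairwiseAlignment()]; tie-breaking among co-optimal
#' alignments is the engine's deterministic traceback.
#'
#' @param query,reference Protein sequences (single strings, 20-letter
#'   alphabet). Empty sequences or illegal characters raise an input error.
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param query_id,reference_id Optional identifiers stored on the result.
#' @return A `pairwise_alignment`: list with `query_id`, `reference_id`,
#'   `aligned_query`, `aligned_reference`, `score`, and `column_map`
#'   (integer vector mapping each reference position to the matched query
#'   position, `NA` where the reference position is deleted in the query).
#' @export
#' @examples
#' aln <- global_align("ACDEFG", "ACDEFG")
#' aln$score
#' aln$column_map
global_align <- function(query, reference, gap_open = 11, gap_extend = 1,
                         matrix = "BLOSUM62",
                         query_id = "query", reference_id = "reference") {
  check_protein(query, "query")
  check_protein(reference, "reference")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(reference),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aq <- as.character(Biostrings::alignedPattern(aln))
  ar <- as.character(Biostrings::alignedSubject(aln))
  qs <- strsplit(aq, "")[[1]]
  rs <- strsplit(ar, "")[[1]]
  cmap <- rep(NA_integer_, nchar(reference))
  qi <- 0L; ri <- 0L
  for (k in seq_along(qs)) {
    if (qs[k] != "-") qi <- qi + 1L
    if (rs[k] != "-") {
      ri <- ri + 1L
      if (qs[k] != "-") cmap[ri] <- qi
    }
  }
  structure(
    list(query_id = query_id, reference_id = reference_id,
         query = query, reference = reference,
         aligned_query = aq, aligned_reference = ar,
         score = Biostrings::score(aln), column_map = cmap),
    class = "pairwise_alignment"
  )
}

#' Scan for the FAD pyrophosphate-recognition motif
#'
#' Finds all non-overlapping matches of the degenerate 9-residue motif
#' `G A G x [A/S] G x E [A/V]` that recognizes the pyrophosphate group of
#' FAD in TrmFO-family methyltransferases.
#'
#' @param seq Protein sequence.
#' @return Integer vector of 1-based match start positions (empty when none).
#' @export
scan_fad_motif <- function(seq) {
  check_protein(seq)
  m <- gregexpr("GAG[A-Z][AS]G[A-Z]E[AV]", seq)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Extract the diagnostic residue signature of a TrmFO-related protein
#'
#' Reads the query residues aligned to the reference catalytic positions
#' (C51/C223 in *T. thermophilus* TrmFO numbering), the folate-binding triad
#' (H308, R/K309, N310), the flavin-stacking Y343, and scans the full query
#' for the FAD motif.
#'
#' @param alignment A `pairwise_alignment` whose reference is the annotated
#'   reference sequence.
#' @param annotation Reference annotation, as in
#'   [load_reference_dataset()]`$annotation`.
#' @return A `residue_signature`: list with `residue_at_51`,
#'   `residue_at_223` (single letters or `"deleted"`), `fad_motif_found`,
#'   `folate_triad_found`, `flavin_stack_Y343`.
#' @export
extract_signature <- function(alignment, annotation) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  if (!identical(alignment$reference, annotation$reference_sequence)) {
    stop("alignment reference does not match the annotated reference (",
         annotation$reference_id, ")")
  }
  q <- strsplit(alignment$query, "")[[1]]
  at <- function(ref_pos) {
    qp <- alignment$column_map[ref_pos]
    if (is.na(qp)) "deleted" else q[qp]
  }
  cat1 <- at(annotation$catalytic_positions[1L])
  cat2 <- at(annotation$catalytic_positions[2L])
  triad <- vapply(annotation$folate_triad_positions, at, character(1))
  triad_ok <- !any(triad == "deleted") &&
    triad[1L] == "H" && triad[2L] %in% c("R", "K") && triad[3L] == "N"
  structure(
    list(residue_at_51 = cat1,
         residue_at_223 = cat2,
         fad_motif_found = length(scan_fad_motif(alignment$query)) > 0L,
         folate_triad_found = triad_ok,
         flavin_stack_Y343 = identical(at(annotation$flavin_stack_position), "Y")),
    class = "residue_signature"
  )
}

#' Flag a coding sequence as a likely pseudogene
#'
#' Rules, applied in order: a CDS whose length is not a multiple of three is
#' frameshift-suspect (`length_frame`); an in-frame stop codon at or before
#' 80% of the reference protein length is a premature stop
#' (`premature_stop`); a CDS shorter than 60% of the reference coding length
#' is a truncation (`truncation`). Otherwise the CDS is called functional.
#'
#' @param cds Nucleotide sequence (A/C/G/T).
#' @param reference_protein_length Length (aa) of the intact reference.
#' @return List with `pseudogene` (logical) and `reason` (`NA` when intact).
#' @export
detect_pseudogene <- function(cds, reference_protein_length) {
  if (!is.character(cds) || length(cds) != 1L || nchar(cds) < 3L) {
    stop("input error: cds must be a single string of length >= 3")
  }
  cds <- toupper(cds)
  bad <- setdiff(strsplit(cds, "")[[1]], c("A", "C", "G", "T"))
  if (length(bad)) {
    stop("input error: illegal nucleotide(s): ",
         paste(unique(bad), collapse = ", "))
  }
  stopifnot(reference_protein_length >= 1)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    return(list(pseudogene = TRUE, reason = "length_frame"))
  }
  codons <- substring(cds, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(stops) && stops[1L] <= floor(0.8 * reference_protein_length)) {
    return(list(pseudogene = TRUE, reason = "premature_stop"))
  }
  if (n < 0.6 * (reference_protein_length * 3L)) {
    return(list(pseudogene = TRUE, reason = "truncation"))
  }
  list(pseudogene = FALSE, reason = NA_character_)
}

#' Assign a TrmFO-related protein to a subfamily
#'
#' Decision rules, in order: (1) tyrosines at both catalytic positions
#' identify TrmFO-like; (2) catalytic cysteines with a conserved RlmFO-type
#' gene neighbourhood (score at or above `threshold`, TrmFO context below
#' it) identify RlmFO; (3) catalytic cysteines with a conserved TrmFO-type
#' neighbourhood identify TrmFO; (4) otherwise an externally supplied gene
#' tree clade label is used; (5) otherwise the call is ambiguous.
#'
#' @param signature A `residue_signature` from [extract_signature()].
#' @param synteny_scores List with `trmfo_context` and `rlmfo_context` in
#'   `[0, 1]`, either possibly `NA`.
#' @param gene_tree_clade Optional clade label (`"TrmFO"`, `"RlmFO"` or
#'   `"TrmFO_like"`) used as a fallback when synteny is uninformative.
#' @param threshold Conserved-context decision threshold (default 0.3).
#' @param pseudogene Logical pseudogene flag carried onto the call.
#' @param protein_id Identifier carried onto the call.
#' @return A `subfamily_call`: list with `protein_id`, `subfamily`,
#'   `signature`, `pseudogene`, `evidence` (rule identifiers fired).
#' @export
classify_subfamily <- function(signature,
                               synteny_scores = list(trmfo_context = NA_real_,
                                                     rlmfo_context = NA_real_),
                               gene_tree_clade = NULL, threshold = 0.3,
                               pseudogene = FALSE, protein_id = "query") {
  stopifnot(inherits(signature, "residue_signature"))
  tc <- synteny_scores$trmfo_context
  rc <- synteny_scores$rlmfo_context
  if (is.null(tc)) tc <- NA_real_
  if (is.null(rc)) rc <- NA_real_
  for (s in c(tc, rc)) {
    if (!is.na(s) && (s < 0 || s > 1)) stop("synteny scores must be in [0, 1]")
  }
  cc <- identical(signature$residue_at_51, "C") &&
    identical(signature$residue_at_223, "C")
  yy <- identical(signature$residue_at_51, "Y") &&
    identical(signature$residue_at_223, "Y")
  subfamily <- "ambiguous"
  evidence <- character(0)
  if (yy) {
    subfamily <- "TrmFO_like"
    evidence <- "YY_catalytic_residues"
  } else if (cc && !is.na(rc) && rc >= threshold && (is.na(tc) || tc < threshold)) {
    subfamily <- "RlmFO"
    evidence <- c("CC_catalytic_residues", "rlmFO_context")
  } else if (cc && !is.na(tc) && tc >= threshold) {
    subfamily <- "TrmFO"
    evidence <- c("CC_catalytic_residues", "trmFO_context")
  } else if (cc && !is.null(gene_tree_clade) && !is.na(gene_tree_clade)) {
    if (!gene_tree_clade %in% c("TrmFO", "RlmFO", "TrmFO_like")) {
      stop("unknown gene_tree_clade: ", gene_tree_clade)
    }
    subfamily <- gene_tree_clade
    evidence <- c("CC_catalytic_residues", "gene_tree_clade")
  }
  structure(
    list(protein_id = protein_id, subfamily = subfamily,
         signature = signature, pseudogene = isTRUE(pseudogene),
         evidence = evidence),
    class = "subfamily_call"
  )
}

#' Classify every protein in a FASTA against the packaged reference
#'
#' Convenience driver: aligns each query to the reference, extracts its
#' residue signature, computes synteny context scores when neighbourhood
#' data is supplied, flags pseudogenes when a CDS is supplied, and applies
#' [classify_subfamily()].
#'
#' @param proteins Named character vector of protein sequences (names are
#'   protein ids), or a path to a protein FASTA.
#' @param reference,annotation Reference sequence and annotation; defaults
#'   to the packaged dataset.
#' @param neighborhoods Optional neighbourhood table (see
#'   [read_neighborhoods_tsv()]) whose anchors match protein ids.
#' @param profiles Optional context profiles (see [read_context_profiles()]).
#' @param cds Optional named character vector of CDS sequences by protein id.
#' @param threshold Synteny decision threshold.
#' @return Data frame with one row per protein: `protein_id`, `subfamily`,
#'   `res51`, `res223`, `fad_motif`, `folate_triad`, `pseudogene`,
#'   `evidence`.
#' @export
classify_proteins <- function(proteins, reference = NULL, annotation = NULL,
                              neighborhoods = NULL, profiles = NULL,
                              cds = NULL, threshold = 0.3) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins)) {
    proteins <- read_fasta(proteins)
  }
  if (is.null(annotation)) annotation <- load_reference_annotation()
  if (is.null(reference)) reference <- annotation$reference_sequence
  rows <- lapply(names(proteins), function(id) {
    aln <- global_align(proteins[[id]], reference, query_id = id,
                        reference_id = annotation$reference_id)
    sig <- extract_signature(aln, annotation)
    scores <- list(trmfo_context = NA_real_, rlmfo_context = NA_real_)
    if (!is.null(neighborhoods) && !is.null(profiles) &&
        id %in% neighborhoods$anchor) {
      nb <- neighborhood_for(neighborhoods, id)
      if (!is.null(profiles$trmFO)) {
        scores$trmfo_context <- context_score(nb, profiles$trmFO)
      }
      if (!is.null(profiles$rlmFO)) {
        scores$rlmfo_context <- context_score(nb, profiles$rlmFO)
      }
    }
    pseudo <- FALSE
    if (!is.null(cds) && id %in% names(cds)) {
      pseudo <- detect_pseudogene(cds[[id]], nchar(reference))$pseudogene
    }
    call <- classify_subfamily(sig, scores, threshold = threshold,
                               pseudogene = pseudo, protein_id = id)
    data.frame(protein_id = id, subfamily = call$subfamily,
               res51 = sig$residue_at_51, res223 = sig$residue_at_223,
               fad_motif = sig$fad_motif_found,
               folate_triad = sig$folate_triad_found,
               pseudogene = pseudo,
               evidence = paste(call$evidence, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read / write FASTA as a named character vector
#' @param path FASTA path.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
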