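ext_path <- function(file) {
  p <- system.file("extdata", file, package = "m5uevo")
  if (!nzchar(p)) stop("integrity error: packaged file missing: ", file)
  p
}

#' Load the packaged reference annotation and synthetic reference sequence
#'
#' Coordinates (catalytic C51/C223, folate triad H308/[R,K]309/N310, flavin
#' stack Y343, FAD motif) follow the published *T. thermophilus* TrmFO
#' numbering (PDB 3G5S); the sequence itself is a synthetic stand-in with
#' those features planted at the published positions (see the package
#' vignette).
#'
#' @return List with `reference_id`, `reference_sequence`,
#'   `catalytic_positions`, `folate_triad_positions`,
#'   `flavin_stack_position`, `fad_motif_pattern`.
#' @export
load_reference_annotation <- function() {
  ann <- jsonlite::read_json(ext_path("reference_annotation.json"),
                             simplifyVector = TRUE)
  seqs <- read_fasta(ext_path("reference_trmfo_synthetic.fasta"))
  if (!ann$reference_id %in% names(seqs)) {
    stop("integrity error: reference id ", ann$reference_id,
         " not found in packaged FASTA")
  }
  ann$reference_sequence <- unname(seqs[[ann$reference_id]])
  ann$catalytic_positions <- as.integer(ann$catalytic_positions)
  ann$folate_triad_positions <- as.integer(ann$folate_triad_positions)
  ann$flavin_stack_position <- as.integer(ann$flavin_stack_position)
  ann
}

#' Load the curated 39-species mollicute reference dataset
#'
#' Returns the packaged species tree (with the cited internal node labels
#' 2, 3, 12, 19, 27, 28, 33, 34, 36, 37, 38), the phyletic matrix of the
#' eleven m5U-related gene families, gene neighbourhoods, empirical
#' RNA-modification phenotypes, context profiles, species group tags and
#' the reference annotation. Text-anchored integrity constraints are
#' verified on load; a corrupted installation raises an integrity error.
#'
#' @return List with elements `tree`, `matrix`, `neighborhoods`,
#'   `phenotypes`, `profiles`, `groups`, `annotation`.
#' @export
#' @examples
#' ref <- load_reference_dataset()
#' length(ref$tree$tip.label)  # 39
load_reference_dataset <- function() {
  tree <- parse_newick(paste(readLines(ext_path("mollicutes_tree_curated.nwk")),
                             collapse = ""))
  matrix <- read_phyletic_tsv(ext_path("phyletic_matrix_curated.tsv"))
  neighborhoods <- read_neighborhoods_tsv(ext_path("neighborhoods_synthetic.tsv"))
  phenotypes <- read_phenotypes_tsv(ext_path("phenotypes_curated.tsv"))
  profiles <- read_context_profiles(ext_path("context_profiles_synthetic.json"))
  groups <- utils::read.delim(ext_path("species_groups_curated.tsv"),
                              sep = "\t", colClasses = c("character",
                                                         "character",
                                                         "logical"))
  annotation <- load_reference_annotation()

  fail <- function(...) stop("integrity error: ", ...)
  if (length(tree$tip.label) != 39L) fail("tree must have 39 leaves")
  cited <- c("2", "3", "12", "19", "27", "28", "33", "34", "36", "37", "38")
  if (!all(cited %in% tree$node.label)) {
    fail("cited internal node labels missing: ",
         paste(setdiff(cited, tree$node.label), collapse = ", "))
  }
  if (!setequal(tree$tip.label, pm_species(matrix))) {
    fail("tree leaf set and matrix species set differ")
  }
  if (!setequal(unique(matrix$family), M5U_FAMILIES)) {
    fail("unexpected family set in matrix")
  }
  for (fam in c("trmA", "rlmC", "rlmCD")) {
    if (count_species(matrix, fam) != 0L) fail(fam, " must be absent everywhere")
  }
  if (count_species(matrix, "tdk", negate = TRUE) != 1L ||
      pm_cell(matrix, "Mycoplasma_bovigenitalium_cl-51080", "tdk")$status !=
        "absent") {
    fail("exactly M. bovigenitalium cl-51080 must lack tdk")
  }
  if (pm_cell(matrix, "Acholeplasma_laidlawii", "rlmD")$copy_count != 4L) {
    fail("A. laidlawii must carry 4 rlmD homologs")
  }
  trmfo_carriers <- matrix$species[matrix$family == "trmFO" &
                                     matrix$status != "absent"]
  if (length(trmfo_carriers) != 5L) fail("trmFO subgroup must have 5 carriers")
  if (pm_cell(matrix, "Spiroplasma_citri", "trmFO")$status != "pseudogene") {
    fail("S. citri trmFO must be a pseudogene")
  }
  if (count_species(matrix, c("trmFO", "rlmFO", "trmFO_like")) != 12L) {
    fail("12 species must carry a TrmFO-related homolog")
  }
  list(tree = tree, matrix = matrix, neighborhoods = neighborhoods,
       phenotypes = phenotypes, profiles = profiles, groups = groups,
       annotation = annotation)
}
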