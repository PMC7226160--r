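#' Phyletic matrix of gene-family states across species
#'
#' A `phyletic_matrix` is a long-format data frame with one row per
#' (species, family) cell, recording the copy number and functional status
#' of that family in that genome. Status semantics: `absent` (no copy),
#' `functional` (>=1 intact copy, none degraded), `pseudogene` (copies
#' present but all degraded), `mixed` (>=2 copies, intact and degraded).
#'
#' @param df Data frame with columns `species`, `family`, `copy_count`,
#'   `status`, and optionally `member_ids` (semicolon-joined) and
#'   `provenance`.
#' @return An object of class `phyletic_matrix` (a validated data frame).
#' @export
phyletic_matrix <- function(df) {
  required <- c("species", "family", "copy_count", "status")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"member_ids" %in% names(df)) df$member_ids <- ""
  if (!"provenance" %in% names(df)) df$provenance <- "curated"
  df$species <- as.character(df$species)
  df$family <- as.character(df$family)
  df$copy_count <- as.integer(df$copy_count)
  df$status <- as.character(df$status)
  df$member_ids[is.na(df$member_ids)] <- ""
  bad <- !df$status %in% PM_STATUSES
  if (any(bad)) {
    stop("unknown status token '", df$status[which(bad)[1L]], "' in row ",
         which(bad)[1L])
  }
  key <- paste(df$species, df$family, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species, family) cell in row ",
         which(duplicated(key))[1L], ": ",
         sub("\r", " / ", key[duplicated(key)][1L]))
  }
  if (any(df$copy_count < 0L)) stop("negative copy_count")
  viol <- (df$copy_count == 0L) != (df$status == "absent")
  if (any(viol)) {
    stop("copy_count = 0 must coincide with status 'absent' (row ",
         which(viol)[1L], ")")
  }
  if (any(df$status == "mixed" & df$copy_count < 2L)) {
    stop("status 'mixed' requires copy_count >= 2")
  }
  structure(df, class = c("phyletic_matrix", class(df)))
}

PM_STATUSES <- c("absent", "functional", "pseudogene", "mixed")

#' Gene families tracked in the reference dataset
#' @export
M5U_FAMILIES <- c("thyA", "tdk", "trmA", "rlmC", "rlmD", "rlmCD", "yfjO",
                  "trmFO", "rlmFO", "trmFO_like", "rlmH")

#' Read / write a phyletic matrix as TSV
#'
#' The TSV dialect has a single header line and columns `species`, `family`,
#' `copy_count`, `status`, `member_ids` (semicolon-joined, may be empty) and
#' `provenance`. `write_phyletic_tsv()` followed by `read_phyletic_tsv()` is
#' the identity on valid matrices.
#'
#' @param path File path.
#' @return `read_phyletic_tsv()` returns a [phyletic_matrix()].
#' @export
read_phyletic_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  required <- c("species", "family", "copy_count", "status")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path)
  }
  bad <- !df$status %in% PM_STATUSES
  if (any(bad)) {
    stop("format error: unknown status token '", df$status[which(bad)[1L]],
         "' at row ", which(bad)[1L] + 1L, " of ", path)
  }
  df$copy_count <- suppressWarnings(as.integer(df$copy_count))
  if (anyNA(df$copy_count)) {
    stop("format error: non-integer copy_count at row ",
         which(is.na(df$copy_count))[1L] + 1L, " of ", path)
  }
  tryCatch(phyletic_matrix(df),
           error = function(e) stop("format error in ", path, ": ",
                                    conditionMessage(e)))
}

#' @rdname read_phyletic_tsv
#' @param matrix A [phyletic_matrix()].
#' @export
write_phyletic_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "phyletic_matrix"))
  cols <- c("species", "family", "copy_count", "status", "member_ids",
            "provenance")
  utils::write.table(as.data.frame(matrix)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up one (species, family) cell
#' @param matrix A [phyletic_matrix()].
#' @param species,family Cell coordinates.
#' @return List with `copy_count`, `status`, `member_ids`.
#' @export
pm_cell <- function(matrix, species, family) {
  i <- which(matrix$species == species & matrix$family == family)
  if (!length(i)) stop("no cell for (", species, ", ", family, ")")
  as.list(matrix[i[1L], c("copy_count", "status", "member_ids")])
}

pm_species <- function(matrix) unique(matrix$species)

## does a species have a functional copy of the family?
pm_functional <- function(matrix, family) {
  sub <- matrix[matrix$family == family, ]
  setNames(sub$status %in% c("functional", "mixed"), sub$species)
}

## historical presence (pseudogenes witness presence)
pm_present <- function(matrix, family) {
  sub <- matrix[matrix$family == family, ]
  setNames(sub$status != "absent", sub$species)
}

#' Binary leaf states of one family for parsimony analyses
#'
#' Pseudogenes are treated as *present*: a degraded copy still witnesses the
#' gene's historical presence on that lineage.
#'
#' @param matrix A [phyletic_matrix()].
#' @param family Family identifier.
#' @param functional_only If `TRUE`, count only functional copies.
#' @return Named logical vector over species.
#' @export
family_leaf_states <- function(matrix, family, functional_only = FALSE) {
  if (!family %in% matrix$family) stop("unknown family: ", family)
  if (functional_only) pm_functional(matrix, family) else pm_present(matrix, family)
}

#' Count species matching a family/status/copy-number predicate
#'
#' Counts species whose total copy number, summed over `families` and
#' restricted to cells whose status is in `status`, reaches `min_copies`.
#'
#' @param matrix A [phyletic_matrix()].
#' @param families Character vector of family identifiers (union semantics).
#' @param status Statuses that qualify (default: any non-absent copy).
#' @param min_copies Minimum total copy number (default 1).
#' @param negate If `TRUE`, count species *not* matching the predicate.
#' @return Integer count.
#' @export
#' @examples
#' # species carrying any TrmFO-related homolog in the reference dataset:
#' ref <- load_reference_dataset()
#' count_species(ref$matrix, c("trmFO", "rlmFO", "trmFO_like"))
count_species <- function(matrix, families,
                          status = c("functional", "pseudogene", "mixed"),
                          min_copies = 1L, negate = FALSE) {
  stopifnot(inherits(matrix, "phyletic_matrix"))
  bad <- setdiff(families, unique(matrix$family))
  if (length(bad)) stop("unknown family: ", paste(bad, collapse = ", "))
  if (!all(status %in% PM_STATUSES)) stop("malformed predicate: bad status")
  if (!is.numeric(min_copies) || min_copies < 0) {
    stop("malformed predicate: min_copies must be a nonnegative number")
  }
  sub <- matrix[matrix$family %in% families & matrix$status %in% status, ]
  tot <- tapply(sub$copy_count, sub$species, sum)
  hit <- names(tot)[tot >= min_copies]
  n <- if (negate) sum(!pm_species(matrix) %in% hit) else length(hit)
  as.integer(n)
}

#' Species carrying two families simultaneously
#'
#' Formalizes the paper-style mutual-exclusivity check: how many species
#' carry both `famA` and `famB` in a qualifying status.
#'
#' @param matrix A [phyletic_matrix()].
#' @param famA,famB Family identifiers.
#' @param functional_only If `TRUE` (default) only functional copies qualify;
#'   pseudogenes count as absent.
#' @return List with `overlap_count` and `species`.
#' @export
mutual_exclusivity <- function(matrix, famA, famB, functional_only = TRUE) {
  for (f in c(famA, famB)) {
    if (!f %in% matrix$family) stop("unknown family: ", f)
  }
  a <- family_leaf_states(matrix, famA, functional_only = functional_only)
  b <- family_leaf_states(matrix, famB, functional_only = functional_only)
  sp <- intersect(names(a)[a], names(b)[b])
  list(overlap_count = length(sp), species = sp)
}
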