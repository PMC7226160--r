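#' Gene neighbourhood tables
#'
#' A neighbourhood table records, for each anchor gene, the ortholog
#' families of its flanking genes: columns `anchor`, `offset` (signed gene
#' offset, nonzero), `ortholog_family`, `strand` (`+`/`-`).
#'
#' @param path TSV path.
#' @return Data frame of class `gene_neighborhoods`.
#' @export
read_neighborhoods_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  required <- c("anchor", "offset", "ortholog_family", "strand")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  df$offset <- suppressWarnings(as.integer(df$offset))
  if (anyNA(df$offset) || any(df$offset == 0L)) {
    stop("format error: offsets must be nonzero integers")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("format error: bad strand")
  key <- paste(df$anchor, df$offset)
  if (anyDuplicated(key)) {
    stop("format error: duplicate offset for anchor ",
         df$anchor[duplicated(key)][1L])
  }
  structure(df, class = c("gene_neighborhoods", class(df)))
}

#' @rdname read_neighborhoods_tsv
#' @param neighborhoods A `gene_neighborhoods` data frame.
#' @export
write_neighborhoods_tsv <- function(neighborhoods, path) {
  cols <- c("anchor", "offset", "ortholog_family", "strand")
  utils::write.table(as.data.frame(neighborhoods)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one anchor's neighbourhood
#' @param neighborhoods A `gene_neighborhoods` table.
#' @param anchor Anchor gene identifier.
#' @return A `gene_neighborhood` (subset data frame for one anchor).
#' @export
neighborhood_for <- function(neighborhoods, anchor) {
  sub <- neighborhoods[neighborhoods$anchor == anchor, , drop = FALSE]
  if (!nrow(sub)) stop("no neighbourhood for anchor ", anchor)
  structure(sub, class = c("gene_neighborhood", "data.frame"))
}

nb_family_set <- function(nb, k) {
  if (is.data.frame(nb)) {
    unique(nb$ortholog_family[abs(nb$offset) <= k])
  } else {
    unique(as.character(nb))  ## plain family set
  }
}

#' Jaccard similarity of two gene neighbourhoods
#'
#' Neighbourhoods are reduced to the *set* of flanking ortholog families
#' within `k` genes of the anchor; gene order and strand are deliberately
#' ignored (the comparison mirrors region gene-content conservation, not
#' exact order conservation). Two empty sets score 0.
#'
#' @param a,b `gene_neighborhood` data frames (or plain character vectors of
#'   family identifiers).
#' @param k Window half-width in genes (default 5); must be >= 1.
#' @return Jaccard index in `[0, 1]`.
#' @export
neighborhood_jaccard <- function(a, b, k = 5L) {
  if (!is.numeric(k) || k < 1) stop("parameter error: k must be >= 1")
  sa <- nb_family_set(a, k)
  sb <- nb_family_set(b, k)
  u <- union(sa, sb)
  if (!length(u)) return(0)
  length(intersect(sa, sb)) / length(u)
}

#' Conserved-context score of a query neighbourhood against a profile
#'
#' The score is the maximum [neighborhood_jaccard()] between the query and
#' each reference neighbour set of the profile.
#'
#' @param query A `gene_neighborhood` (or character vector of families).
#' @param profile A `context_profile`: list with `family_id`, `window`, and
#'   `sets` (list of character vectors of ortholog families).
#' @return Score in `[0, 1]`.
#' @export
context_score <- function(query, profile) {
  if (is.null(profile$sets) || !length(profile$sets)) {
    stop("empty profile")
  }
  k <- if (!is.null(profile$window)) profile$window else 5L
  max(vapply(profile$sets, function(s) neighborhood_jaccard(query, s, k),
             numeric(1)))
}

#' Read context profiles from JSON
#'
#' Profiles are serialized as a JSON object keyed by family id, each entry
#' holding `window` and `sets` (the reference neighbour sets, one per
#' reference genome, excluding the anchor family itself).
#'
#' @param path JSON path.
#' @return Named list of `context_profile` objects.
#' @export
read_context_profiles <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(names(raw), function(fam) {
    entry <- raw[[fam]]
    sets <- lapply(entry$sets, function(s) unlist(s, use.names = FALSE))
    structure(list(family_id = fam,
                   window = as.integer(entry$window),
                   sets = sets),
              class = "context_profile")
  })
  setNames(out, names(raw))
}

#' Build a context profile from a neighbourhood table
#'
#' @param neighborhoods A `gene_neighborhoods` table.
#' @param anchors Anchor ids whose neighbourhoods form the reference sets.
#' @param family_id Family the profile describes.
#' @param window Window half-width in genes.
#' @return A `context_profile`.
#' @export
build_context_profile <- function(neighborhoods, anchors, family_id,
                                  window = 5L) {
  if (window < 1) stop("parameter error: window must be >= 1")
  sets <- lapply(anchors, function(a) {
    nb_family_set(neighborhood_for(neighborhoods, a), window)
  })
  structure(list(family_id = family_id, window = as.integer(window),
                 sets = sets),
            class = "context_profile")
}
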