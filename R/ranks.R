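#' Standard taxonomic ranks
#'
#' The seven standard Linnaean ranks used throughout the package, ordered
#' from most inclusive (kingdom) to least inclusive (species). Reference
#' databases built by barcoderef display only these ranks.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' standard_ranks()
standard_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

# internal shorthand
.RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

#' Create an empty lineage
#'
#' A lineage is a named character vector with one slot per standard rank;
#' unfilled slots are `NA`.
#'
#' @param ... named rank values, e.g. `kingdom = "Animalia"`.
#' @return Named character vector over the 7 standard ranks.
#' @export
#' @examples
#' lineage(kingdom = "Animalia", genus = "Apis", species = "Apis mellifera")
lineage <- function(...) {
  out <- stats::setNames(rep(NA_character_, 7L), .RANKS)
  vals <- c(...)
  if (length(vals)) {
    bad <- setdiff(names(vals), .RANKS)
    if (length(bad)) stop("unknown rank(s): ", paste(bad, collapse = ", "))
    vals[!nzchar(vals)] <- NA_character_
    out[names(vals)] <- unname(vals)
  }
  out
}

#' Taxonomic resolution of a lineage
#'
#' The lowest (finest) non-empty standard rank, or `NA` for an empty lineage.
#'
#' @param lin lineage vector as returned by [lineage()].
#' @return Rank name or `NA`.
#' @export
lineage_resolution <- function(lin) {
  filled <- which(!is.na(lin[.RANKS]) & nzchar(lin[.RANKS]))
  if (!length(filled)) return(NA_character_)
  .RANKS[max(filled)]
}

# rank -> integer depth (kingdom = 1 ... species = 7); NA -> 0
.rank_depth <- function(rank) {
  d <- match(rank, .RANKS)
  d[is.na(d)] <- 0L
  d
}

#' Lowest common ancestor of two lineages
#'
#' Walks the ranks kingdom to species and keeps slots while both lineages
#' agree; the first disagreement (including one side empty) truncates the
#' result there and below.
#'
#' @param a,b lineage vectors as returned by [lineage()].
#' @return A lineage vector.
#' @export
#' @examples
#' a <- lineage(kingdom = "Animalia", genus = "Apis", species = "Apis mellifera")
#' b <- lineage(kingdom = "Animalia", genus = "Apis", species = "Apis cerana")
#' lineage_lca(a, b)
lineage_lca <- function(a, b) {
  a <- lineage_as_vector(a); b <- lineage_as_vector(b)
  out <- stats::setNames(rep(NA_character_, 7L), .RANKS)
  for (i in seq_along(.RANKS)) {
    va <- a[[i]]; vb <- b[[i]]
    if (is.na(va) || is.na(vb) || !nzchar(va) || !nzchar(vb) || va != vb) break
    out[[i]] <- va
  }
  out
}

# coerce one row of rank columns (list, 1-row df, or named vector) to lineage
lineage_as_vector <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- unlist(lapply(x[intersect(.RANKS, names(x))], as.character))
  }
  out <- stats::setNames(rep(NA_character_, 7L), .RANKS)
  keep <- intersect(.RANKS, names(x))
  vals <- as.character(x[keep])
  vals[!nzchar(vals) | is.na(vals)] <- NA_character_
  out[keep] <- vals
  out
}

# lineage list-column helpers: turn a list of lineage vectors into 7 columns
lineage_cols <- function(lins) {
  m <- do.call(rbind, lapply(lins, lineage_as_vector))
  tibble::as_tibble(as.data.frame(m, stringsAsFactors = FALSE))
}
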