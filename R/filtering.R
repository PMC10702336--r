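# Record filters: sequence quality, taxonomic resolution, amino-acid
# translation plausibility, and geographic scope.

#' Filter configuration
#'
#' @param max_N maximum number of ambiguous `N` bases (only `N` is counted;
#'   other ambiguity codes are bounded separately via `max_ambiguous`).
#' @param min_length,max_length sequence length bounds in base pairs. The
#'   defaults bracket the ~658 bp CO1 Folmer barcode.
#' @param min_rank coarsest acceptable identification; records resolved
#'   above (coarser than) this rank are dropped. `NULL` disables the rule.
#' @param max_ambiguous optional bound on the total count of non-ACGT
#'   IUPAC ambiguity codes; `Inf` disables it.
#' @param translation_check `"off"`, `"warn"` or `"drop"`: what to do with
#'   sequences that contain stop codons in all three forward frames.
#' @param genetic_code_table NCBI genetic code id; default 5, the
#'   invertebrate mitochondrial code, appropriate for animal CO1.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_N = 0L, min_length = 400L, max_length = 2000L,
                          min_rank = NULL, max_ambiguous = Inf,
                          translation_check = c("warn", "off", "drop"),
                          genetic_code_table = 5L) {
  stopifnot(min_length <= max_length, max_N >= 0)
  structure(
    list(
      max_N = max_N, min_length = min_length, max_length = max_length,
      min_rank = min_rank, max_ambiguous = max_ambiguous,
      translation_check = match.arg(translation_check),
      genetic_code_table = genetic_code_table
    ),
    class = "filter_config"
  )
}

#' Sequence-quality and resolution filter
#'
#' Pure predicate over each record: drops it if the `N` count exceeds
#' `max_N`, the length falls outside `[min_length, max_length]`, the total
#' ambiguity-code count exceeds `max_ambiguous`, or the taxonomic
#' resolution is coarser than `min_rank`. The first failing rule names the
#' drop reason.
#'
#' @param records harmonized table (needs `sequence` and `resolution`).
#' @param config a [filter_config()].
#' @return Input with logical `keep` and character `reason` columns added.
#' @export
quality_filter <- function(records, config = filter_config()) {
  seqs <- records$sequence
  n_count <- stringr::str_count(seqs, "N")
  len <- nchar(seqs)
  amb <- stringr::str_count(seqs, "[RYSWKMBDHVN]")
  depth <- .rank_depth(records$resolution)
  keep <- rep(TRUE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  fail <- function(bad, why) {
    hit <- bad & keep
    reason[hit] <<- why
    keep[hit] <<- FALSE
  }
  fail(n_count > config$max_N, "max_N")
  fail(len < config$min_length | len > config$max_length, "length")
  fail(amb > config$max_ambiguous, "ambiguity")
  if (!is.null(config$min_rank)) {
    fail(depth < .rank_depth(config$min_rank), "rank")
  }
  records$keep <- keep
  records$reason <- reason
  records
}

# translate one frame of a sequence; ambiguous codons become X, never stops
.translate_frames <- function(seq, genetic_code) {
  vapply(0:2, function(off) {
    s <- substr(seq, off + 1L, nchar(seq))
    s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)   # ignore trailing partial codon
    if (!nzchar(s)) return("")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- genetic_code[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, "")
}

#' Amino-acid translation filter
#'
#' Translates each sequence in the three forward reading frames under the
#' configured mitochondrial genetic code and keeps records with at least
#' one stop-free frame (trailing partial codons are ignored; ambiguous
#' codons translate to X, never to a stop). Frameshifted or pseudogene-like
#' sequences (NUMTs) fail in all frames. Reverse-complement frames are not
#' checked: barcodes are deposited in coding orientation.
#'
#' @param records harmonized table.
#' @param config a [filter_config()]; `translation_check` selects off /
#'   warn / drop behaviour.
#' @return Input with `keep`/`reason` updated (`translation_ok` column
#'   always added unless the check is off).
#' @export
translation_filter <- function(records, config = filter_config()) {
  if (config$translation_check == "off" || !nrow(records)) {
    return(dplyr::mutate(records,
                         keep = if ("keep" %in% names(records)) .data$keep else TRUE))
  }
  code <- Biostrings::getGeneticCode(as.character(config$genetic_code_table))
  ok <- vapply(records$sequence, function(s) {
    any(!grepl("\\*", .translate_frames(s, code)))
  }, logical(1), USE.NAMES = FALSE)
  out <- dplyr::mutate(records, translation_ok = ok)
  if (!("keep" %in% names(out))) {
    out$keep <- TRUE
    out$reason <- NA_character_
  }
  if (config$translation_check == "drop") {
    hit <- !ok & out$keep
    out$reason[hit] <- "translation"
    out$keep[hit] <- FALSE
  } else if (any(!ok)) {
    warning(sum(!ok), " record(s) have stop codons in all forward frames")
  }
  out
}

#' Region specification
#'
#' @param kind one of `"country"`, `"continent"`, `"biogeographic_realm"`,
#'   `"custom_polygon"`.
#' @param names region labels to retain (country/continent/realm names, or
#'   polygon names for custom polygons).
#' @param polygons named list of (lon, lat) rings (see
#'   [read_polygons_geojson()]); required for `custom_polygon`.
#' @return A `region_spec` list.
#' @export
region_spec <- function(kind = c("country", "continent",
                                 "biogeographic_realm", "custom_polygon"),
                        names = character(), polygons = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom_polygon") {
    if (is.null(polygons) || !length(polygons)) {
      stop("custom_polygon region needs at least one polygon")
    }
    if (!length(names)) names <- base::names(polygons)
  } else if (!length(names)) {
    stop("region spec needs at least one region name")
  }
  structure(list(kind = kind, names = names, polygons = polygons),
            class = "region_spec")
}

#' Assign region labels to records
#'
#' Country text yields the country plus its continent and biogeographic
#' realm from the gazetteer; coordinates (WGS84 lon/lat) yield the names of
#' every polygon containing the point (boundary-inclusive). Text and point
#' labels are unioned. Unknown country names produce no labels and a
#' warning.
#'
#' @param records harmonized table (uses `country`, `latitude`, `longitude`).
#' @param gazetteer tibble `country`, `continent`, `realm`.
#' @param polygons optional named list of rings.
#' @return List-column-compatible list of character label sets, one per
#'   record.
#' @export
assign_region <- function(records, gazetteer = default_gazetteer(),
                          polygons = NULL) {
  unknown <- character()
  labels <- lapply(seq_len(nrow(records)), function(i) {
    out <- character()
    ctry <- records$country[[i]]
    if (!is.na(ctry) && nzchar(ctry)) {
      row <- gazetteer[tolower(gazetteer$country) == tolower(ctry), , drop = FALSE]
      if (nrow(row)) {
        out <- c(out, row$country[[1]], row$continent[[1]], row$realm[[1]])
      } else {
        unknown <<- c(unknown, ctry)
      }
    }
    lat <- records$latitude[[i]]; lon <- records$longitude[[i]]
    if (!is.na(lat) && !is.na(lon) && length(polygons)) {
      inside <- vapply(polygons, function(rg) point_in_ring(lon, lat, rg),
                       logical(1))
      out <- c(out, names(polygons)[inside])
    }
    unique(out)
  })
  if (length(unknown)) {
    warning("country name(s) not in gazetteer: ",
            paste(unique(unknown), collapse = ", "))
  }
  labels
}

#' Geographic region filter
#'
#' Keeps records whose assigned region labels intersect the specification.
#' Records without any location information (no country, no coordinates)
#' are dropped while a region filter is active, since their provenance
#' cannot be established.
#'
#' @param records harmonized table.
#' @param spec a [region_spec()].
#' @param gazetteer tibble `country`, `continent`, `realm`.
#' @return Input with logical `keep_region` column added.
#' @export
region_filter <- function(records, spec, gazetteer = default_gazetteer()) {
  stopifnot(inherits(spec, "region_spec"))
  labels <- assign_region(records, gazetteer, polygons = spec$polygons)
  records$keep_region <- vapply(labels, function(l)
    any(tolower(l) %in% tolower(spec$names)), logical(1))
  records
}
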