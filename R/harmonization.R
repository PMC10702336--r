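# Taxonomic harmonization: map cleaned record names onto a backbone
# taxonomy, or merge sources unmapped (pass-through).

.harmonized_cols <- function() {
  c("record_id", "source_db", "original_name", "cleaned_name",
    "matched_name", "matched_taxon_id", "action", "resolution",
    .RANKS, "sequence", "country", "latitude", "longitude", "marker")
}

#' Harmonize records against a backbone taxonomy
#'
#' For each record the cleaned lowest-rank name is looked up in the backbone
#' (using the record's own higher lineage as homonym context). An accepted
#' match keeps the name (`action = "exact"`); a synonym match replaces the
#' name with its accepted partner (`action = "synonym_replaced"`) unless
#' `allow_synonyms`, in which case the synonym is displayed at its own rank
#' while the higher ranks still come from the accepted node's ancestry. When
#' neither is found, the record's raw lineage is walked upward and the first
#' higher taxon found in the backbone becomes the determination
#' (`action = "rank_fallback"`, strictly coarser resolution). Records whose
#' names match nowhere are retained with an empty lineage
#' (`action = "unmatched"`); the minimal-rank filter can drop them later.
#'
#' @param records record table (see [read_bold_tsv()] and friends).
#' @param backbone a `taxonomy_store` from [import_backbone()].
#' @param allow_synonyms keep synonym names instead of replacing them.
#' @param tokens open-nomenclature token list for name cleaning.
#' @return Harmonized table: one row per input record with the 7 standard
#'   rank columns, `action`, `resolution`, `matched_name`,
#'   `matched_taxon_id`, plus the record's sequence and location fields.
#' @export
harmonize_records <- function(records, backbone,
                              allow_synonyms = FALSE,
                              tokens = open_nomenclature_tokens()) {
  stopifnot(inherits(backbone, "taxonomy_store"))
  cleaned <- clean_name(records$raw_name, tokens = tokens)$cleaned
  rows <- lapply(seq_len(nrow(records)), function(i) {
    .harmonize_one(records[i, , drop = FALSE], cleaned[[i]], backbone,
                   allow_synonyms)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- .empty_harmonized()
  out
}

.empty_harmonized <- function() {
  cols <- .harmonized_cols()
  out <- tibble::as_tibble(stats::setNames(
    lapply(cols, function(c) if (c %in% c("latitude", "longitude")) double() else character()),
    cols
  ))
  out
}

.harmonize_one <- function(rec, cleaned, backbone, allow_synonyms) {
  lin_raw <- rec$raw_lineage[[1]]
  higher <- rev(unname(lin_raw[nzchar(lin_raw)]))       # lowest -> highest
  higher <- higher[!duplicated(higher)]
  context <- {
    filled <- lin_raw[nzchar(lin_raw)]
    if (length(filled)) unname(filled[[1]]) else NULL   # most inclusive name
  }

  # candidate names: cleaned lowest identification first, then raw lineage
  # bottom-up (skipping the raw name itself)
  raw <- rec$raw_name[[1]]
  cands <- c(
    if (!is.na(cleaned) && nzchar(cleaned)) cleaned,
    setdiff(higher, c(raw, cleaned))
  )

  base <- tibble::tibble(
    record_id = rec$record_id, source_db = rec$source_db,
    original_name = raw, cleaned_name = cleaned,
    matched_name = NA_character_, matched_taxon_id = NA_character_,
    action = "unmatched", resolution = NA_character_,
    sequence = rec$sequence, country = rec$country,
    latitude = rec$latitude, longitude = rec$longitude, marker = rec$marker
  )
  lin <- lineage()

  for (k in seq_along(cands)) {
    hit <- tax_lookup(backbone, cands[[k]], context = context)
    if (!nrow(hit) || hit$ambiguous[[1]]) next   # unresolved homonym: go up
    node <- hit[1, , drop = FALSE]
    acc <- accepted_of(backbone, node)
    lin <- lineage_of(backbone, acc)
    is_fallback <- k > 1L
    if (is_fallback) {
      base$action <- "rank_fallback"
      base$matched_name <- acc$canonical_name[[1]]
    } else if (node$status[[1]] == "synonym") {
      if (allow_synonyms) {
        # display the synonym at its own rank, accepted ancestry above it
        if (node$rank[[1]] %in% .RANKS) lin[[node$rank[[1]]]] <- node$canonical_name[[1]]
        base$action <- "exact"
        base$matched_name <- node$canonical_name[[1]]
      } else {
        base$action <- "synonym_replaced"
        base$matched_name <- acc$canonical_name[[1]]
      }
    } else {
      base$action <- "exact"
      base$matched_name <- acc$canonical_name[[1]]
    }
    base$matched_taxon_id <- acc$taxon_id[[1]]
    break
  }
  base$resolution <- lineage_resolution(lin)
  dplyr::bind_cols(base[, 1:8], tibble::as_tibble(as.list(lin)),
                   base[, 9:13])
}

#' Merge records without backbone mapping
#'
#' Pass-through mode: each record's raw lineage is projected verbatim onto
#' the 7 standard rank slots (only pairs labelled with a standard rank are
#' projected). Source-specific kingdom labels are left as they are, so
#' Animalia (GBOL), Metazoa (GenBank) and an empty kingdom (BOLD) coexist
#' in the output. When the genus/species slots are unlabelled in the source
#' (GenBank), they are filled from the record's own lowest identification.
#'
#' @param records record table.
#' @return Harmonized table with `action = "passthrough"` for every row.
#' @export
unmapped_merge <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    lin <- lineage_as_vector(rec$raw_lineage[[1]])
    raw <- rec$raw_name[[1]]
    if (!is.na(raw) && nzchar(raw)) {
      toks <- strsplit(trimws(raw), "\\s+")[[1]]
      if (length(toks) >= 2) {
        if (is.na(lin[["species"]])) lin[["species"]] <- raw
        if (is.na(lin[["genus"]])) lin[["genus"]] <- toks[[1]]
      }
    }
    tibble::tibble(
      record_id = rec$record_id, source_db = rec$source_db,
      original_name = raw, cleaned_name = raw,
      matched_name = NA_character_, matched_taxon_id = NA_character_,
      action = "passthrough", resolution = lineage_resolution(lin),
      !!!as.list(lin),
      sequence = rec$sequence, country = rec$country,
      latitude = rec$latitude, longitude = rec$longitude, marker = rec$marker
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) out <- .empty_harmonized()
  out
}

#' Build the name-comparison table
#'
#' Aggregates harmonization actions into one row per distinct
#' (provided name, accepted name, action) with its record count, sorted by
#' accepted name. The table shows which provided names were synonyms of
#' which accepted names under the chosen backbone, approximating a
#' reconciliation group for each taxon.
#'
#' @param harmonized harmonized table from [harmonize_records()].
#' @return Tibble with columns `accepted_name`, `provided_name`, `action`,
#'   `n_records`.
#' @export
build_comparison <- function(harmonized) {
  harmonized |>
    dplyr::count(
      accepted_name = .data$matched_name,
      provided_name = .data$original_name,
      action = .data$action,
      name = "n_records"
    ) |>
    dplyr::arrange(.data$accepted_name, .data$provided_name) |>
    dplyr::select("accepted_name", "provided_name", "action", "n_records")
}
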