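# Source-record ingestion: three snapshot dialects -> one tidy record table.
#
# A record table has one row per specimen record:
#   source_db, record_id, raw_name, raw_lineage (list-column of named
#   character vectors, names = rank labels, "" where the source gives none),
#   sequence, country, latitude, longitude, marker.

.IUPAC <- c("A","C","G","T","R","Y","S","W","K","M","B","D","H","V","N")

.clean_seq <- function(x) {
  x <- toupper(gsub("[-. ]", "", x))
  x
}

.empty_records <- function() {
  tibble::tibble(
    source_db = character(), record_id = character(),
    raw_name = character(), raw_lineage = list(),
    sequence = character(), country = character(),
    latitude = double(), longitude = double(), marker = character()
  )
}

# default CO1 gene/product synonyms for GenBank feature qualifiers
co1_synonyms <- function() {
  c("cox1", "coi", "co1", "coxi", "cytochrome c oxidase subunit i",
    "cytochrome c oxidase subunit 1", "cytochrome oxidase subunit i",
    "cytochrome oxidase subunit 1")
}

#' Read a GenBank flat file
#'
#' Parses a GBFF snapshot (optionally gzipped) into a record table, keeping
#' only entries annotated with a CO1 coding region or CO1 barcode.
#' Gene/product qualifiers are matched case-insensitively against the usual
#' CO1 synonyms (COX1, COI, CO1, "cytochrome c oxidase subunit I", ...).
#' The ORGANISM classification is parsed into `raw_lineage` (first element
#' labelled kingdom, deeper clades unlabelled, since GenBank prints no rank
#' labels); a `country` qualifier of the form "Germany: Bonn" is split at the
#' first colon and only the country part kept; `lat_lon` qualifiers are
#' converted to signed decimal degrees (WGS84).
#'
#' @param path GBFF file, plain or gzipped.
#' @param marker_synonyms lowercase qualifier values recognized as CO1.
#' @return Record table; attribute `n_skipped` counts entries without a CO1
#'   annotation, `n_truncated` counts malformed entries dropped.
#' @export
read_genbank_flatfile <- function(path, marker_synonyms = co1_synonyms()) {
  if (!file.exists(path)) stop("cannot read GenBank flat file: ", path)
  lines <- readr::read_lines(path, progress = FALSE)
  if (!length(lines)) {
    out <- .empty_records()
    attr(out, "n_skipped") <- 0L; attr(out, "n_truncated") <- 0L
    return(out)
  }
  starts <- grep("^LOCUS", lines)
  ends <- grep("^//\\s*$", lines)
  n_truncated <- 0L
  rows <- list()
  n_skipped <- 0L
  for (s in starts) {
    e <- ends[ends > s][1]
    if (is.na(e)) { n_truncated <- n_truncated + 1L; next }
    entry <- lines[s:e]
    rec <- tryCatch(.parse_gb_entry(entry, marker_synonyms),
                    error = function(err) {
                      warning("skipping truncated GenBank entry: ",
                              conditionMessage(err))
                      NULL
                    })
    if (is.null(rec)) { n_truncated <- n_truncated + 1L; next }
    if (isFALSE(rec$is_co1)) { n_skipped <- n_skipped + 1L; next }
    rows[[length(rows) + 1L]] <- rec$row
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else .empty_records()
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_truncated") <- n_truncated
  out
}

.parse_gb_entry <- function(entry, marker_synonyms) {
  acc_line <- grep("^ACCESSION", entry, value = TRUE)
  id <- if (length(acc_line)) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "\\s+")[[1]][1]
  } else {
    strsplit(trimws(sub("^LOCUS", "", entry[1])), "\\s+")[[1]][1]
  }
  if (is.na(id) || !nzchar(id)) stop("entry without identifier")

  org_i <- grep("^  ORGANISM", entry)
  raw_name <- NA_character_
  lin <- stats::setNames(character(), character())
  if (length(org_i)) {
    raw_name <- trimws(sub("^  ORGANISM", "", entry[org_i[1]]))
    j <- org_i[1] + 1L
    lin_txt <- character()
    while (j <= length(entry) && grepl("^ {6,}", entry[j])) {
      lin_txt <- c(lin_txt, trimws(entry[j]))
      if (grepl("\\.$", entry[j])) break
      j <- j + 1L
    }
    if (length(lin_txt)) {
      names_vec <- strsplit(sub("\\.$", "", paste(lin_txt, collapse = " ")),
                            ";\\s*")[[1]]
      names_vec <- trimws(names_vec)
      names_vec <- names_vec[nzchar(names_vec)]
      if (length(names_vec)) {
        labels <- c("kingdom", rep("", max(0L, length(names_vec) - 1L)))
        lin <- stats::setNames(names_vec, labels)
      }
    }
  }

  quals <- .gb_qualifiers(entry)
  is_co1 <- any(tolower(c(quals$gene, quals$product)) %in% marker_synonyms)

  country <- NA_character_
  if (length(quals$country)) {
    country <- trimws(strsplit(quals$country[[1]], ":", fixed = TRUE)[[1]][1])
  }
  lat <- NA_real_; lon <- NA_real_
  if (length(quals$lat_lon)) {
    ll <- .parse_lat_lon(quals$lat_lon[[1]])
    lat <- ll[1]; lon <- ll[2]
  }

  ori <- grep("^ORIGIN", entry)
  seq <- ""
  if (length(ori)) {
    seq_lines <- entry[(ori[1] + 1L):(length(entry) - 1L)]
    seq <- .clean_seq(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  }
  if (!nzchar(seq)) stop("entry ", id, " has no sequence")

  list(
    is_co1 = is_co1,
    row = tibble::tibble(
      source_db = "GenBank", record_id = id, raw_name = raw_name,
      raw_lineage = list(lin), sequence = seq, country = country,
      latitude = lat, longitude = lon, marker = "CO1"
    )
  )
}

.gb_qualifiers <- function(entry) {
  get <- function(key) {
    m <- regmatches(entry, regexpr(sprintf('/%s="[^"]*"', key), entry))
    sub(sprintf('/%s="', key), "", sub('"$', "", m))
  }
  list(gene = get("gene"), product = get("product"),
       country = get("country"), lat_lon = get("lat_lon"))
}

.parse_lat_lon <- function(x) {
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  if (length(toks) != 4) return(c(NA_real_, NA_real_))
  lat <- suppressWarnings(as.numeric(toks[1]))
  lon <- suppressWarnings(as.numeric(toks[3]))
  if (toupper(toks[2]) == "S") lat <- -lat
  if (toupper(toks[4]) == "W") lon <- -lon
  c(lat, lon)
}

# rank columns accepted in BOLD data packages (either <rank>_name or <rank>)
.bold_rank_col <- function(df, rank) {
  for (cand in c(paste0(rank, "_name"), rank)) {
    if (cand %in% names(df)) return(cand)
  }
  NA_character_
}

#' Read a BOLD data-package TSV
#'
#' One record per row; rank columns (`phylum_name` ... `species_name`, or the
#' release's bare rank names) are mapped into `raw_lineage` in rank order.
#' Rows whose `markercode` does not match `marker` are skipped, as are rows
#' with an empty nucleotide cell (counted in attribute `n_skipped`).
#'
#' @param path TSV file, plain or gzipped.
#' @param marker marker code to retain (default `"COI-5P"`).
#' @return Record table.
#' @export
read_bold_tsv <- function(path, marker = "COI-5P") {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = c("", "NA"))
  id_col <- if ("processid" %in% names(df)) "processid" else NA
  seq_col <- if ("nucleotides" %in% names(df)) "nucleotides" else
    if ("nuc" %in% names(df)) "nuc" else NA
  if (is.na(id_col) || is.na(seq_col)) {
    stop("BOLD TSV lacks required header (processid, nucleotides)")
  }
  mk_col <- intersect(c("markercode", "marker_code"), names(df))[1]
  .read_rank_table(
    df, source_db = "BOLD", id_col = id_col, seq_col = seq_col,
    marker_col = mk_col, marker = marker,
    ranks = c("phylum", "class", "order", "family", "genus", "species"),
    rank_col = function(r) .bold_rank_col(df, r),
    country_col = intersect(c("country", "country/ocean"), names(df))[1],
    lat_col = intersect(c("lat"), names(df))[1],
    lon_col = intersect(c("lon"), names(df))[1]
  )
}

#' Read a GBOL release CSV
#'
#' GBOL (German Barcode of Life) release rows carry explicit rank columns
#' `kingdom` ... `species`; empty rank cells mean the rank pair is absent
#' from `raw_lineage` (repair with [repair_ranks()] before merging with the
#' other sources). Quoted fields with embedded commas are handled.
#'
#' @param path CSV file, plain or gzipped.
#' @param marker marker code to retain (default `"COI-5P"`).
#' @return Record table.
#' @export
read_gbol_csv <- function(path, marker = "COI-5P") {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = c("", "NA"))
  if (!("specimen_id" %in% names(df)) || !("sequence" %in% names(df))) {
    stop("GBOL CSV lacks required header (specimen_id, sequence)")
  }
  .read_rank_table(
    df, source_db = "GBOL", id_col = "specimen_id", seq_col = "sequence",
    marker_col = intersect("marker", names(df))[1], marker = marker,
    ranks = .RANKS,
    rank_col = function(r) if (r %in% names(df)) r else NA_character_,
    country_col = intersect("country", names(df))[1],
    lat_col = intersect("latitude", names(df))[1],
    lon_col = intersect("longitude", names(df))[1]
  )
}

.read_rank_table <- function(df, source_db, id_col, seq_col, marker_col,
                             marker, ranks, rank_col, country_col,
                             lat_col, lon_col) {
  n_skipped <- 0L
  if (!is.na(marker_col)) {
    keep <- !is.na(df[[marker_col]]) & df[[marker_col]] == marker
    n_skipped <- n_skipped + sum(!keep)
    df <- df[keep, , drop = FALSE]
  }
  no_seq <- is.na(df[[seq_col]]) | !nzchar(trimws(df[[seq_col]]))
  n_skipped <- n_skipped + sum(no_seq)
  df <- df[!no_seq, , drop = FALSE]

  cols <- vapply(ranks, rank_col, "")
  lineages <- lapply(seq_len(nrow(df)), function(i) {
    vals <- vapply(seq_along(ranks), function(j) {
      if (is.na(cols[[j]])) NA_character_ else df[[cols[[j]]]][[i]]
    }, "")
    keep <- !is.na(vals) & nzchar(vals)
    stats::setNames(vals[keep], ranks[keep])
  })
  raw_name <- vapply(lineages, function(l) {
    if (length(l)) unname(l[[length(l)]]) else NA_character_
  }, "")
  num <- function(col) {
    if (is.na(col)) rep(NA_real_, nrow(df))
    else suppressWarnings(as.numeric(df[[col]]))
  }
  out <- tibble::tibble(
    source_db = rep(source_db, nrow(df)),
    record_id = df[[id_col]],
    raw_name = raw_name,
    raw_lineage = lineages,
    sequence = .clean_seq(df[[seq_col]]),
    country = if (is.na(country_col)) rep(NA_character_, nrow(df)) else df[[country_col]],
    latitude = num(lat_col),
    longitude = num(lon_col),
    marker = rep(marker, nrow(df))
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Repair missing ranks in record lineages
#'
#' Some releases use ranks inconsistently: not every record carries every
#' rank at the same position of its higher classification. This makes the
#' raw lineage of every record contain all `expected_ranks`, in canonical
#' order, inserting empty names for absent ranks. Existing names are never
#' altered; labelled pairs outside `expected_ranks` are kept after them.
#'
#' @param records record table.
#' @param expected_ranks ordered rank labels, default the 7 standard ranks.
#' @return Record table with repaired `raw_lineage`.
#' @export
repair_ranks <- function(records, expected_ranks = standard_ranks()) {
  records$raw_lineage <- lapply(records$raw_lineage, function(lin) {
    have <- names(lin)
    vals <- vapply(expected_ranks, function(r) {
      if (!is.null(have) && r %in% have) unname(lin[[match(r, have)]]) else ""
    }, "")
    extra <- if (!is.null(have)) lin[!(have %in% expected_ranks)] else lin[0]
    c(stats::setNames(vals, expected_ranks), extra)
  })
  records
}

#' Merge record tables from several sources
#'
#' Concatenates record tables, preserving within-source order, and prefixes
#' `record_id` with the source tag so identifiers are globally unique.
#' A duplicated (source, id) pair keeps its first occurrence with a warning.
#'
#' @param ... record tables.
#' @return One record table.
#' @export
merge_sources <- function(...) {
  tabs <- list(...)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (!length(tabs)) return(.empty_records())
  out <- dplyr::bind_rows(tabs)
  if (!nrow(out)) return(out)
  key <- paste(out$source_db, out$record_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicated record id(s) within a source; keeping first")
    out <- out[!dup, , drop = FALSE]
  }
  out$record_id <- paste(out$source_db, out$record_id, sep = ":")
  out
}
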