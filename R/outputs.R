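# Reference-database serialization: table, FASTA, comparison, and the
# classifier dialects (SINTAX, qiime2, kraken2, dada2).

.out_formats <- c("table", "fasta", "comparison", "sintax", "qiime2",
                  "kraken2", "dada2_taxonomy", "dada2_species")

# writers accept harmonized record tables or dereplicated cluster tables
.norm_out_records <- function(records) {
  if (!("record_id" %in% names(records)) &&
      "representative_id" %in% names(records)) {
    records$record_id <- records$representative_id
  }
  for (col in c("action", "country")) {
    if (!(col %in% names(records))) records[[col]] <- NA_character_
  }
  for (col in c("latitude", "longitude")) {
    if (!(col %in% names(records))) records[[col]] <- NA_real_
  }
  if (!("source_db" %in% names(records))) records$source_db <- NA_character_
  records
}

.rank_or_empty <- function(records) {
  m <- as.matrix(records[, .RANKS])
  m[is.na(m)] <- ""
  m
}

.wrap80 <- function(seq) {
  vapply(seq, function(s) {
    paste(substring(s, seq(1, nchar(s), 80), pmin(seq(80, nchar(s) + 79, 80), nchar(s))),
          collapse = "\n")
  }, "", USE.NAMES = FALSE)
}

#' Write the table output
#'
#' Tab-separated, one row per record or cluster, with the 7 standard rank
#' columns and location information; empty cells for missing values, UTF-8,
#' LF line endings.
#'
#' @param records harmonized or dereplicated table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_table_output <- function(records, path) {
  records <- .norm_out_records(records)
  out <- tibble::as_tibble(cbind(
    records[, c("record_id", "source_db")],
    tibble::as_tibble(as.data.frame(.rank_or_empty(records),
                                    stringsAsFactors = FALSE)),
    records[, c("action", "country", "latitude", "longitude", "sequence")]
  ))
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read back a table output
#'
#' Strict reader for the format written by [write_table_output()].
#'
#' @param path table file.
#' @return Tibble.
#' @export
read_table_output <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  for (col in c("latitude", "longitude")) {
    v <- out[[col]]
    v[!nzchar(v)] <- NA_character_
    out[[col]] <- as.numeric(v)
  }
  out
}

#' Write the default FASTA output
#'
#' Headers carry the full 7-rank lineage in greengenes-style prefixes:
#' `>id|k__K;p__P;c__C;o__O;f__F;g__G;s__S` (empty ranks keep their bare
#' prefix); sequences wrap at 80 columns.
#'
#' @inheritParams write_table_output
#' @export
write_fasta_output <- function(records, path) {
  records <- .norm_out_records(records)
  m <- .rank_or_empty(records)
  tax <- apply(m, 1, function(r) {
    paste0(c("k__", "p__", "c__", "o__", "f__", "g__", "s__"), r,
           collapse = ";")
  })
  lines <- paste0(">", records$record_id, "|", tax, "\n",
                  .wrap80(records$sequence))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write the comparison file
#'
#' @param comparison tibble from [build_comparison()].
#' @param path output file.
#' @export
write_comparison_output <- function(comparison, path) {
  readr::write_tsv(comparison, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write a SINTAX-annotated FASTA
#'
#' Headers `>id;tax=k:K,p:P,c:C,o:O,f:F,g:G,s:S;` with empty ranks omitted
#' and spaces replaced by underscores (SINTAX tolerates missing ranks but
#' not empty fields).
#'
#' @inheritParams write_table_output
#' @export
write_sintax <- function(records, path) {
  records <- .norm_out_records(records)
  m <- .rank_or_empty(records)
  prefixes <- c("k", "p", "c", "o", "f", "g", "s")
  tax <- apply(m, 1, function(r) {
    keep <- nzchar(r)
    paste0(prefixes[keep], ":", gsub(" ", "_", r[keep]), collapse = ",")
  })
  lines <- paste0(">", records$record_id, ";tax=", tax, ";\n",
                  .wrap80(records$sequence))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write qiime2 reference files
#'
#' A FASTA with bare ids and a taxonomy TSV (`Feature ID` TAB `Taxon`)
#' whose taxon strings are greengenes-style with exactly 7 segments; empty
#' ranks keep their bare prefixes, which qiime2 accepts.
#'
#' @param records harmonized or dereplicated table.
#' @param fasta_path,taxonomy_path output files.
#' @export
write_qiime2 <- function(records, fasta_path, taxonomy_path) {
  records <- .norm_out_records(records)
  readr::write_lines(paste0(">", records$record_id, "\n",
                            .wrap80(records$sequence)), fasta_path)
  m <- .rank_or_empty(records)
  tax <- apply(m, 1, function(r) {
    paste0(c("k__", "p__", "c__", "o__", "f__", "g__", "s__"), r,
           collapse = "; ")
  })
  readr::write_tsv(
    tibble::tibble(`Feature ID` = records$record_id, Taxon = tax),
    taxonomy_path, progress = FALSE
  )
  invisible(c(fasta_path, taxonomy_path))
}

#' Write kraken2 library files
#'
#' A FASTA with `>id|kraken:taxid|T` headers, where `T` is the backbone
#' taxon id of the record's lowest resolved rank, plus companion `nodes.dmp`
#' and `names.dmp` stubs restricted to the taxa used (closed under parents)
#' so a kraken2 database builder can consume them. Records that cannot be
#' tied to a backbone taxon are excluded and counted in attribute
#' `n_excluded`.
#'
#' @param records harmonized or dereplicated table.
#' @param backbone the `taxonomy_store` the records were harmonized
#'   against.
#' @param fasta_path output FASTA.
#' @param taxonomy_dir directory for `nodes.dmp` / `names.dmp` stubs.
#' @export
write_kraken2 <- function(records, backbone, fasta_path, taxonomy_dir) {
  records <- .norm_out_records(records)
  taxids <- vapply(seq_len(nrow(records)), function(i) {
    .lowest_taxon_id(records[i, , drop = FALSE], backbone)
  }, "")
  keep <- !is.na(taxids) & nzchar(taxids)
  kept <- records[keep, , drop = FALSE]
  ids <- taxids[keep]
  readr::write_lines(
    paste0(">", kept$record_id, "|kraken:taxid|", ids, "\n",
           .wrap80(kept$sequence)),
    fasta_path
  )
  # ancestry closure over the used taxa
  used <- unique(ids)
  closure <- character()
  for (tid in used) {
    cur <- tid
    while (!is.null(cur) && !(cur %in% closure)) {
      closure <- c(closure, cur)
      node <- .node_by_id(backbone, cur)
      if (is.null(node)) break
      pid <- node$parent_id[[1]]
      cur <- if (is.na(pid) || !nzchar(pid)) NULL else pid
    }
  }
  closure <- closure[closure %in% backbone$nodes$taxon_id]
  dir.create(taxonomy_dir, showWarnings = FALSE, recursive = TRUE)
  nodes_lines <- vapply(closure, function(tid) {
    node <- .node_by_id(backbone, tid)
    pid <- node$parent_id[[1]]
    if (is.na(pid) || !nzchar(pid)) pid <- tid    # taxdump roots self-parent
    paste(tid, pid, node$rank[[1]], "", sep = "\t|\t")
  }, "")
  names_lines <- vapply(closure, function(tid) {
    node <- .node_by_id(backbone, tid)
    paste(tid, node$canonical_name[[1]], "", "scientific name", sep = "\t|\t")
  }, "")
  readr::write_lines(paste0(nodes_lines, "\t|"),
                     file.path(taxonomy_dir, "nodes.dmp"))
  readr::write_lines(paste0(names_lines, "\t|"),
                     file.path(taxonomy_dir, "names.dmp"))
  out <- c(fasta_path, taxonomy_dir)
  attr(out, "n_excluded") <- sum(!keep)
  invisible(out)
}

# backbone taxon id of the record's lowest resolved rank
.lowest_taxon_id <- function(rec, backbone) {
  if ("matched_taxon_id" %in% names(rec) && !is.na(rec$matched_taxon_id[[1]]) &&
      identical(rec$action[[1]], "exact")) {
    return(rec$matched_taxon_id[[1]])
  }
  lin <- lineage_as_vector(rec[, .RANKS])
  res <- lineage_resolution(lin)
  if (is.na(res)) return(NA_character_)
  hit <- tax_lookup(backbone, lin[[res]], rank_hint = res,
                    context = lin[["kingdom"]])
  if (!nrow(hit) || hit$ambiguous[[1]]) return(NA_character_)
  accepted_of(backbone, hit[1, , drop = FALSE])$taxon_id[[1]]
}

#' Write dada2 reference files
#'
#' The taxonomy file uses genus-level headers `>K;P;C;O;F;G;` (trailing
#' semicolon, as `assignTaxonomy` expects) and the species file uses
#' `>id Genus species` headers (as `assignSpecies` expects); records with
#' an empty genus are excluded from the species file.
#'
#' @param records harmonized or dereplicated table.
#' @param taxonomy_path,species_path output FASTA files.
#' @export
write_dada2 <- function(records, taxonomy_path, species_path) {
  records <- .norm_out_records(records)
  m <- .rank_or_empty(records)
  tax <- apply(m[, 1:6, drop = FALSE], 1, function(r) {
    paste0(paste(r, collapse = ";"), ";")
  })
  readr::write_lines(paste0(">", tax, "\n", .wrap80(records$sequence)),
                     taxonomy_path)
  has_sp <- nzchar(m[, "genus"]) & nzchar(m[, "species"])
  sp <- records[has_sp, , drop = FALSE]
  epithet <- vapply(seq_len(nrow(sp)), function(i) {
    toks <- strsplit(m[has_sp, "species"][[i]], "\\s+")[[1]]
    if (length(toks) >= 2) toks[[2]] else toks[[1]]
  }, "")
  readr::write_lines(
    paste0(">", sp$record_id, " ", m[has_sp, "genus"], " ", epithet, "\n",
           .wrap80(sp$sequence)),
    species_path
  )
  invisible(c(taxonomy_path, species_path))
}

#' Write a reference-database output bundle
#'
#' Serializes the final record set into the requested formats. The table,
#' FASTA and comparison files are always produced; classifier formats are
#' opt-in. A JSON run manifest recording the parameters, format list and
#' per-format record counts is written alongside.
#'
#' @param records harmonized or dereplicated table.
#' @param comparison tibble from [build_comparison()] (or `NULL`).
#' @param dir output directory, created if needed.
#' @param formats subset of
#'   `c("sintax", "qiime2", "kraken2", "dada2")` in addition to the
#'   defaults.
#' @param backbone `taxonomy_store`; required for the kraken2 format.
#' @param parameters named list recorded in the manifest.
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(records, comparison, dir,
                          formats = character(), backbone = NULL,
                          parameters = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table = file.path(dir, "reference.tsv"),
    fasta = file.path(dir, "reference.fasta"),
    comparison = file.path(dir, "comparison.tsv")
  )
  write_table_output(records, paths[["table"]])
  write_fasta_output(records, paths[["fasta"]])
  if (is.null(comparison)) {
    comparison <- tibble::tibble(accepted_name = character(),
                                 provided_name = character(),
                                 action = character(),
                                 n_records = integer())
  }
  write_comparison_output(comparison, paths[["comparison"]])
  if ("sintax" %in% formats) {
    paths[["sintax"]] <- file.path(dir, "reference.sintax.fasta")
    write_sintax(records, paths[["sintax"]])
  }
  if ("qiime2" %in% formats) {
    paths[["qiime2_fasta"]] <- file.path(dir, "reference.qiime2.fasta")
    paths[["qiime2_taxonomy"]] <- file.path(dir, "reference.qiime2.tsv")
    write_qiime2(records, paths[["qiime2_fasta"]], paths[["qiime2_taxonomy"]])
  }
  if ("kraken2" %in% formats) {
    if (is.null(backbone)) stop("kraken2 output needs a backbone store")
    paths[["kraken2_fasta"]] <- file.path(dir, "reference.kraken2.fasta")
    paths[["kraken2_taxonomy"]] <- file.path(dir, "kraken2_taxonomy")
    write_kraken2(records, backbone, paths[["kraken2_fasta"]],
                  paths[["kraken2_taxonomy"]])
  }
  if ("dada2" %in% formats) {
    paths[["dada2_taxonomy"]] <- file.path(dir, "reference.dada2.taxonomy.fasta")
    paths[["dada2_species"]] <- file.path(dir, "reference.dada2.species.fasta")
    write_dada2(records, paths[["dada2_taxonomy"]], paths[["dada2_species"]])
  }
  manifest <- list(
    package = "barcoderef",
    version = as.character(utils::packageVersion("barcoderef")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    n_records = nrow(records),
    formats = I(c("table", "fasta", "comparison", formats)),
    parameters = parameters
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
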