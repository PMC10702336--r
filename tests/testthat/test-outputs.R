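# output writers: table, fasta, comparison, classifier dialects, manifest

out_records <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      record_id = "BOLD:BD0001", source_db = "BOLD",
      kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
      order = "Hymenoptera", family = "Apidae", genus = "Apis",
      species = "Apis mellifera", action = "exact", resolution = "species",
      country = "Germany", latitude = 50.7, longitude = 7.1,
      sequence = strrep("ACGTTGCA", 25)
    ),
    tibble::tibble(
      record_id = "GBOL:GL0001", source_db = "GBOL",
      kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
      order = "Hymenoptera", family = "Apidae", genus = "Apis",
      species = NA_character_, action = "exact", resolution = "genus",
      country = NA_character_, latitude = NA_real_, longitude = NA_real_,
      sequence = strrep("TTGGCCAA", 20)
    )
  )
}

test_that("table output round-trips with empty cells for missing values", {
  p <- tempfile(fileext = ".tsv")
  write_table_output(out_records(), p)
  back <- read_table_output(p)
  expect_equal(nrow(back), 2L)
  expect_equal(names(back)[1:2], c("record_id", "source_db"))
  expect_true(all(standard_ranks() %in% names(back)))
  expect_equal(back$species[1], "Apis mellifera")
  expect_equal(back$species[2], "")      # empty cell, not NA
  expect_true(is.na(back$latitude[2]))
  expect_equal(back$sequence, out_records()$sequence)
  raw <- readChar(p, file.size(p), useBytes = TRUE)
  expect_false(grepl("\r", raw))          # LF endings
})

test_that("fasta output carries the 7-rank header and wraps at 80 columns", {
  p <- tempfile(fileext = ".fasta")
  write_fasta_output(out_records(), p)
  lines <- readLines(p)
  headers <- grep("^>", lines, value = TRUE)
  expect_length(headers, 2L)
  expect_equal(headers[1],
    ">BOLD:BD0001|k__Animalia;p__Arthropoda;c__Insecta;o__Hymenoptera;f__Apidae;g__Apis;s__Apis mellifera")
  expect_true(grepl("s__$", headers[2]))  # empty rank keeps bare prefix
  expect_true(all(nchar(lines[!grepl("^>", lines)]) <= 80))
  # parses with a strict FASTA reader and preserves the sequences
  seqs <- Biostrings::readDNAStringSet(p)
  expect_equal(unname(as.character(seqs)), out_records()$sequence)
})

test_that("SINTAX headers omit empty ranks and underscore spaces", {
  p <- tempfile(fileext = ".fasta")
  write_sintax(out_records(), p)
  h <- grep("^>", readLines(p), value = TRUE)
  expect_equal(h[1],
    ">BOLD:BD0001;tax=k:Animalia,p:Arthropoda,c:Insecta,o:Hymenoptera,f:Apidae,g:Apis,s:Apis_mellifera;")
  expect_equal(length(strsplit(sub(".*tax=", "", h[1]), ",")[[1]]), 7L)
  expect_equal(length(strsplit(sub(".*tax=", "", h[2]), ",")[[1]]), 6L)
  expect_false(grepl("s:", h[2]))
})

test_that("qiime2 writes paired files with aligned ids and 7 taxon segments", {
  f <- tempfile(fileext = ".fasta"); t <- tempfile(fileext = ".tsv")
  write_qiime2(out_records(), f, t)
  seqs <- Biostrings::readDNAStringSet(f)
  tax <- readr::read_tsv(t, col_types = "cc", progress = FALSE)
  expect_equal(names(seqs), tax$`Feature ID`)
  expect_equal(nrow(tax), 2L)
  segs <- strsplit(tax$Taxon, "; ")
  expect_true(all(lengths(segs) == 7L))
  expect_equal(segs[[2]][7], "s__")
})

test_that("dada2 taxonomy and species files follow assignTaxonomy/assignSpecies", {
  tp <- tempfile(); sp <- tempfile()
  write_dada2(out_records(), tp, sp)
  th <- grep("^>", readLines(tp), value = TRUE)
  expect_length(th, 2L)
  expect_equal(th[1], ">Animalia;Arthropoda;Insecta;Hymenoptera;Apidae;Apis;")
  expect_true(all(vapply(strsplit(sub("^>", "", th), ";"), length, 0L) == 6L))
  sh <- grep("^>", readLines(sp), value = TRUE)
  expect_length(sh, 1L)                   # genus-only record excluded
  expect_equal(sh[1], ">BOLD:BD0001 Apis mellifera")
})

test_that("kraken2 headers carry backbone taxids and stubs close over parents", {
  fx <- toy_fixture()
  store <- import_backbone(fx$paths$backbone_gbif, "gbif",
                           homonyms = fx$paths$homonyms)
  recs <- merge_sources(read_bold_tsv(fx$paths$bold))
  h <- harmonize_records(recs, store)
  fp <- tempfile(fileext = ".fasta"); td <- tempfile()
  res <- write_kraken2(h, store, fp, td)
  lines <- grep("^>", readLines(fp), value = TRUE)
  n_unmatched <- sum(h$action == "unmatched")
  expect_equal(length(lines), nrow(h) - n_unmatched)
  expect_equal(attr(res, "n_excluded"), n_unmatched)
  expect_true(all(grepl("\\|kraken:taxid\\|T\\d+$", lines)))
  # a species-level record points at its species node
  sp_rec <- h[h$action == "exact" & h$resolution == "species", ][1, ]
  want_id <- tax_lookup(store, sp_rec$species, rank_hint = "species")$taxon_id
  expect_true(any(grepl(paste0(sp_rec$record_id, "|kraken:taxid|", want_id),
                        lines, fixed = TRUE)))
  # nodes stub is closed under parents
  nodes <- readLines(file.path(td, "nodes.dmp"))
  ids <- sub("\t\\|.*$", "", nodes)
  parents <- vapply(strsplit(nodes, "\t\\|\t"), `[`, "", 2)
  expect_true(all(parents %in% ids))
  names_ids <- sub("\t\\|.*$", "", readLines(file.path(td, "names.dmp")))
  expect_setequal(names_ids, ids)
})

test_that("write_outputs always emits table+fasta+comparison and a manifest", {
  d <- tempfile()
  cmp <- tibble::tibble(accepted_name = "Apis mellifera",
                        provided_name = "Apis mellifica",
                        action = "synonym_replaced", n_records = 3L)
  paths <- write_outputs(out_records(), cmp, d,
                         formats = c("sintax", "qiime2", "dada2"))
  expect_true(all(file.exists(unlist(
    paths[c("table", "fasta", "comparison", "sintax")]))))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$n_records, 2L)
  expect_true("parameters" %in% names(man))
  expect_true(all(c("table", "fasta", "comparison") %in%
                  unlist(man$formats)))
})
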