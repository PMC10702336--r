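# Deterministic synthetic fixtures: a toy backbone taxonomy, source-database
# snapshots in all three dialects, regions, benchmark queries, and ground
# truth tables for every record. Same seed -> byte-identical files.

#' Fixture specification
#'
#' Parameters of the synthetic data generator. Defaults emulate a small but
#' structurally complete snapshot: a few hundred backbone nodes, three
#' source files with shared sequences, synonyms, homonyms, open
#' nomenclature, missing ranks, and records with and without location
#' information.
#'
#' @param seed integer; same seed gives byte-identical outputs.
#' @param n_species number of accepted species in the backbone.
#' @param synonym_fraction fraction of species that also carry a synonym
#'   name (and of records that use it).
#' @param homonym_count genus names duplicated under a second kingdom.
#' @param open_nomenclature_fraction fraction of records whose name carries
#'   an open-nomenclature qualifier (e.g. "cf.").
#' @param fallback_fraction fraction of records with a genus absent from
#'   the backbone (family present), expected to harmonize by rank fallback.
#' @param unmatched_fraction fraction of records with a fully fabricated
#'   lineage, expected to stay unmatched.
#' @param missing_rank_fraction fraction of GBOL rows with an empty order
#'   cell (the release's rank inconsistency).
#' @param duplicate_sequence_fraction fraction of records that reuse their
#'   species' base sequence verbatim (creating cross-source duplicates for
#'   dereplication).
#' @param n_fraction fraction of records with one ambiguous base (N).
#' @param sequence_length barcode length in bp (default 658, the CO1 Folmer
#'   region).
#' @param n_records named integer vector: records per source.
#' @param n_queries benchmark queries generated from reference sequences.
#' @param query_substitutions planted substitution counts, cycled across
#'   queries.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_species = 60L,
                         synonym_fraction = 0.1, homonym_count = 2L,
                         open_nomenclature_fraction = 0.1,
                         fallback_fraction = 0.05,
                         unmatched_fraction = 0.02,
                         missing_rank_fraction = 0.3,
                         duplicate_sequence_fraction = 0.2,
                         n_fraction = 0.05,
                         sequence_length = 658L,
                         n_records = c(GenBank = 30L, BOLD = 30L, GBOL = 30L),
                         n_queries = 50L,
                         query_substitutions = c(0L, 1L, 3L, 5L, 10L, 30L)) {
  fr <- c(synonym_fraction, open_nomenclature_fraction, fallback_fraction,
          unmatched_fraction, missing_rank_fraction,
          duplicate_sequence_fraction, n_fraction)
  stopifnot(all(fr >= 0 & fr <= 1), n_species >= 10, sequence_length >= 60)
  n_genera <- ceiling(n_species / 3)
  if (homonym_count > n_genera) stop("more homonyms than genera")
  structure(as.list(environment())[c(
    "seed", "n_species", "synonym_fraction", "homonym_count",
    "open_nomenclature_fraction", "fallback_fraction", "unmatched_fraction",
    "missing_rank_fraction", "duplicate_sequence_fraction", "n_fraction",
    "sequence_length", "n_records", "n_queries", "query_substitutions"
  )], class = "fixture_spec")
}

# deterministic pseudo-Latin names: base-18 syllable expansion of an index
.SYL <- c("ba", "ce", "di", "fo", "gu", "la", "me", "ni", "po", "ra",
          "su", "te", "vi", "xo", "zu", "ka", "lo", "mi")

.syn_name <- function(i, prefix = "", capital = TRUE) {
  n <- length(.SYL)
  d3 <- i %% n; i <- i %/% n
  d2 <- i %% n; d1 <- i %/% n
  nm <- paste0(prefix, .SYL[d1 %% n + 1], .SYL[d2 + 1], .SYL[d3 + 1])
  if (capital) nm <- paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)))
  nm
}

# stop-free coding-strand sequence under the invertebrate mito code
.random_coding_seq <- function(len) {
  bases <- c("A", "C", "G", "T")
  n_codons <- ceiling(len / 3)
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cd %in% c("TAA", "TAG")) break
    }
    codons[i] <- cd
  }
  substr(paste(codons, collapse = ""), 1, len)
}

.substitute_at <- function(seq, pos) {
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    old <- substr(seq, p, p)
    new <- sample(setdiff(bases, old), 1)
    substr(seq, p, p) <- new
  }
  seq
}

#' Generate the synthetic fixture set
#'
#' Writes a complete toy data set into `dir`: a GBIF-style backbone dump
#' and an equivalent NCBI-taxdump pair, a homonym list, a GenBank flat
#' file, a BOLD TSV, a GBOL CSV, a gazetteer, a GeoJSON polygon, reference
#' and query FASTA files, and ground-truth tables recording for every
#' record its true lineage, expected cleaned name, expected harmonization
#' action and expected sequence cluster, and for every query its planted
#' substitution count and expected identity bin.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created).
#' @return List with the written `paths`, the truth tibbles (`records`,
#'   `queries`), and `summary` counts (backbone nodes, synonyms, per-source
#'   records, non-target entries).
#' @export
generate_fixtures <- function(spec = fixture_spec(), dir = tempfile("fix")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)

  tax <- .build_toy_taxonomy(spec)
  .write_backbone_files(tax, dir)
  recs <- .build_toy_records(spec, tax)
  .write_source_files(spec, recs, dir)
  qry <- .build_toy_queries(spec, tax, dir)

  readr::write_tsv(recs$truth, file.path(dir, "truth_records.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(qry$truth, file.path(dir, "truth_queries.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(default_gazetteer(), file.path(dir, "gazetteer.tsv"),
                   progress = FALSE)
  .write_box_geojson(file.path(dir, "regions.geojson"))

  summary <- list(
    n_backbone_nodes = nrow(tax$nodes),
    n_backbone_synonyms = sum(tax$nodes$status == "synonym"),
    n_records = spec$n_records,
    n_non_target = c(GenBank = 1L, BOLD = 1L, GBOL = 0L)
  )
  jsonlite::write_json(summary, file.path(dir, "truth_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(
    paths = list(
      dir = dir,
      backbone_gbif = file.path(dir, "backbone_gbif.tsv"),
      backbone_ncbi = file.path(dir, "ncbi"),
      homonyms = file.path(dir, "homonyms.tsv"),
      genbank = file.path(dir, "genbank.gbff"),
      bold = file.path(dir, "bold.tsv"),
      gbol = file.path(dir, "gbol.csv"),
      gazetteer = file.path(dir, "gazetteer.tsv"),
      regions = file.path(dir, "regions.geojson"),
      references = file.path(dir, "references.fasta"),
      queries = file.path(dir, "queries.fasta")
    ),
    records = recs$truth, queries = qry$truth, summary = summary,
    taxonomy = tax
  )
}

.build_toy_taxonomy <- function(spec) {
  nodes <- list()
  nid <- 0L
  add <- function(name, rank, parent, status = "accepted", accepted = NULL) {
    nid <<- nid + 1L
    id <- paste0("T", nid)
    nodes[[nid]] <<- tibble::tibble(
      taxon_id = id, canonical_name = name, rank = rank, status = status,
      parent_id = parent %||% NA_character_,
      accepted_id = accepted %||% id
    )
    id
  }
  kingdom <- add("Animalia", "kingdom", NULL)
  fam_ids <- character(); fam_names <- character()
  fi <- 0L
  for (p in 1:2) {
    pid <- add(.syn_name(fi * 31 + 7, prefix = "phy"), "phylum", kingdom)
    for (cl in 1:2) {
      cid <- add(.syn_name(fi * 47 + cl * 5 + 100, prefix = "cla"), "class", pid)
      for (o in 1:2) {
        oid <- add(.syn_name(fi * 59 + o * 3 + 200, prefix = "ord"), "order", cid)
        for (f in 1:2) {
          fi <- fi + 1L
          fam_ids <- c(fam_ids, add(.syn_name(fi + 300, prefix = "fam"),
                                    "family", oid))
          fam_names <- c(fam_names, nodes[[nid]]$canonical_name)
        }
      }
    }
  }
  n_genera <- ceiling(spec$n_species / 3)
  gen_ids <- character(n_genera); gen_names <- character(n_genera)
  for (g in seq_len(n_genera)) {
    gen_names[g] <- .syn_name(g + 600)
    gen_ids[g] <- add(gen_names[g], "genus",
                      fam_ids[(g - 1) %% length(fam_ids) + 1])
  }
  sp_ids <- character(spec$n_species)
  sp_names <- character(spec$n_species)
  sp_genus <- integer(spec$n_species)
  for (s in seq_len(spec$n_species)) {
    g <- (s - 1) %% n_genera + 1
    sp_genus[s] <- g
    sp_names[s] <- paste(gen_names[g], .syn_name(s + 900, capital = FALSE))
    sp_ids[s] <- add(sp_names[s], "species", gen_ids[g])
  }
  n_syn <- round(spec$synonym_fraction * spec$n_species)
  syn_names <- character(n_syn)
  for (i in seq_len(n_syn)) {
    g <- sp_genus[i]
    syn_names[i] <- paste(gen_names[g], .syn_name(i + 1500, capital = FALSE))
    add(syn_names[i], "species", gen_ids[g], status = "synonym",
        accepted = sp_ids[i])
  }
  # a second kingdom carrying homonym genus names
  pk <- add("Plantae", "kingdom", NULL)
  pp <- add("Plantophyta", "phylum", pk)
  pc <- add("Plantopsida", "class", pp)
  po <- add("Plantales", "order", pc)
  pf <- add("Plantaceae", "family", po)
  hom_names <- gen_names[seq_len(spec$homonym_count)]
  for (h in hom_names) add(h, "genus", pf)

  list(
    nodes = dplyr::bind_rows(nodes),
    fam_names = fam_names, gen_names = gen_names, gen_ids = gen_ids,
    sp_names = sp_names, sp_ids = sp_ids, sp_genus = sp_genus,
    syn_names = syn_names, hom_names = hom_names, n_genera = n_genera,
    base_seqs = vapply(seq_len(spec$n_species), function(i)
      .random_coding_seq(spec$sequence_length), "")
  )
}

.write_backbone_files <- function(tax, dir) {
  gbif <- tibble::tibble(
    taxonID = tax$nodes$taxon_id,
    parentNameUsageID = tax$nodes$parent_id,
    acceptedNameUsageID = tax$nodes$accepted_id,
    canonicalName = tax$nodes$canonical_name,
    taxonRank = tax$nodes$rank,
    taxonomicStatus = tax$nodes$status
  )
  readr::write_tsv(gbif, file.path(dir, "backbone_gbif.tsv"), na = "",
                   progress = FALSE)
  # equivalent taxdump pair: accepted nodes in nodes.dmp, synonyms as
  # synonym-class names of their accepted taxon
  ncbi_dir <- file.path(dir, "ncbi")
  dir.create(ncbi_dir, showWarnings = FALSE)
  acc <- tax$nodes[tax$nodes$status == "accepted", ]
  syn <- tax$nodes[tax$nodes$status == "synonym", ]
  nodes_lines <- paste0(acc$taxon_id, "\t|\t",
                        ifelse(is.na(acc$parent_id), acc$taxon_id,
                               acc$parent_id),
                        "\t|\t", acc$rank, "\t|")
  names_lines <- c(
    paste0(acc$taxon_id, "\t|\t", acc$canonical_name,
           "\t|\t\t|\tscientific name\t|"),
    if (nrow(syn)) paste0(syn$accepted_id, "\t|\t", syn$canonical_name,
                          "\t|\t\t|\tsynonym\t|")
  )
  readr::write_lines(nodes_lines, file.path(ncbi_dir, "nodes.dmp"))
  readr::write_lines(names_lines, file.path(ncbi_dir, "names.dmp"))
  hom <- tibble::tibble(name = tax$hom_names,
                        rank = rep("genus", length(tax$hom_names)),
                        resolving_kingdom = rep("Animalia",
                                                length(tax$hom_names)))
  readr::write_tsv(hom, file.path(dir, "homonyms.tsv"), progress = FALSE)
}

# location patterns cycled over records
.LOC <- list(
  list(country = "Germany", lat = NA, lon = NA),
  list(country = "Canada", lat = NA, lon = NA),
  list(country = NA, lat = 0.5, lon = 0.3),     # inside the Box polygon
  list(country = "China", lat = NA, lon = NA),
  list(country = NA, lat = NA, lon = NA),       # no location at all
  list(country = "Portugal", lat = NA, lon = NA)
)

.build_toy_records <- function(spec, tax) {
  N <- sum(spec$n_records)
  n_syn_rec <- round(spec$synonym_fraction * N)
  n_open <- round(spec$open_nomenclature_fraction * N)
  n_fb <- round(spec$fallback_fraction * N)
  n_unm <- round(spec$unmatched_fraction * N)
  n_hom <- spec$homonym_count
  n_syn_sp <- length(tax$syn_names)
  if (n_syn_rec > 0 && n_syn_sp == 0) n_syn_rec <- 0L
  category <- c(rep("synonym", n_syn_rec), rep("open", n_open),
                rep("fallback", n_fb), rep("unmatched", n_unm),
                rep("homonym", n_hom))
  category <- c(category, rep("normal", max(0L, N - length(category))))[1:N]
  # cycle sources so every category reaches every source file
  remaining <- spec$n_records
  sources <- character(N)
  src_names <- names(spec$n_records)
  j <- 0L
  for (i in seq_len(N)) {
    repeat {
      j <- j %% length(src_names) + 1L
      if (remaining[[j]] > 0L) break
    }
    sources[[i]] <- src_names[[j]]
    remaining[[j]] <- remaining[[j]] - 1L
  }
  n_dup <- round(spec$duplicate_sequence_fraction * N)
  n_with_n <- round(spec$n_fraction * N)

  rows <- vector("list", N)
  sp_cursor <- 0L
  variant_counter <- integer(spec$n_species)
  for (i in seq_len(N)) {
    cat_i <- category[[i]]
    src <- sources[[i]]
    sp_cursor <- sp_cursor + 1L
    # duplicates only make sense for records whose sequence can legally
    # recur; concentrate them on few species so identical sequences occur
    is_dup <- i <= n_dup && cat_i %in% c("normal", "open", "synonym")
    s <- if (cat_i == "synonym") {
      (i - 1L) %% n_syn_sp + 1L
    } else if (is_dup) {
      (i - 1L) %% max(1L, n_dup %/% 3L) + 1L
    } else {
      (sp_cursor - 1L) %% spec$n_species + 1L
    }
    g <- tax$sp_genus[s]
    lin_true <- .species_lineage(tax, s)
    seq <- tax$base_seqs[[s]]
    if (!is_dup) {
      variant_counter[s] <- variant_counter[s] + 1L
      pos <- (variant_counter[s] * 7L) %% (spec$sequence_length - 10L) + 5L
      seq <- .substitute_at(seq, pos)
    }
    if (i > N - n_with_n && !is_dup) {
      substr(seq, 3, 3) <- "N"
    }
    loc <- .LOC[[(i - 1L) %% length(.LOC) + 1L]]

    raw_name <- tax$sp_names[[s]]
    expected_cleaned <- raw_name
    expected_action <- "exact"
    expected_lin <- lin_true
    if (cat_i == "synonym") {
      raw_name <- tax$syn_names[[s]]
      expected_cleaned <- raw_name
      expected_action <- "synonym_replaced"
    } else if (cat_i == "open") {
      parts <- strsplit(tax$sp_names[[s]], " ")[[1]]
      raw_name <- paste(parts[1], "cf.", parts[2])
      expected_cleaned <- parts[1]
      expected_action <- "exact"
      expected_lin[["species"]] <- NA_character_
    } else if (cat_i == "homonym") {
      raw_name <- tax$hom_names[[(i - 1L) %% length(tax$hom_names) + 1L]]
      expected_cleaned <- raw_name
      g <- match(raw_name, tax$gen_names)
      expected_lin <- .genus_lineage(tax, g)
      expected_action <- "exact"
    } else if (cat_i == "fallback") {
      fake_gen <- paste0("Zyx", .syn_name(i + 3000))
      raw_name <- paste(fake_gen, .syn_name(i + 3100, capital = FALSE))
      expected_cleaned <- raw_name
      expected_action <- "rank_fallback"
      expected_lin[c("genus", "species")] <- NA_character_
    } else if (cat_i == "unmatched") {
      raw_name <- paste0("Qwv", .syn_name(i + 3200), " ",
                         .syn_name(i + 3300, capital = FALSE))
      expected_cleaned <- raw_name
      expected_action <- "unmatched"
      expected_lin[] <- NA_character_
    }
    # the raw lineage shown by the source (may carry the fake names)
    lin_shown <- expected_lin
    if (cat_i %in% c("normal", "synonym", "open")) {
      lin_shown <- lin_true
      lin_shown[["species"]] <- raw_name
    } else if (cat_i == "fallback") {
      lin_shown <- lin_true
      lin_shown[["genus"]] <- strsplit(raw_name, " ")[[1]][1]
      lin_shown[["species"]] <- raw_name
    } else if (cat_i == "unmatched") {
      lin_shown <- lineage(
        kingdom = paste0("Qwvking", i), phylum = paste0("Qwvphy", i),
        class = paste0("Qwvcla", i), order = paste0("Qwvord", i),
        family = paste0("Qwvfam", i),
        genus = strsplit(raw_name, " ")[[1]][1], species = raw_name
      )
    } else if (cat_i == "homonym") {
      lin_shown[["species"]] <- NA_character_
    }
    rows[[i]] <- tibble::tibble(
      idx = i, source_db = src, category = cat_i, species_idx = s,
      raw_name = raw_name, expected_cleaned = expected_cleaned,
      expected_action = expected_action,
      sequence = seq, cluster_id = NA_character_,
      country = loc$country, latitude = loc$lat, longitude = loc$lon,
      n_count = stringr::str_count(seq, "N"),
      !!!stats::setNames(as.list(expected_lin), paste0("expected_", .RANKS)),
      !!!stats::setNames(as.list(lin_shown), paste0("shown_", .RANKS))
    )
  }
  truth <- dplyr::bind_rows(rows)
  # cluster identity is the sequence itself; label clusters by first use
  truth$cluster_id <- paste0("c", match(truth$sequence,
                                        unique(truth$sequence)))
  # per-source running ids; merged ids are "<source>:<id>"
  truth <- truth |>
    dplyr::group_by(.data$source_db) |>
    dplyr::mutate(local_id = sprintf("%s%04d",
                                     c(GenBank = "GB", BOLD = "BD",
                                       GBOL = "GL")[.data$source_db[1]],
                                     dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::mutate(record_id = paste(.data$source_db, .data$local_id,
                                    sep = ":"))
  truth$expected_resolution <- vapply(seq_len(nrow(truth)), function(i) {
    lineage_resolution(lineage_as_vector(
      stats::setNames(as.list(truth[i, paste0("expected_", .RANKS)]), .RANKS)
    ))
  }, "")
  truth$has_location <- !is.na(truth$country) | !is.na(truth$latitude)
  list(truth = truth)
}

.species_lineage <- function(tax, s) {
  lin <- .genus_lineage(tax, tax$sp_genus[s])
  lin[["species"]] <- tax$sp_names[[s]]
  lin
}

.genus_lineage <- function(tax, g) {
  # walk the node table upward from the genus
  id <- tax$gen_ids[[g]]
  lin <- lineage()
  nodes <- tax$nodes
  while (!is.na(id)) {
    row <- nodes[nodes$taxon_id == id, ]
    if (row$rank %in% .RANKS) lin[[row$rank]] <- row$canonical_name
    id <- row$parent_id
  }
  lin
}

.write_source_files <- function(spec, recs, dir) {
  truth <- recs$truth
  .write_gbff(truth[truth$source_db == "GenBank", ],
              file.path(dir, "genbank.gbff"))
  .write_bold(truth[truth$source_db == "BOLD", ], file.path(dir, "bold.tsv"))
  .write_gbol(spec, truth[truth$source_db == "GBOL", ],
              file.path(dir, "gbol.csv"))
}

.write_gbff <- function(truth, path) {
  entries <- vapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    shown <- unlist(r[paste0("shown_", .RANKS)])
    lin_names <- c("Metazoa", shown[2:5], shown[6])
    lin_names <- lin_names[!is.na(lin_names)]
    quals <- c(
      sprintf('                     /organism="%s"', r$raw_name)
    )
    if (!is.na(r$country)) {
      quals <- c(quals, sprintf('                     /country="%s: Locality %d"',
                                r$country, i))
    }
    if (!is.na(r$latitude)) {
      quals <- c(quals, sprintf('                     /lat_lon="%.2f N %.2f E"',
                                r$latitude, r$longitude))
    }
    seq_lines <- .gb_origin(r$sequence)
    paste(c(
      sprintf("LOCUS       %s             %d bp    DNA     linear   INV 15-DEC-2021",
              r$local_id, nchar(r$sequence)),
      sprintf("DEFINITION  %s cytochrome c oxidase subunit I (COX1) gene, partial cds.",
              r$raw_name),
      sprintf("ACCESSION   %s", r$local_id),
      sprintf("SOURCE      %s", r$raw_name),
      sprintf("  ORGANISM  %s", r$raw_name),
      sprintf("            %s.", paste(lin_names, collapse = "; ")),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", nchar(r$sequence)),
      quals,
      sprintf("     CDS             1..%d", nchar(r$sequence)),
      '                     /gene="COX1"',
      '                     /product="cytochrome c oxidase subunit I"',
      "ORIGIN      ",
      seq_lines,
      "//"
    ), collapse = "\n")
  }, "")
  # one non-CO1 entry that parsers must skip
  rrna <- paste(c(
    "LOCUS       NT000001             120 bp    DNA     linear   INV 15-DEC-2021",
    "DEFINITION  Test organism 16S ribosomal RNA gene, partial sequence.",
    "ACCESSION   NT000001",
    "SOURCE      Testus organismus",
    "  ORGANISM  Testus organismus",
    "            Metazoa; Testphylum.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    '                     /organism="Testus organismus"',
    "     rRNA            1..120",
    '                     /product="16S ribosomal RNA"',
    "ORIGIN      ",
    .gb_origin(strrep("ACGT", 30)),
    "//"
  ), collapse = "\n")
  readr::write_lines(c(entries, rrna), path)
}

.gb_origin <- function(seq) {
  starts <- seq(1, nchar(seq), 60)
  vapply(starts, function(st) {
    chunk <- substr(seq, st, min(st + 59, nchar(seq)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", st, tolower(paste(groups, collapse = " ")))
  }, "")
}

.write_bold <- function(truth, path) {
  df <- tibble::tibble(
    processid = truth$local_id,
    phylum_name = truth$shown_phylum,
    class_name = truth$shown_class,
    order_name = truth$shown_order,
    family_name = truth$shown_family,
    genus_name = truth$shown_genus,
    species_name = truth$shown_species,
    markercode = rep("COI-5P", nrow(truth)),
    nucleotides = truth$sequence,
    country = truth$country,
    lat = truth$latitude,
    lon = truth$longitude
  )
  # one non-target marker row that readers must skip
  extra <- df[1, ]
  extra$processid <- "BDRRNA1"
  extra$markercode <- "16S"
  readr::write_tsv(dplyr::bind_rows(df, extra), path, na = "",
                   progress = FALSE)
}

.write_gbol <- function(spec, truth, path) {
  df <- tibble::tibble(
    specimen_id = truth$local_id,
    kingdom = dplyr::coalesce(truth$shown_kingdom,
                              rep("Animalia", nrow(truth))),
    phylum = truth$shown_phylum,
    class = truth$shown_class,
    order = truth$shown_order,
    family = truth$shown_family,
    genus = truth$shown_genus,
    species = truth$shown_species,
    sequence = truth$sequence,
    marker = rep("COI-5P", nrow(truth)),
    country = truth$country,
    latitude = truth$latitude,
    longitude = truth$longitude,
    locality = sprintf("Site %d, plot A, near river", seq_len(nrow(truth)))
  )
  n_missing <- round(spec$missing_rank_fraction * nrow(df))
  if (n_missing > 0) df$order[seq_len(n_missing)] <- NA_character_
  readr::write_csv(df, path, na = "", progress = FALSE)
}

.build_toy_queries <- function(spec, tax, dir) {
  refs <- stats::setNames(tax$base_seqs,
                          sprintf("REF%03d", seq_len(spec$n_species)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs),
                              file.path(dir, "references.fasta"), width = 80)
  L <- spec$sequence_length
  ks <- spec$query_substitutions
  rows <- vector("list", spec$n_queries)
  qseqs <- character(spec$n_queries)
  for (i in seq_len(spec$n_queries)) {
    s <- (i - 1L) %% spec$n_species + 1L
    k <- ks[[(i - 1L) %% length(ks) + 1L]]
    pos <- if (k > 0) sample.int(L, k) else integer()
    qseqs[[i]] <- .substitute_at(tax$base_seqs[[s]], pos)
    identity <- 100 * (L - k) / L
    rows[[i]] <- tibble::tibble(
      query_id = sprintf("Q%03d", i),
      ref_id = sprintf("REF%03d", s),
      k = k,
      identity = identity,
      expected_bin = round_half_up(identity)
    )
  }
  qs <- stats::setNames(qseqs, sprintf("Q%03d", seq_len(spec$n_queries)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(qs),
                              file.path(dir, "queries.fasta"), width = 80)
  list(truth = dplyr::bind_rows(rows))
}

.write_box_geojson <- function(path) {
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(name = "Box"),
      geometry = list(
        type = "Polygon",
        coordinates = list(list(
          list(0, 0), list(1, 0), list(1, 1), list(0, 1), list(0, 0)
        ))
      )
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE)
}
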