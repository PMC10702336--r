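# quality, translation, and geographic filters

rec_row <- function(seq, resolution = "species", country = NA,
                    lat = NA_real_, lon = NA_real_) {
  tibble::tibble(
    record_id = "R1", source_db = "BOLD", original_name = "x",
    cleaned_name = "x", matched_name = NA_character_,
    matched_taxon_id = NA_character_, action = "exact",
    resolution = resolution,
    kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
    order = "Hymenoptera", family = "Apidae", genus = "Apis",
    species = "Apis mellifera",
    sequence = seq, country = country, latitude = lat, longitude = lon,
    marker = "CO1"
  )
}

test_that("quality filter applies N, length and rank rules in order", {
  cfg <- filter_config(max_N = 0, min_length = 400)
  good <- quality_filter(rec_row(strrep("ACGT", 165)), cfg)  # 660 bp
  expect_true(good$keep)
  short <- quality_filter(rec_row(paste0(strrep("ACGT", 99), "ACG")), cfg)  # 399 bp
  expect_false(short$keep)
  expect_equal(short$reason, "length")
  n1 <- quality_filter(rec_row(paste0("N", strrep("ACGT", 165))), cfg)
  expect_false(n1$keep)
  expect_equal(n1$reason, "max_N")
  fam <- quality_filter(rec_row(strrep("ACGT", 165), resolution = "family"),
                        filter_config(min_rank = "genus"))
  expect_false(fam$keep)
  expect_equal(fam$reason, "rank")
  # boundary: exactly min_length is kept
  expect_true(quality_filter(rec_row(strrep("ACGT", 100)), cfg)$keep)
  # ambiguity-code bound is separate from the N rule
  amb <- quality_filter(rec_row(paste0("RY", strrep("ACGT", 165))),
                        filter_config(max_N = 5, max_ambiguous = 1))
  expect_equal(amb$reason, "ambiguity")
})

test_that("translation filter keeps stop-free frames under the mito code", {
  # codon-wise construction without stops in frame 1
  clean <- strrep("ATGGCA", 80)
  cfg_drop <- filter_config(translation_check = "drop")
  expect_true(translation_filter(rec_row(clean), cfg_drop)$keep)
  # TAA planted at positions 1, 5 and 9, one per reading frame
  base <- strrep("ATGGCA", 70)
  s3 <- paste0("TAACTAACTAAC", base)
  res <- translation_filter(rec_row(s3), cfg_drop)
  expect_false(res$keep)
  expect_equal(res$reason, "translation")
  # warn mode annotates but keeps
  expect_warning(w <- translation_filter(rec_row(s3),
                                         filter_config(translation_check = "warn")),
                 "stop codons")
  expect_true(w$keep)
  expect_false(w$translation_ok)
  # disabled check keeps everything
  off <- translation_filter(rec_row(s3),
                            filter_config(translation_check = "off"))
  expect_true(off$keep)
})

test_that("point_in_ring matches ray-casting and winding oracles", {
  set.seed(21)
  polys <- list(
    unit = cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)),
    tri = cbind(c(0, 2, 1, 0), c(0, 0, 2, 0)),
    concave = cbind(c(0, 4, 4, 2, 2, 0, 0), c(0, 0, 4, 4, 2, 2, 0))
  )
  for (nm in names(polys)) {
    ring <- polys[[nm]]
    lon <- runif(1000, -1, 5)
    lat <- runif(1000, -1, 5)
    mine <- point_in_ring(lon, lat, ring)
    oracle <- vapply(seq_along(lon), function(i)
      winding_pip_oracle(lon[i], lat[i], ring), logical(1))
    expect_equal(mine, oracle, info = nm)
    if (requireNamespace("mgcv", quietly = TRUE)) {
      inout <- mgcv::in.out(ring, cbind(lon, lat))
      expect_equal(mine, inout, info = paste(nm, "mgcv"))
    }
  }
  # boundary counts as inside
  expect_true(point_in_ring(0.5, 0, polys$unit))
  expect_true(point_in_ring(0, 0, polys$unit))
  expect_true(point_in_ring(1, 1, polys$unit))
  expect_false(point_in_ring(1.0001, 1, polys$unit))
})

test_that("assign_region unions country and polygon labels", {
  box <- list(Box = cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
  r <- dplyr::bind_rows(
    rec_row("ACGT", country = "Germany"),
    rec_row("ACGT", lat = 0.5, lon = 0.5),
    rec_row("ACGT")
  )
  labs <- assign_region(r, polygons = box)
  expect_setequal(labs[[1]], c("Germany", "Europe", "Palearctic"))
  expect_equal(labs[[2]], "Box")
  expect_equal(labs[[3]], character())
  expect_warning(assign_region(rec_row("ACGT", country = "Atlantis")),
                 "not in gazetteer")
})

test_that("region filter keeps intersecting records, drops locationless ones", {
  r <- dplyr::bind_rows(
    rec_row("ACGT", country = "Germany"),
    rec_row("ACGT", country = "Canada"),
    rec_row("ACGT", lat = 0.5, lon = 0.5),
    rec_row("ACGT")
  )
  spec_c <- region_spec("country", names = c("Germany", "Austria"))
  expect_equal(region_filter(r, spec_c)$keep_region,
               c(TRUE, FALSE, FALSE, FALSE))
  spec_e <- region_spec("continent", names = "Europe")
  expect_equal(region_filter(r, spec_e)$keep_region,
               c(TRUE, FALSE, FALSE, FALSE))
  box <- list(Box = cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0)))
  spec_p <- region_spec("custom_polygon", polygons = box)
  expect_equal(region_filter(r, spec_p)$keep_region,
               c(FALSE, FALSE, TRUE, FALSE))
  # all-countries spec keeps exactly the records with any known location
  gaz <- default_gazetteer()
  spec_all <- region_spec("country", names = gaz$country)
  expect_equal(region_filter(r, spec_all)$keep_region,
               c(TRUE, TRUE, FALSE, FALSE))
})

test_that("GeoJSON polygons load and filter coordinate-only records", {
  fx <- toy_fixture()
  polys <- read_polygons_geojson(fx$paths$regions)
  expect_named(polys, "Box")
  r <- rec_row("ACGT", lat = 0.5, lon = 0.3)
  spec <- region_spec("custom_polygon", polygons = polys)
  expect_true(region_filter(r, spec)$keep_region)
})

test_that("filters are pure predicates: outcome independent of row order", {
  fx <- toy_fixture()
  h <- unmapped_merge(merge_sources(
    read_bold_tsv(fx$paths$bold),
    repair_ranks(read_gbol_csv(fx$paths$gbol))
  ))
  cfg <- filter_config(max_N = 0, min_length = 400)
  fwd <- quality_filter(h, cfg)
  rev_in <- h[rev(seq_len(nrow(h))), ]
  bwd <- quality_filter(rev_in, cfg)
  m <- match(fwd$record_id, bwd$record_id)
  expect_equal(fwd$keep, bwd$keep[m])
  expect_equal(fwd$reason, bwd$reason[m])
})
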