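# backbone taxonomy store: import, lookup, synonym and homonym resolution,
# ancestry projection, lowest common ancestor

write_toy_gbif <- function(path, extra = NULL) {
  rows <- c(
    "taxonID\tparentNameUsageID\tacceptedNameUsageID\tcanonicalName\ttaxonRank\ttaxonomicStatus",
    "1\t\t1\tAnimalia\tkingdom\taccepted",
    "2\t1\t2\tHymenoptera\torder\taccepted",
    "3\t2\t3\tApis\tgenus\taccepted",
    "4\t3\t4\tApis mellifera\tspecies\taccepted",
    "5\t3\t4\tApis mellifica\tspecies\tsynonym",
    extra
  )
  writeLines(rows, path)
  path
}

test_that("GBIF dump import counts nodes and synonyms", {
  store <- import_backbone(write_toy_gbif(tempfile()), "gbif")
  expect_equal(store$report$n_nodes, 5L)
  expect_equal(store$report$n_synonyms, 1L)
  expect_equal(store$report$n_skipped, 0L)

  empty <- tempfile()
  file.create(empty)
  store0 <- import_backbone(empty, "gbif")
  expect_equal(store0$report$n_nodes, 0L)
  expect_equal(nrow(tax_lookup(store0, "Apis")), 0L)
})

test_that("malformed rows are skipped with a warning, unknown dialect fatal", {
  p <- write_toy_gbif(tempfile(), extra = "\t\t\t\tspecies\taccepted")
  expect_warning(store <- import_backbone(p, "gbif"), "malformed")
  expect_equal(store$report$n_nodes, 5L)
  expect_equal(store$report$n_skipped, 1L)
  expect_error(import_backbone(p, "gbol"))
})

test_that("fixture dumps import with generator-recorded counts in both dialects", {
  fx <- toy_fixture()
  g <- import_backbone(fx$paths$backbone_gbif, "gbif")
  expect_equal(g$report$n_nodes, fx$summary$n_backbone_nodes)
  expect_equal(g$report$n_synonyms, fx$summary$n_backbone_synonyms)

  n <- import_backbone(fx$paths$backbone_ncbi, "ncbi")
  expect_equal(n$report$n_nodes, fx$summary$n_backbone_nodes)
  expect_equal(n$report$n_synonyms, fx$summary$n_backbone_synonyms)

  # every accepted name recorded by the generator is findable
  acc <- fx$taxonomy$nodes[fx$taxonomy$nodes$status == "accepted", ]
  found_g <- vapply(acc$canonical_name, function(nm)
    nrow(tax_lookup(g, nm)) >= 1L, logical(1))
  found_n <- vapply(acc$canonical_name, function(nm)
    nrow(tax_lookup(n, nm)) >= 1L, logical(1))
  expect_true(all(found_g))
  expect_true(all(found_n))
})

test_that("lookup resolves names, homonyms by context and list, misses empty", {
  store <- import_backbone(write_toy_gbif(tempfile()), "gbif")
  hit <- tax_lookup(store, "Apis", rank_hint = "genus")
  expect_equal(nrow(hit), 1L)
  expect_false(hit$ambiguous)
  expect_equal(nrow(tax_lookup(store, "Nonexistus")), 0L)
  expect_equal(nrow(tax_lookup(store, "apis mellifera")), 1L)  # case-insensitive

  # homonym genus under two kingdoms
  hom_file <- tempfile()
  writeLines(c("name\trank\tresolving_kingdom", "Morus\tgenus\tAnimalia"),
             hom_file)
  p <- write_toy_gbif(tempfile(), extra = c(
    "6\t\t6\tPlantae\tkingdom\taccepted",
    "7\t6\t7\tMorus\tgenus\taccepted",
    "8\t1\t8\tMorus\tgenus\taccepted"
  ))
  store2 <- import_backbone(p, "gbif", homonyms = hom_file)
  both <- tax_lookup(store2, "Morus")
  expect_equal(nrow(both), 1L)     # homonym list already resolves
  ctx <- tax_lookup(import_backbone(p, "gbif"), "Morus", context = "Plantae")
  expect_equal(nrow(ctx), 1L)
  expect_equal(lineage_of(import_backbone(p, "gbif"), ctx)[["kingdom"]],
               "Plantae")
  amb <- tax_lookup(import_backbone(p, "gbif"), "Morus")
  expect_equal(nrow(amb), 2L)
  expect_true(all(amb$ambiguous))
})

test_that("accepted_of resolves synonyms transitively and is idempotent", {
  store <- import_backbone(write_toy_gbif(tempfile()), "gbif")
  apis <- tax_lookup(store, "Apis mellifera")
  expect_equal(accepted_of(store, apis)$taxon_id, apis$taxon_id)
  syn <- tax_lookup(store, "Apis mellifica")
  acc <- accepted_of(store, syn)
  expect_equal(acc$canonical_name, "Apis mellifera")
  expect_equal(accepted_of(store, acc)$taxon_id, acc$taxon_id)

  # chained synonym syn -> syn -> accepted
  p <- write_toy_gbif(tempfile(), extra = c(
    "6\t3\t5\tApis chainus\tspecies\tsynonym"
  ))
  store2 <- import_backbone(p, "gbif")
  chain <- tax_lookup(store2, "Apis chainus")
  expect_equal(accepted_of(store2, chain)$canonical_name, "Apis mellifera")

  # dangling accepted_id errors naming the node
  p2 <- write_toy_gbif(tempfile(), extra = c(
    "7\t3\t99\tApis danglus\tspecies\tsynonym"
  ))
  store3 <- import_backbone(p2, "gbif")
  expect_error(accepted_of(store3, tax_lookup(store3, "Apis danglus")),
               "danglus")
})

test_that("every fixture synonym resolves to an accepted node", {
  fx <- toy_fixture()
  store <- import_backbone(fx$paths$backbone_gbif, "gbif")
  syn_rows <- store$nodes[store$nodes$status == "synonym", ]
  for (i in seq_len(nrow(syn_rows))) {
    acc <- accepted_of(store, syn_rows[i, ])
    expect_equal(acc$status, "accepted")
  }
})

test_that("lineage_of projects only the 7 standard ranks", {
  p <- write_toy_gbif(tempfile(), extra = c(
    "6\t3\t6\tApinae\tsubfamily\taccepted",
    "7\t6\t7\tApis subfam mellifera\tspecies\taccepted"
  ))
  store <- import_backbone(p, "gbif")
  lin <- lineage_of(store, tax_lookup(store, "Apis mellifera"))
  expect_equal(unname(lin[c("kingdom", "order", "genus", "species")]),
               c("Animalia", "Hymenoptera", "Apis", "Apis mellifera"))
  root <- lineage_of(store, tax_lookup(store, "Animalia"))
  expect_equal(unname(root[["kingdom"]]), "Animalia")
  expect_true(all(is.na(root[setdiff(standard_ranks(), "kingdom")])))
  # species sitting below a subfamily: the subfamily is skipped
  through <- lineage_of(store, tax_lookup(store, "Apis subfam mellifera"))
  expect_false("Apinae" %in% through)
  expect_equal(unname(through[["order"]]), "Hymenoptera")
})

test_that("species lineage in the fixture store matches generator truth", {
  fx <- toy_fixture()
  store <- import_backbone(fx$paths$backbone_gbif, "gbif")
  tr <- fx$records[fx$records$category == "normal", ][1, ]
  lin <- lineage_of(store, tax_lookup(store, tr$raw_name))
  expect_equal(unname(lin), unname(unlist(
    tr[paste0("expected_", standard_ranks())])))
})

test_that("lca truncates at the first disagreement", {
  a <- toy_prefix_lineage(genus = "Apis", species = "Apis mellifera")
  b <- toy_prefix_lineage(genus = "Apis", species = "Apis cerana")
  expect_equal(lineage_lca(a, a), a)
  got <- lineage_lca(a, b)
  expect_equal(unname(got[["genus"]]), "Apis")
  expect_true(is.na(got[["species"]]))
  c2 <- lineage(kingdom = "Plantae")
  expect_true(all(is.na(lineage_lca(a, c2))))
})

test_that("lca is commutative, idempotent, and never finer than its inputs", {
  set.seed(11)
  pool <- list(
    toy_prefix_lineage(),
    toy_prefix_lineage(genus = "Apis"),
    toy_prefix_lineage(genus = "Apis", species = "Apis mellifera"),
    toy_prefix_lineage(genus = "Bombus", species = "Bombus terrestris"),
    lineage(kingdom = "Plantae", phylum = "Tracheophyta")
  )
  depth <- function(l) {
    r <- lineage_resolution(l)
    if (is.na(r)) 0L else match(r, standard_ranks())
  }
  for (rep in 1:40) {
    a <- pool[[sample.int(length(pool), 1)]]
    b <- pool[[sample.int(length(pool), 1)]]
    ab <- lineage_lca(a, b)
    expect_equal(ab, lineage_lca(b, a))
    expect_equal(lineage_lca(ab, ab), ab)
    expect_lte(depth(ab), min(depth(a), depth(b)))
  }
})

test_that("null backbone returns no candidates", {
  none <- taxonomy_none()
  expect_equal(none$report$n_nodes, 0L)
  expect_equal(nrow(tax_lookup(none, "Apis")), 0L)
})
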