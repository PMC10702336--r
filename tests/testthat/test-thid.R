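# top-hit identity distribution: aligner, search, histogram, ranks,
# cross-coverage

test_that("pairwise identity: trivial cases and symmetry", {
  a <- strrep("ACGT", 25)
  expect_equal(pairwise_identity(a, a), 100)
  set.seed(3)
  b <- a
  for (p in c(2, 50, 99)) {
    old <- substr(b, p, p)
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  expect_equal(pairwise_identity(a, b), 97)
  set.seed(13)
  for (i in 1:10) {
    x <- random_dna(1, 60); y <- random_dna(1, 60)
    expect_equal(pairwise_identity(x, y), pairwise_identity(y, x))
  }
})

test_that("aligner agrees with an independent dynamic-programming oracle", {
  set.seed(17)
  for (i in 1:12) {
    x <- random_dna(1, 60)
    # mix of related and unrelated targets, some with indels
    y <- switch(i %% 3 + 1,
      random_dna(1, 60),
      paste0(substr(x, 1, 25), substr(x, 31, 60)),          # 5-base deletion
      paste0(substr(x, 1, 40), "GGGGG", substr(x, 41, 60))  # 5-base insertion
    )
    got <- align_params()
    mine <- barcoderef:::align_identity_cpp(x, y)
    oracle <- nw_identity_oracle(x, y)
    expect_equal(mine$score, oracle$score, info = i)
    expect_equal(mine$identity, oracle$identity, tolerance = 1e-9, info = i)
  }
})

test_that("alignment score matches Biostrings pairwiseAlignment", {
  set.seed(19)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -4,
                                                  baseOnly = TRUE)
  for (i in 1:8) {
    x <- random_dna(1, 80)
    y <- if (i %% 2) random_dna(1, 80) else
      paste0(substr(x, 1, 30), substr(x, 36, 80))
    al <- Biostrings::pairwiseAlignment(x, y, type = "global",
                                        substitutionMatrix = mat,
                                        gapOpening = 20, gapExtension = 2)
    mine <- barcoderef:::align_identity_cpp(x, y)
    expect_equal(mine$score, Biostrings::score(al), info = i)
  }
})

test_that("top_hit_search equals the brute-force all-pairs oracle", {
  set.seed(23)
  refs <- stats::setNames(random_dna(20, 120), sprintf("R%02d", 1:20))
  queries <- lapply(1:50, function(i) {
    src <- sample(20, 1)
    k <- sample(0:8, 1)
    s <- refs[[src]]
    pos <- if (k) sample(120, k) else integer()
    for (p in pos) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  })
  queries <- stats::setNames(unlist(queries), sprintf("Q%02d", 1:50))
  th <- top_hit_search(queries, refs, threshold = 0.7)

  # oracle: full identity matrix + independent best-hit selection
  idm <- matrix(NA_real_, 50, 20, dimnames = list(names(queries), names(refs)))
  for (q in seq_len(50)) {
    for (r in seq_len(20)) {
      idm[q, r] <- pairwise_identity(queries[[q]], refs[[r]])
    }
  }
  ref_order <- sort(names(refs))
  for (q in seq_len(50)) {
    ids <- idm[q, ref_order]
    ok <- ids >= 70
    row <- th$hits[th$hits$query_id == names(queries)[q], ]
    if (!any(ok)) {
      expect_true(is.na(row$target_id))
    } else {
      best <- ref_order[which(ids == max(ids[ok]) & ok)][1]
      expect_equal(row$target_id, best)
      expect_equal(row$identity, max(ids[ok]))
    }
  }
  # histogram mass equals queries with hits
  expect_equal(sum(th$histogram$n), sum(!is.na(th$hits$identity)))
})

test_that("identical query and reference give a 100% hit, below-threshold none", {
  refs <- c(ref1 = strrep("ACGGTTCA", 20))
  th <- top_hit_search(c(q = refs[["ref1"]]), refs)
  expect_equal(th$hits$target_id, "ref1")
  expect_equal(th$hits$identity, 100)
  set.seed(29)
  far <- top_hit_search(c(q = random_dna(1, 160)), refs, threshold = 0.95)
  expect_true(is.na(far$hits$target_id))
})

test_that("histogram bins round half-up and conserve mass", {
  h <- thid_histogram(c(99.5, 99.49, 98.4, NA, 100))
  expect_equal(h$identity, c(98L, 99L, 100L))
  expect_equal(h$n, c(1L, 1L, 2L))
  expect_equal(sum(h$n), 4L)
  expect_equal(nrow(thid_histogram(c(NA_real_, NA_real_))), 0L)
})

test_that("dense ranks replace ties by their minimum", {
  expect_equal(unname(dense_ranks(c(5, 10, 20, 20))), c(1L, 2L, 3L, 3L))
  expect_equal(unname(dense_ranks(c(7, 7, 7))), c(1L, 1L, 1L))
  expect_equal(unname(dense_ranks(c(1, 2, 3, 4))), 1:4)
  # permutation-invariant up to label alignment
  x <- c(a = 4, b = 9, c = 9, d = 1)
  p <- c("d", "b", "a", "c")
  expect_equal(dense_ranks(x)[p], dense_ranks(x[p]))
})

test_that("subsample cross-coverage: identical databases hit only at 100", {
  set.seed(31)
  seqs <- stats::setNames(random_dna(12, 100), sprintf("S%02d", 1:12))
  res <- subsample_cross_coverage(list(db1 = seqs, db2 = seqs), n = 6,
                                  reps = 3, seed = 99)
  s <- res$summary
  expect_equal(s$mean_hits[s$identity == 100], c(6, 6))
  expect_equal(s$mean_hits[s$identity %in% c(98, 99)], rep(0, 4))
  expect_equal(s$sd_hits[s$identity == 100], c(0, 0))
  # unrelated databases at threshold 0.7 give ~no hits anywhere
  other <- stats::setNames(random_dna(12, 100), sprintf("T%02d", 1:12))
  res2 <- subsample_cross_coverage(list(a = seqs, b = other), n = 6,
                                   reps = 2, seed = 7)
  expect_true(all(res2$summary$mean_hits <= 1))
  expect_error(subsample_cross_coverage(list(a = seqs, b = other), n = 50),
               "exceeds")
})

test_that("one-substitution copies of 150-mers concentrate at bin 99", {
  set.seed(37)
  refs <- stats::setNames(random_dna(10, 150), sprintf("R%02d", 1:10))
  mutated <- vapply(refs, function(s) {
    p <- sample(150, 1)
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    s
  }, "")
  names(mutated) <- sprintf("M%02d", 1:10)
  res <- subsample_cross_coverage(list(orig = refs, mut = mutated), n = 10,
                                  reps = 2, seed = 3)
  s <- res$summary
  # 149/150 = 99.33 rounds to 99
  expect_equal(s$mean_hits[s$identity == 99], c(10, 10))
  expect_equal(s$mean_hits[s$identity == 100], c(0, 0))
})

test_that("tidy, glance and autoplot work on thid tables", {
  refs <- c(r1 = strrep("ACGT", 30))
  th <- top_hit_search(c(q1 = refs[["r1"]]), refs)
  expect_s3_class(tidy(th), "tbl_df")
  g <- glance(th)
  expect_equal(g$n_hits, 1L)
  expect_equal(g$hits_100, 1L)
  p <- ggplot2::autoplot(th)
  expect_s3_class(p, "ggplot")
})
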