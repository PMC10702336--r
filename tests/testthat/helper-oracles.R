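# Independent oracles used across the suite. Each is written from the
# definition, not from the package implementation it checks.

# --- global alignment identity oracle (pure-R Gotoh with traceback) -------
# Returns list(score, identity) under the same scoring convention as
# align_params(): positive gap penalty magnitudes, terminal gap columns
# excluded from the identity denominator.
nw_identity_oracle <- function(a, b, match = 2, mismatch = -4,
                               gap_open = 20, gap_extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEGI <- -1e18
  M <- matrix(NEGI, n + 1, m + 1)
  X <- matrix(NEGI, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(NEGI, n + 1, m + 1)  # gap in a (horizontal)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + gap_extend * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + gap_extend * (j - 1))
  tb <- array("", dim = c(n + 1, m + 1, 3))
  tb[, 1, 2] <- "X"; tb[1, , 3] <- "Y"
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      opts <- c(M = M[i - 1, j - 1], X = X[i - 1, j - 1], Y = Y[i - 1, j - 1])
      M[i, j] <- max(opts) + s
      tb[i, j, 1] <- names(opts)[which.max(opts)]
      opts <- c(M = M[i - 1, j] - gap_open - gap_extend,
                X = X[i - 1, j] - gap_extend,
                Y = Y[i - 1, j] - gap_open - gap_extend)
      X[i, j] <- max(opts)
      tb[i, j, 2] <- names(opts)[which.max(opts)]
      opts <- c(M = M[i, j - 1] - gap_open - gap_extend,
                Y = Y[i, j - 1] - gap_extend,
                X = X[i, j - 1] - gap_open - gap_extend)
      Y[i, j] <- max(opts)
      tb[i, j, 3] <- names(opts)[which.max(opts)]
    }
  }
  finals <- c(M = M[n + 1, m + 1], X = X[n + 1, m + 1], Y = Y[n + 1, m + 1])
  state <- names(finals)[which.max(finals)]
  # traceback into aligned strings
  ai <- character(); bi <- character()
  i <- n + 1; j <- m + 1
  while (i > 1 || j > 1) {
    k <- match(state, c("M", "X", "Y"))
    nxt <- tb[i, j, k]
    if (state == "M") {
      ai <- c(av[i - 1], ai); bi <- c(bv[j - 1], bi); i <- i - 1; j <- j - 1
    } else if (state == "X") {
      ai <- c(av[i - 1], ai); bi <- c("-", bi); i <- i - 1
    } else {
      ai <- c("-", ai); bi <- c(bv[j - 1], bi); j <- j - 1
    }
    state <- nxt
  }
  gap <- ai == "-" | bi == "-"
  interior <- rep(TRUE, length(ai))
  r <- rle(gap)
  if (length(r$lengths) && r$values[1]) interior[seq_len(r$lengths[1])] <- FALSE
  if (length(r$lengths) > 1 && r$values[length(r$values)]) {
    interior[seq(length(gap) - r$lengths[length(r$lengths)] + 1, length(gap))] <- FALSE
  }
  cols <- sum(interior)
  matches <- sum(interior & ai == bi)
  list(score = unname(max(finals)),
       identity = if (cols > 0) 100 * matches / cols else 0)
}

# --- point-in-polygon oracle (winding number) -----------------------------
winding_pip_oracle <- function(lon, lat, ring) {
  ring <- as.matrix(ring)
  if (all(ring[1, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  n <- nrow(ring)
  wn <- 0
  for (i in seq_len(n)) {
    j <- i %% n + 1
    x1 <- ring[i, 1]; y1 <- ring[i, 2]; x2 <- ring[j, 1]; y2 <- ring[j, 2]
    isleft <- (x2 - x1) * (lat - y1) - (lon - x1) * (y2 - y1)
    if (y1 <= lat) {
      if (y2 > lat && isleft > 0) wn <- wn + 1
    } else {
      if (y2 <= lat && isleft < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# --- dereplication decision-table oracle ----------------------------------
# members: list of lineage vectors (one per record, duplicates allowed).
# Hand-coded cascade from the stated rules: (a) all pairwise consistent ->
# deepest; (b) unique plurality over distinct lineages -> winner; (c) tie
# -> LCA of the tied lineages.
derep_oracle <- function(members) {
  keys <- vapply(members, function(l) paste(ifelse(is.na(l), ".", l),
                                            collapse = "|"), "")
  counts <- table(keys)
  distinct <- members[!duplicated(keys)]
  names(distinct) <- keys[!duplicated(keys)]
  depth_of <- function(l) {
    f <- which(!is.na(l))
    if (length(f)) max(f) else 0L
  }
  consistent <- TRUE
  if (length(distinct) > 1) {
    for (p in seq_along(distinct)) {
      for (q in seq_along(distinct)) {
        if (p < q) {
          l1 <- distinct[[p]]; l2 <- distinct[[q]]
          both <- !is.na(l1) & !is.na(l2)
          if (any(l1[both] != l2[both])) consistent <- FALSE
        }
      }
    }
  }
  if (consistent) {
    depths <- vapply(distinct, depth_of, 0L)
    return(distinct[[which.max(depths)]])
  }
  cnt <- as.integer(counts[names(distinct)])
  mx <- max(cnt)
  tied <- which(cnt == mx)
  if (length(tied) == 1) return(distinct[[tied]])
  out <- distinct[[tied[1]]]
  for (t in tied[-1]) out <- lineage_lca(out, distinct[[t]])
  out
}

# build a harmonized-like table from lineage vectors for dereplicate()
members_table <- function(lins, seq = "ACGT", ids = NULL) {
  n <- length(lins)
  if (is.null(ids)) ids <- sprintf("R%02d", seq_len(n))
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(
      record_id = ids[[i]], source_db = "BOLD",
      original_name = "x", cleaned_name = "x",
      matched_name = NA_character_, matched_taxon_id = NA_character_,
      action = "exact",
      resolution = lineage_resolution(lins[[i]]),
      !!!as.list(lins[[i]]),
      sequence = seq, country = NA_character_,
      latitude = NA_real_, longitude = NA_real_, marker = "CO1"
    )
  }))
}

# small prefix-style lineages used in dereplication enumerations
toy_prefix_lineage <- function(genus = NA, species = NA) {
  lineage(kingdom = "Animalia", phylum = "Arthropoda", class = "Insecta",
          order = "Hymenoptera", family = "Apidae",
          genus = if (is.na(genus)) NULL else genus,
          species = if (is.na(species)) NULL else species)
}

# random DNA
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# shared small fixture, generated once per test run
toy_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixtures(fixture_spec(seed = 42),
                                  dir = file.path(tempdir(), "barcoderef_fx42"))
    }
    cache
  }
})
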