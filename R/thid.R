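# Top-hit identity distribution (THID) benchmark: how well a reference
# database covers a query set, measured as the histogram of best-hit
# percent identities.

# accept a FASTA path, a DNAStringSet, or a named character vector
.as_seqs <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      is.null(names(x))) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  toupper(x)
}

#' Alignment scoring parameters
#'
#' Defaults mirror the usual nucleotide settings of usearch-style global
#' aligners: match +2, mismatch -4, gap open 20, gap extend 2 (penalties
#' are positive magnitudes). Identity is computed from the optimal
#' alignment and does not depend on the score scale beyond which alignment
#' is optimal.
#'
#' @param match,mismatch match reward and mismatch penalty.
#' @param gap_open,gap_extend affine gap penalties (positive magnitudes);
#'   a gap of length L costs `gap_open + gap_extend * L`.
#' @return List of scoring parameters.
#' @export
align_params <- function(match = 2, mismatch = -4, gap_open = 20,
                         gap_extend = 2) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend)
}

#' Global-alignment percent identity of two sequences
#'
#' Aligns the two sequences globally (affine gap penalties, Gotoh
#' algorithm) and reports 100 x matching columns / alignment columns, with
#' terminal gap columns excluded from the column count. Symmetric in its
#' arguments.
#'
#' @param query,target DNA sequences (character scalars).
#' @param params scoring parameters from [align_params()].
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")
pairwise_identity <- function(query, target, params = align_params()) {
  al <- align_identity_cpp(toupper(query), toupper(target),
                           match = params$match, mismatch = params$mismatch,
                           gap_open = params$gap_open,
                           gap_extend = params$gap_extend)
  al$identity
}

# half-up rounding to integer percent
round_half_up <- function(x) floor(x + 0.5)

#' Top-hit search of a query set against a reference database
#'
#' Every query is aligned against every reference (exact exhaustive scan,
#' no heuristic pruning, so the reported hit is the true best hit). The
#' single best hit with identity at or above `threshold` is kept per query;
#' equal-identity ties are broken toward the lexicographically smallest
#' reference id. Queries with no qualifying hit are recorded with `NA`.
#'
#' @param queries,refs FASTA path, `DNAStringSet`, or named character
#'   vector of DNA sequences.
#' @param threshold minimum identity as a fraction (default 0.7).
#' @param params scoring parameters from [align_params()].
#' @return A `thid_table`: list with `hits` (tibble `query_id`,
#'   `target_id`, `identity`), `histogram` (tibble `identity` integer
#'   percent, `n`), and `threshold`. Use [tidy()], [glance()],
#'   [autoplot()] on it.
#' @export
top_hit_search <- function(queries, refs, threshold = 0.7,
                           params = align_params()) {
  q <- .as_seqs(queries)
  r <- .as_seqs(refs)
  r <- r[order(names(r))]   # ties break toward the smallest reference id
  res <- lapply(seq_along(q), function(i) {
    hit <- best_hit_cpp(q[[i]], unname(r), 100 * threshold,
                        match = params$match, mismatch = params$mismatch,
                        gap_open = params$gap_open,
                        gap_extend = params$gap_extend)
    tibble::tibble(
      query_id = names(q)[[i]],
      target_id = if (hit$index > 0) names(r)[[hit$index]] else NA_character_,
      identity = if (hit$index > 0) hit$identity else NA_real_
    )
  })
  hits <- dplyr::bind_rows(res)
  structure(
    list(hits = hits, histogram = thid_histogram(hits$identity),
         threshold = threshold),
    class = "thid_table"
  )
}

#' Integer-binned identity histogram
#'
#' Identities are rounded half-up to integer percent and tallied; `NA`
#' (queries without a hit) are dropped, so the histogram mass equals the
#' number of queries with at least one hit.
#'
#' @param identities numeric vector of percent identities (may contain NA).
#' @return Tibble with columns `identity` (integer) and `n`.
#' @export
thid_histogram <- function(identities) {
  ids <- round_half_up(identities[!is.na(identities)])
  if (!length(ids)) {
    return(tibble::tibble(identity = integer(), n = integer()))
  }
  tab <- table(ids)
  tibble::tibble(identity = as.integer(names(tab)), n = as.integer(tab))
}

#' @export
print.thid_table <- function(x, ...) {
  cat("<thid_table>", nrow(x$hits), "queries,",
      sum(!is.na(x$hits$identity)), "with a hit at >=",
      100 * x$threshold, "% identity\n")
  print(x$histogram, n = 10)
  invisible(x)
}

#' @export
#' @method tidy thid_table
tidy.thid_table <- function(x, ...) x$hits

#' @export
#' @method glance thid_table
glance.thid_table <- function(x, ...) {
  ids <- x$hits$identity
  bins <- round_half_up(ids[!is.na(ids)])
  tibble::tibble(
    n_queries = nrow(x$hits),
    n_hits = sum(!is.na(ids)),
    mean_identity = if (length(bins)) mean(ids, na.rm = TRUE) else NA_real_,
    hits_100 = sum(bins == 100),
    hits_99 = sum(bins == 99),
    hits_98 = sum(bins == 98),
    threshold = x$threshold
  )
}

#' @export
#' @method autoplot thid_table
autoplot.thid_table <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$identity, y = .data$n)) +
    ggplot2::geom_step(direction = "mid") +
    ggplot2::labs(x = "identity (%)", y = "best hits",
                  title = "Top-hit identity distribution") +
    ggplot2::theme_minimal()
}

#' Dense ranks of per-database hit counts
#'
#' Ascending dense ranking of the number of 100%-identity best hits per
#' reference database: the fewest hits get rank 1, equal counts share a
#' rank (ties are replaced by their minimum), and ranks increase by one per
#' distinct value. With counts (5, 10, 20, 20) the two tied databases both
#' get rank 3 instead of ranks 3 and 4.
#'
#' @param hit_counts numeric vector, one count per database.
#' @return Integer ranks, same length and names as `hit_counts`.
#' @export
#' @examples
#' dense_ranks(c(db_a = 5, db_b = 10, db_c = 20, db_d = 20))
dense_ranks <- function(hit_counts) {
  stats::setNames(dplyr::dense_rank(hit_counts), names(hit_counts))
}

#' Subsample cross-coverage between reference databases
#'
#' For every target database, `reps` subsamples of `n` sequences are drawn
#' (without replacement, seeded) from each *other* database and searched
#' against the target; the hits whose identities round to 100, 99 and 98
#' percent are tallied. The per-target mean and standard deviation across
#' subsamples measure how completely one database covers the sequences of
#' the others.
#'
#' @param dbs named list of databases (FASTA paths, `DNAStringSet`s, or
#'   named character vectors).
#' @param n subsample size; must not exceed the smallest source database.
#' @param reps subsamples per (source, target) pair.
#' @param seed integer seed for the subsampling.
#' @param threshold minimum identity fraction for the search.
#' @param params scoring parameters.
#' @return List with `detail` (one row per target, source, replicate and
#'   identity bin) and `summary` (mean and sd of hits per target database
#'   and bin).
#' @export
subsample_cross_coverage <- function(dbs, n, reps = 10, seed = 1,
                                     threshold = 0.7,
                                     params = align_params()) {
  seqs <- lapply(dbs, .as_seqs)
  too_small <- names(seqs)[vapply(seqs, length, 0L) < n]
  if (length(too_small)) {
    stop("subsample size ", n, " exceeds database size for: ",
         paste(too_small, collapse = ", "))
  }
  rng <- .seeded_rng(seed)
  detail <- list()
  for (target in names(seqs)) {
    for (src in setdiff(names(seqs), target)) {
      for (rep_i in seq_len(reps)) {
        idx <- .rng_sample(rng, length(seqs[[src]]), n)
        th <- top_hit_search(seqs[[src]][idx], seqs[[target]],
                             threshold = threshold, params = params)
        bins <- round_half_up(th$hits$identity)
        for (b in c(100L, 99L, 98L)) {
          detail[[length(detail) + 1L]] <- tibble::tibble(
            target_db = target, source_db = src, rep = rep_i,
            identity = b, hits = sum(bins == b, na.rm = TRUE)
          )
        }
      }
    }
  }
  detail <- dplyr::bind_rows(detail)
  summary <- detail |>
    dplyr::group_by(.data$target_db, .data$identity) |>
    dplyr::summarise(mean_hits = mean(.data$hits),
                     sd_hits = stats::sd(.data$hits), .groups = "drop")
  list(detail = detail, summary = summary)
}

# local RNG so benchmark subsampling never disturbs the caller's RNG state
.seeded_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  env
}

.rng_sample <- function(rng, n_total, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  out <- sample.int(n_total, n)
  rng$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  out
}
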