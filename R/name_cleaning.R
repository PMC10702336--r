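#' Default open-nomenclature token list
#'
#' Reads the token list shipped with the package (one token per line, `#`
#' comments). Tokens are qualifiers such as `cf.`, `aff.`, `sp.` that mark an
#' uncertain identification; the name parts they qualify are not reliable
#' and are dropped during cleaning.
#'
#' @param path optional path to a user token list in the same format.
#' @return Character vector of tokens.
#' @export
open_nomenclature_tokens <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "open_nomenclature.txt", package = "barcoderef")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

# canonical token form: lowercase, trailing period stripped
.token_key <- function(x) sub("\\.$", "", tolower(x))

#' Clean taxon names
#'
#' Strips the parts of a taxon name whose identification was not certain:
#' digits are erased everywhere; the first open-nomenclature qualifier and
#' everything after it are dropped (in "Apis cf. mellifera" the epithet
#' after "cf." is an uncertain identification, so cleaning yields "Apis");
#' hybrid markers and stray punctuation are removed; whitespace is
#' normalized. The result contains only letters, spaces and hyphens and may
#' legitimately be empty.
#'
#' @param name character vector of raw taxon names.
#' @param tokens open-nomenclature token list; defaults to
#'   [open_nomenclature_tokens()]. Matching is case-insensitive and a
#'   trailing period is optional.
#' @return Tibble with columns `original`, `cleaned`, and list-column
#'   `removed_tokens`.
#' @export
#' @examples
#' clean_name(c("Apis cf. mellifera", "Bombus sp. 2", "Apis mellifera"))
clean_name <- function(name, tokens = open_nomenclature_tokens()) {
  keys <- .token_key(tokens)
  one <- function(orig) {
    if (is.na(orig)) {
      return(list(cleaned = NA_character_, removed = character()))
    }
    toks <- strsplit(trimws(orig), "\\s+")[[1]]
    kept <- character()
    removed <- character()
    for (i in seq_along(toks)) {
      tk <- toks[[i]]
      if (.token_key(tk) %in% keys) {
        # qualifier: drop it and every following token
        removed <- c(removed, toks[seq(i, length(toks))])
        break
      }
      stripped <- gsub("[0-9×]", "", tk)  # digits and hybrid sign
      stripped <- gsub("[^A-Za-zÀ-ÖØ-ɏ -]", "", stripped)
      if (!identical(stripped, tk)) removed <- c(removed, tk)
      if (nzchar(stripped)) kept <- c(kept, stripped)
    }
    list(cleaned = trimws(paste(kept, collapse = " ")), removed = removed)
  }
  res <- lapply(name, one)
  tibble::tibble(
    original = name,
    cleaned = vapply(res, function(x) x$cleaned, ""),
    removed_tokens = lapply(res, function(x) x$removed)
  )
}

#' Split a cleaned name into genus and epithet
#'
#' One token gives a genus part only; two tokens give genus plus epithet;
#' extra tokens (subspecific epithets, author fragments that survived
#' cleaning) are reported as `remainder` and not used.
#'
#' @param cleaned character vector of cleaned names.
#' @return Tibble with columns `genus_part`, `epithet`, `remainder`.
#' @export
parse_binomial <- function(cleaned) {
  one <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) {
      return(c(NA_character_, NA_character_, NA_character_))
    }
    toks <- strsplit(trimws(x), "\\s+")[[1]]
    c(toks[1],
      if (length(toks) >= 2) toks[2] else NA_character_,
      if (length(toks) > 2) paste(toks[-(1:2)], collapse = " ") else NA_character_)
  }
  m <- t(vapply(cleaned, one, character(3), USE.NAMES = FALSE))
  tibble::tibble(
    genus_part = m[, 1], epithet = m[, 2], remainder = m[, 3]
  )
}
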