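#' Import a backbone taxonomy dump
#'
#' Reads a backbone taxonomy from a local dump file into an indexed in-memory
#' store used for name harmonization. Two dialects are supported: a
#' GBIF-backbone-style TSV (columns `taxonID`, `parentNameUsageID`,
#' `acceptedNameUsageID`, `canonicalName`, `taxonRank`, `taxonomicStatus`)
#' and an NCBI-taxdump-style pair of pipe-delimited files (`nodes.dmp`,
#' `names.dmp`); for the latter pass the directory that contains both files.
#' Synonym rows become their own nodes pointing at the accepted node via
#' `accepted_id`. Name lookups are served from a hash index, so query cost
#' does not depend on dump order or size.
#'
#' @param dump_path path to the GBIF-style TSV, or to the directory holding
#'   `nodes.dmp` and `names.dmp` for the NCBI dialect. Gzipped TSV accepted.
#' @param dialect `"gbif"` or `"ncbi"`.
#' @param homonyms optional path to a homonym list: a 3-column TSV
#'   (`name`, `rank`, `resolving_kingdom`) used to disambiguate identical
#'   names applied to different taxa (e.g. a genus name used in both
#'   Animalia and Plantae).
#' @return A `taxonomy_store` object. Its `report` element counts nodes
#'   imported, synonyms among them, and malformed rows skipped.
#' @seealso [tax_lookup()], [accepted_of()], [lineage_of()], [taxonomy_none()]
#' @export
import_backbone <- function(dump_path, dialect = c("gbif", "ncbi"),
                            homonyms = NULL) {
  dialect <- match.arg(dialect)
  nodes <- switch(dialect,
    gbif = .import_gbif(dump_path),
    ncbi = .import_ncbi(dump_path)
  )
  hom <- NULL
  if (!is.null(homonyms)) {
    hom <- readr::read_tsv(homonyms, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    names(hom) <- c("name", "rank", "resolving_kingdom")[seq_along(names(hom))]
  }
  .build_store(nodes$nodes, source = dialect, homonyms = hom,
               n_skipped = nodes$n_skipped)
}

#' Null backbone (no harmonization authority)
#'
#' A store that contains no nodes: every lookup returns zero candidates.
#' Use together with unmapped (pass-through) harmonization when no backbone
#' taxonomy should be imposed on the records.
#'
#' @return An empty `taxonomy_store`.
#' @export
taxonomy_none <- function() {
  .build_store(.empty_nodes(), source = "none", homonyms = NULL, n_skipped = 0L)
}

.empty_nodes <- function() {
  tibble::tibble(
    taxon_id = character(), canonical_name = character(),
    rank = character(), status = character(),
    parent_id = character(), accepted_id = character()
  )
}

.norm_rank <- function(rank) {
  r <- tolower(trimws(rank))
  ifelse(r %in% .RANKS, r, "other")
}

.norm_status <- function(status) {
  s <- tolower(trimws(status))
  out <- rep("accepted", length(s))
  out[grepl("synonym", s)] <- "synonym"
  out[s %in% c("doubtful", "misapplied")] <- "doubtful"
  out
}

.import_gbif <- function(path) {
  if (file.exists(path) && file.size(path) == 0) {
    return(list(nodes = .empty_nodes(), n_skipped = 0L))
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE, na = c("", "NA"))
  need <- c("taxonID", "canonicalName", "taxonRank", "taxonomicStatus")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("GBIF dump lacks column(s): ", paste(miss, collapse = ", "))
  bad <- is.na(df$taxonID) | is.na(df$canonicalName)
  if (any(bad)) {
    warning(sum(bad), " malformed backbone row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  status <- .norm_status(df$taxonomicStatus)
  acc <- if ("acceptedNameUsageID" %in% names(df)) df$acceptedNameUsageID else NA_character_
  nodes <- tibble::tibble(
    taxon_id = df$taxonID,
    canonical_name = df$canonicalName,
    rank = .norm_rank(df$taxonRank),
    status = status,
    parent_id = if ("parentNameUsageID" %in% names(df)) df$parentNameUsageID else NA_character_,
    accepted_id = ifelse(status == "synonym" & !is.na(acc), acc, df$taxonID)
  )
  list(nodes = nodes, n_skipped = sum(bad))
}

.read_dmp <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t\\|\t")
  parts
}

.import_ncbi <- function(dir) {
  nodes_path <- file.path(dir, "nodes.dmp")
  names_path <- file.path(dir, "names.dmp")
  if (!file.exists(nodes_path) || !file.exists(names_path)) {
    stop("NCBI dialect expects a directory containing nodes.dmp and names.dmp")
  }
  np <- .read_dmp(nodes_path)
  n_skipped <- sum(lengths(np) < 3L)
  np <- np[lengths(np) >= 3L]
  node_tab <- tibble::tibble(
    taxon_id = vapply(np, function(x) trimws(x[[1]]), ""),
    parent_id = vapply(np, function(x) trimws(x[[2]]), ""),
    rank = .norm_rank(vapply(np, function(x) x[[3]], ""))
  )
  # NCBI roots are self-parented; normalize to NA
  node_tab$parent_id[node_tab$parent_id == node_tab$taxon_id] <- NA_character_

  nm <- .read_dmp(names_path)
  nm <- nm[lengths(nm) >= 3L]
  name_tab <- tibble::tibble(
    taxon_id = vapply(nm, function(x) trimws(x[[1]]), ""),
    name = vapply(nm, function(x) trimws(x[[2]]), ""),
    class = vapply(nm, function(x) trimws(x[[length(x)]]), "")
  )
  sci <- name_tab[name_tab$class == "scientific name", ]
  syn <- name_tab[name_tab$class %in% c("synonym", "equivalent name"), ]

  accepted <- dplyr::left_join(node_tab, sci[, c("taxon_id", "name")],
                               by = "taxon_id")
  keep <- !is.na(accepted$name)
  n_skipped <- n_skipped + sum(!keep)
  accepted <- accepted[keep, ]
  acc_nodes <- tibble::tibble(
    taxon_id = accepted$taxon_id,
    canonical_name = accepted$name,
    rank = accepted$rank,
    status = "accepted",
    parent_id = accepted$parent_id,
    accepted_id = accepted$taxon_id
  )
  syn_nodes <- NULL
  if (nrow(syn)) {
    syn <- syn[syn$taxon_id %in% acc_nodes$taxon_id, ]
    rank_of <- stats::setNames(acc_nodes$rank, acc_nodes$taxon_id)
    syn_nodes <- tibble::tibble(
      taxon_id = paste0(syn$taxon_id, "#syn", seq_len(nrow(syn))),
      canonical_name = syn$name,
      rank = unname(rank_of[syn$taxon_id]),
      status = "synonym",
      parent_id = NA_character_,
      accepted_id = syn$taxon_id
    )
  }
  list(nodes = dplyr::bind_rows(acc_nodes, syn_nodes), n_skipped = n_skipped)
}

.build_store <- function(nodes, source, homonyms, n_skipped) {
  nodes$source <- rep(source, nrow(nodes))
  idx_name <- new.env(parent = emptyenv(), size = max(16L, nrow(nodes)))
  idx_id <- new.env(parent = emptyenv(), size = max(16L, nrow(nodes)))
  if (nrow(nodes)) {
    keys <- tolower(nodes$canonical_name)
    for (i in seq_len(nrow(nodes))) {
      k <- keys[[i]]
      idx_name[[k]] <- c(idx_name[[k]], i)
    }
    for (i in seq_len(nrow(nodes))) idx_id[[nodes$taxon_id[[i]]]] <- i
  }
  structure(
    list(
      nodes = nodes, idx_name = idx_name, idx_id = idx_id,
      homonyms = homonyms, source = source,
      report = list(
        n_nodes = nrow(nodes),
        n_synonyms = sum(nodes$status == "synonym"),
        n_skipped = n_skipped
      )
    ),
    class = "taxonomy_store"
  )
}

#' @export
print.taxonomy_store <- function(x, ...) {
  cat("<taxonomy_store> source:", x$source,
      "| nodes:", x$report$n_nodes,
      "| synonyms:", x$report$n_synonyms,
      "| skipped rows:", x$report$n_skipped, "\n")
  invisible(x)
}

.node_by_id <- function(store, taxon_id) {
  i <- store$idx_id[[taxon_id]]
  if (is.null(i)) return(NULL)
  store$nodes[i, , drop = FALSE]
}

#' Look up a taxon name in a backbone store
#'
#' Exact, case-insensitive match on canonical names. When several nodes share
#' the name (a homonym), candidates are narrowed in order by `rank_hint`,
#' then by `context` (a candidate whose ancestry contains the context name
#' wins), then by the imported homonym list (matching the candidate's
#' kingdom against the list's resolving kingdom). Candidates that remain
#' plural are returned flagged `ambiguous`.
#'
#' @param store a `taxonomy_store`.
#' @param name taxon name to find.
#' @param rank_hint optional rank the name is expected to have.
#' @param context optional higher-taxon name known to contain the target.
#' @return Tibble of candidate nodes (possibly empty) with a logical
#'   `ambiguous` column.
#' @export
tax_lookup <- function(store, name, rank_hint = NULL, context = NULL) {
  stopifnot(inherits(store, "taxonomy_store"))
  hits <- store$idx_name[[tolower(trimws(name))]]
  if (is.null(hits)) {
    return(dplyr::mutate(.empty_nodes(), source = character(), ambiguous = logical()))
  }
  cand <- store$nodes[hits, , drop = FALSE]
  if (nrow(cand) > 1L && !is.null(rank_hint)) {
    sub <- cand[cand$rank == .norm_rank(rank_hint), , drop = FALSE]
    if (nrow(sub)) cand <- sub
  }
  if (nrow(cand) > 1L && !is.null(context) && nzchar(context)) {
    in_ctx <- vapply(seq_len(nrow(cand)), function(i) {
      anc <- .ancestor_names(store, cand[i, , drop = FALSE])
      tolower(context) %in% tolower(anc)
    }, logical(1))
    if (any(in_ctx)) cand <- cand[in_ctx, , drop = FALSE]
  }
  if (nrow(cand) > 1L && !is.null(store$homonyms)) {
    hl <- store$homonyms
    row <- hl[tolower(hl$name) == tolower(name), , drop = FALSE]
    if (nrow(row)) {
      want <- tolower(row$resolving_kingdom[[1]])
      in_k <- vapply(seq_len(nrow(cand)), function(i) {
        lin <- lineage_of(store, cand[i, , drop = FALSE])
        identical(tolower(lin[["kingdom"]]), want)
      }, logical(1))
      if (any(in_k)) cand <- cand[in_k, , drop = FALSE]
    }
  }
  cand$ambiguous <- rep(nrow(cand) > 1L, nrow(cand))
  cand
}

# names on the parent chain of a node (accepted partner's chain for synonyms)
.ancestor_names <- function(store, node) {
  node <- accepted_of(store, node)
  out <- character()
  cur <- node
  depth <- 0L
  while (!is.null(cur) && depth < 100L) {
    out <- c(out, cur$canonical_name[[1]])
    pid <- cur$parent_id[[1]]
    if (is.na(pid) || !nzchar(pid)) break
    cur <- .node_by_id(store, pid)
    depth <- depth + 1L
  }
  out
}

#' Resolve a node to its accepted name node
#'
#' Accepted nodes return themselves; synonym nodes are followed through
#' `accepted_id`, transitively (chains are bounded at depth 10 and cycles
#' are an error). A dangling `accepted_id` is an error naming the node.
#'
#' @param store a `taxonomy_store`.
#' @param node a one-row node tibble (as returned by [tax_lookup()]) or a
#'   `taxon_id` string.
#' @return One-row node tibble with `status == "accepted"` (or doubtful
#'   nodes, which stand for themselves).
#' @export
accepted_of <- function(store, node) {
  if (is.character(node)) node <- .node_by_id(store, node)
  if (is.null(node) || !nrow(node)) stop("node not in store")
  cur <- node[1, , drop = FALSE]
  for (i in seq_len(10L)) {
    if (cur$status[[1]] != "synonym" || cur$accepted_id[[1]] == cur$taxon_id[[1]]) {
      return(cur)
    }
    nxt <- .node_by_id(store, cur$accepted_id[[1]])
    if (is.null(nxt)) {
      stop("dangling accepted_id for node '", cur$canonical_name[[1]],
           "' (", cur$taxon_id[[1]], ")")
    }
    if (nxt$taxon_id[[1]] == node$taxon_id[[1]]) {
      stop("synonym cycle at node '", node$canonical_name[[1]], "'")
    }
    cur <- nxt
  }
  stop("synonym chain deeper than 10 at node '", node$canonical_name[[1]], "'")
}

#' Standard-rank lineage of a backbone node
#'
#' Walks the parent chain from the node to the root and projects the names
#' of the seven standard ranks into a lineage; nodes at non-standard ranks
#' (subfamily, tribe, ...) are skipped. Synonym nodes are first resolved to
#' their accepted partner.
#'
#' @param store a `taxonomy_store`.
#' @param node one-row node tibble or `taxon_id` string.
#' @return Lineage vector (see [lineage()]).
#' @export
lineage_of <- function(store, node) {
  if (is.character(node)) node <- .node_by_id(store, node)
  if (is.null(node) || !nrow(node)) stop("node not in store")
  node <- accepted_of(store, node)
  out <- lineage()
  cur <- node
  seen <- character()
  while (!is.null(cur)) {
    id <- cur$taxon_id[[1]]
    if (id %in% seen) stop("cycle in parent chain at node '", id, "'")
    seen <- c(seen, id)
    r <- cur$rank[[1]]
    if (r %in% .RANKS && is.na(out[[r]])) out[[r]] <- cur$canonical_name[[1]]
    pid <- cur$parent_id[[1]]
    if (is.na(pid) || !nzchar(pid)) break
    cur <- .node_by_id(store, pid)
  }
  out
}
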