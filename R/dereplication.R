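# Dereplication: collapse identical sequences, reconcile their taxonomies.

# are two lineages consistent, i.e. equal wherever both are filled?
.lineage_consistent <- function(a, b) {
  both <- !is.na(a) & !is.na(b)
  all(a[both] == b[both])
}

# decide the consensus lineage for one group of identical sequences.
# counts: integer record count per distinct lineage; lins: list of lineage
# vectors. Returns list(lineage, winners = indices of the lineage groups
# that carried the decision).
.resolve_lineages <- function(lins, counts) {
  if (length(lins) == 1L) {
    return(list(lineage = lins[[1]], winners = 1L))
  }
  # (a) all lineages mutually consistent: differ only in resolution ->
  #     take the most resolved one
  pairs <- utils::combn(length(lins), 2)
  consistent <- all(apply(pairs, 2, function(p) {
    .lineage_consistent(lins[[p[1]]], lins[[p[2]]])
  }))
  if (consistent) {
    depth <- vapply(lins, function(l) .rank_depth(lineage_resolution(l)), 0L)
    win <- which.max(depth)
    return(list(lineage = lins[[win]], winners = win))
  }
  # (b) contradiction: the lineage with more records wins
  top <- which(counts == max(counts))
  if (length(top) == 1L) {
    return(list(lineage = lins[[top]], winners = top))
  }
  # (c) tie: lowest common ancestor of the tied lineages
  lca <- Reduce(lineage_lca, lins[top])
  list(lineage = lca, winners = top)
}

#' Dereplicate identical sequences
#'
#' Collapses records with byte-identical sequences into one cluster each
#' and reconciles conflicting taxonomic labels: (a) if the member lineages
#' differ only in resolution (they agree at every rank both have filled),
#' the most resolved lineage is kept; (b) otherwise the lineage carried by
#' the most records wins; (c) a tie is resolved to the lowest common
#' ancestor of the tied lineages. The cluster representative is the
#' lexicographically smallest record id among the members of the winning
#' lineage group(s), which makes the output deterministic and independent
#' of input order.
#'
#' @param records harmonized table.
#' @return Cluster table: one row per distinct sequence with the consensus
#'   rank columns, `resolution`, `member_count`, list-column `member_ids`,
#'   and `representative_id`. Location fields are taken from the
#'   representative record.
#' @export
dereplicate <- function(records) {
  if (!nrow(records)) {
    out <- .empty_harmonized()[, c("sequence", .RANKS)]
    out$resolution <- character()
    out$member_count <- integer()
    out$member_ids <- list()
    out$representative_id <- character()
    return(out)
  }
  groups <- split(seq_len(nrow(records)), records$sequence)
  # stable cluster order: first appearance of each sequence in the input
  first_seen <- vapply(groups, min, 0L)
  groups <- groups[order(first_seen)]

  rows <- lapply(groups, function(idx) {
    sub <- records[idx, , drop = FALSE]
    lin_vecs <- lapply(seq_len(nrow(sub)), function(i) {
      lineage_as_vector(sub[i, .RANKS])
    })
    key <- vapply(lin_vecs, function(l) paste(ifelse(is.na(l), "", l),
                                              collapse = "\r"), "")
    grp <- split(seq_along(key), key)
    # deterministic group order independent of member order
    grp <- grp[order(names(grp))]
    lins <- lapply(grp, function(g) lin_vecs[[g[[1]]]])
    counts <- lengths(grp)
    dec <- .resolve_lineages(unname(lins), unname(counts))
    winner_members <- sort(sub$record_id[unlist(grp[dec$winners], use.names = FALSE)])
    rep_id <- winner_members[[1]]
    rep_row <- sub[match(rep_id, sub$record_id), , drop = FALSE]
    tibble::tibble(
      sequence = sub$sequence[[1]],
      !!!as.list(dec$lineage),
      resolution = lineage_resolution(dec$lineage),
      member_count = nrow(sub),
      member_ids = list(sort(sub$record_id)),
      representative_id = rep_id,
      source_db = rep_row$source_db,
      country = rep_row$country,
      latitude = rep_row$latitude,
      longitude = rep_row$longitude
    )
  })
  dplyr::bind_rows(rows)
}
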