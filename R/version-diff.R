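# Diffing two database versions: superfamily mapping, split/merge events,
# per-member fates (retention, supersession, outlier filtering, rescue by
# search or by forced-alignment identity) and the staged accounting cascade
# for members that go missing between versions.

#' Map superfamily codes between two versions
#'
#' Partitions the union of both versions' superfamily codes into codes common
#' to both, codes absent from the newer version, and codes new in it.
#'
#' @param v1,v2 [database_version()] objects (old, new).
#' @return Object of class `superfamily_mapping` with character vectors
#'   `common`, `absent_from_new` and `new_in_new`.
#' @export
map_superfamilies <- function(v1, v2) {
  c1 <- names(v1$superfamilies)
  c2 <- names(v2$superfamilies)
  structure(
    list(common = sort(intersect(c1, c2)),
         absent_from_new = sort(setdiff(c1, c2)),
         new_in_new = sort(setdiff(c2, c1))),
    class = "superfamily_mapping"
  )
}

#' @export
print.superfamily_mapping <- function(x, ...) {
  cat("<superfamily_mapping> common ", length(x$common),
      ", absent from new ", length(x$absent_from_new),
      ", new ", length(x$new_in_new), "\n", sep = "")
  invisible(x)
}

#' Detect superfamily splits and merges
#'
#' Builds the bipartite member-overlap graph between old and new
#' superfamilies (members identified by `member_id`). An old superfamily
#' linked to two or more new superfamilies, each sharing at least
#' `min_shared` members, is a split; symmetrically, a new superfamily fed by
#' two or more old ones is a merge. Events are sorted by (first) old code.
#'
#' @param v1,v2 [database_version()] objects.
#' @param min_shared Minimum shared members for a graph edge.
#' @return List of `split_merge_event` objects, each with `kind` ("split" or
#'   "merge"), `old_codes`, `new_codes`, and `shared_member_counts` (a data
#'   frame old, new, n_shared).
#' @export
detect_splits_merges <- function(v1, v2, min_shared = 1) {
  edges <- list()
  for (old_sf in v1$superfamilies) {
    old_ids <- names(old_sf$members)
    for (new_sf in v2$superfamilies) {
      n_shared <- length(intersect(old_ids, names(new_sf$members)))
      if (n_shared >= min_shared)
        edges[[length(edges) + 1L]] <-
          data.frame(old = old_sf$code, new = new_sf$code,
                     n_shared = n_shared, stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0L) return(list())
  edges <- do.call(rbind, edges)
  events <- list()
  for (oc in unique(edges$old)) {           # splits: one old, >= 2 new
    sub <- edges[edges$old == oc, , drop = FALSE]
    if (nrow(sub) >= 2L)
      events[[length(events) + 1L]] <- structure(
        list(kind = "split", old_codes = oc, new_codes = sort(sub$new),
             shared_member_counts = sub[order(sub$new), , drop = FALSE]),
        class = "split_merge_event")
  }
  for (nc in unique(edges$new)) {           # merges: >= 2 old, one new
    sub <- edges[edges$new == nc, , drop = FALSE]
    if (nrow(sub) >= 2L)
      events[[length(events) + 1L]] <- structure(
        list(kind = "merge", old_codes = sort(sub$old), new_codes = nc,
             shared_member_counts = sub[order(sub$old), , drop = FALSE]),
        class = "split_merge_event")
  }
  events[order(vapply(events, function(e) e$old_codes[1], character(1)))]
}

#' @export
print.split_merge_event <- function(x, ...) {
  cat("<split_merge_event> ", x$kind, ": {",
      paste(x$old_codes, collapse = ", "), "} -> {",
      paste(x$new_codes, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Detect supersession of a member by a newer structure
#'
#' A member is superseded when the new version of its superfamily holds a
#' structure of the same protein under a different PDB code: a candidate of
#' equal domain length with 100% global sequence identity. The first match in
#' sorted member-id order is returned.
#'
#' @param member A [domain_member()] from the old version.
#' @param candidates List of [domain_member()] objects from the same
#'   superfamily in the new version.
#' @return The matching candidate, or `NULL`.
#' @export
detect_supersession <- function(member, candidates) {
  if (length(candidates) == 0L) return(NULL)
  ids <- vapply(candidates, `[[`, character(1), "member_id")
  for (cand in candidates[order(ids)]) {
    if (cand$pdb_code == member$pdb_code) next
    if (cand$length != member$length) next
    if (global_align_identity(member$sequence, cand$sequence)$identity == 100)
      return(cand)
  }
  NULL
}

#' Assign a fate to every member across two versions
#'
#' For each member of the old version, the first matching rule wins:
#' \enumerate{
#'   \item \strong{retained} -- its `member_id` is present in the new version;
#'   \item \strong{superseded} -- a same-superfamily candidate passes
#'     [detect_supersession()];
#'   \item \strong{outlier} -- its id is in the new version's outlier set;
#'   \item \strong{rescued_by_search} -- the best global identity against the
#'     new members of its original superfamily reaches
#'     `search_identity_cutoff` (a stand-in for sequence-search hits);
#'   \item \strong{rescued_by_identity} -- that best identity exceeds
#'     `placement_identity_cutoff` (forced-alignment placement);
#'   \item \strong{unaccounted} -- otherwise (including the case that its
#'     superfamily is absent from the new version).
#' }
#' Members present only in the new version get fate \strong{new}.
#'
#' @param v1,v2 [database_version()] objects (old, new).
#' @param search_identity_cutoff Percent identity for the search-rescue rule.
#' @param placement_identity_cutoff Percent identity (exclusive) for the
#'   forced-alignment placement rule.
#' @return Data frame with columns `member_id`, `fate`, `evidence`.
#' @export
assign_member_fates <- function(v1, v2, search_identity_cutoff = 40,
                                placement_identity_cutoff = 30) {
  v2_ids <- version_member_ids(v2)
  rows <- list()
  add <- function(id, fate, evidence)
    rows[[length(rows) + 1L]] <<- data.frame(
      member_id = id, fate = fate, evidence = evidence,
      stringsAsFactors = FALSE)
  for (sf in v1$superfamilies) {
    new_sf <- v2$superfamilies[[sf$code]]
    candidates <- if (is.null(new_sf)) list() else unname(new_sf$members)
    for (member in sf$members) {
      id <- member$member_id
      if (id %in% v2_ids) {
        add(id, "retained", "member_id present in new version")
        next
      }
      sup <- detect_supersession(member, candidates)
      if (!is.null(sup)) {
        add(id, "superseded",
            sprintf("superseded by %s (100%% identity, equal length)",
                    sup$member_id))
        next
      }
      if (id %in% v2$outliers) {
        add(id, "outlier", "listed in new version's outlier set")
        next
      }
      if (is.null(new_sf)) {
        add(id, "unaccounted", "superfamily absent")
        next
      }
      best <- -Inf
      best_id <- NA_character_
      for (cand in candidates) {
        ident <- global_align_identity(member$sequence, cand$sequence)$identity
        if (ident > best) {
          best <- ident
          best_id <- cand$member_id
        }
      }
      if (is.finite(best) && best >= search_identity_cutoff) {
        add(id, "rescued_by_search",
            sprintf("best identity %.1f%% vs %s", best, best_id))
      } else if (is.finite(best) && best > placement_identity_cutoff) {
        add(id, "rescued_by_identity",
            sprintf("best identity %.1f%% vs %s", best, best_id))
      } else {
        add(id, "unaccounted",
            if (is.finite(best))
              sprintf("best identity %.1f%% below placement cutoff", best)
            else "no candidates in new superfamily")
      }
    }
  }
  v1_ids <- version_member_ids(v1)
  for (id in setdiff(v2_ids, v1_ids))
    add(id, "new", "absent from old version")
  do.call(rbind, rows)
}

#' Staged accounting of members missing between two versions
#'
#' Reproduces the bookkeeping cascade used to trace what happened to the
#' members of a set of superfamilies across an update: how many were carried
#' over unchanged, how many of the missing ones were outlier-filtered, how
#' many of the remaining queries were recovered by sequence search, how many
#' more by forced-alignment identity placement, and how many stay
#' unaccounted. A superseded member is counted as a search-stage hit (it is
#' found in its superfamily at 100% identity), keeping every telescoping
#' identity exact.
#'
#' @param v1_subset A [database_version()] holding the superfamilies under
#'   study (typically a subset of the full old version).
#' @param v2 The new [database_version()].
#' @param search_identity_cutoff,placement_identity_cutoff Passed to
#'   [assign_member_fates()].
#' @return Object of class `accounting_report` with stage counts
#'   (`n_v1_total`, `n_retained`, `n_missing`, `n_outlier`, `n_queries`,
#'   `n_search_hits`, `n_search_missing`, `n_identity_rescued`,
#'   `n_unaccounted`) and the per-member fate table.
#' @export
accounting_cascade <- function(v1_subset, v2, search_identity_cutoff = 40,
                               placement_identity_cutoff = 30) {
  fates <- assign_member_fates(v1_subset, v2,
                               search_identity_cutoff = search_identity_cutoff,
                               placement_identity_cutoff = placement_identity_cutoff)
  v1_fates <- fates[fates$fate != "new", , drop = FALSE]
  n_total <- nrow(v1_fates)
  n_retained <- sum(v1_fates$fate == "retained")
  n_missing <- n_total - n_retained
  n_outlier <- sum(v1_fates$fate == "outlier")
  n_queries <- n_missing - n_outlier
  n_search_hits <- sum(v1_fates$fate %in% c("rescued_by_search", "superseded"))
  n_search_missing <- n_queries - n_search_hits
  n_identity_rescued <- sum(v1_fates$fate == "rescued_by_identity")
  structure(
    list(n_v1_total = n_total, n_retained = n_retained,
         n_missing = n_missing, n_outlier = n_outlier,
         n_queries = n_queries, n_search_hits = n_search_hits,
         n_search_missing = n_search_missing,
         n_identity_rescued = n_identity_rescued,
         n_unaccounted = n_search_missing - n_identity_rescued,
         per_member = fates),
    class = "accounting_report"
  )
}

#' @export
print.accounting_report <- function(x, ...) {
  cat("<accounting_report>\n",
      "  members in old version:     ", x$n_v1_total, "\n",
      "  carried over (retained):    ", x$n_retained, "\n",
      "  missing:                    ", x$n_missing, "\n",
      "  outlier-filtered:           ", x$n_outlier, "\n",
      "  queries for search:         ", x$n_queries, "\n",
      "  search hits:                ", x$n_search_hits, "\n",
      "  still missing after search: ", x$n_search_missing, "\n",
      "  identity-rescued:           ", x$n_identity_rescued, "\n",
      "  unaccounted:                ", x$n_unaccounted, "\n", sep = "")
  invisible(x)
}

#' Export a per-member fate table as TSV
#'
#' @param fates Data frame from [assign_member_fates()] (or the `per_member`
#'   component of an accounting report).
#' @param path Output path.
#' @export
write_fates_tsv <- function(fates, path) {
  write.table(fates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
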