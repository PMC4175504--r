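# Version-level summaries, cross-version comparisons and significance tests.

#' Welch two-sample t-test
#'
#' Unequal-variance two-sided t-test (Welch statistic with
#' Welch-Satterthwaite degrees of freedom), as used to compare
#' per-superfamily metrics between two database versions.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least two values.
#' @return List with `t`, `df` and `p`.
#' @examples
#' welch_t_test(1:5, 2:6)  # t = -1, df = 8
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs at least 2 observations")
  if (var(sample_a) + var(sample_b) == 0)
    stop("degenerate variance: both samples are constant")
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Summarise a database version
#'
#' One row per superfamily (member count, mean domain length, variation SD
#' and the labels under both classification schemes) plus version totals.
#'
#' @param db A [database_version()].
#' @param config A [classification_config()].
#' @return Object of class `version_summary` with fields `label`,
#'   `n_superfamilies`, `n_members` and the `per_superfamily` data frame.
#' @export
summarize_version <- function(db, config = classification_config()) {
  rows <- lapply(db$superfamilies, function(sf) {
    prof <- superfamily_profile(sf)
    data.frame(
      code = sf$code,
      n_members = prof$n_members,
      mean_length = prof$mean_length,
      sd_variation = prof$sd_variation,
      label_old = classify_old(prof, config)$label,
      label_improved = classify_improved(prof, config)$label,
      stringsAsFactors = FALSE
    )
  })
  per_sf <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(
    list(label = db$label,
         n_superfamilies = nrow(per_sf),
         n_members = sum(per_sf$n_members),
         per_superfamily = per_sf),
    class = "version_summary"
  )
}

#' @export
print.version_summary <- function(x, ...) {
  cat("<version_summary> ", x$label, ": ", x$n_superfamilies,
      " superfamilies, ", x$n_members, " members\n", sep = "")
  invisible(x)
}

# Member-count histogram over bins of `bin_width` members: 1-5, 6-10, ...
# (half-open on the integer grid), matching the membership-frequency plots.
membership_histogram <- function(counts, bin_width = 5) {
  if (length(counts) == 0L)
    return(structure(list(bin_width = bin_width, counts = integer(0),
                          n = 0L), class = "membership_histogram"))
  idx <- (pmax(counts, 1L) - 1L) %/% bin_width + 1L
  tab <- tabulate(idx, nbins = max(idx))
  lo <- (seq_along(tab) - 1L) * bin_width + 1L
  names(tab) <- paste0(lo, "-", lo + bin_width - 1L)
  structure(list(bin_width = bin_width, counts = tab, n = length(counts)),
            class = "membership_histogram")
}

#' @export
print.membership_histogram <- function(x, ...) {
  cat("<membership_histogram> ", x$n, " superfamilies\n", sep = "")
  print(x$counts)
  invisible(x)
}

# Run a Welch test, or record why it was omitted.
try_test <- function(a, b, what) {
  if (length(a) < 2L || length(b) < 2L)
    return(list(omitted = paste0("insufficient data for ", what)))
  if (all(is.na(a)) || all(is.na(b)))
    return(list(omitted = paste0("omitted: no ", what)))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    return(list(omitted = paste0("insufficient data for ", what)))
  tryCatch(welch_t_test(a, b),
           error = function(e) list(omitted = conditionMessage(e)))
}

#' Compare two database versions
#'
#' Version-level comparison: per-version membership histograms (bins of 5
#' members), member-level absolute length-variation histograms, variation-SD
#' histograms, and Welch t-tests on per-superfamily member counts, mean
#' domain lengths and (where coordinates are available) consensus RMSDs.
#' Tests that cannot be run are recorded with the reason instead of a
#' statistic.
#'
#' @param dbA,dbB [database_version()] objects.
#' @param config A [classification_config()].
#' @return Object of class `comparison_report`.
#' @export
compare_versions <- function(dbA, dbB, config = classification_config()) {
  sa <- summarize_version(dbA, config)
  sb <- summarize_version(dbB, config)
  profiles <- function(db) lapply(db$superfamilies, superfamily_profile)
  rmsds <- function(db) vapply(db$superfamilies, function(sf) {
    q <- quality_report(sf)
    if (is.na(q$consensus_rmsd)) q$mean_pairwise_rmsd else q$consensus_rmsd
  }, numeric(1))
  ra <- rmsds(dbA); rb <- rmsds(dbB)
  rmsd_test <- if (all(is.na(ra)) || all(is.na(rb)))
    list(omitted = "omitted: no coordinates")
  else try_test(ra, rb, "alignment quality (RMSD)")
  structure(
    list(
      labels = c(sa$label, sb$label),
      summaries = list(sa, sb),
      membership_histograms = list(
        membership_histogram(sa$per_superfamily$n_members),
        membership_histogram(sb$per_superfamily$n_members)),
      variation_histograms = list(
        bin_variations(profiles(dbA), by = "member"),
        bin_variations(profiles(dbB), by = "member")),
      sd_histograms = list(
        bin_variations(profiles(dbA), by = "superfamily", measure = "sd"),
        bin_variations(profiles(dbB), by = "superfamily", measure = "sd")),
      tests = list(
        member_counts = try_test(sa$per_superfamily$n_members,
                                 sb$per_superfamily$n_members,
                                 "member counts"),
        mean_lengths = try_test(sa$per_superfamily$mean_length,
                                sb$per_superfamily$mean_length,
                                "mean lengths"),
        rmsd = rmsd_test)),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$labels[1], " vs ", x$labels[2], "\n", sep = "")
  for (nm in names(x$tests)) {
    tt <- x$tests[[nm]]
    if (!is.null(tt$omitted))
      cat("  ", nm, ": ", tt$omitted, "\n", sep = "")
    else
      cat("  ", nm, ": t = ", format(tt$t, digits = 4),
          ", df = ", format(tt$df, digits = 4),
          ", p = ", format(tt$p, digits = 4), "\n", sep = "")
  }
  invisible(x)
}
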