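# Per-member and per-superfamily domain-length variation statistics,
# and their binned distributions.

#' Mean domain length of a superfamily
#'
#' @param sf A [superfamily()].
#' @return Arithmetic mean of the member lengths, in residues.
#' @export
mean_domain_length <- function(sf) {
  if (length(sf$members) == 0L)
    stop("superfamily ", sf$code, " has no members; mean length undefined")
  mean(vapply(sf$members, `[[`, integer(1), "length"))
}

#' Signed percent length variation of a member
#'
#' The extent of length variation of a domain relative to its superfamily's
#' mean length: `((domain_length - mean_length) / mean_length) * 100`.
#' Sign is preserved (shorter-than-mean members are negative).
#'
#' @param domain_length Integer domain length(s), residues.
#' @param mean_length Positive mean superfamily length, residues.
#' @return Signed percent variation (vectorised over `domain_length`).
#' @examples
#' variation_percent(130, 100)  # +30
#' variation_percent(70, 100)   # -30
#' @export
variation_percent <- function(domain_length, mean_length) {
  if (!is.numeric(mean_length) || length(mean_length) != 1L || mean_length <= 0)
    stop("`mean_length` must be a single positive number")
  (domain_length - mean_length) / mean_length * 100
}

#' Length-variation profile of a superfamily
#'
#' Computes the mean domain length, each member's signed percent variation
#' from it, the population standard deviation of those variations (the
#' superfamily is the full population of its members, not a sample), and the
#' maximum absolute variation.
#'
#' @param sf A [superfamily()].
#' @return An object of class `length_stats` with fields `superfamily_code`,
#'   `mean_length`, `per_member_variation` (named signed percents),
#'   `sd_variation`, `max_abs_variation` and `n_members`.
#' @export
superfamily_profile <- function(sf) {
  mu <- mean_domain_length(sf)
  lens <- vapply(sf$members, `[[`, integer(1), "length")
  v <- variation_percent(lens, mu)
  names(v) <- names(sf$members)
  structure(
    list(superfamily_code = sf$code,
         mean_length = mu,
         per_member_variation = v,
         sd_variation = sqrt(mean((v - mean(v))^2)),
         max_abs_variation = max(abs(v)),
         n_members = length(v)),
    class = "length_stats"
  )
}

#' @export
print.length_stats <- function(x, ...) {
  cat("<length_stats> ", x$superfamily_code, ": mean length ",
      round(x$mean_length, 1), " aa, sd of variation ",
      round(x$sd_variation, 2), "%, max |variation| ",
      round(x$max_abs_variation, 2), "% over ", x$n_members, " members\n",
      sep = "")
  invisible(x)
}

# Bin labels/breaks shared by the histogram builders. Bins are half-open
# [lo, hi); the terminal bin [overflow_min, Inf) is open-ended; when signed
# values are binned a mirrored negative range plus (-Inf, -overflow_min) is
# prepended.
variation_breaks <- function(bin_width, overflow_min, signed) {
  pos <- seq(0, overflow_min, by = bin_width)
  if (signed) c(-Inf, rev(-pos[-1]), pos, Inf) else c(pos, Inf)
}

make_histogram <- function(values, bin_width, overflow_min, signed) {
  breaks <- variation_breaks(bin_width, overflow_min, signed)
  idx <- findInterval(values, breaks, left.open = FALSE)  # [lo, hi)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  lab <- function(lo, hi) {
    if (is.infinite(hi)) paste0(">=", lo)
    else if (is.infinite(lo)) paste0("<", hi)
    else paste0("[", lo, ",", hi, ")")
  }
  names(counts) <- mapply(lab, breaks[-length(breaks)], breaks[-1])
  structure(
    list(bin_width = bin_width, overflow_min = overflow_min,
         breaks = breaks, counts = counts, n = length(values)),
    class = "variation_histogram"
  )
}

#' Bin length variations into a histogram
#'
#' Bins are half-open 5-percent-wide intervals `[lo, hi)` with an open-ended
#' terminal bin starting at `overflow_min` (default `>= 45%`); a value of
#' exactly 5 falls in `[5, 10)`. With `by = "member"` every member's
#' variation is binned; with `by = "superfamily"` one value per superfamily
#' is binned, chosen by `measure` (default the maximum absolute member
#' variation; the mean absolute variation or the variation SD are selectable
#' alternatives).
#'
#' @param stats A single `length_stats` or a list of them.
#' @param by `"member"` or `"superfamily"`.
#' @param use_absolute Bin `|variation|` (default); if `FALSE`, signed values
#'   are binned over a mirrored bin range.
#' @param measure Per-superfamily summary used when `by = "superfamily"`.
#' @param bin_width Bin width in percent.
#' @param overflow_min Start of the open-ended terminal bin, percent.
#' @return An object of class `variation_histogram`; `counts` always sum to
#'   the number of observations.
#' @export
bin_variations <- function(stats, by = c("member", "superfamily"),
                           use_absolute = TRUE,
                           measure = c("max_abs", "mean_abs", "sd"),
                           bin_width = 5, overflow_min = 45) {
  by <- match.arg(by)
  measure <- match.arg(measure)
  if (inherits(stats, "length_stats")) stats <- list(stats)
  stopifnot(all(vapply(stats, inherits, logical(1), "length_stats")))
  values <- if (by == "member") {
    unlist(lapply(stats, `[[`, "per_member_variation"), use.names = FALSE)
  } else {
    vapply(stats, function(s) switch(measure,
      max_abs = s$max_abs_variation,
      mean_abs = mean(abs(s$per_member_variation)),
      sd = s$sd_variation), numeric(1))
  }
  if (use_absolute) values <- abs(values)
  make_histogram(values, bin_width, overflow_min, signed = !use_absolute)
}

#' @export
print.variation_histogram <- function(x, ...) {
  cat("<variation_histogram> ", x$n, " observations, bin width ",
      x$bin_width, "%\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Histogram as a data frame
#'
#' @param x A `variation_histogram`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Data frame with columns `bin_lo`, `bin_hi`, `count`.
#' @export
as.data.frame.variation_histogram <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  data.frame(bin_lo = x$breaks[-length(x$breaks)],
             bin_hi = x$breaks[-1],
             count = as.integer(x$counts),
             stringsAsFactors = FALSE)
}

#' Export a histogram as TSV
#'
#' @param x A `variation_histogram`.
#' @param path Output path.
#' @export
write_histogram_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Per-class distribution of member length variations
#'
#' Splits all members of a database version by SCOP structural class and
#' returns one member-level variation histogram per class present. Classes
#' with no members are absent from the result (not zero-filled).
#'
#' @param db A [database_version()].
#' @param use_absolute,bin_width,overflow_min As in [bin_variations()].
#' @return Named list, class label to `variation_histogram`.
#' @export
class_distribution <- function(db, use_absolute = TRUE, bin_width = 5,
                               overflow_min = 45) {
  values <- list()
  for (sf in db$superfamilies) {
    prof <- superfamily_profile(sf)
    cls <- vapply(sf$members, `[[`, character(1), "scop_class")
    for (k in seq_along(cls)) {
      values[[cls[k]]] <- c(values[[cls[k]]], prof$per_member_variation[[k]])
    }
  }
  lapply(values, function(v) {
    if (use_absolute) v <- abs(v)
    make_histogram(v, bin_width, overflow_min, signed = !use_absolute)
  })
}
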