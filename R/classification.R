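# Length-variation classification of superfamilies: the old 75%-majority
# scheme and the improved scheme that treats sparsely populated
# superfamilies separately.

#' Classification configuration
#'
#' Thresholds and rules for the length-variation classification schemes.
#' A member is length-deviant when `|variation| > deviant_cutoff` and
#' length-rigid when `|variation| < rigid_cutoff` (absolute values; the
#' intermediate band `[rigid_cutoff, deviant_cutoff]` is length-normal).
#' A superfamily counts as sparsely populated when it has fewer than
#' `sparse_max_members` members.
#'
#' @param deviant_cutoff Percent variation above which a member is deviant
#'   (default 30).
#' @param rigid_cutoff Percent variation below which a member is rigid
#'   (default 10).
#' @param majority_fraction Fraction of members that must agree for the dense
#'   branch (default 0.75).
#' @param sparse_max_members Superfamilies with fewer members than this take
#'   the sparse branch (default 10; exactly 10 members is dense).
#' @param sparse_deviant_min In the sparse branch, this many deviant members
#'   suffice for a deviant call regardless of majority (default 2, the
#'   "more-than-one" rule; set to 1 for the single-member variant).
#' @param tie_rule How sparse-branch ties (equal nonzero deviant and rigid
#'   member counts) are resolved: `"normal"` labels them length-normal with
#'   `tie_broken = TRUE`; `"manual_map"` looks the code up in `tie_map`.
#' @param tie_map Named character vector code -> label, used by
#'   `tie_rule = "manual_map"`; unlisted codes fall back to `"normal"`.
#' @return An object of class `classification_config`.
#' @export
classification_config <- function(deviant_cutoff = 30, rigid_cutoff = 10,
                                  majority_fraction = 0.75,
                                  sparse_max_members = 10,
                                  sparse_deviant_min = 2,
                                  tie_rule = c("normal", "manual_map"),
                                  tie_map = NULL) {
  tie_rule <- match.arg(tie_rule)
  if (!(rigid_cutoff > 0 && deviant_cutoff > rigid_cutoff))
    stop("need 0 < rigid_cutoff < deviant_cutoff")
  if (!(majority_fraction > 0 && majority_fraction <= 1))
    stop("majority_fraction must be in (0, 1]")
  if (sparse_deviant_min < 1) stop("sparse_deviant_min must be >= 1")
  structure(
    list(deviant_cutoff = deviant_cutoff, rigid_cutoff = rigid_cutoff,
         majority_fraction = majority_fraction,
         sparse_max_members = as.integer(sparse_max_members),
         sparse_deviant_min = as.integer(sparse_deviant_min),
         tie_rule = tie_rule, tie_map = tie_map),
    class = "classification_config"
  )
}

band_counts <- function(profile, config) {
  v <- abs(profile$per_member_variation)
  list(n = length(v),
       n_dev = sum(v > config$deviant_cutoff),
       n_rig = sum(v < config$rigid_cutoff))
}

new_classification_result <- function(code, label, scheme, bands,
                                      tie_broken = FALSE) {
  structure(
    list(superfamily_code = code, label = label, scheme = scheme,
         fraction_deviant_members = bands$n_dev / bands$n,
         fraction_rigid_members = bands$n_rig / bands$n,
         n_members = bands$n, tie_broken = tie_broken),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> ", x$superfamily_code, ": length-", x$label,
      " (", x$scheme, " scheme; ", x$n_members, " members, ",
      round(100 * x$fraction_deviant_members), "% deviant, ",
      round(100 * x$fraction_rigid_members), "% rigid",
      if (x$tie_broken) "; tie broken" else "", ")\n", sep = "")
  invisible(x)
}

#' Classify a superfamily under the old majority scheme
#'
#' Length-deviant when at least `majority_fraction` (default 75%) of members
#' exceed the deviant cutoff; length-rigid when at least that fraction sit
#' below the rigid cutoff; otherwise length-normal (standing in for the
#' unclassified remainder of the original scheme).
#'
#' @param profile A `length_stats` from [superfamily_profile()].
#' @param config A [classification_config()].
#' @return A `classification_result` with `scheme = "old"`.
#' @export
classify_old <- function(profile, config = classification_config()) {
  b <- band_counts(profile, config)
  label <- if (b$n_dev / b$n >= config$majority_fraction) "deviant"
           else if (b$n_rig / b$n >= config$majority_fraction) "rigid"
           else "normal"
  new_classification_result(profile$superfamily_code, label, "old", b)
}

#' Classify a superfamily under the improved scheme
#'
#' Densely populated superfamilies (`n >= sparse_max_members`) follow the
#' majority rule three ways: deviant if the deviant fraction reaches the
#' majority, rigid if the rigid fraction does, else normal (members in the
#' 10-30% band are length-normal members). Sparsely populated superfamilies
#' use the relaxed "more-than-one" rule: `sparse_deviant_min` deviant members
#' already make the superfamily deviant; otherwise deviant and rigid member
#' counts are compared and the majority wins. Equal nonzero counts are a tie,
#' resolved by the configured tie rule (default: length-normal, flagged
#' `tie_broken`); when both counts are zero every member sits in the middle
#' band and the superfamily is plainly length-normal.
#'
#' @inheritParams classify_old
#' @return A `classification_result` with `scheme = "improved"`.
#' @export
classify_improved <- function(profile, config = classification_config()) {
  b <- band_counts(profile, config)
  code <- profile$superfamily_code
  if (b$n >= config$sparse_max_members) {   # dense branch
    label <- if (b$n_dev / b$n >= config$majority_fraction) "deviant"
             else if (b$n_rig / b$n >= config$majority_fraction) "rigid"
             else "normal"
    return(new_classification_result(code, label, "improved", b))
  }
  # sparse branch
  if (b$n_dev >= config$sparse_deviant_min)
    return(new_classification_result(code, "deviant", "improved", b))
  if (b$n_dev > b$n_rig)
    return(new_classification_result(code, "deviant", "improved", b))
  if (b$n_rig > b$n_dev)
    return(new_classification_result(code, "rigid", "improved", b))
  if (b$n_dev == 0L)  # every member in the middle band: genuinely normal
    return(new_classification_result(code, "normal", "improved", b))
  label <- "normal"
  if (identical(config$tie_rule, "manual_map") &&
      !is.null(config$tie_map) && code %in% names(config$tie_map))
    label <- unname(config$tie_map[[code]])
  new_classification_result(code, label, "improved", b, tie_broken = TRUE)
}

#' Classify every superfamily of a database version
#'
#' @param db A [database_version()].
#' @param scheme `"improved"` (default) or `"old"`.
#' @param config A [classification_config()].
#' @return An object of class `classification_set`: a list with `results`
#'   (one `classification_result` per superfamily, keyed by code) and
#'   `counts` (named integer vector over deviant/rigid/normal, summing to the
#'   number of superfamilies).
#' @export
classify_database <- function(db, scheme = c("improved", "old"),
                              config = classification_config()) {
  scheme <- match.arg(scheme)
  fun <- if (scheme == "improved") classify_improved else classify_old
  results <- lapply(db$superfamilies,
                    function(sf) fun(superfamily_profile(sf), config))
  labels <- vapply(results, `[[`, character(1), "label")
  counts <- vapply(c("deviant", "rigid", "normal"),
                   function(l) sum(labels == l), integer(1))
  structure(list(label = db$label, scheme = scheme, results = results,
                 counts = counts),
            class = "classification_set")
}

#' @export
print.classification_set <- function(x, ...) {
  cat("<classification_set> ", x$label, " (", x$scheme, " scheme): ",
      "length-deviant ", x$counts[["deviant"]],
      ", length-rigid ", x$counts[["rigid"]],
      ", length-normal ", x$counts[["normal"]], "\n", sep = "")
  invisible(x)
}

#' Classification set as a data frame
#'
#' @param x A `classification_set`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return One row per superfamily: code, scheme, label, n, frac_deviant,
#'   frac_rigid, tie_broken.
#' @export
as.data.frame.classification_set <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  rs <- x$results
  data.frame(
    code = vapply(rs, `[[`, character(1), "superfamily_code"),
    scheme = vapply(rs, `[[`, character(1), "scheme"),
    label = vapply(rs, `[[`, character(1), "label"),
    n = vapply(rs, `[[`, integer(1), "n_members"),
    frac_deviant = vapply(rs, `[[`, numeric(1), "fraction_deviant_members"),
    frac_rigid = vapply(rs, `[[`, numeric(1), "fraction_rigid_members"),
    tie_broken = vapply(rs, `[[`, logical(1), "tie_broken"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Export a classification table as TSV
#'
#' @param x A `classification_set`.
#' @param path Output path.
#' @export
write_classification_tsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
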