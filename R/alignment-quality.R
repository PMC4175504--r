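# Structure-based alignment quality metrics: gapless-column equivalences,
# secondary-structural equivalences, Kabsch superposition and an iterative
# consensus (fit-to-framework) superposition.

alignment_matrix <- function(alignment) {
  if (length(alignment) == 0L) stop("empty alignment")
  do.call(rbind, strsplit(unname(alignment), "", fixed = TRUE))
}

#' Initial equivalences of a multiple alignment
#'
#' The number of alignment columns holding a residue in every member (no
#' gaps anywhere in the column).
#'
#' @param alignment Named character vector of equal-length gapped strings.
#' @return Integer column count.
#' @export
initial_equivalences <- function(alignment) {
  m <- alignment_matrix(alignment)
  sum(colSums(m == "-") == 0L)
}

# Indices (per member) mapping alignment columns to residue positions.
gapless_columns <- function(alignment) {
  m <- alignment_matrix(alignment)
  which(colSums(m == "-") == 0L)
}

# Residue index of each alignment column for one aligned string (NA at gaps).
residue_index <- function(aligned) {
  chars <- strsplit(aligned, "", fixed = TRUE)[[1]]
  idx <- cumsum(chars != "-")
  idx[chars == "-"] <- NA_integer_
  idx
}

#' Secondary-structural equivalences of a multiple alignment
#'
#' The number of gapless columns whose residues carry the identical
#' secondary-structure state (over the coarse alphabet H/E/C) in every
#' member. Always bounded above by [initial_equivalences()].
#'
#' @param alignment Named character vector of equal-length gapped strings.
#' @param ss_map Named character vector or list, member id to
#'   secondary-structure string covering that member's residues.
#' @return Integer column count.
#' @export
sst_equivalences <- function(alignment, ss_map) {
  ids <- names(alignment)
  missing_ss <- setdiff(ids, names(ss_map))
  if (length(missing_ss) > 0L)
    stop("no secondary-structure string for member(s): ",
         paste(missing_ss, collapse = ", "))
  cols <- gapless_columns(alignment)
  if (length(cols) == 0L) return(0L)
  states <- vapply(ids, function(id) {
    aligned <- alignment[[id]]
    n_res <- nchar(gsub("-", "", aligned, fixed = TRUE))
    ss <- ss_map[[id]]
    if (nchar(ss) != n_res)
      stop("ss string of '", id, "' has ", nchar(ss),
           " states for ", n_res, " residues")
    strsplit(ss, "", fixed = TRUE)[[1]][residue_index(aligned)[cols]]
  }, character(length(cols)))
  states <- matrix(states, nrow = length(cols))
  sum(apply(states, 1L, function(s) length(unique(s)) == 1L))
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `y` onto point set `x`: returns
#' the proper rotation (determinant +1; reflections are excluded by the
#' usual determinant correction of the SVD solution) and translation
#' minimising the RMSD, together with that RMSD.
#'
#' @param x,y Numeric n x 3 matrices of paired points (Angstrom), n >= 3.
#' @return Object of class `superposition` with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd`. The transformed copy of `y` is
#'   `y %*% t(rotation) + translation` (rows as points).
#' @export
kabsch_superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y) || ncol(x) != 3L || ncol(y) != 3L)
    stop("point sets must be n x 3 matrices of equal size")
  if (nrow(x) < 3L)
    stop("at least 3 points are required for a unique superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  s <- svd(t(yc) %*% xc)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- yc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((xc - fitted)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(cx - rot %*% cy),
         rmsd = rmsd),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> rmsd ", format(x$rmsd, digits = 6), " A\n", sep = "")
  invisible(x)
}

apply_superposition <- function(sup, y) {
  sweep(y %*% t(sup$rotation), 2L, sup$translation, "+")
}

#' Iterative consensus superposition of a superfamily
#'
#' Fits every member with coordinates onto a common framework, in the spirit
#' of iterative multiple-structure superposition: starting from the first
#' member in lexicographic id order as reference, each member is rigidly
#' superposed onto the current mean coordinates at the equivalenced positions
#' (alignment columns gapless across the members considered), the mean is
#' recomputed, and the loop repeats until the mean moves less than `tol` or
#' `max_iter` is reached. The summed squared deviation from the mean is
#' non-increasing across iterations.
#'
#' @param members List of [domain_member()] objects, at least 2 of which
#'   carry `ca_trace` coordinates.
#' @param alignment Gapped alignment covering those members.
#' @param tol Convergence tolerance on the maximum mean-coordinate shift
#'   (Angstrom).
#' @param max_iter Iteration cap.
#' @return List with `per_member_rmsd` (named, RMSD of each member to the
#'   consensus), `consensus_rmsd` (their mean), `n_positions`, `n_iter` and
#'   `converged`.
#' @export
consensus_superpose <- function(members, alignment, tol = 1e-6,
                                max_iter = 50) {
  has_coords <- vapply(members, function(m) !is.null(m$ca_trace), logical(1))
  members <- members[has_coords]
  if (length(members) < 2L)
    stop("consensus superposition needs at least 2 members with coordinates")
  ids <- sort(vapply(members, `[[`, character(1), "member_id"))
  members <- members[match(ids, vapply(members, `[[`, character(1), "member_id"))]
  sub_aln <- alignment[ids]
  cols <- gapless_columns(sub_aln)
  if (length(cols) < 3L)
    stop("fewer than 3 equivalenced (gapless) positions; cannot superpose")
  coords <- lapply(members, function(m)
    m$ca_trace[residue_index(sub_aln[[m$member_id]])[cols], , drop = FALSE])
  names(coords) <- ids
  consensus <- coords[[1L]]   # deterministic start: first id lexicographically
  n_iter <- 0L
  converged <- FALSE
  fitted <- coords
  objective <- numeric(0)     # summed squared deviation from the mean
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    fitted <- lapply(coords, function(p)
      apply_superposition(kabsch_superpose(consensus, p), p))
    new_consensus <- Reduce(`+`, fitted) / length(fitted)
    objective <- c(objective, sum(vapply(fitted, function(p)
      sum((p - new_consensus)^2), numeric(1))))
    shift <- max(abs(new_consensus - consensus))
    consensus <- new_consensus
    if (shift < tol) {
      converged <- TRUE
      break
    }
  }
  per_rmsd <- vapply(fitted, function(p)
    sqrt(mean(rowSums((p - consensus)^2))), numeric(1))
  list(per_member_rmsd = per_rmsd,
       consensus_rmsd = mean(per_rmsd),
       n_positions = length(cols),
       n_iter = n_iter,
       objective_trace = objective,
       converged = converged)
}

#' Alignment-quality report for a superfamily
#'
#' Assembles the quality metrics used to compare alignments across database
#' versions: initial equivalences, secondary-structural equivalences (when
#' every member carries a secondary-structure string), and two RMSD
#' summaries over the members with coordinates -- the mean of all pairwise
#' Kabsch RMSDs (each pair superposed on the columns gapless across that
#' pair) and the consensus RMSD from [consensus_superpose()] (computed on
#' columns gapless across all members with coordinates).
#'
#' @param sf A [superfamily()].
#' @return Object of class `quality_metrics`; RMSD fields are `NA` when
#'   fewer than two members carry coordinates, and `n_sst_equivalences` is
#'   `NA` when a member lacks its secondary-structure string.
#' @export
quality_report <- function(sf) {
  aln <- sf$alignment
  n_initial <- initial_equivalences(aln)
  ss_map <- lapply(sf$members, `[[`, "ss_string")
  n_sst <- if (any(vapply(ss_map, is.null, logical(1)))) NA_integer_
           else sst_equivalences(aln, ss_map)
  with_coords <- Filter(function(m) !is.null(m$ca_trace), sf$members)
  mean_pairwise <- NA_real_
  consensus <- NA_real_
  if (length(with_coords) >= 2L) {
    ids <- names(with_coords)
    pair_rmsds <- c()
    for (i in seq_len(length(ids) - 1L)) for (j in seq((i + 1L), length(ids))) {
      pair_aln <- aln[c(ids[i], ids[j])]
      cols <- gapless_columns(pair_aln)
      if (length(cols) < 3L) next
      pi_ <- with_coords[[i]]$ca_trace[residue_index(pair_aln[[1L]])[cols], , drop = FALSE]
      pj <- with_coords[[j]]$ca_trace[residue_index(pair_aln[[2L]])[cols], , drop = FALSE]
      pair_rmsds <- c(pair_rmsds, kabsch_superpose(pi_, pj)$rmsd)
    }
    if (length(pair_rmsds) > 0L) mean_pairwise <- mean(pair_rmsds)
    consensus <- tryCatch(
      consensus_superpose(with_coords, aln)$consensus_rmsd,
      error = function(e) NA_real_)
  }
  structure(
    list(superfamily_code = sf$code,
         n_initial_equivalences = n_initial,
         n_sst_equivalences = n_sst,
         mean_pairwise_rmsd = mean_pairwise,
         consensus_rmsd = consensus,
         n_members_with_coords = length(with_coords),
         alignment_length = nchar(aln[[1L]])),
    class = "quality_metrics"
  )
}

#' @export
print.quality_metrics <- function(x, ...) {
  cat("<quality_metrics> ", x$superfamily_code, ": ",
      x$n_initial_equivalences, "/", x$alignment_length,
      " initial equivalences, ",
      if (is.na(x$n_sst_equivalences)) "no-ss"
      else paste0(x$n_sst_equivalences, " SST equivalences"),
      ", mean pairwise RMSD ",
      if (is.na(x$mean_pairwise_rmsd)) "n/a"
      else format(x$mean_pairwise_rmsd, digits = 4),
      "\n", sep = "")
  invisible(x)
}
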