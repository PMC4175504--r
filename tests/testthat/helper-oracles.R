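# Independent oracles and quick fixture builders used across the suite.

# ---- brute-force global-alignment oracle ----------------------------------
# Enumerates every global alignment of a and b as a move sequence
# (1 = diagonal, 2 = consume a only, 3 = consume b only), scores each one,
# and among the maximum-score alignments picks the one a traceback from the
# terminal cell with preference diagonal > up > left would choose: the
# alignment whose reversed move sequence is lexicographically smallest.
enumerate_moves <- function(n, m) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i == n && j == m) return(memo[[key]] <- list(integer(0)))
    out <- list()
    if (i < n && j < m)
      out <- c(out, lapply(rec(i + 1L, j + 1L), function(p) c(1L, p)))
    if (i < n) out <- c(out, lapply(rec(i + 1L, j), function(p) c(2L, p)))
    if (j < m) out <- c(out, lapply(rec(i, j + 1L), function(p) c(3L, p)))
    memo[[key]] <- out
  }
  rec(0L, 0L)
}

oracle_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  paths <- enumerate_moves(length(ca), length(cb))
  eval_path <- function(p) {
    i <- 0L; j <- 0L; score <- 0; matches <- 0L; pairs <- 0L
    for (mv in p) {
      if (mv == 1L) {
        i <- i + 1L; j <- j + 1L
        pairs <- pairs + 1L
        if (ca[i] == cb[j]) {
          score <- score + match
          matches <- matches + 1L
        } else score <- score + mismatch
      } else if (mv == 2L) {
        i <- i + 1L; score <- score + gap
      } else {
        j <- j + 1L; score <- score + gap
      }
    }
    list(score = score, matches = matches, pairs = pairs)
  }
  stats <- lapply(paths, eval_path)
  scores <- vapply(stats, `[[`, numeric(1), "score")
  best <- max(scores)
  opt <- which(scores == best)
  keys <- vapply(paths[opt], function(p) paste(rev(p), collapse = ""),
                 character(1))
  chosen <- opt[order(keys, method = "radix")[1L]]
  st <- stats[[chosen]]
  list(score = best,
       identity = if (st$pairs == 0L) 0 else 100 * st$matches / st$pairs)
}

# ---- numeric superposition oracle -----------------------------------------
# Minimises RMSD over explicit rotation parameters (Euler angles): coarse
# grid scan followed by Nelder-Mead refinement from the best starts.
oracle_min_rmsd <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  rot <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    rz <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, ca[3], -sa[3], 0, sa[3], ca[3]), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(ang) sqrt(mean(rowSums((xc - yc %*% t(rot(ang)))^2)))
  grid <- seq(-pi, pi, length.out = 9)
  starts <- expand.grid(a = grid, b = grid, c = grid)
  vals <- apply(starts, 1L, obj)
  best <- Inf
  for (k in order(vals)[1:6]) {
    r <- stats::optim(as.numeric(starts[k, ]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
    best <- min(best, r$value)
  }
  best
}

# ---- quick builders --------------------------------------------------------
# Build a superfamily directly from aligned (gapped) strings. Member ids are
# derived from the code (pdb = last 4 digits, chain A, B, C, ...) so
# superfamilies with distinct codes can share a database version.
make_sf <- function(aligned, code = "10001", scop_class = "a",
                    strict = TRUE, ss = NULL, coords = NULL) {
  n <- length(aligned)
  num <- suppressWarnings(as.integer(code))
  if (is.na(num)) num <- sum(utf8ToInt(code))
  pdb <- sprintf("%04d", num %% 10000L)
  ids <- sprintf("%s_%s", pdb, LETTERS[seq_len(n)])
  aligned <- unname(aligned)
  members <- lapply(seq_len(n), function(i) {
    seq <- gsub("-", "", aligned[i], fixed = TRUE)
    domain_member(ids[i], pdb, LETTERS[i], code, scop_class, seq,
                  ss_string = if (is.null(ss)) NULL else ss[[i]],
                  ca_trace = if (is.null(coords)) NULL else coords[[i]])
  })
  names(aligned) <- ids
  superfamily(code, members, aligned, strict = strict)
}

# Build a superfamily whose member lengths are given; sequences are
# deterministic homopolymer-free strings (no identity control).
make_sf_lengths <- function(lengths, code = "10001", scop_class = "a",
                            strict = TRUE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  seqs <- vapply(seq_along(lengths), function(i)
    paste(aa[(seq_len(lengths[i]) + i) %% 20 + 1], collapse = ""),
    character(1))
  make_sf(vapply(seqs, function(s)
    paste0(s, strrep("-", max(lengths) - nchar(s))), character(1),
    USE.NAMES = FALSE),
    code = code, scop_class = scop_class, strict = strict)
}

# A length_stats object with prescribed per-member variations.
fake_profile <- function(variations, code = "sf") {
  structure(
    list(superfamily_code = code, mean_length = 100,
         per_member_variation = variations,
         sd_variation = sqrt(mean((variations - mean(variations))^2)),
         max_abs_variation = max(abs(variations)),
         n_members = length(variations)),
    class = "length_stats")
}

# Independent restatement of the sparse-branch decision rule, driven only by
# the deviant/rigid member counts.
sparse_oracle <- function(n_dev, n_rig, sparse_min = 2) {
  if (n_dev >= sparse_min) return("deviant")
  if (n_dev > n_rig) return("deviant")
  if (n_rig > n_dev) return("rigid")
  "normal"
}

random_aa_seq <- function(n, alphabet = c("A", "C", "G")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
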