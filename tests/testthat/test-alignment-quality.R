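test_that("initial equivalences count fully gapless columns", {
  aln <- c(strrep("A", 50), strrep("C", 50), strrep("D", 50))
  expect_equal(initial_equivalences(aln), 50L)
  aln2 <- c(paste0(strrep("A", 49), "-"), strrep("C", 50), strrep("D", 50))
  expect_equal(initial_equivalences(aln2), 49L)
  aln3 <- c(strrep("-", 50), strrep("C", 50), strrep("D", 50))
  expect_equal(initial_equivalences(aln3), 0L)
  expect_error(initial_equivalences(character(0)), "empty")
})

test_that("secondary-structural equivalences count state-unanimous gapless columns", {
  aln <- c(strrep("A", 30), strrep("C", 30), strrep("D", 30))
  ss_all_h <- list(strrep("H", 30), strrep("H", 30), strrep("H", 30))
  names(ss_all_h) <- names(aln) <- c("m1", "m2", "m3")
  expect_equal(sst_equivalences(aln, ss_all_h), 30L)

  ss_mixed <- ss_all_h
  ss_mixed[["m3"]] <- paste0(strrep("H", 29), "E")   # one column H/H/E
  expect_equal(sst_equivalences(aln, ss_mixed), 29L)

  # 40 gapless columns of which 25 unanimous, built explicitly
  aln4 <- c(strrep("A", 40), strrep("C", 40))
  names(aln4) <- c("m1", "m2")
  ss4 <- list(m1 = strrep("H", 40),
              m2 = paste0(strrep("H", 25), strrep("E", 15)))
  expect_equal(sst_equivalences(aln4, ss4), 25L)

  expect_error(sst_equivalences(aln, ss_all_h[1:2]), "m3")
  expect_lte(sst_equivalences(aln, ss_mixed), initial_equivalences(aln))
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  x <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 1), ncol = 3,
              byrow = TRUE)
  sup0 <- kabsch_superpose(x, x)
  expect_equal(sup0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sup0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sup0$rotation), 1, tolerance = 1e-9)

  th <- pi / 2                                  # 90 degrees about z
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, byrow = TRUE)
  y <- x %*% t(rot) + matrix(rep(c(3, -2, 7), each = nrow(x)), ncol = 3)
  sup <- kabsch_superpose(x, y)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(x[1:2, ], y[1:2, ]), "at least 3")
})

test_that("Kabsch RMSD equals a rotation-parameter numeric minimisation on noisy toys", {
  for (seed in c(2, 3)) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(15, sd = 3), ncol = 3)
      y <- x + matrix(rnorm(15, sd = 0.4), ncol = 3)
    })
    got <- kabsch_superpose(x, y)$rmsd
    want <- oracle_min_rmsd(x, y)
    expect_equal(got, want, tolerance = 1e-6)
    expect_lte(got, want + 1e-9)   # never above the numeric search
  }
})

test_that("Kabsch RMSD is invariant to common rigid motions and never exceeds raw RMSD", {
  withr::with_seed(5, {
    x <- matrix(rnorm(24, sd = 2), ncol = 3)
    y <- x + matrix(rnorm(24, sd = 0.5), ncol = 3)
  })
  base <- kabsch_superpose(x, y)$rmsd
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, byrow = TRUE)
  shift <- matrix(rep(c(-4, 2, 9), each = nrow(x)), ncol = 3)
  moved <- kabsch_superpose(x %*% t(rot) + shift, y %*% t(rot) + shift)$rmsd
  expect_equal(base, moved, tolerance = 1e-9)
  raw <- sqrt(mean(rowSums((x - y)^2)))
  expect_lte(base, raw + 1e-12)

  # translation-only difference superposes to zero
  expect_equal(kabsch_superpose(x, x + shift)$rmsd, 0, tolerance = 1e-9)
})

test_that("consensus superposition converges with a non-increasing objective", {
  tr <- generate_coordinates(20, noise_sigma = 0, seed = 1)
  aln <- setNames(rep(strrep("A", 20), 3), c("m1", "m2", "m3"))
  members <- lapply(names(aln), function(id)
    domain_member(id, "0001", substr(id, 2, 2), "1", "a", strrep("A", 20),
                  ca_trace = tr))
  res <- consensus_superpose(members, aln)
  expect_equal(res$consensus_rmsd, 0, tolerance = 1e-9)
  expect_true(res$converged)

  # noisy copies of a template: objective trace never increases
  withr::with_seed(8, {
    members_n <- lapply(c("a1", "a2", "a3", "a4"), function(id)
      domain_member(id, "0002", substr(id, 2, 2), "1", "a", strrep("A", 20),
                    ca_trace = tr + matrix(rnorm(60, sd = 1.5), ncol = 3)))
  })
  aln_n <- setNames(rep(strrep("A", 20), 4), c("a1", "a2", "a3", "a4"))
  res_n <- consensus_superpose(members_n, aln_n)
  expect_true(res_n$converged)
  expect_true(all(diff(res_n$objective_trace) <= 1e-9))
  expect_gt(res_n$consensus_rmsd, 0)
})

test_that("consensus RMSD grows with coordinate noise", {
  tr <- generate_coordinates(25, noise_sigma = 0, seed = 1)
  aln <- setNames(rep(strrep("A", 25), 3), c("a1", "a2", "a3"))
  mean_rmsd <- vapply(c(0.2, 1, 3), function(sigma) {
    vals <- vapply(1:6, function(seed) {
      withr::with_seed(seed * 100 + round(sigma * 10), {
        members <- lapply(c("a1", "a2", "a3"), function(id)
          domain_member(id, "0003", substr(id, 2, 2), "1", "a",
                        strrep("A", 25),
                        ca_trace = tr + matrix(rnorm(75, sd = sigma),
                                               ncol = 3)))
      })
      consensus_superpose(members, aln)$consensus_rmsd
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_rmsd) > 0))
})

test_that("quality report assembles equivalences and RMSDs coherently", {
  sf_plain <- generate_superfamily("rigid", 4, 60, seed = 2, code = "300")
  q0 <- quality_report(sf_plain)
  expect_true(is.na(q0$mean_pairwise_rmsd))    # no coordinates
  expect_true(is.na(q0$n_sst_equivalences))    # no secondary structure
  expect_gt(q0$n_initial_equivalences, 0L)

  aln <- setNames(rep("ACDEFGIKLNPQRSTV", 3), c("b1", "b2", "b3"))
  tr <- generate_coordinates(16, noise_sigma = 0, seed = 3)
  members <- lapply(names(aln), function(id)
    domain_member(id, "0004", substr(id, 2, 2), "77", "a",
                  "ACDEFGIKLNPQRSTV",
                  ss_string = strrep("H", 16), ca_trace = tr))
  sf_id <- superfamily("77", members, aln)
  q <- quality_report(sf_id)
  expect_equal(q$mean_pairwise_rmsd, 0, tolerance = 1e-9)
  expect_equal(q$consensus_rmsd, 0, tolerance = 1e-9)
  expect_equal(q$n_sst_equivalences, q$n_initial_equivalences)
  expect_equal(q$n_members_with_coords, 3L)
  expect_lte(q$n_sst_equivalences, q$n_initial_equivalences)
  expect_lte(q$n_initial_equivalences, q$alignment_length)

  # a rigid superfamily has a larger gapless fraction than a deviant one
  rigid <- generate_superfamily("rigid", 5, 100, seed = 4, code = "301")
  deviant <- generate_superfamily("deviant", 5, 100, seed = 4, code = "302")
  frac <- function(sf) {
    q <- quality_report(sf)
    q$n_initial_equivalences / q$alignment_length
  }
  expect_gte(frac(rigid), frac(deviant))
})
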