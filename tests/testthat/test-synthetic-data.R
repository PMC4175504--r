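test_that("mutate_to_identity lands within five points of its target", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  s100 <- withr::with_seed(1, paste(sample(aa, 100, TRUE), collapse = ""))
  expect_identical(mutate_to_identity(s100, 100, 1), s100)

  low <- mutate_to_identity(s100, 0, 2)
  expect_lte(global_align_identity(s100, low)$identity, 5)
  expect_equal(nchar(low), 100L)               # substitutions only

  s200 <- withr::with_seed(2, paste(sample(aa, 200, TRUE), collapse = ""))
  for (seed in 1:20) {
    m <- mutate_to_identity(s200, 30, seed)
    ident <- global_align_identity(s200, m)$identity
    expect_gte(ident, 25)
    expect_lte(ident, 35)
  }
  expect_error(mutate_to_identity(s100, 101, 1), "\\[0, 100\\]")
})

test_that("generated superfamilies recover their label under the improved scheme", {
  grid <- expand.grid(label = c("deviant", "rigid", "normal"),
                      n = c(3, 4, 6, 12), stringsAsFactors = FALSE)
  for (k in seq_len(nrow(grid))) {
    sf <- generate_superfamily(grid$label[k], grid$n[k], 150,
                               seed = 100 + k, code = as.character(k))
    got <- classify_improved(superfamily_profile(sf))$label
    expect_equal(got, grid$label[k],
                 label = sprintf("%s n=%d", grid$label[k], grid$n[k]))
    # alignment invariant: de-gapping reproduces each member's sequence
    for (id in names(sf$members))
      expect_equal(gsub("-", "", sf$alignment[[id]], fixed = TRUE),
                   sf$members[[id]]$sequence)
  }
  expect_error(generate_superfamily("deviant", 3, 4), "collapses")
})

test_that("generated rigid and normal superfamilies respect the redundancy cutoff", {
  for (seed in 1:5) {
    sf_r <- generate_superfamily("rigid", 5, 90, seed = seed, code = "400")
    sf_n <- generate_superfamily("normal", 5, 90, seed = seed, code = "401")
    expect_s3_class(
      database_version("chk", list(sf_r), check_redundancy = TRUE),
      "database_version")
    expect_s3_class(
      database_version("chk", list(sf_n), check_redundancy = TRUE),
      "database_version")
  }
})

test_that("coordinate traces are deterministic and noise shows up as RMSD", {
  t1 <- generate_coordinates(30, 0, seed = 5)
  t2 <- generate_coordinates(30, 0, seed = 9)
  expect_identical(t1, t2)                      # noiseless: seed-independent
  expect_equal(kabsch_superpose(t1, t2)$rmsd, 0, tolerance = 1e-12)
  expect_error(generate_coordinates(2, 0), "at least 3")
  expect_error(generate_coordinates(10, -1), "non-negative")

  # RMSD to the clean trace tracks the injected noise magnitude:
  # per-point displacement has sd sqrt(3)*sigma, superposition absorbs a bit
  rmsds <- vapply(1:50, function(seed)
    kabsch_superpose(t1, generate_coordinates(30, 1, seed = seed))$rmsd,
    numeric(1))
  expect_gt(mean(rmsds), 1.2)
  expect_lt(mean(rmsds), sqrt(3))
})

test_that("version pairs are bit-stable under a fixed seed", {
  sp <- generator_spec(n_superfamilies = c(rigid = 3, deviant = 1),
                       members_per_superfamily = c(4, 6),
                       mean_length = c(50, 80),
                       fate_counts = NULL, seed = 77)
  a <- generate_version_pair(sp)
  b <- generate_version_pair(sp)
  expect_identical(lapply(a$v1$superfamilies, `[[`, "alignment"),
                   lapply(b$v1$superfamilies, `[[`, "alignment"))
  expect_identical(a$truth$fates, b$truth$fates)
})

test_that("an all-retained plan produces a diff with zero changes", {
  pair <- generate_version_pair(generator_spec(
    n_superfamilies = c(rigid = 2, normal = 1),
    members_per_superfamily = c(3, 5), mean_length = c(50, 70), seed = 13))
  m <- map_superfamilies(pair$v1, pair$v2)
  expect_length(m$absent_from_new, 0L)
  expect_length(m$new_in_new, 0L)
  expect_length(detect_splits_merges(pair$v1, pair$v2), 0L)
  fates <- assign_member_fates(pair$v1, pair$v2)
  expect_true(all(fates$fate == "retained"))
})

test_that("split and merge plans are realised and recovered from member overlap", {
  pair <- generate_version_pair(generator_spec(
    n_superfamilies = c(rigid = 3),
    members_per_superfamily = rep(8L, 3), mean_length = c(50, 70),
    split_plans = list(list(old_code = "s1", n_descendants = 4)),
    merge_plans = list(list(old_codes = c("s2", "s3"), new_code = "s2")),
    seed = 21))
  ev <- detect_splits_merges(pair$v1, pair$v2)
  kinds <- vapply(ev, `[[`, character(1), "kind")
  expect_setequal(kinds, c("split", "merge"))
  split_ev <- ev[[which(kinds == "split")]]
  expect_length(split_ev$new_codes, 4L)
  truth_split <- pair$truth$events[[1]]
  expect_equal(split_ev$new_codes, truth_split$new_codes)
  merge_ev <- ev[[which(kinds == "merge")]]
  expect_equal(merge_ev$old_codes, pair$truth$events[[2]]$old_codes)
})

test_that("planned fates are recovered exactly across seeds", {
  for (seed in c(3, 14, 159)) {
    pair <- generate_version_pair(generator_spec(
      n_superfamilies = c(rigid = 5), members_per_superfamily = rep(5L, 5),
      mean_length = c(60, 90),
      fate_counts = c(retained = 9, superseded = 2, outlier = 5,
                      rescued_by_search = 4, rescued_by_identity = 3,
                      unaccounted = 2, new = 2),
      seed = seed))
    fates <- assign_member_fates(pair$v1, pair$v2)
    merged <- merge(fates, pair$truth$fates, by = "member_id")
    expect_equal(merged$fate.x, merged$fate.y, label = paste("seed", seed))
  }
})

test_that("infeasible generator plans fail loudly", {
  expect_error(generate_version_pair(generator_spec(
    n_superfamilies = c(rigid = 2), members_per_superfamily = rep(4L, 2),
    mean_length = c(50, 60), fate_counts = c(retained = 5), seed = 1)),
    "sum to")
  expect_error(generate_version_pair(generator_spec(
    n_superfamilies = c(rigid = 2), members_per_superfamily = rep(4L, 2),
    mean_length = c(50, 60),
    fate_counts = c(retained = 5, unaccounted = 3), seed = 1)),
    "unaccounted")
  expect_error(generator_spec(fate_counts = c(vanished = 3)), "unknown fate")
})
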