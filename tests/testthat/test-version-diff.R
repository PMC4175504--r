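test_that("superfamily mapping partitions the union of codes", {
  pair <- generate_version_pair(generator_spec(
    n_superfamilies = c(rigid = 3), members_per_superfamily = c(3, 4),
    mean_length = c(40, 60), seed = 1))
  same <- map_superfamilies(pair$v1, pair$v1)
  expect_length(same$common, 3L)
  expect_length(same$absent_from_new, 0L)
  expect_length(same$new_in_new, 0L)

  fx <- split_fixture("viral_4way")
  m <- map_superfamilies(fx$v1, fx$v2)
  expect_equal(m$common, character(0))         # disjoint codes
  expect_equal(m$absent_from_new, "49611")
  expect_length(m$new_in_new, 4L)
})

test_that("mapping recovers a database-scale common/absent/new composition", {
  old_codes <- as.character(1:397)
  new_codes <- as.character(c(21:397, 1001:1259))  # 377 common, 259 new
  v1 <- database_version("old", lapply(old_codes, function(cd)
    make_sf_lengths(c(4, 5, 6), code = cd)))
  v2 <- database_version("new", lapply(new_codes, function(cd)
    make_sf_lengths(c(4, 5, 6), code = cd)))
  m <- map_superfamilies(v1, v2)
  expect_length(m$common, 377L)
  expect_length(m$absent_from_new, 20L)
  expect_length(m$new_in_new, 259L)
})

test_that("split and merge detection recovers the fixture events and is symmetric", {
  fx <- split_fixture("viral_4way")
  ev <- detect_splits_merges(fx$v1, fx$v2)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$kind, "split")
  expect_equal(ev[[1]]$old_codes, "49611")
  expect_equal(ev[[1]]$new_codes, c("88633", "88645", "88648", "88650"))

  # swapping the version arguments turns the split into a merge
  ev_rev <- detect_splits_merges(fx$v2, fx$v1)
  expect_length(ev_rev, 1L)
  expect_equal(ev_rev[[1]]$kind, "merge")
  expect_equal(sort(ev_rev[[1]]$old_codes), ev[[1]]$new_codes)

  fx2 <- split_fixture("ovomucoid_2way")
  ev2 <- detect_splits_merges(fx2$v1, fx2$v2)
  expect_equal(ev2[[1]]$new_codes, c("100895", "100897"))

  fx3 <- split_fixture("etfp_merge")
  ev3 <- detect_splits_merges(fx3$v1, fx3$v2)
  expect_length(ev3, 1L)
  expect_equal(ev3[[1]]$kind, "merge")
  expect_equal(ev3[[1]]$old_codes, c("52402", "52431"))

  # identical versions produce no events
  expect_length(detect_splits_merges(fx$v1, fx$v1), 0L)
})

test_that("supersession needs equal length, full identity and a new pdb code", {
  base <- domain_member("1foi_A", "1foi", "A", "56024", "a/b", "ACDEFGIKLN")
  same_seq <- domain_member("1vow_A", "1vow", "A", "56024", "a/b", "ACDEFGIKLN")
  near <- domain_member("2aaa_A", "2aaa", "A", "56024", "a/b", "ACDEFGIKLP")
  same_pdb <- domain_member("1foi_B", "1foi", "B", "56024", "a/b", "ACDEFGIKLN")
  hit <- detect_supersession(base, list(near, same_seq))
  expect_equal(hit$member_id, "1vow_A")
  expect_null(detect_supersession(base, list(near)))
  expect_null(detect_supersession(base, list(same_pdb)))
  expect_null(detect_supersession(base, list()))
})

test_that("fate rules fire in their stated order on a constructed pair", {
  pair <- generate_version_pair(generator_spec(
    n_superfamilies = c(rigid = 4), members_per_superfamily = rep(5L, 4),
    mean_length = c(70, 90),
    fate_counts = c(retained = 8, superseded = 2, outlier = 4,
                    rescued_by_search = 3, rescued_by_identity = 2,
                    unaccounted = 1, new = 3),
    seed = 31))
  fates <- assign_member_fates(pair$v1, pair$v2)
  truth <- pair$truth$fates
  merged <- merge(fates, truth, by = "member_id")
  expect_equal(merged$fate.x, merged$fate.y)

  # identical versions: everything retained
  f_same <- assign_member_fates(pair$v1, pair$v1)
  expect_true(all(f_same$fate == "retained"))

  # evidence strings carry the measured identity for rescues
  resc <- fates[fates$fate %in% c("rescued_by_search", "rescued_by_identity"), ]
  expect_true(all(grepl("best identity", resc$evidence)))
})

test_that("a member whose superfamily vanished is unaccounted with that evidence", {
  sf <- make_sf_lengths(c(50, 55, 60), code = "111")
  v1 <- database_version("v1", list(sf))
  v2 <- database_version("v2", list())
  fates <- assign_member_fates(v1, v2)
  expect_true(all(fates$fate == "unaccounted"))
  expect_true(all(fates$evidence == "superfamily absent"))
})

test_that("accounting cascade telescopes for arbitrary generated pairs", {
  for (seed in 1:12) {
    n_per <- 5L
    pair <- generate_version_pair(generator_spec(
      n_superfamilies = c(rigid = 4), members_per_superfamily = rep(n_per, 4),
      mean_length = c(60, 90),
      fate_counts = c(retained = 7, superseded = 1, outlier = 4,
                      rescued_by_search = 3, rescued_by_identity = 3,
                      unaccounted = 2),
      seed = seed))
    rep <- accounting_cascade(pair$v1, pair$v2)
    fates <- rep$per_member[rep$per_member$fate != "new", ]
    # independent recount of the fate list against the stage counts
    expect_equal(rep$n_v1_total, nrow(fates))
    expect_equal(rep$n_retained, sum(fates$fate == "retained"))
    expect_equal(rep$n_missing, rep$n_v1_total - rep$n_retained)
    expect_equal(rep$n_queries, rep$n_missing - rep$n_outlier)
    expect_equal(rep$n_search_missing, rep$n_queries - rep$n_search_hits)
    expect_equal(rep$n_unaccounted,
                 rep$n_search_missing - rep$n_identity_rescued)
    # fate partition: every old member gets exactly one non-"new" fate
    expect_equal(
      sum(fates$fate %in% c("retained", "superseded", "outlier",
                            "rescued_by_search", "rescued_by_identity",
                            "unaccounted")),
      rep$n_v1_total)
  }
})

test_that("fate tables export as TSV", {
  fx <- split_fixture("etfp_merge")
  fates <- assign_member_fates(fx$v1, fx$v2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fates_tsv(fates, path)
  expect_equal(nrow(read.delim(path)), nrow(fates))
})
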