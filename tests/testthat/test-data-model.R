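test_that("member table parsing derives lengths and reports bad rows by line", {
  txt <- paste(
    "member_id\tpdb\tchain\tsf_code\tclass\tsequence\tss\tresolution",
    "1abc_A\t1abc\tA\t53067\ta/b\tACDEFG\tHHHEEC\t1.8",
    "2xyz_B\t2xyz\tB\t53067\ta/b\tACDE\t\t",
    "3pqr_A\t3pqr\tA\t47598\ta\tMKV\tCCC\t2.5",
    sep = "\n")
  members <- read_members_table(txt)
  expect_length(members, 3L)
  expect_equal(vapply(members, `[[`, integer(1), "length"), c(6L, 4L, 3L))
  expect_equal(members[[1]]$ss_string, "HHHEEC")
  expect_null(members[[2]]$ss_string)
  expect_equal(members[[3]]$resolution, 2.5)

  bad_ss <- paste(
    "member_id\tpdb\tchain\tsf_code\tclass\tsequence\tss",
    "1abc_A\t1abc\tA\t53067\ta/b\tACDEFG\tHHH",
    sep = "\n")
  expect_error(read_members_table(bad_ss), "line 2")

  expect_error(
    read_members_table("member_id\tpdb\tchain\tsf_code\tclass\tsequence\n1abc_A\t1abc\tA\t1\ta\tACDEFJ"),
    "line 2")  # J is not an amino acid

  expect_equal(
    read_members_table("member_id\tpdb\tchain\tsf_code\tclass\tsequence"),
    list())
  expect_error(read_members_table("member_id\tpdb\tchain\tsequence\n"),
               "mandatory column")
})

test_that("member table round-trips through write_members_table", {
  m <- list(
    domain_member("1abc_A", "1abc", "A", "53067", "a+b", "ACDEF",
                  ss_string = "HHEEC", resolution = 2.1),
    domain_member("2def_B", "2def", "B", "53067", "a+b", "MKVLN"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_members_table(m, path)
  back <- read_members_table(path)
  expect_equal(back, m)
})

test_that("gapped FASTA reader enforces the alignment dialect", {
  ok <- ">1abc_A some description\nACD-EF\n>2def_B\nAC--EF\n>3ghi_C\nACDCEF\n"
  aln <- read_alignment_fasta(ok)
  expect_named(aln, c("1abc_A", "2def_B", "3ghi_C"))
  expect_true(all(nchar(aln) == 6L))

  expect_error(read_alignment_fasta(">a\nACDE\n>b\nACD\n"), "unequal")
  expect_error(read_alignment_fasta(">a\nAC.E\n>b\nACDE\n"), "'\\.'")
  expect_error(read_alignment_fasta(">a\nACDE\n>a\nACDE\n"), "duplicate")

  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, path)
  expect_equal(read_alignment_fasta(path), aln)
})

test_that("CA trace reader handles PDB ATOM records and xyz tables", {
  pdb <- c(
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(1, 2, 3), c(0, 1, 2), c(0, 0, 1)),
    "ATOM      4  CB  ALA A   4       9.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL",
    "ATOM      5  CA  ALA A   5       7.000   7.000   7.000  1.00  0.00           C")
  tr <- read_ca_trace(pdb)
  expect_equal(dim(tr), c(3L, 3L))        # CB dropped, second model dropped
  expect_equal(tr[, 1], c(1, 2, 3))

  xyz <- read_ca_trace("0 0 0\n1.5,0,0\n3 0 0")
  expect_equal(dim(xyz), c(3L, 3L))
  expect_equal(xyz[2, 1], 1.5)

  expect_equal(nrow(read_ca_trace("")), 0L)
  expect_error(read_ca_trace("1 2 x"), "non-numeric")
})

test_that("superfamily invariants: degapping, width, membership, size", {
  expect_error(make_sf(c("ACD-", "AC-D", "ACD")), "unequal")
  aln <- c("ACD-", "AC-D", "A-CD")
  sf <- make_sf(aln)
  expect_equal(sf$members[["0001_A"]]$sequence, "ACD")
  expect_error(make_sf(c("ACD-", "AC-D")), "at least 3")
  expect_s3_class(make_sf(c("ACD-", "AC-D"), strict = FALSE), "superfamily")

  m <- domain_member("1abc_A", "1abc", "A", "1", "a", "ACDE")
  expect_error(superfamily("1", list(m), c("1abc_A" = "AC-E"),
                           strict = FALSE),
               "does not de-gap")
})

test_that("database version enforces unique ids and coherent outliers", {
  sf1 <- make_sf(c("ACD", "ACE", "ADE"), code = "10001")
  # codes 10001 and 20001 map to the same member ids in the helper,
  # deliberately forcing a cross-superfamily id clash
  sf2 <- make_sf(c("KLM", "KLN", "KMN"), code = "20001")
  expect_error(database_version("v", list(sf1, sf2)), "duplicated")
  db <- database_version("v", list(sf1))
  expect_equal(length(db$superfamilies), 1L)
  expect_error(database_version("v", list(sf1), outliers = "0001_A"),
               "also present")
  db2 <- database_version("v", list(sf1), outliers = "9zzz_Z")
  expect_equal(db2$outliers, "9zzz_Z")
})

test_that("redundancy flag rejects near-identical members", {
  aln <- c("ACDEFGIKLN", "ACDEFGIKLP", "PNLKIGFEDC")
  sf <- make_sf(aln, code = "7")
  expect_error(database_version("v", list(sf), check_redundancy = TRUE),
               "redundancy cutoff")
})

test_that("JSON reports round-trip with stable key order and reject non-finite values", {
  fx <- split_fixture("etfp_merge")
  rep <- accounting_cascade(fx$v1, fx$v2)
  path <- withr::local_tempfile(fileext = ".json")
  write_json_report(rep, path)
  back <- read_json_report(path)
  expect_s3_class(back, "accounting_report")
  for (f in c("n_v1_total", "n_retained", "n_missing", "n_outlier",
              "n_queries", "n_search_hits", "n_search_missing",
              "n_identity_rescued", "n_unaccounted"))
    expect_equal(back[[f]], rep[[f]])
  expect_equal(as.data.frame(back$per_member), rep$per_member,
               ignore_attr = TRUE)

  path2 <- withr::local_tempfile(fileext = ".json")
  write_json_report(rep, path2)
  expect_identical(readLines(path), readLines(path2))  # byte-stable

  expect_error(write_json_report(list(x = Inf), path), "non-finite")
})

test_that("a version directory round-trips through write/read", {
  pair <- generate_version_pair(generator_spec(
    n_superfamilies = c(rigid = 2, normal = 1),
    members_per_superfamily = c(3, 4), mean_length = c(40, 60),
    with_coords = TRUE, seed = 5))
  dir <- withr::local_tempdir()
  write_version_dir(pair$v1, dir)
  back <- read_version_dir(dir)
  expect_equal(back$label, pair$v1$label)
  expect_setequal(names(back$superfamilies), names(pair$v1$superfamilies))
  for (code in names(pair$v1$superfamilies)) {
    expect_equal(back$superfamilies[[code]]$alignment,
                 pair$v1$superfamilies[[code]]$alignment)
    for (id in names(pair$v1$superfamilies[[code]]$members))
      expect_equal(back$superfamilies[[code]]$members[[id]]$ca_trace,
                   pair$v1$superfamilies[[code]]$members[[id]]$ca_trace,
                   tolerance = 1e-3)   # text round-trip precision
  }
})
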