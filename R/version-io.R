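# On-disk layout for a database version: one directory holding members.tsv,
# one gapped FASTA alignment per superfamily (sf_<code>.fasta), outliers.txt
# and optionally coords/<member_id>.xyz and ss/<member_id>.txt.

#' Write a database version to a directory
#'
#' @param db A [database_version()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_version_dir <- function(db, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  members <- version_members(db)
  write_members_table(members, file.path(dir, "members.tsv"))
  for (sf in db$superfamilies)
    write_alignment_fasta(sf$alignment,
                          file.path(dir, paste0("sf_", sf$code, ".fasta")))
  writeLines(db$outliers, file.path(dir, "outliers.txt"))
  writeLines(db$label, file.path(dir, "label.txt"))
  has_coords <- Filter(function(m) !is.null(m$ca_trace), members)
  if (length(has_coords) > 0L) {
    dir.create(file.path(dir, "coords"), showWarnings = FALSE)
    for (m in has_coords)
      write_ca_trace(m$ca_trace,
                     file.path(dir, "coords", paste0(m$member_id, ".xyz")))
  }
  invisible(dir)
}

#' Read a database version from a directory
#'
#' Reads the layout written by [write_version_dir()]. Outlier members appear
#' only in `outliers.txt`, never in the member table or the alignments.
#'
#' @param dir Directory path.
#' @param strict Require >= 3 members per superfamily.
#' @param label Version label; defaults to the stored one, else the
#'   directory basename.
#' @return A [database_version()].
#' @export
read_version_dir <- function(dir, strict = TRUE, label = NULL) {
  if (!dir.exists(dir)) stop("no such version directory: ", dir)
  members_file <- file.path(dir, "members.tsv")
  if (!file.exists(members_file))
    stop("version directory has no members.tsv: ", dir)
  members <- read_members_table(members_file)
  coords_dir <- file.path(dir, "coords")
  if (dir.exists(coords_dir)) {
    members <- lapply(members, function(m) {
      f <- file.path(coords_dir, paste0(m$member_id, ".xyz"))
      if (file.exists(f))
        m <- domain_member(m$member_id, m$pdb_code, m$chain,
                           m$superfamily_code, m$scop_class, m$sequence,
                           ss_string = m$ss_string,
                           ca_trace = read_ca_trace(f),
                           resolution = m$resolution)
      m
    })
  }
  by_code <- split(members,
                   vapply(members, `[[`, character(1), "superfamily_code"))
  sfs <- lapply(names(by_code), function(code) {
    aln <- read_alignment_fasta(file.path(dir, paste0("sf_", code, ".fasta")))
    superfamily(code, by_code[[code]], aln, strict = strict)
  })
  outlier_file <- file.path(dir, "outliers.txt")
  outliers <- if (file.exists(outlier_file)) {
    x <- readLines(outlier_file, warn = FALSE)
    x[nzchar(x)]
  } else character(0)
  if (is.null(label)) {
    label_file <- file.path(dir, "label.txt")
    label <- if (file.exists(label_file)) readLines(label_file, warn = FALSE)[1]
             else basename(dir)
  }
  database_version(label, sfs, outliers = outliers)
}
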