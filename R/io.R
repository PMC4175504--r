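# Readers and writers for the plain-text formats the pipeline touches:
# member metadata TSV, gapped FASTA alignments, CA traces, JSON reports.

# Accept either a file path or literal text: an existing single-line file
# path is read; anything else is taken as the text itself.
input_lines <- function(path_or_text) {
  if (length(path_or_text) > 1L) return(as.character(path_or_text))
  if (grepl("\n", path_or_text, fixed = TRUE))
    return(strsplit(path_or_text, "\n", fixed = TRUE)[[1]])
  if (file.exists(path_or_text))
    return(readLines(path_or_text, warn = FALSE))
  path_or_text
}

#' Read a member metadata table
#'
#' Parses a TSV with a header row holding at least the columns `member_id`,
#' `pdb`, `chain`, `sf_code`, `class` and `sequence`; optional columns `ss`
#' and `resolution` are picked up when present. Domain lengths are derived
#' from the sequences. Malformed rows are reported with their line numbers.
#'
#' @param path_or_text Path to a TSV file, or the table itself as a string or
#'   character vector of lines.
#' @return A list of [domain_member()] objects.
#' @export
read_members_table <- function(path_or_text) {
  lines <- input_lines(path_or_text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty members table: no header row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  mandatory <- c("member_id", "pdb", "chain", "sf_code", "class", "sequence")
  missing_cols <- setdiff(mandatory, header)
  if (length(missing_cols) > 0L)
    stop("members table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  col <- function(fields, name) {
    idx <- match(name, header)
    if (is.na(idx) || idx > length(fields)) NA_character_ else fields[idx]
  }
  members <- vector("list", length(lines) - 1L)
  for (i in seq_along(members)) {
    line_no <- i + 1L
    fields <- strsplit(lines[line_no], "\t", fixed = TRUE)[[1]]
    ss <- col(fields, "ss")
    if (!is.na(ss) && !nzchar(ss)) ss <- NA_character_
    res <- col(fields, "resolution")
    res_num <- if (is.na(res) || !nzchar(res)) NULL else suppressWarnings(as.numeric(res))
    if (!is.null(res_num) && is.na(res_num))
      stop("line ", line_no, ": non-numeric resolution '", res, "'")
    members[[i]] <- tryCatch(
      domain_member(
        member_id = col(fields, "member_id"),
        pdb_code = col(fields, "pdb"),
        chain = col(fields, "chain"),
        superfamily_code = col(fields, "sf_code"),
        scop_class = col(fields, "class"),
        sequence = col(fields, "sequence"),
        ss_string = if (is.na(ss)) NULL else ss,
        resolution = res_num
      ),
      error = function(e) stop("line ", line_no, ": ", conditionMessage(e),
                               call. = FALSE)
    )
  }
  members
}

#' Write a member metadata table
#'
#' Inverse of [read_members_table()]: emits the TSV dialect that reader
#' accepts, including optional `ss` and `resolution` columns.
#'
#' @param members List of [domain_member()] objects.
#' @param path Output file path.
#' @export
write_members_table <- function(members, path) {
  df <- data.frame(
    member_id = vapply(members, `[[`, character(1), "member_id"),
    pdb = vapply(members, `[[`, character(1), "pdb_code"),
    chain = vapply(members, `[[`, character(1), "chain"),
    sf_code = vapply(members, `[[`, character(1), "superfamily_code"),
    class = vapply(members, `[[`, character(1), "scop_class"),
    sequence = vapply(members, `[[`, character(1), "sequence"),
    ss = vapply(members, function(m) if (is.null(m$ss_string)) "" else m$ss_string,
                character(1)),
    resolution = vapply(members, function(m)
      if (is.null(m$resolution)) "" else format(m$resolution), character(1)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gapped FASTA alignment
#'
#' Headers carry the member id as their first whitespace-delimited token; any
#' description after it is dropped. The only accepted gap character is `'-'`;
#' `'.'` gaps and unequal aligned lengths are format errors, as are duplicate
#' ids.
#'
#' @param path_or_text Path to a FASTA file, or the FASTA text itself.
#' @return Named character vector mapping member id to aligned string.
#' @export
read_alignment_fasta <- function(path_or_text) {
  lines <- input_lines(path_or_text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L || !startsWith(lines[1], ">"))
    stop("not FASTA: first non-blank line must start with '>'")
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  groups <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], groups[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""),
                 character(1))
  if (length(seqs) != length(ids))
    stop("FASTA record without sequence lines")
  names(seqs) <- ids
  if (any(grepl(".", seqs, fixed = TRUE)))
    stop("alignment uses '.' gap characters; only '-' is accepted")
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L)
    stop("aligned sequences have unequal lengths: ",
         paste(unique(widths), collapse = ", "))
  seqs
}

#' Write a gapped FASTA alignment
#'
#' @param alignment Named character vector of equal-length gapped strings.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @export
write_alignment_fasta <- function(alignment, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(alignment)) {
    writeLines(paste0(">", id), con)
    s <- alignment[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a C-alpha trace
#'
#' Accepts either PDB-format `ATOM` records (only CA atoms are kept; first
#' model only; altloc blank or `'A'` only) or a plain table with one
#' `x y z` (or `x,y,z`) triple per line. Points are returned in file order.
#'
#' @param path_or_text Path or literal text.
#' @return Numeric matrix with one row per residue and columns x, y, z.
#' @export
read_ca_trace <- function(path_or_text) {
  lines <- input_lines(path_or_text)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(matrix(numeric(0), ncol = 3L))
  if (any(startsWith(lines, "ATOM"))) {
    end <- match("ENDMDL", substr(lines, 1, 6))
    if (!is.na(end)) lines <- lines[seq_len(end - 1L)]  # first model only
    atom <- lines[startsWith(lines, "ATOM")]
    name <- trimws(substr(atom, 13, 16))
    altloc <- substr(atom, 17, 17)
    keep <- name == "CA" & altloc %in% c(" ", "", "A")
    atom <- atom[keep]
    xyz <- cbind(substr(atom, 31, 38), substr(atom, 39, 46), substr(atom, 47, 54))
    coords <- suppressWarnings(matrix(as.numeric(xyz), ncol = 3L))
  } else {
    parts <- strsplit(trimws(lines), "[,[:space:]]+")
    if (any(lengths(parts) != 3L))
      stop("coordinate table rows must hold exactly 3 values")
    coords <- suppressWarnings(
      matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE))
  }
  if (anyNA(coords)) stop("non-numeric coordinate in CA trace input")
  coords
}

#' Write a C-alpha trace as an x,y,z table
#'
#' @param ca_trace Numeric n x 3 matrix.
#' @param path Output file path.
#' @export
write_ca_trace <- function(ca_trace, path) {
  write.table(format(ca_trace, trim = TRUE), path, sep = " ",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Recursively check a report for non-finite numbers before serialisation.
assert_finite <- function(x, where = "report") {
  if (is.numeric(x) && any(!is.finite(x) & !is.na(x)))
    stop("non-finite value in ", where, "; refusing to serialise")
  if (is.list(x))
    for (i in seq_along(x)) {
      nm <- if (!is.null(names(x)) && nzchar(names(x)[i]))
        paste0(where, "$", names(x)[i]) else where
      assert_finite(x[[i]], nm)
    }
  invisible(TRUE)
}

# Recursively sort list names for stable key order across runs.
sort_keys <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x))))
      x <- x[order(names(x))]
    return(lapply(x, sort_keys))
  }
  x
}

#' Write a pipeline report as JSON
#'
#' Serialises any of the pipeline's report objects (accounting reports,
#' classification results, quality metrics, ...) to UTF-8 JSON with sorted
#' keys, so output is byte-stable across runs. Reports containing non-finite
#' floats are rejected. [read_json_report()] reconstructs an object with equal
#' content.
#'
#' @param report A report object (a classed list or data frame).
#' @param path Output file path.
#' @export
write_json_report <- function(report, path) {
  assert_finite(report)
  payload <- list(report_class = class(report)[1],
                  data = sort_keys(unclass(report)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report written by [write_json_report()]
#'
#' @param path File path.
#' @return The reconstructed report object, with its original class.
#' @export
read_json_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- payload$data
  cls <- payload$report_class
  if (!identical(cls, "list")) class(out) <- cls
  out
}
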