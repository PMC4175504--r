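#' Construct a protein domain member
#'
#' A `domain_member` is one entry of a superfamily: a protein domain with its
#' identifiers, ungapped amino-acid sequence and optional structural
#' annotations (secondary-structure string and C-alpha trace).
#'
#' @param member_id Member identifier, conventionally the lowercase PDB code,
#'   an underscore and the chain (e.g. `"1jce_A"`); an opaque region suffix
#'   may follow.
#' @param pdb_code Four-character PDB code.
#' @param chain Single-character chain identifier.
#' @param superfamily_code Superfamily code (e.g. a SCOP sunid such as
#'   `"53067"`).
#' @param scop_class SCOP structural class, one of `"a"`, `"b"`, `"a/b"`,
#'   `"a+b"`.
#' @param sequence Ungapped amino-acid sequence over the 20 standard one-letter
#'   codes. The domain length is derived from it.
#' @param ss_string Optional secondary-structure string over `{H,E,C}`, one
#'   character per residue.
#' @param ca_trace Optional numeric matrix of C-alpha coordinates in Angstrom,
#'   one row per residue, three columns (x, y, z).
#' @param resolution Optional crystallographic resolution in Angstrom.
#'
#' @return An object of class `domain_member`.
#' @export
domain_member <- function(member_id, pdb_code, chain, superfamily_code,
                          scop_class, sequence, ss_string = NULL,
                          ca_trace = NULL, resolution = NULL) {
  stopifnot(is.character(member_id), length(member_id) == 1L, nzchar(member_id))
  if (!is.character(pdb_code) || length(pdb_code) != 1L || nchar(pdb_code) != 4L)
    stop("`pdb_code` must be a 4-character string, got: ", pdb_code)
  if (!is.character(chain) || length(chain) != 1L || nchar(chain) != 1L)
    stop("`chain` must be a single character, got: ", chain)
  if (!scop_class %in% SCOP_CLASSES)
    stop("unknown SCOP class '", scop_class, "' (expected one of: ",
         paste(SCOP_CLASSES, collapse = ", "), ")")
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(residues), AA_ALPHABET)
  if (length(bad) > 0L)
    stop("sequence of '", member_id, "' contains non-amino-acid characters: ",
         paste(bad, collapse = ""))
  len <- length(residues)
  if (len == 0L) stop("sequence of '", member_id, "' is empty")
  if (!is.null(ss_string)) {
    if (nchar(ss_string) != len)
      stop("ss_string of '", member_id, "' has ", nchar(ss_string),
           " characters but the sequence has ", len, " residues")
    ss_chars <- strsplit(ss_string, "", fixed = TRUE)[[1]]
    if (!all(ss_chars %in% SS_STATES))
      stop("ss_string of '", member_id, "' contains states outside {H,E,C}")
  }
  if (!is.null(ca_trace)) {
    ca_trace <- as.matrix(ca_trace)
    if (!is.numeric(ca_trace) || ncol(ca_trace) != 3L)
      stop("ca_trace of '", member_id, "' must be a numeric n x 3 matrix")
    if (nrow(ca_trace) != len)
      stop("ca_trace of '", member_id, "' has ", nrow(ca_trace),
           " points but the sequence has ", len, " residues")
    dimnames(ca_trace) <- NULL
  }
  structure(
    list(member_id = member_id, pdb_code = pdb_code, chain = chain,
         superfamily_code = superfamily_code, scop_class = scop_class,
         sequence = sequence, length = len, ss_string = ss_string,
         ca_trace = ca_trace, resolution = resolution),
    class = "domain_member"
  )
}

#' @export
print.domain_member <- function(x, ...) {
  cat("<domain_member> ", x$member_id, " (", x$length, " aa, class ",
      x$scop_class, ", superfamily ", x$superfamily_code, ")\n", sep = "")
  invisible(x)
}

#' Construct a superfamily
#'
#' A superfamily is a coded set of domain members together with a gapped
#' multiple sequence alignment covering exactly those members.
#'
#' @param code Superfamily code.
#' @param members List of [domain_member()] objects.
#' @param alignment Named character vector mapping each `member_id` to its
#'   aligned (gapped) sequence; gap character is `'-'`. All aligned strings
#'   must have identical length and de-gap to the member's sequence.
#' @param name Human-readable name; defaults to the code.
#' @param scop_class Structural class of the superfamily; defaults to the most
#'   common class among the members.
#' @param strict If `TRUE` (the database default) require at least 3 members;
#'   set to `FALSE` for small fixtures or version-diff intermediates.
#'
#' @return An object of class `superfamily`.
#' @export
superfamily <- function(code, members, alignment, name = code,
                        scop_class = NULL, strict = TRUE) {
  stopifnot(is.character(code), length(code) == 1L, is.list(members))
  ids <- vapply(members, function(m) m$member_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate member ids in superfamily ", code, ": ",
         paste(ids[duplicated(ids)], collapse = ", "))
  if (strict && length(members) < 3L)
    stop("superfamily ", code, " has ", length(members),
         " members; at least 3 are required")
  if (!is.character(alignment) || is.null(names(alignment)))
    stop("alignment must be a named character vector")
  if (!setequal(names(alignment), ids))
    stop("alignment ids do not match member ids for superfamily ", code)
  widths <- nchar(alignment)
  if (length(unique(widths)) > 1L)
    stop("aligned strings of superfamily ", code,
         " have unequal lengths: ", paste(unique(widths), collapse = ", "))
  if (any(grepl(".", alignment, fixed = TRUE)))
    stop("alignment of superfamily ", code,
         " uses '.' gaps; only '-' is accepted")
  for (m in members) {
    degapped <- gsub("-", "", alignment[[m$member_id]], fixed = TRUE)
    if (!identical(degapped, m$sequence))
      stop("aligned string of '", m$member_id,
           "' does not de-gap to its sequence")
  }
  names(members) <- ids
  if (is.null(scop_class)) {
    classes <- vapply(members, function(m) m$scop_class, character(1))
    scop_class <- names(sort(table(classes), decreasing = TRUE))[1]
  }
  structure(
    list(code = code, name = name, scop_class = scop_class,
         members = members, alignment = alignment[ids]),
    class = "superfamily"
  )
}

#' @export
print.superfamily <- function(x, ...) {
  cat("<superfamily> ", x$code, ": ", length(x$members), " members, alignment ",
      nchar(x$alignment[[1]]), " columns\n", sep = "")
  invisible(x)
}

#' Construct a database version
#'
#' A labelled collection of superfamilies keyed by superfamily code, plus the
#' set of members annotated as outliers (members that could not be
#' structurally aligned with the rest of their superfamily and therefore sit
#' outside every alignment).
#'
#' @param label Version label (e.g. `"v2004"`).
#' @param superfamilies List of [superfamily()] objects (named or unnamed;
#'   keyed by code on construction).
#' @param outliers Character vector of outlier member ids. Each must be absent
#'   from every alignment in the version.
#' @param check_redundancy If `TRUE`, enforce the database entry rule that all
#'   pairwise member identities within a superfamily are below
#'   `redundancy_cutoff` (computed with [global_align_identity()]).
#' @param redundancy_cutoff Percent identity ceiling for the redundancy check.
#'
#' @return An object of class `database_version`.
#' @export
database_version <- function(label, superfamilies, outliers = character(),
                             check_redundancy = FALSE,
                             redundancy_cutoff = 40) {
  stopifnot(is.character(label), length(label) == 1L, is.list(superfamilies))
  codes <- vapply(superfamilies, function(s) s$code, character(1))
  if (anyDuplicated(codes))
    stop("duplicate superfamily codes: ",
         paste(codes[duplicated(codes)], collapse = ", "))
  names(superfamilies) <- codes
  all_ids <- unlist(lapply(superfamilies, function(s) names(s$members)),
                    use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("member ids duplicated across superfamilies: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  outliers <- unique(as.character(outliers))
  clash <- intersect(outliers, all_ids)
  if (length(clash) > 0L)
    stop("outlier ids also present in alignments: ",
         paste(clash, collapse = ", "))
  if (check_redundancy) {
    for (sf in superfamilies) {
      ms <- sf$members
      n <- length(ms)
      if (n < 2L) next
      for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
        ident <- global_align_identity(ms[[i]]$sequence, ms[[j]]$sequence)$identity
        if (ident >= redundancy_cutoff)
          stop("members '", ms[[i]]$member_id, "' and '", ms[[j]]$member_id,
               "' of superfamily ", sf$code, " share ", round(ident, 1),
               "% identity (>= ", redundancy_cutoff, "% redundancy cutoff)")
      }
    }
  }
  structure(
    list(label = label, superfamilies = superfamilies, outliers = outliers),
    class = "database_version"
  )
}

#' @export
print.database_version <- function(x, ...) {
  n_mem <- sum(vapply(x$superfamilies, function(s) length(s$members), integer(1)))
  cat("<database_version> ", x$label, ": ", length(x$superfamilies),
      " superfamilies, ", n_mem, " members, ", length(x$outliers),
      " outliers\n", sep = "")
  invisible(x)
}

# All member ids of a version, across superfamilies (alignment members only).
version_member_ids <- function(db) {
  unlist(lapply(db$superfamilies, function(s) names(s$members)),
         use.names = FALSE)
}

# Flat list of all members of a version, named by member_id.
version_members <- function(db) {
  out <- unlist(lapply(db$superfamilies, function(s) s$members),
                recursive = FALSE, use.names = FALSE)
  names(out) <- vapply(out, function(m) m$member_id, character(1))
  out
}
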