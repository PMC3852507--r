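#' Read precursor hairpin records
#'
#' Joins three files by miRNA id into `hairpin_record` objects for the
#' sequence/structure analysis: a FASTA of precursor sequences, a Vienna
#' dot-bracket file of their secondary structures (`>id` line followed by the
#' structure line), and a coordinate TSV (`mirna_id`, `mature_start`,
#' `mature_end`, 1-based inclusive positions of the mature miRNA on the
#' precursor). DNA input (`T`) is transliterated to the RNA alphabet (`U`).
#' Ids present in only some of the three files are reported and skipped.
#'
#' @param fasta_path FASTA file of precursor sequences keyed by miRNA id.
#' @param struct_path Vienna dot-bracket file keyed by the same ids.
#' @param coords_path TSV of mature coordinates (optional header).
#' @return A named list of `hairpin_record` objects, each with fields
#'   `mirna_id`, `mature_seq`, `precursor_seq`, `precursor_struct`,
#'   `mature_start`, `mature_end`.
#' @export
read_hairpins <- function(fasta_path, struct_path, coords_path) {
  .check_string(fasta_path, "fasta_path")
  .check_string(struct_path, "struct_path")
  .check_string(coords_path, "coords_path")

  seqs <- Biostrings::readBStringSet(fasta_path)
  seq_ids <- trimws(sub("\\s.*$", "", names(seqs)))
  seqs <- setNames(toupper(as.character(seqs)), seq_ids)
  seqs <- chartr("T", "U", seqs)

  structs <- .read_vienna(struct_path)
  coords <- .read_coords(coords_path)

  common <- Reduce(intersect, list(.norm_id(seq_ids), .norm_id(names(structs)),
                                   .norm_id(coords$mirna_id)))
  missing <- setdiff(unique(c(.norm_id(seq_ids), .norm_id(names(structs)),
                              .norm_id(coords$mirna_id))), common)
  if (length(missing)) {
    rlang::inform(sprintf(
      "read_hairpins: %d id(s) absent from at least one input were skipped: %s",
      length(missing), paste(utils::head(missing, 5L), collapse = ", ")
    ))
  }
  names(seqs) <- .norm_id(seq_ids)
  names(structs) <- .norm_id(names(structs))
  ord <- match(common, .norm_id(coords$mirna_id))

  records <- lapply(seq_along(common), function(k) {
    key <- common[k]
    new_hairpin_record(
      mirna_id = coords$mirna_id[ord[k]],
      precursor_seq = seqs[[key]],
      precursor_struct = structs[[key]],
      mature_start = coords$mature_start[ord[k]],
      mature_end = coords$mature_end[ord[k]]
    )
  })
  setNames(records, vapply(records, `[[`, character(1), "mirna_id"))
}

#' Construct a hairpin record
#'
#' Validates the invariants tying a precursor sequence, its dot-bracket
#' structure and the mature-arm coordinates together. The mature sequence is
#' the precursor substring at `[mature_start, mature_end]`.
#'
#' @param mirna_id miRNA identifier.
#' @param precursor_seq Precursor RNA sequence (A/C/G/U; T is transliterated).
#' @param precursor_struct Dot-bracket string, same length as the sequence.
#' @param mature_start,mature_end 1-based inclusive mature coordinates.
#' @return A `hairpin_record`.
#' @export
new_hairpin_record <- function(mirna_id, precursor_seq, precursor_struct,
                               mature_start, mature_end) {
  .check_string(mirna_id, "mirna_id")
  precursor_seq <- chartr("T", "U", toupper(precursor_seq))
  if (grepl("[^ACGU]", precursor_seq)) {
    rlang::abort(sprintf("hairpin '%s': precursor contains non-RNA characters.", mirna_id))
  }
  if (nchar(precursor_struct) != nchar(precursor_seq)) {
    rlang::abort(sprintf(
      "hairpin '%s': structure length (%d) != sequence length (%d).",
      mirna_id, nchar(precursor_struct), nchar(precursor_seq)
    ))
  }
  bal <- .dotbracket_balance(precursor_struct)
  if (!is.null(bal)) {
    rlang::abort(sprintf("hairpin '%s': unbalanced dot-bracket at position %d.",
                         mirna_id, bal))
  }
  mature_start <- .check_count(mature_start, "mature_start", min = 1L)
  mature_end <- .check_count(mature_end, "mature_end", min = 1L)
  if (mature_start > mature_end || mature_end > nchar(precursor_seq)) {
    rlang::abort(sprintf("hairpin '%s': mature window [%d, %d] outside precursor (length %d).",
                         mirna_id, mature_start, mature_end, nchar(precursor_seq)))
  }
  mature_seq <- substr(precursor_seq, mature_start, mature_end)
  if (nchar(mature_seq) < 8L) {
    rlang::abort(sprintf("hairpin '%s': mature sequence shorter than 8 nt.", mirna_id))
  }
  structure(
    list(mirna_id = mirna_id, mature_seq = mature_seq,
         precursor_seq = precursor_seq, precursor_struct = precursor_struct,
         mature_start = mature_start, mature_end = mature_end),
    class = "hairpin_record"
  )
}

#' @export
print.hairpin_record <- function(x, ...) {
  cat(sprintf("<hairpin_record> %s: %d nt precursor, mature %d-%d\n",
              x$mirna_id, nchar(x$precursor_seq), x$mature_start, x$mature_end))
  invisible(x)
}

# returns NULL when balanced, else the 1-based position of the first defect
.dotbracket_balance <- function(struct) {
  chars <- strsplit(struct, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad)) return(bad[1L])
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(i)
    }
  }
  if (depth != 0L) return(length(chars))
  NULL
}

.read_vienna <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) rlang::abort(sprintf("empty structure file: '%s'.", path))
  headers <- grepl("^>", lines)
  if (!headers[1L]) rlang::abort(sprintf("'%s' does not start with a '>' header line.", path))
  ids <- trimws(sub("^>\\s*", "", lines[headers]))
  ids <- sub("\\s.*$", "", ids)
  out <- split(lines[!headers], cumsum(headers)[!headers])
  structs <- vapply(out, function(x) paste(trimws(x), collapse = ""), character(1))
  if (length(structs) != length(ids)) {
    rlang::abort(sprintf("'%s': header without a structure line.", path))
  }
  # structure lines may carry a trailing free-energy annotation " (-12.30)"
  structs <- sub("\\s+\\(\\s*-?[0-9.]+\\s*\\)\\s*$", "", structs)
  setNames(structs, ids)
}

.read_coords <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) rlang::abort(sprintf("empty coordinate file: '%s'.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- if (suppressWarnings(is.na(as.integer(fields[[1L]][2L])))) 2L else 1L
  if (start > length(fields)) rlang::abort(sprintf("'%s' has a header only.", path))
  rows <- fields[seq(start, length(fields))]
  bad <- which(lengths(rows) < 3L)
  if (length(bad)) {
    rlang::abort(sprintf("malformed coordinate row at line %d of '%s'.",
                         bad[1L] + start - 1L, path))
  }
  list(
    mirna_id = vapply(rows, function(f) trimws(f[1L]), character(1)),
    mature_start = as.integer(vapply(rows, `[`, character(1), 2L)),
    mature_end = as.integer(vapply(rows, `[`, character(1), 3L))
  )
}
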