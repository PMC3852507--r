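#' Read a static miRNA-to-target map
#'
#' Reads a two-column TSV of (miRNA id, gene id) pairs — the TargetScan-style
#' static target prediction table — collapsing duplicate rows into sets.
#' A header line is detected heuristically (first row whose second field is
#' one of `gene`, `gene_id`, `target`, `target_id`, case-insensitive) and
#' skipped.
#'
#' @param path Path to the TSV file.
#' @return A `target_map`: list with `targets_of` (named list, miRNA id ->
#'   character vector of gene ids) and `n_pairs` (unique pair count).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("miR-1\tGENE1", "miR-1\tGENE1", "miR-1\tGENE2"), tf)
#' tm <- read_target_map(tf)
#' tm$n_pairs
#' @export
read_target_map <- function(path) {
  pairs <- .read_pair_table(path, what = "target map",
                            header_keys = c("gene", "gene_id", "target", "target_id"))
  .new_target_map(pairs[[1L]], pairs[[2L]])
}

.new_target_map <- function(mirna, gene) {
  key <- .norm_id(mirna)
  # keep first-seen spelling per id
  display <- setNames(mirna, key)[!duplicated(key)]
  uniq <- !duplicated(paste(key, .norm_id(gene), sep = "\r"))
  mirna <- mirna[uniq]; gene <- gene[uniq]; key <- key[uniq]
  targets_of <- split(gene, factor(display[key], levels = unname(display)))
  targets_of <- lapply(targets_of, unique)
  structure(
    list(targets_of = targets_of, n_pairs = length(gene)),
    class = "target_map"
  )
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("<target_map> %d miRNAs, %d unique miRNA-gene pairs\n",
              length(x$targets_of), x$n_pairs))
  invisible(x)
}

#' @describeIn read_target_map One row per unique (miRNA, gene) pair.
#' @param x A `target_map`.
#' @param ... Unused.
#' @export
tidy.target_map <- function(x, ...) {
  tibble::tibble(
    mirna_id = rep(names(x$targets_of), lengths(x$targets_of)),
    gene_id = unlist(x$targets_of, use.names = FALSE)
  )
}

# shared two-column TSV reader with line-numbered errors
.read_pair_table <- function(path, what, header_keys) {
  .check_string(path, "path")
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) rlang::abort(sprintf("empty file: '%s' (%s).", path, what))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(fields[[1L]]) >= 2L &&
      .norm_id(fields[[1L]][2L]) %in% header_keys) {
    start <- 2L
    if (length(fields) < 2L) rlang::abort(sprintf("empty file: '%s' has a header only.", path))
  }
  a <- character(0); b <- character(0)
  for (i in seq(start, length(fields))) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L])) {
      rlang::abort(sprintf("malformed row at line %d of '%s': expected 2 tab-separated fields.",
                           i, path))
    }
    a <- c(a, f[1L]); b <- c(b, f[2L])
  }
  list(a, b)
}

#' Read pathway gene sets (GMT)
#'
#' Standard GMT dialect: one pathway per line, tab-separated fields
#' `name`, `description`, then gene ids. Genes are de-duplicated per set.
#'
#' @param path Path to the `.gmt` file.
#' @return A `gene_set_collection`: list with `sets` (named list of gene id
#'   vectors) and `descriptions` (named character vector).
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("P1\tdemo pathway\tg1\tg2\tg2", tf)
#' gs <- read_gene_sets(tf)
#' gs$sets$P1
#' @export
read_gene_sets <- function(path) {
  .check_string(path, "path")
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) rlang::abort(sprintf("empty GMT file: '%s'.", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- list(); descriptions <- character(0)
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    f <- f[nzchar(f) | seq_along(f) <= 2L]
    if (length(f) < 3L) {
      rlang::abort(sprintf("malformed GMT line %d of '%s': need name, description and >=1 gene.",
                           i, path))
    }
    id <- f[1L]
    if (.norm_id(id) %in% .norm_id(names(sets))) {
      rlang::abort(sprintf("duplicate pathway id '%s' at line %d of '%s'.", id, i, path))
    }
    sets[[id]] <- unique(f[-(1:2)])
    descriptions[id] <- f[2L]
  }
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d gene sets (sizes %d-%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read miRNA-to-TF-motif annotations
#'
#' Two-column TSV mapping miRNA ids to transcription-factor motif ids
#' (predicted binding sites upstream of the miRNA). The annotation universe
#' size `N` — the denominator of the co-occurrence test — is the number of
#' distinct miRNA ids present in the file.
#'
#' @param path Path to the TSV file.
#' @return A `motif_annotation`: list with `motifs_of` (named list, miRNA id
#'   -> motif id vector), `mirnas` (annotated miRNA ids) and `universe_size`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("miR-1\tTFa", "miR-1\tTFb", "miR-2\tTFa"), tf)
#' read_motif_annotations(tf)$universe_size
#' @export
read_motif_annotations <- function(path) {
  pairs <- .read_pair_table(path, what = "motif annotation",
                            header_keys = c("motif", "motif_id", "tf", "tfbs"))
  mirna <- pairs[[1L]]; motif <- pairs[[2L]]
  key <- .norm_id(mirna)
  display <- setNames(mirna, key)[!duplicated(key)]
  motifs_of <- lapply(split(motif, factor(display[key], levels = unname(display))), unique)
  structure(
    list(motifs_of = motifs_of,
         mirnas = names(motifs_of),
         universe_size = length(motifs_of)),
    class = "motif_annotation"
  )
}

#' @export
print.motif_annotation <- function(x, ...) {
  cat(sprintf("<motif_annotation> %d annotated miRNAs, %d distinct motifs\n",
              x$universe_size,
              length(unique(unlist(x$motifs_of, use.names = FALSE)))))
  invisible(x)
}
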