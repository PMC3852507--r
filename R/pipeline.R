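#' Pipeline run configuration
#'
#' Collects and validates every knob of the end-to-end workflow. All
#' thresholds are checked up front so a bad configuration fails before any
#' stage runs.
#'
#' @param conditions Data frame with columns `condition`, `mirna_path`,
#'   `mrna_path` (one row per experimental condition).
#' @param targets_path Static miRNA-target TSV ([read_target_map()]).
#' @param out_dir Output directory for all stage artifacts.
#' @param motifs_path,gene_sets_path Optional annotation inputs; the
#'   corresponding stages are skipped when `NULL`.
#' @param hairpin_fasta,hairpin_struct,hairpin_coords Optional hairpin
#'   inputs for the sequence/structure stage.
#' @param r_max,cor_alpha Inverse-expression filter (see
#'   [inverse_pair_filter()]).
#' @param alpha_edge,sig_method,n_perm Edge test (see
#'   [build_condition_mran()]).
#' @param vwp,haircut,fluff,fluff_density,min_core Module detection (see
#'   [mcode_complexes()]).
#' @param cooccur_alpha,cooccur_correction Motif co-occurrence regime
#'   (default Bonferroni-corrected `1e-5`).
#' @param enrich_alpha Pathway enrichment significance (default 0.05,
#'   uncorrected).
#' @param background `"measured"` (genes in the condition's mRNA matrix) or
#'   `"collection"` (union of the pathway collection).
#' @param seed_window Seed window for the similarity stage.
#' @param n_random_pairs Between/random pair cap for the similarity stage.
#' @param rng_seed Master seed; recorded in the run log and all derived
#'   draws.
#' @return A validated `run_config` object.
#' @export
run_config <- function(conditions, targets_path, out_dir,
                       motifs_path = NULL, gene_sets_path = NULL,
                       hairpin_fasta = NULL, hairpin_struct = NULL,
                       hairpin_coords = NULL,
                       r_max = 0, cor_alpha = NULL,
                       alpha_edge = 0.05,
                       sig_method = c("exact", "permutation"), n_perm = 1000L,
                       vwp = 0.2, haircut = TRUE, fluff = FALSE,
                       fluff_density = 0.1, min_core = 2L,
                       cooccur_alpha = 1e-5,
                       cooccur_correction = c("bonferroni", "none"),
                       enrich_alpha = 0.05,
                       background = c("measured", "collection"),
                       seed_window = c(2L, 8L), n_random_pairs = 200L,
                       rng_seed = 1L) {
  conditions <- tibble::as_tibble(conditions)
  need <- c("condition", "mirna_path", "mrna_path")
  if (!all(need %in% names(conditions)) || !nrow(conditions)) {
    rlang::abort("`conditions` must have >= 1 row and columns condition, mirna_path, mrna_path.")
  }
  if (anyDuplicated(conditions$condition)) rlang::abort("duplicate condition labels.")
  .check_string(targets_path, "targets_path")
  .check_string(out_dir, "out_dir")
  .check_number(r_max, "r_max", max = 0)
  if (!is.null(cor_alpha)) .check_number(cor_alpha, "cor_alpha", min = 0, max = 1,
                                         strict_min = TRUE)
  .check_number(alpha_edge, "alpha_edge", min = 0, max = 1, strict_min = TRUE)
  .check_number(vwp, "vwp", min = 0, max = 1, strict_max = TRUE)
  .check_number(fluff_density, "fluff_density", min = 0, max = 1)
  .check_number(cooccur_alpha, "cooccur_alpha", min = 0, max = 1, strict_min = TRUE)
  .check_number(enrich_alpha, "enrich_alpha", min = 0, max = 1, strict_min = TRUE)
  if (length(seed_window) != 2L || seed_window[1L] > seed_window[2L]) {
    rlang::abort("`seed_window` must be two non-decreasing positions.")
  }
  structure(
    list(conditions = conditions, targets_path = targets_path, out_dir = out_dir,
         motifs_path = motifs_path, gene_sets_path = gene_sets_path,
         hairpin_fasta = hairpin_fasta, hairpin_struct = hairpin_struct,
         hairpin_coords = hairpin_coords,
         r_max = r_max, cor_alpha = cor_alpha, alpha_edge = alpha_edge,
         sig_method = match.arg(sig_method), n_perm = .check_count(n_perm, "n_perm", 1L),
         vwp = vwp, haircut = isTRUE(haircut), fluff = isTRUE(fluff),
         fluff_density = fluff_density, min_core = .check_count(min_core, "min_core", 1L),
         cooccur_alpha = cooccur_alpha,
         cooccur_correction = match.arg(cooccur_correction),
         enrich_alpha = enrich_alpha, background = match.arg(background),
         seed_window = as.integer(seed_window),
         n_random_pairs = .check_count(n_random_pairs, "n_random_pairs", 1L),
         rng_seed = .check_count(rng_seed, "rng_seed")),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()]; `conditions` is a
#' list of mappings with `condition`, `mirna_path`, `mrna_path`. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  .check_string(path, "path")
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  raw$conditions <- dplyr::bind_rows(lapply(raw$conditions, tibble::as_tibble))
  raw$conditions$mirna_path <- fix(raw$conditions$mirna_path)
  raw$conditions$mrna_path <- fix(raw$conditions$mrna_path)
  for (key in c("targets_path", "motifs_path", "gene_sets_path",
                "hairpin_fasta", "hairpin_struct", "hairpin_coords", "out_dir")) {
    if (!is.null(raw[[key]])) raw[[key]] <- fix(raw[[key]])
  }
  do.call(run_config, raw)
}

#' Run the full workflow
#'
#' Executes the stages in order — per-condition network construction,
#' merging into the global MRAN, module extraction, motif co-occurrence,
#' pathway enrichment, sequence/structure similarity — writing every
#' intermediate artifact under `config$out_dir`:
#'
#' * `network_<condition>.tsv` / `.graphml` — condition MRANs
#' * `condition_summary.tsv` — miRNA/gene/pair counts per condition
#' * `global_network.tsv` — merged MRAN (per-condition records)
#' * `modules.tsv` — module table (id, sizes, link and target counts, members)
#' * `cooccurrence.tsv` — significant TF motif pairs per condition
#' * `enrichment.tsv` / `enrichment_matrix.tsv` — pathway enrichment cells
#'   and the modules x pathways `-log10(p)` matrix
#' * `similarity.tsv` — the four-layer within/between/random comparison
#' * `run_log.txt` — parameters and seed (no timestamps, so identical
#'   configurations produce byte-identical outputs)
#'
#' A stage failure aborts with the stage name; artifacts of completed
#' stages are left in place.
#'
#' @param config A [run_config()].
#' @return Invisibly, a `pipeline_result` list: `condition_nets`, `global`,
#'   `modules`, `cooccurrence`, `enrichment`, `similarity`, `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  targets <- stage("read_inputs", read_target_map(config$targets_path))

  condition_nets <- list()
  filtered_list <- list()
  for (i in seq_len(nrow(config$conditions))) {
    cond <- config$conditions$condition[i]
    staged <- stage(paste0("condition_network[", cond, "]"), {
      mi <- read_expression(config$conditions$mirna_path[i], cond)
      mr <- read_expression(config$conditions$mrna_path[i], cond)
      flt <- inverse_pair_filter(mi, mr, targets,
                                 r_max = config$r_max, cor_alpha = config$cor_alpha)
      net <- build_condition_mran(flt, alpha_edge = config$alpha_edge,
                                  sig_method = config$sig_method,
                                  n_perm = config$n_perm,
                                  rng_seed = config$rng_seed + i)
      list(flt = flt, net = net)
    })
    filtered_list[[cond]] <- staged$flt
    net <- staged$net
    condition_nets[[cond]] <- net
    write_network(net, file.path(out, sprintf("network_%s.tsv", cond)), "edgelist")
    write_network(net, file.path(out, sprintf("network_%s.graphml", cond)), "graphml")
  }
  cond_summary <- dplyr::bind_rows(lapply(condition_nets, glance))
  readr::write_tsv(cond_summary, file.path(out, "condition_summary.tsv"))

  global <- stage("merge", merge_condition_mrans(condition_nets))
  write_network(global, file.path(out, "global_network.tsv"), "edgelist")

  modules <- stage("modules", {
    cmms <- mcode_complexes(global, vwp = config$vwp, haircut = config$haircut,
                            fluff = config$fluff,
                            fluff_density = config$fluff_density,
                            min_core = config$min_core)
    annotate_modules(cmms, global)
  })
  readr::write_tsv(tidy(modules), file.path(out, "modules.tsv"))

  cooccurrence <- NULL
  if (!is.null(config$motifs_path)) {
    cooccurrence <- stage("cooccurrence", {
      ann <- read_motif_annotations(config$motifs_path)
      res <- lapply(names(condition_nets), function(cond) {
        scope <- intersect(igraph::V(condition_nets[[cond]]$graph)$name, ann$mirnas)
        if (length(scope) < 2L) return(.empty_cooccurrence(cond))
        motif_cooccurrence(ann, scope, alpha = config$cooccur_alpha,
                           correction = config$cooccur_correction,
                           condition = cond)
      })
      n_tested <- sum(vapply(res, function(x) attr(x, "n_tested") %||% 0L, numeric(1)))
      out_tb <- dplyr::bind_rows(res)
      attr(out_tb, "n_tested") <- n_tested
      out_tb
    })
    readr::write_tsv(cooccurrence, file.path(out, "cooccurrence.tsv"))
  }

  enrichment <- NULL
  if (!is.null(config$gene_sets_path) && nrow(modules)) {
    enrichment <- stage("enrichment", {
      sets <- read_gene_sets(config$gene_sets_path)
      bg <- if (config$background == "collection") {
        unique(unlist(sets$sets, use.names = FALSE))
      } else {
        unique(unlist(lapply(filtered_list, `[[`, "measured_genes"),
                      use.names = FALSE))
      }
      cells <- dplyr::bind_rows(lapply(seq_len(nrow(modules)), function(i) {
        pathway_enrichment(intersect(modules$targets[[i]], .norm_id(bg)), bg, sets,
                           alpha = config$enrich_alpha,
                           module_id = sprintf("CMM%d", modules$module_id[i]))
      }))
      class(cells) <- c("enrichment_table", class(cells))
      cells
    })
    readr::write_tsv(enrichment, file.path(out, "enrichment.tsv"))
    mat <- enrichment_matrix(enrichment)
    mat_tb <- tibble::as_tibble(mat, rownames = "module_id")
    readr::write_tsv(mat_tb, file.path(out, "enrichment_matrix.tsv"))
  }

  similarity <- NULL
  if (!is.null(config$hairpin_fasta) && nrow(modules)) {
    similarity <- stage("seqstruct", {
      records <- read_hairpins(config$hairpin_fasta, config$hairpin_struct,
                               config$hairpin_coords)
      similarity_report(modules, records,
                        n_random_pairs = config$n_random_pairs,
                        rng_seed = config$rng_seed,
                        seed_window = config$seed_window)
    })
    readr::write_tsv(similarity, file.path(out, "similarity.tsv"))
  }

  .write_run_log(config, file.path(out, "run_log.txt"))

  res <- structure(
    list(condition_nets = condition_nets, global = global, modules = modules,
         cooccurrence = cooccurrence, enrichment = enrichment,
         similarity = similarity,
         summary = list(conditions = cond_summary, global = glance(global),
                        n_modules = nrow(modules))),
    class = "pipeline_result"
  )
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary$conditions)
  cat(sprintf("global: %d miRNAs, %d connections; %d module(s)\n",
              x$summary$global$n_mirnas, x$summary$global$n_connections,
              x$summary$n_modules))
  invisible(x)
}

.write_run_log <- function(config, path) {
  # record the scientific parameters and seed; paths stay out so the same
  # analysis written to two places leaves identical artifacts
  scalars <- config[!names(config) %in%
                      c("conditions", "cor_alpha", "out_dir", "targets_path",
                        "motifs_path", "gene_sets_path", "hairpin_fasta",
                        "hairpin_struct", "hairpin_coords")]
  scalars <- scalars[!vapply(scalars, is.null, logical(1))]
  lines <- c(
    "# mircoop run log",
    sprintf("conditions: %s", paste(config$conditions$condition, collapse = ", ")),
    sprintf("cor_alpha: %s", if (is.null(config$cor_alpha)) "none" else config$cor_alpha),
    vapply(names(scalars), function(k) {
      sprintf("%s: %s", k, paste(format(scalars[[k]]), collapse = " "))
    }, character(1))
  )
  readr::write_lines(lines, path)
}
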