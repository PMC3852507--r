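#' Planted ground truth for a synthetic co-transcriptomic study
#'
#' Parameter container for [simulate_dataset()]. The defaults are the
#' package's reference study conditions: three cooperative groups of five
#' miRNAs whose members share 80% of a common target pool, anti-correlate
#' with their targets at about -0.8 around a residual noise of sd 0.3, carry
#' planted co-occurring TF motifs, and fold into a shared hairpin
#' architecture per group.
#'
#' @param n_groups Number of planted cooperative miRNA groups.
#' @param group_size Members per group (groups are disjoint).
#' @param shared_target_fraction Fraction of each member's target set drawn
#'   from the group's common pool; `0` is the explicit negative control
#'   (no planted sharing).
#' @param anti_corr_strength Mean planted miRNA-target correlation, strictly
#'   negative in `(-1, 0)`.
#' @param noise_sd Residual sd of target-gene expression around the planted
#'   linear response.
#' @param targets_per_mirna Static target-set size per miRNA.
#' @param member_sd Within-group spread of member expression around the
#'   group activity (controls member co-expression).
#' @param n_background_motifs Number of unplanted TF motifs.
#' @param motif_extra_carriers Background miRNAs added to each planted
#'   motif's carrier set (regulatory programs extend beyond the module).
#' @param hairpin_mut_rate Fraction of template positions resampled per
#'   member hairpin; paired positions mutate jointly (complementarity
#'   preserved) so the group's architecture survives. At the default `1`
#'   the member sequences are fully randomized under the fixed structure
#'   template — sequence similarity within a group is then exactly at
#'   background level while structure similarity carries the planted
#'   signal.
#' @return A `planted_truth` parameter object; [simulate_dataset()] fills in
#'   concrete member ids, target pools, motif pairs and templates.
#' @export
planted_truth <- function(n_groups = 3L, group_size = 5L,
                          shared_target_fraction = 0.8,
                          anti_corr_strength = -0.8,
                          noise_sd = 0.3,
                          targets_per_mirna = 20L,
                          member_sd = 0.3,
                          n_background_motifs = 30L,
                          motif_extra_carriers = 8L,
                          hairpin_mut_rate = 1) {
  n_groups <- .check_count(n_groups, "n_groups", min = 1L)
  group_size <- .check_count(group_size, "group_size", min = 2L)
  .check_number(shared_target_fraction, "shared_target_fraction", min = 0, max = 1)
  .check_number(anti_corr_strength, "anti_corr_strength",
                min = -1, max = 0, strict_min = TRUE, strict_max = TRUE)
  .check_number(noise_sd, "noise_sd", min = 0, strict_min = TRUE)
  targets_per_mirna <- .check_count(targets_per_mirna, "targets_per_mirna", min = 1L)
  .check_number(member_sd, "member_sd", min = 0)
  n_background_motifs <- .check_count(n_background_motifs, "n_background_motifs")
  motif_extra_carriers <- .check_count(motif_extra_carriers, "motif_extra_carriers")
  .check_number(hairpin_mut_rate, "hairpin_mut_rate", min = 0, max = 1)
  # anti_corr must be reachable: r^2 (1 + member_sd^2) < 1
  if (anti_corr_strength^2 * (1 + member_sd^2) >= 1) {
    rlang::abort("infeasible: |anti_corr_strength| too large for the given member_sd.")
  }
  structure(
    list(n_groups = n_groups, group_size = group_size,
         shared_target_fraction = shared_target_fraction,
         anti_corr_strength = anti_corr_strength,
         noise_sd = noise_sd,
         targets_per_mirna = targets_per_mirna,
         member_sd = member_sd,
         n_background_motifs = n_background_motifs,
         motif_extra_carriers = motif_extra_carriers,
         hairpin_mut_rate = hairpin_mut_rate,
         groups = NULL, planted_motif_pairs = NULL,
         structure_templates = NULL, rng_seed = NULL),
    class = "planted_truth"
  )
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d groups x %d miRNAs, shared fraction %.2f, anti-corr %.2f\n",
              x$n_groups, x$group_size, x$shared_target_fraction, x$anti_corr_strength))
  invisible(x)
}

#' Simulate a complete toy co-transcriptomic study
#'
#' Generates, under one seed, everything the pipeline consumes: paired
#' miRNA/mRNA expression matrices for each condition, a static target map,
#' TF-motif annotations and hairpin records — with the ground truth planted
#' by `truth` recorded alongside.
#'
#' The expression model is linear-Gaussian. Each planted group has a latent
#' activity per sample in the conditions where it is active (groups cycle
#' over conditions); member miRNAs track the activity (`member_sd`), shared
#' pool genes respond as `baseline - slope * activity + noise`, private
#' targets respond to their own miRNA, and everything else is independent.
#' The slope is solved from `anti_corr_strength` and `noise_sd` so the
#' planted pairs have the requested expected correlation. Group target
#' pools are disjoint. Hairpins are drawn from per-group structure
#' templates (see [planted_truth()]) and folded with [nussinov_fold()].
#'
#' @param n_mirnas,n_genes,n_samples,n_conditions Dimensions of the study.
#' @param truth A [planted_truth()] parameter object.
#' @param rng_seed Integer seed; identical seeds give identical studies.
#' @return An `mran_simulation`: list with `expression` (per condition:
#'   `mirna` and `mrna` `expression_matrix`), `targets`, `motifs`,
#'   `hairpins`, `gene_sets` (one synthetic pathway per group pool plus
#'   decoys) and the completed `truth` (concrete `groups`,
#'   `planted_motif_pairs`, `structure_templates`, `active_condition`,
#'   `rng_seed`).
#' @export
simulate_dataset <- function(n_mirnas = 60L, n_genes = 400L, n_samples = 12L,
                             n_conditions = 2L, truth = planted_truth(),
                             rng_seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  n_mirnas <- .check_count(n_mirnas, "n_mirnas", min = 2L)
  n_genes <- .check_count(n_genes, "n_genes", min = 2L)
  n_samples <- .check_count(n_samples, "n_samples", min = 3L)
  n_conditions <- .check_count(n_conditions, "n_conditions", min = 1L)
  rng_seed <- .check_count(rng_seed, "rng_seed")
  n_planted <- truth$n_groups * truth$group_size
  if (n_planted > n_mirnas) {
    rlang::abort("planted groups need more miRNAs than `n_mirnas` provides.")
  }
  n_shared <- round(truth$shared_target_fraction * truth$targets_per_mirna)
  if (truth$n_groups * n_shared + truth$targets_per_mirna > n_genes) {
    rlang::abort("`n_genes` too small for disjoint group target pools.")
  }

  .with_seed(rng_seed, {
    mirna_ids <- sprintf("mir-%03d", seq_len(n_mirnas))
    gene_ids <- sprintf("gene-%04d", seq_len(n_genes))
    sample_ids <- sprintf("s%02d", seq_len(n_samples))
    cond_ids <- sprintf("cond%d", seq_len(n_conditions))

    groups <- split(mirna_ids[seq_len(n_planted)],
                    rep(seq_len(truth$n_groups), each = truth$group_size))
    names(groups) <- sprintf("group%d", seq_len(truth$n_groups))
    background <- setdiff(mirna_ids, unlist(groups))
    active_condition <- setNames(((seq_len(truth$n_groups) - 1L) %% n_conditions) + 1L,
                                 names(groups))

    # --- static target map: disjoint shared pools + private targets -------
    pool_genes <- if (n_shared > 0L) {
      split(sample(gene_ids, truth$n_groups * n_shared),
            rep(seq_len(truth$n_groups), each = n_shared))
    } else {
      rep(list(character(0)), truth$n_groups)
    }
    names(pool_genes) <- names(groups)
    non_pool <- setdiff(gene_ids, unlist(pool_genes))
    targets_of <- list()
    private_of <- list()
    for (gname in names(groups)) {
      for (m in groups[[gname]]) {
        priv <- sample(non_pool, truth$targets_per_mirna - n_shared)
        targets_of[[m]] <- c(pool_genes[[gname]], priv)
        private_of[[m]] <- priv
      }
    }
    for (m in background) {
      targets_of[[m]] <- sample(non_pool, truth$targets_per_mirna)
    }
    target_map <- .new_target_map(
      rep(names(targets_of), lengths(targets_of)),
      unlist(targets_of, use.names = FALSE)
    )

    # --- expression ------------------------------------------------------
    r <- abs(truth$anti_corr_strength)
    sn <- truth$noise_sd
    sm <- truth$member_sd
    c0 <- r^2 * (1 + sm^2)
    slope_shared <- sn * sqrt(c0 / (1 - c0))          # target ~ group activity
    slope_priv <- r * sn / (sqrt(1 + sm^2) * sqrt(1 - r^2))  # target ~ member
    mu_mi <- 8; mu_g <- 10

    expression <- list()
    for (ci in seq_len(n_conditions)) {
      activity <- lapply(groups, function(g) stats::rnorm(n_samples))
      mi <- matrix(stats::rnorm(n_mirnas * n_samples, mu_mi, 1),
                   n_mirnas, n_samples, dimnames = list(mirna_ids, sample_ids))
      for (gname in names(groups)) {
        if (active_condition[[gname]] != ci) next
        for (m in groups[[gname]]) {
          mi[m, ] <- mu_mi + activity[[gname]] +
            stats::rnorm(n_samples, 0, sm)
        }
      }
      mr <- matrix(stats::rnorm(n_genes * n_samples, mu_g, 1),
                   n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
      for (gname in names(groups)) {
        if (active_condition[[gname]] != ci) next
        for (gene in pool_genes[[gname]]) {
          mr[gene, ] <- mu_g - slope_shared * activity[[gname]] +
            stats::rnorm(n_samples, 0, sn)
        }
        for (m in groups[[gname]]) {
          x_centered <- mi[m, ] - mu_mi
          for (gene in private_of[[m]]) {
            mr[gene, ] <- mu_g - slope_priv * x_centered +
              stats::rnorm(n_samples, 0, sn)
          }
        }
      }
      expression[[cond_ids[ci]]] <- list(
        mirna = new_expression_matrix(cond_ids[ci], mi),
        mrna = new_expression_matrix(cond_ids[ci], mr)
      )
    }

    # --- TF motif annotations -------------------------------------------
    motif_rows_mirna <- character(0); motif_rows_motif <- character(0)
    planted_pairs <- list()
    for (gi in seq_along(groups)) {
      gname <- names(groups)[gi]
      ma <- sprintf("TF-%s-a", gname); mb <- sprintf("TF-%s-b", gname)
      carriers <- c(groups[[gname]],
                    sample(background, min(truth$motif_extra_carriers,
                                           length(background))))
      motif_rows_mirna <- c(motif_rows_mirna, rep(carriers, 2L))
      motif_rows_motif <- c(motif_rows_motif,
                            rep(ma, length(carriers)), rep(mb, length(carriers)))
      planted_pairs[[gname]] <- c(ma, mb)
    }
    for (k in seq_len(truth$n_background_motifs)) {
      carriers <- mirna_ids[stats::runif(n_mirnas) < 0.15]
      motif_rows_mirna <- c(motif_rows_mirna, carriers)
      motif_rows_motif <- c(motif_rows_motif, rep(sprintf("TF-bg-%02d", k),
                                                  length(carriers)))
    }
    # every miRNA must be annotated so the universe is the full panel
    bare <- setdiff(mirna_ids, unique(motif_rows_mirna))
    if (length(bare)) {
      motif_rows_mirna <- c(motif_rows_mirna, bare)
      motif_rows_motif <- c(motif_rows_motif,
                            sprintf("TF-bg-%02d",
                                    1L + (seq_along(bare) %% max(1L, truth$n_background_motifs))))
    }
    ord <- order(motif_rows_mirna, motif_rows_motif)
    motifs <- structure(
      list(motifs_of = lapply(split(motif_rows_motif[ord],
                                    factor(motif_rows_mirna[ord], levels = mirna_ids)),
                              unique),
           mirnas = mirna_ids, universe_size = n_mirnas),
      class = "motif_annotation"
    )

    # --- hairpins --------------------------------------------------------
    templates <- lapply(seq_along(groups), .hairpin_architecture)
    names(templates) <- names(groups)
    hairpins <- list()
    for (gi in seq_along(groups)) {
      gname <- names(groups)[gi]
      ref <- .sample_template_sequence(templates[[gname]])
      for (m in groups[[gname]]) {
        seqm <- .mutate_template_sequence(ref, templates[[gname]],
                                          truth$hairpin_mut_rate)
        hairpins[[m]] <- new_hairpin_record(
          m, seqm, nussinov_fold(seqm), mature_start = 4L, mature_end = 25L
        )
      }
    }
    for (m in background) {
      seqm <- paste(sample(c("A", "C", "G", "U"), 72L, replace = TRUE), collapse = "")
      hairpins[[m]] <- new_hairpin_record(
        m, seqm, nussinov_fold(seqm), mature_start = 4L, mature_end = 25L
      )
    }
    hairpins <- hairpins[mirna_ids]

    # --- synthetic pathway collection -----------------------------------
    sets <- list(); descs <- character(0)
    for (gname in names(groups)) {
      pid <- sprintf("PW-%s", gname)
      extra <- sample(non_pool, 10L)
      sets[[pid]] <- unique(c(pool_genes[[gname]], extra))
      descs[pid] <- sprintf("synthetic pathway seeded from %s target pool", gname)
    }
    for (k in 1:10) {
      pid <- sprintf("PW-decoy-%02d", k)
      sets[[pid]] <- sample(gene_ids, 20L)
      descs[pid] <- "synthetic decoy pathway"
    }
    gene_sets <- structure(list(sets = sets, descriptions = descs),
                           class = "gene_set_collection")

    truth$groups <- groups
    truth$planted_motif_pairs <- planted_pairs
    truth$structure_templates <- vapply(templates, `[[`, character(1), "dotbracket")
    truth$active_condition <- active_condition
    truth$rng_seed <- rng_seed

    structure(
      list(expression = expression, targets = target_map, motifs = motifs,
           hairpins = hairpins, gene_sets = gene_sets, truth = truth,
           dims = list(n_mirnas = n_mirnas, n_genes = n_genes,
                       n_samples = n_samples, n_conditions = n_conditions)),
      class = "mran_simulation"
    )
  })
}

#' @export
print.mran_simulation <- function(x, ...) {
  cat(sprintf("<mran_simulation> %d miRNAs x %d genes x %d samples, %d condition(s); %d planted group(s)\n",
              x$dims$n_mirnas, x$dims$n_genes, x$dims$n_samples,
              x$dims$n_conditions, x$truth$n_groups))
  invisible(x)
}

# distinct hairpin architecture per group: flank/stem/bulge/stem/loop layout,
# constant total length 72 so sequence-level comparisons see no length cue
.hairpin_architecture <- function(g) {
  presets <- list(
    list(s1 = 14L, b = 4L, s2 = 12L, loop = 10L),
    list(s1 = 10L, b = 8L, s2 = 16L, loop = 6L),
    list(s1 = 18L, b = 2L, s2 = 8L, loop = 12L),
    list(s1 = 12L, b = 6L, s2 = 14L, loop = 8L),
    list(s1 = 16L, b = 10L, s2 = 9L, loop = 10L),
    list(s1 = 8L, b = 4L, s2 = 19L, loop = 4L)
  )
  p <- presets[[((g - 1L) %% length(presets)) + 1L]]
  flank <- (72L - (2L * p$s1 + 2L * p$s2 + p$b + p$loop)) %/% 2L
  extra <- 72L - (2L * p$s1 + 2L * p$s2 + p$b + p$loop) - 2L * flank
  db <- paste0(
    strrep(".", flank),
    strrep("(", p$s1), strrep(".", p$b), strrep("(", p$s2),
    strrep(".", p$loop),
    strrep(")", p$s2), strrep(")", p$s1),
    strrep(".", flank + extra)
  )
  tree <- parse_dotbracket(db)
  list(dotbracket = db, pairs = tree$pairs)
}

# draw a sequence compatible with a template: unpaired positions uniform,
# paired positions Watson-Crick complementary
.sample_template_sequence <- function(template) {
  db <- strsplit(template$dotbracket, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  seqv <- character(length(db))
  unpaired <- which(db == ".")
  seqv[unpaired] <- sample(bases, length(unpaired), replace = TRUE)
  for (r in seq_len(nrow(template$pairs))) {
    i <- template$pairs[r, 1L]; j <- template$pairs[r, 2L]
    seqv[i] <- sample(bases, 1L)
    seqv[j] <- comp[[seqv[i]]]
  }
  paste(seqv, collapse = "")
}

# compensatory mutation: each pair / unpaired position resampled with
# probability `rate`, keeping complementarity at paired positions
.mutate_template_sequence <- function(ref, template, rate) {
  seqv <- strsplit(ref, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  db <- strsplit(template$dotbracket, "", fixed = TRUE)[[1L]]
  unpaired <- which(db == ".")
  hit <- unpaired[stats::runif(length(unpaired)) < rate]
  seqv[hit] <- sample(bases, length(hit), replace = TRUE)
  for (r in seq_len(nrow(template$pairs))) {
    if (stats::runif(1) >= rate) next
    i <- template$pairs[r, 1L]; j <- template$pairs[r, 2L]
    seqv[i] <- sample(bases, 1L)
    seqv[j] <- comp[[seqv[i]]]
  }
  paste(seqv, collapse = "")
}

#' Score recovery of the planted modules
#'
#' Best-match Jaccard between each planted group and the detected modules,
#' averaged over planted groups: 1 when every group is recovered exactly, 0
#' when nothing is detected.
#'
#' @param detected Module table from [mcode_complexes()] (or list of member
#'   vectors).
#' @param truth Completed `planted_truth` (from an `mran_simulation`).
#' @return Agreement in `[0, 1]`.
#' @export
truth_recovery_score <- function(detected, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  if (is.null(truth$groups)) {
    rlang::abort("`truth` has no concrete groups; pass the truth from simulate_dataset().")
  }
  modules <- .module_member_list(detected)
  if (!length(modules)) return(0)
  mean(vapply(truth$groups, function(g) {
    gk <- .norm_id(g)
    max(vapply(modules, function(m) {
      mk <- .norm_id(m)
      length(intersect(gk, mk)) / length(union(gk, mk))
    }, numeric(1)))
  }, numeric(1)))
}

#' Write a simulated study to disk in the pipeline's file dialects
#'
#' Emits every fixture the file-based pipeline consumes — per-condition
#' expression TSVs, the target map, motif annotations, a GMT pathway file,
#' hairpin FASTA + Vienna structures + mature coordinates — plus a
#' machine-readable truth manifest (JSON).
#'
#' @param sim An `mran_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written, including a
#'   `conditions` tibble suitable for [run_config()].
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "mran_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  conds <- names(sim$expression)
  cond_tbl <- tibble::tibble(condition = conds,
                             mirna_path = file.path(dir, sprintf("mirna_%s.tsv", conds)),
                             mrna_path = file.path(dir, sprintf("mrna_%s.tsv", conds)))
  for (k in seq_along(conds)) {
    .write_expression_tsv(sim$expression[[k]]$mirna, cond_tbl$mirna_path[k])
    .write_expression_tsv(sim$expression[[k]]$mrna, cond_tbl$mrna_path[k])
  }
  paths$conditions <- cond_tbl

  paths$targets <- file.path(dir, "targets.tsv")
  tt <- tidy(sim$targets)
  readr::write_lines(c("mirna_id\tgene_id",
                       sprintf("%s\t%s", tt$mirna_id, tt$gene_id)),
                     paths$targets)

  paths$motifs <- file.path(dir, "motifs.tsv")
  mo <- sim$motifs$motifs_of
  readr::write_lines(c("mirna_id\tmotif_id",
                       sprintf("%s\t%s", rep(names(mo), lengths(mo)),
                               unlist(mo, use.names = FALSE))),
                     paths$motifs)

  paths$gene_sets <- file.path(dir, "pathways.gmt")
  gs <- sim$gene_sets
  readr::write_lines(
    vapply(names(gs$sets), function(pid) {
      paste(c(pid, gs$descriptions[[pid]], gs$sets[[pid]]), collapse = "\t")
    }, character(1)),
    paths$gene_sets
  )

  paths$hairpin_fasta <- file.path(dir, "hairpins.fasta")
  paths$hairpin_struct <- file.path(dir, "hairpins.vienna")
  paths$hairpin_coords <- file.path(dir, "mature_coords.tsv")
  hp <- sim$hairpins
  readr::write_lines(
    unlist(lapply(hp, function(h) c(paste0(">", h$mirna_id), h$precursor_seq))),
    paths$hairpin_fasta
  )
  readr::write_lines(
    unlist(lapply(hp, function(h) c(paste0(">", h$mirna_id), h$precursor_struct))),
    paths$hairpin_struct
  )
  readr::write_lines(
    c("mirna_id\tmature_start\tmature_end",
      vapply(hp, function(h) sprintf("%s\t%d\t%d", h$mirna_id,
                                     h$mature_start, h$mature_end), character(1))),
    paths$hairpin_coords
  )

  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(groups = sim$truth$groups,
         active_condition = as.list(sim$truth$active_condition),
         planted_motif_pairs = sim$truth$planted_motif_pairs,
         structure_templates = as.list(sim$truth$structure_templates),
         shared_target_fraction = sim$truth$shared_target_fraction,
         anti_corr_strength = sim$truth$anti_corr_strength,
         noise_sd = sim$truth$noise_sd,
         rng_seed = sim$truth$rng_seed),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(paths)
}

.write_expression_tsv <- function(em, path) {
  header <- paste(c("feature_id", em$sample_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(em$values)), function(i) {
    paste(c(em$feature_ids[i], sprintf("%.10g", em$values[i, ])), collapse = "\t")
  }, character(1))
  readr::write_lines(c(header, rows), path)
}
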