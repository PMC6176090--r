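#' Pipeline run configuration
#'
#' Collects every threshold of the analysis with the study's values as
#' defaults: SERE keep threshold 1.7, adjusted-p cutoff 1e-5, minimum
#' fold change 2, RPKM floor 4, correlation p-max 0.1, cluster validation
#' 0.5, KO e-value cutoff 1e-5 and retention 0.9, BRH minimum score 300.
#'
#' @param partition a [stage_partition()].
#' @param sere_threshold,alpha,min_fold,rpkm_floor,cor_p_max,cut_height,validation_r,ko_e_max,ko_retention,brh_min_score thresholds (see description).
#' @param force_keep sample ids exempt from QC dropping.
#' @param seed root RNG seed for any stochastic step.
#' @param outdir optional output directory; stage outputs and the run
#'   report are written there when set.
#' @return List of class `run_config`.
#' @export
run_config <- function(partition, sere_threshold = 1.7, alpha = 1e-5,
                       min_fold = 2, rpkm_floor = 4, cor_p_max = 0.1,
                       cut_height = 0.5, validation_r = 0.5,
                       ko_e_max = 1e-5, ko_retention = 0.9,
                       brh_min_score = 300, force_keep = character(),
                       seed = 1L, outdir = NULL) {
  stopifnot(inherits(partition, "stage_partition"))
  if (sere_threshold < 0 || alpha <= 0 || alpha > 1 || min_fold < 1 ||
      rpkm_floor < 0 || cor_p_max < 0 || cor_p_max > 1 ||
      ko_retention < 0 || ko_retention > 1)
    stopf("a threshold is outside its documented domain")
  structure(list(partition = partition, sere_threshold = sere_threshold,
                 alpha = alpha, min_fold = min_fold, rpkm_floor = rpkm_floor,
                 cor_p_max = cor_p_max, cut_height = cut_height,
                 validation_r = validation_r, ko_e_max = ko_e_max,
                 ko_retention = ko_retention, brh_min_score = brh_min_score,
                 force_keep = force_keep, seed = as.integer(seed),
                 outdir = outdir), class = "run_config")
}

#' Run the full expression-analysis pipeline
#'
#' Executes the stages in order: replicate QC (SERE), size factors and
#' RPKM, all-vs-all pairwise differential expression, URG stage
#' classification, and correlation sub-clustering of URG2 and URG3.
#' Optionally rolls up BRITE functional categories (when a hit table and
#' KO/BRITE maps are given) and calls orthologs between two peptide sets.
#' Identical inputs, config and seed give identical outputs.
#'
#' @param cm a [count_matrix].
#' @param lengths named gene length vector (bp).
#' @param config a [run_config()].
#' @param hits,ko_map,brite_map optional annotation inputs.
#' @param peptides_a,peptides_b optional named peptide vectors for
#'   orthology.
#' @return List of class `pipeline_result`: `qc`, `profile`, `contrasts`,
#'   `urg`, `subgroups` (URG2/URG3), `ko`, `brite`, `orthologs`, and
#'   `report` (per-stage record counts and the echoed config).
#' @export
run_pipeline <- function(cm, lengths, config, hits = NULL, ko_map = NULL,
                         brite_map = NULL, peptides_a = NULL,
                         peptides_b = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- proc.time()[["elapsed"]]
  stage_times <- c()
  tick <- function() {
    t <- proc.time()[["elapsed"]]; dt <- t - t_start
    t_start <<- t
    dt
  }

  qc <- qc_replicates(cm, config$sere_threshold, config$force_keep)
  cm_kept <- qc$cm
  stage_times["qc"] <- tick()

  profile <- rpkm(cm_kept, lengths)
  contrasts <- build_contrast_set(cm_kept, alpha = config$alpha,
                                  min_fold = config$min_fold)
  stage_times["de"] <- tick()

  urg <- assign_urg(contrasts, profile, config$partition,
                    floor = config$rpkm_floor)
  stage_times["urg"] <- tick()

  subgroups <- list()
  for (group in c("URG2", "URG3")) {
    members <- names(urg$labels)[urg$labels == group]
    if (length(members) >= 2) {
      tab <- filter_significant(
        correlate_profiles(profile$rpkm_time, members), config$cor_p_max)
      subgroups[[group]] <- cluster_subgroups(
        tab, profile$rpkm_time, cut_height = config$cut_height,
        validation_r = config$validation_r)
    }
  }
  stage_times["subgroups"] <- tick()

  ko <- NULL; brite <- NULL
  if (!is.null(hits) && !is.null(ko_map)) {
    ko <- assign_ko(hits, ko_map, config$ko_e_max, config$ko_retention)
    if (!is.null(brite_map))
      brite <- brite_rollup(ko, brite_map, urg, profile, config$partition)
  }
  stage_times["annotation"] <- tick()

  orthologs <- NULL
  if (!is.null(peptides_a) && !is.null(peptides_b))
    orthologs <- reciprocal_best_hits(peptides_a, peptides_b,
                                      config$brh_min_score)
  stage_times["orthology"] <- tick()

  report <- list(
    n_genes = nrow(cm$counts),
    samples_in = ncol(cm$counts),
    samples_kept = ncol(cm_kept$counts),
    samples_dropped = ncol(cm$counts) - ncol(cm_kept$counts),
    deg_per_contrast = count_degs(contrasts),
    n_deg_total = urg$n_deg,
    urg_sizes = as.list(urg$counts),
    validated_subgroups = lapply(subgroups, function(s)
      sum(s$clusters$validated)),
    ko_coverage = if (!is.null(ko) && nrow(cm$counts) > 0)
      length(unique(ko$assignments$query)) / nrow(cm$counts) else NA,
    brh_pairs = if (!is.null(orthologs)) nrow(orthologs$pairs) else NA,
    stage_seconds = as.list(round(stage_times, 3)),
    config = config[setdiff(names(config), "partition")],
    partition = list(t0 = config$partition$t0,
                     early = config$partition$early,
                     late = config$partition$late),
    version = as.character(utils::packageVersion("urgflow")))

  result <- structure(list(qc = qc, profile = profile, contrasts = contrasts,
                           urg = urg, subgroups = subgroups, ko = ko,
                           brite = brite, orthologs = orthologs,
                           report = report), class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_outputs(result, config$outdir)
  result
}

count_degs <- function(contrasts) {
  tps <- contrasts$time_points
  out <- list()
  for (i in seq_along(tps)) for (j in seq_along(tps)) {
    if (j <= i) next
    out[[sprintf("T%d_vs_T%d", tps[i], tps[j])]] <-
      sum(contrasts$sig[, i, j])
  }
  out
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) write.table(df, file.path(outdir, name),
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE)
  w(result$qc$report$pairs, "qc_pairs.tsv")
  w(result$qc$report$samples, "qc_samples.tsv")
  rt <- result$profile$rpkm_time
  w(data.frame(gene_id = rownames(rt), round(rt, 4), check.names = FALSE),
    "rpkm_time.tsv")
  w(contrast_long(result$contrasts), "de_contrasts.tsv")
  w(result$urg$trace, "urg_assignment.tsv")
  for (group in names(result$subgroups)) {
    s <- result$subgroups[[group]]
    w(s$clusters, sprintf("subgroups_%s.tsv", tolower(group)))
    w(data.frame(gene_id = names(s$membership), cluster = s$membership),
      sprintf("subgroup_members_%s.tsv", tolower(group)))
  }
  if (!is.null(result$ko)) w(result$ko$assignments, "ko_assignments.tsv")
  if (!is.null(result$brite)) w(result$brite, "brite_signal.tsv")
  if (!is.null(result$orthologs)) w(result$orthologs$pairs, "orthologs.tsv")
  jsonlite::write_json(result$report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Long-format export of a contrast set
#' @param contrasts a `contrast_set`.
#' @return data.frame: gene, a, b, log2fc, p, padj, significant (one row
#'   per gene and unordered time-point pair).
#' @export
contrast_long <- function(contrasts) {
  tps <- contrasts$time_points
  rows <- list()
  for (i in seq_along(tps)) for (j in seq_along(tps)) {
    if (j <= i) next
    rows[[length(rows) + 1]] <- data.frame(
      gene = dimnames(contrasts$lfc)[[1]], a = tps[i], b = tps[j],
      log2fc = contrasts$lfc[, i, j], p = contrasts$p[, i, j],
      padj = contrasts$padj[, i, j], significant = contrasts$sig[, i, j])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Self-contained synthetic demonstration run
#'
#' Simulates a full synthetic dataset (counts, hit table, KO/BRITE maps,
#' two peptide sets), runs the pipeline end to end and writes all stage
#' outputs plus the run report. Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param outdir output directory.
#' @param n_genes number of simulated genes (default 600 for a quick
#'   demonstration).
#' @param time_grid simulated grid (default the 7-point grid).
#' @return The `pipeline_result`, invisibly.
#' @export
demo_run <- function(seed = 1L, outdir, n_genes = 600,
                     time_grid = seq(0L, 36L, by = 6L)) {
  cfg <- sim_config(n_genes = n_genes, time_grid = time_grid,
                    late = time_grid[time_grid >= 24L], seed = seed)
  sim <- simulate_counts(cfg)
  hits <- simulate_hit_table(n_query = min(200, n_genes), n_ko = 40,
                             seed = seed + 1L)
  # tie hit queries to simulated gene ids so the roll-up has members
  gene_ids <- rownames(sim$cm$counts)
  hits$hits$query <- gene_ids[as.integer(sub("q", "", hits$hits$query))]
  brite <- data.frame(ko = unique(hits$ko_map$ko),
                      levelA = "09100 Metabolism",
                      levelB = paste("group", seq_along(unique(hits$ko_map$ko)) %% 8))
  pep <- simulate_peptides(40, seed = seed + 2L)
  partition <- stage_partition(time_grid, early = c(6L, 12L, 18L),
                               late = time_grid[time_grid >= 24L])
  config <- run_config(partition, seed = seed, outdir = outdir)
  lengths <- setNames(sim$lengths$length_bp, sim$lengths$gene_id)
  result <- run_pipeline(sim$cm, lengths, config, hits = hits$hits,
                         ko_map = hits$ko_map, brite_map = brite,
                         peptides_a = pep$a, peptides_b = pep$b)
  invisible(result)
}
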