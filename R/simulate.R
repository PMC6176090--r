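#' Simulation configuration for the synthetic infection time course
#'
#' Defines the generative model for synthetic count data emulating the
#' study design: a time grid sampled every 6 h starting at the free-living
#' dinospore stage (0 h), three replicates per time point,
#' negative-binomially dispersed counts with library-size variation,
#' planted stage-specific expression classes, and occasional corrupted
#' replicates.
#'
#' Gene classes: `urg1`-like genes peak at 0 h only (dinospore stage),
#' `urg2`-like at one or more early time points (beginning of infection),
#' `urg3`-like at one or more late time points (end of infection),
#' `flat` genes are constant, and `noise` genes sit below the RPKM floor.
#'
#' @param n_genes number of genes.
#' @param time_grid ordered integer hours; first entry is the
#'   dinospore/T0 condition. Default is the 7-point grid (0-36 h);
#'   use `seq(0, 36, 6)` plus `c(42, 44)` for the 9-point grid.
#' @param early,late disjoint subsets of `time_grid` marking the
#'   beginning and end of infection (defaults 6/12/18 h and all points
#'   from 24 h on).
#' @param n_replicates replicates per time point (default 3).
#' @param class_fractions named proportions over
#'   `c("urg1","urg2","urg3","flat","noise")`, summing to 1.
#' @param effect_size fold change of the peak mean over baseline (>= 1).
#' @param dispersion NB dispersion alpha >= 0 (variance = mu + alpha*mu^2);
#'   0 gives Poisson counts. The default 0.01 keeps concordant replicates
#'   clearly below the SERE 1.7 keep threshold (between clean replicates
#'   SERE ~ sqrt(1 + alpha * mu)), consistent with a design whose retained
#'   replicates passed that screen.
#' @param libsize_cv coefficient of variation of per-sample library-size
#'   factors (log-normal, mean 1).
#' @param bad_replicate_rate probability each sample is corrupted
#'   (half of its gene means permuted), emulating the discordant
#'   replicates the study discarded.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   per-gene baseline mean count.
#' @param rpkm_floor RPKM floor used to scale `noise`-class means.
#' @param seed integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       time_grid = seq(0L, 36L, by = 6L),
                       early = c(6L, 12L, 18L),
                       late = time_grid[time_grid >= 24L],
                       n_replicates = 3,
                       class_fractions = c(urg1 = 0.15, urg2 = 0.15,
                                           urg3 = 0.20, flat = 0.35,
                                           noise = 0.15),
                       effect_size = 4,
                       dispersion = 0.01,
                       libsize_cv = 0.2,
                       bad_replicate_rate = 0.2,
                       baseline_meanlog = log(50),
                       baseline_sdlog = 0.5,
                       rpkm_floor = 4,
                       seed = 1L) {
  if (!is_count_scalar(n_genes)) stopf("n_genes must be a positive integer")
  if (!is_count_scalar(n_replicates)) stopf("n_replicates must be a positive integer")
  if (length(time_grid) == 0) stopf("time_grid must not be empty")
  time_grid <- as.integer(time_grid)
  if (is.unsorted(time_grid, strictly = TRUE)) stopf("time_grid must be strictly increasing")
  if (length(intersect(early, late)) > 0) stopf("early and late sets must be disjoint")
  if (!all(c(early, late) %in% time_grid[-1])) stopf("early/late must be non-T0 grid points")
  cls <- c("urg1", "urg2", "urg3", "flat", "noise")
  if (!setequal(names(class_fractions), cls)) stopf("class_fractions must be named %s", paste(cls, collapse = "/"))
  class_fractions <- class_fractions[cls]
  if (abs(sum(class_fractions) - 1) > 1e-9) stopf("class_fractions must sum to 1")
  if (effect_size < 1) stopf("effect_size must be >= 1")
  if (dispersion < 0) stopf("dispersion must be >= 0")
  structure(list(n_genes = as.integer(n_genes), time_grid = time_grid,
                 early = as.integer(early), late = as.integer(late),
                 n_replicates = as.integer(n_replicates),
                 class_fractions = class_fractions,
                 effect_size = effect_size, dispersion = dispersion,
                 libsize_cv = libsize_cv,
                 bad_replicate_rate = bad_replicate_rate,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 rpkm_floor = rpkm_floor, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic infection time-course count matrix
#'
#' Draws a genes x samples matrix of NB counts with planted URG1/URG2/URG3
#' expression profiles and records the planted truth. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cm` ([count_matrix]), `truth`
#'   (data.frame: gene_id, class, peak_times, baseline_mean, length_bp),
#'   `lengths` (data.frame gene_id, length_bp), `bad_samples` (character),
#'   and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    ng <- config$n_genes
    tg <- config$time_grid
    gene_id <- sprintf("g%05d", seq_len(ng))
    length_bp <- sample(300:3000, ng, replace = TRUE)
    class <- sample(names(config$class_fractions), ng, replace = TRUE,
                    prob = config$class_fractions)
    baseline <- rlnorm(ng, config$baseline_meanlog, config$baseline_sdlog)

    # scale noise-class means to sit below the RPKM floor given the
    # expected library total of the signal genes
    n_ref <- sum(baseline[class != "noise"])
    floor_counts <- config$rpkm_floor * length_bp * n_ref / 1e9
    baseline[class == "noise"] <- 0.5 * floor_counts[class == "noise"]

    peak_sets <- list(urg1 = tg[1], urg2 = config$early, urg3 = config$late)
    peaks <- vector("list", ng)
    mu <- matrix(baseline, nrow = ng, ncol = length(tg),
                 dimnames = list(gene_id, as.character(tg)))
    for (g in seq_len(ng)) {
      cl <- class[g]
      if (cl %in% names(peak_sets) && length(peak_sets[[cl]]) == 0) {
        class[g] <- cl <- "flat"   # no candidate peak points on this grid
      }
      if (cl %in% names(peak_sets)) {
        cand <- peak_sets[[cl]]
        k <- sample.int(length(cand), 1)
        pk <- sort(cand[sample.int(length(cand), k)])
        peaks[[g]] <- pk
        mu[g, as.character(pk)] <- baseline[g] * config$effect_size
      } else peaks[[g]] <- integer(0)
    }

    nr <- config$n_replicates
    sample_id <- as.vector(t(outer(tg, seq_len(nr),
                                   function(t, r) sprintf("T%02d_r%d", t, r))))
    samples <- data.frame(sample_id = sample_id,
                          time = rep(tg, each = nr),
                          replicate = rep(seq_len(nr), times = length(tg)))
    sdlog <- sqrt(log(1 + config$libsize_cv^2))
    libfac <- rlnorm(nrow(samples), -sdlog^2 / 2, sdlog)
    bad <- runif(nrow(samples)) < config$bad_replicate_rate

    counts <- matrix(0L, ng, nrow(samples),
                     dimnames = list(gene_id, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      m <- mu[, as.character(samples$time[s])] * libfac[s]
      if (bad[s]) {
        sel <- sample.int(ng, floor(ng / 2))
        m[sel] <- m[sample(sel)]
      }
      counts[, s] <- if (config$dispersion == 0) rpois(ng, m)
                     else rnbinom(ng, mu = m, size = 1 / config$dispersion)
    }

    truth <- data.frame(gene_id = gene_id, class = class,
                        peak_times = vapply(peaks, paste, "", collapse = ","),
                        baseline_mean = baseline, length_bp = length_bp)
    list(cm = count_matrix(counts, samples), truth = truth,
         lengths = data.frame(gene_id = gene_id, length_bp = length_bp),
         bad_samples = samples$sample_id[bad], config = config)
  })
}

#' Simulate a protein homology hit table with known KO ground truth
#'
#' Produces BLAST-tabular-shaped hit records, a subject-to-KO map, and the
#' per-(query, KO) cumulative bit-scores of the hits passing the e-value
#' cutoff, aggregated by a plain loop so downstream KO assignment can be
#' checked against planted truth.
#'
#' @param n_query,n_ko numbers of query proteins and KO terms (>= 1).
#' @param seed integer RNG seed.
#' @param max_hits maximum hits per query.
#' @param e_max e-value cutoff used when computing the truth table.
#' @return List with `hits` (data.frame: query, subject, pident, length,
#'   evalue, bitscore), `ko_map` (subject, ko), and `truth`
#'   (query, ko, cum_score over passing hits).
#' @export
simulate_hit_table <- function(n_query, n_ko, seed = 1L, max_hits = 6,
                               e_max = 1e-5) {
  if (!is_count_scalar(n_query) || !is_count_scalar(n_ko))
    stopf("n_query and n_ko must be positive integers")
  with_seed(seed, {
    n_subj <- 2L * n_ko
    subject <- sprintf("s%04d", seq_len(n_subj))
    kos <- sprintf("K%05d", seq_len(n_ko))
    ko_map <- data.frame(subject = subject,
                         ko = kos[1 + (seq_len(n_subj) - 1) %% n_ko])
    # a fifth of subjects carry a second KO
    extra <- sample(n_subj, max(1, floor(n_subj / 5)))
    ko_map <- rbind(ko_map,
                    data.frame(subject = subject[extra],
                               ko = sample(kos, length(extra), replace = TRUE)))
    ko_map <- unique(ko_map[order(ko_map$subject, ko_map$ko), ])
    rownames(ko_map) <- NULL

    rows <- vector("list", n_query)
    for (q in seq_len(n_query)) {
      nh <- sample.int(max_hits + 1, 1) - 1L   # 0..max_hits
      if (nh == 0) { rows[[q]] <- NULL; next }
      ev <- 10^runif(nh, -30, -3)              # some hits fail e_max
      rows[[q]] <- data.frame(
        query = sprintf("q%04d", q),
        subject = sample(subject, nh, replace = TRUE),
        pident = round(runif(nh, 30, 100), 1),
        length = sample(50:400, nh, replace = TRUE),
        evalue = ev,
        bitscore = round(runif(nh, 40, 300), 1))
    }
    hits <- do.call(rbind, rows)
    if (is.null(hits))
      hits <- data.frame(query = character(), subject = character(),
                         pident = numeric(), length = integer(),
                         evalue = numeric(), bitscore = numeric())

    # ground truth by brute-force loop over passing hits
    pass <- hits[hits$evalue <= e_max, , drop = FALSE]
    acc <- list()
    for (i in seq_len(nrow(pass))) {
      for (ko in ko_map$ko[ko_map$subject == pass$subject[i]]) {
        key <- paste(pass$query[i], ko, sep = "\r")
        acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + pass$bitscore[i]
      }
    }
    truth <- if (length(acc) == 0)
      data.frame(query = character(), ko = character(), cum_score = numeric())
    else {
      parts <- strsplit(names(acc), "\r", fixed = TRUE)
      data.frame(query = vapply(parts, `[`, "", 1),
                 ko = vapply(parts, `[`, "", 2),
                 cum_score = unname(unlist(acc)))
    }
    truth <- truth[order(truth$query, truth$ko), ]
    rownames(truth) <- NULL
    list(hits = hits, ko_map = ko_map, truth = truth)
  })
}

#' Simulate two peptide sets with planted ortholog pairs
#'
#' Set B contains point-mutated copies of set A members (in shuffled
#' order), with the true pairing recorded, as a fixture for
#' reciprocal-best-hit orthology.
#'
#' @param n number of peptides per set (>= 1).
#' @param seed integer RNG seed.
#' @param substitution_rate per-residue substitution probability for the
#'   B copies (0 gives identical pairs).
#' @param length_range integer range of peptide lengths.
#' @return List with `a`, `b` (named character vectors of amino-acid
#'   sequences) and `truth` (data.frame: gene_a, gene_b).
#' @export
simulate_peptides <- function(n, seed = 1L, substitution_rate = 0.05,
                              length_range = c(80L, 200L)) {
  if (!is_count_scalar(n)) stopf("n must be a positive integer")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    a <- vapply(lens, function(L) paste(sample(aa, L, replace = TRUE),
                                        collapse = ""), "")
    names(a) <- sprintf("a%03d", seq_len(n))
    b <- vapply(a, function(s) {
      ch <- strsplit(s, "")[[1]]
      mut <- which(runif(length(ch)) < substitution_rate)
      for (i in mut) ch[i] <- sample(setdiff(aa, ch[i]), 1)
      paste(ch, collapse = "")
    }, "")
    ord <- sample.int(n)
    b <- b[ord]
    names(b) <- sprintf("b%03d", seq_len(n))
    truth <- data.frame(gene_a = names(a)[ord], gene_b = names(b))
    list(a = a, b = b, truth = truth)
  })
}
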