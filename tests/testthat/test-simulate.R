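test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 120, seed = 5)
  s1 <- simulate_counts(cfg)
  s2 <- simulate_counts(cfg)
  expect_identical(s1$cm$counts, s2$cm$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$bad_samples, s2$bad_samples)
  s3 <- simulate_counts(sim_config(n_genes = 120, seed = 6))
  expect_false(identical(s1$cm$counts, s3$cm$counts))
})

test_that("planted peak means match the configured effect size", {
  # law-of-large-numbers check: many replicates, no library-size noise
  cfg <- sim_config(n_genes = 200, n_replicates = 200, effect_size = 4,
                    dispersion = 0.1, libsize_cv = 0, bad_replicate_rate = 0,
                    seed = 2)
  sim <- simulate_counts(cfg)
  urg1 <- which(sim$truth$class == "urg1")[1:5]
  t0_cols <- sim$cm$samples$sample_id[sim$cm$samples$time == 0]
  t24_cols <- sim$cm$samples$sample_id[sim$cm$samples$time == 24]
  for (g in urg1) {
    base <- sim$truth$baseline_mean[g]
    m0 <- mean(sim$cm$counts[g, t0_cols])
    m24 <- mean(sim$cm$counts[g, t24_cols])
    se0 <- sd(sim$cm$counts[g, t0_cols]) / sqrt(length(t0_cols))
    se24 <- sd(sim$cm$counts[g, t24_cols]) / sqrt(length(t24_cols))
    expect_lt(abs(m0 - 4 * base), 4 * se0 + 1e-9)
    expect_lt(abs(m24 - base), 4 * se24 + 1e-9)
  }
})

test_that("class fractions are realized within multinomial error", {
  cfg <- sim_config(n_genes = 4000, seed = 3)
  sim <- simulate_counts(cfg)
  frac <- table(sim$truth$class)[names(cfg$class_fractions)] / cfg$n_genes
  # 4 sd of a binomial proportion at n = 4000
  tol <- 4 * sqrt(cfg$class_fractions * (1 - cfg$class_fractions) / cfg$n_genes)
  expect_true(all(abs(frac - cfg$class_fractions) < tol))
})

test_that("degenerate config gives flat Poisson-only variation", {
  cfg <- sim_config(n_genes = 150, effect_size = 1, dispersion = 0,
                    libsize_cv = 0, bad_replicate_rate = 0, seed = 4)
  sim <- simulate_counts(cfg)
  # no planted signal: per-gene time-point means all estimate the same
  # baseline; index of dispersion across all samples ~ 1 (Poisson)
  big <- sim$truth$baseline_mean > 30
  idx <- apply(sim$cm$counts[big, ], 1, var) / rowMeans(sim$cm$counts[big, ])
  expect_gt(mean(idx), 0.8)
  expect_lt(mean(idx), 1.2)
})

test_that("noise-class genes sit below the RPKM floor", {
  cfg <- sim_config(n_genes = 800, bad_replicate_rate = 0, seed = 8)
  sim <- simulate_counts(cfg)
  prof <- rpkm(sim$cm, setNames(sim$lengths$length_bp, sim$lengths$gene_id))
  noise <- sim$truth$class == "noise"
  # generative means sit below the floor equivalent; at this depth a
  # single stray read can push one time point above RPKM 4, but the
  # all-time-points floor gate still rejects these genes
  expect_gt(mean(rowMeans(prof$rpkm_time[noise, ]) < 4), 0.95)
  floor_pass <- rowSums(prof$rpkm_time[noise, ] > 4) == ncol(prof$rpkm_time)
  expect_lt(mean(floor_pass), 0.05)
  signal <- sim$truth$class %in% c("urg1", "urg2", "urg3", "flat")
  above <- rowSums(prof$rpkm_time[signal, ] > 4) == ncol(prof$rpkm_time)
  expect_gt(mean(above), 0.95)
})

test_that("config validation rejects malformed inputs", {
  expect_error(sim_config(n_genes = 10.5), "positive integer")
  expect_error(sim_config(n_replicates = 0), "positive integer")
  expect_error(sim_config(time_grid = integer(0)), "empty")
  expect_error(sim_config(effect_size = 0.5), "effect_size")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(early = c(6L, 24L)), "disjoint")
  cf <- c(urg1 = 0.3, urg2 = 0.3, urg3 = 0.3, flat = 0.2, noise = 0.1)
  expect_error(sim_config(class_fractions = cf), "sum to 1")
})

test_that("hit-table simulator truth equals brute-force aggregation", {
  ht <- simulate_hit_table(60, 10, seed = 21)
  pass <- ht$hits[ht$hits$evalue <= 1e-5, ]
  m <- merge(pass, ht$ko_map, by = "subject")
  agg <- aggregate(bitscore ~ query + ko, data = m, FUN = sum)
  agg <- agg[order(agg$query, agg$ko), ]
  expect_equal(ht$truth$cum_score,
               agg$bitscore[match(paste(ht$truth$query, ht$truth$ko),
                                  paste(agg$query, agg$ko))])
})

test_that("peptide simulator plants recoverable pairs", {
  p0 <- simulate_peptides(5, seed = 1, substitution_rate = 0)
  m <- p0$truth
  expect_true(all(p0$a[m$gene_a] == p0$b[m$gene_b]))
  p5 <- simulate_peptides(5, seed = 1, substitution_rate = 0.05)
  # same lengths, mostly identical residues (pairing via p5's own truth:
  # the shuffle order depends on how much RNG the mutation step consumed)
  m5 <- p5$truth
  for (k in seq_len(5)) {
    sa <- strsplit(p5$a[[m5$gene_a[k]]], "")[[1]]
    sb <- strsplit(p5$b[[m5$gene_b[k]]], "")[[1]]
    expect_equal(length(sa), length(sb))
    expect_gt(mean(sa == sb), 0.85)
  }
  expect_identical(simulate_peptides(5, seed = 9)$b,
                   simulate_peptides(5, seed = 9)$b)
})
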