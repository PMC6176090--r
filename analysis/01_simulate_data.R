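#!/usr/bin/env Rscript
# Simulate the two-strain infection time-course study design: a 7-point
# grid (0-36 h, "strain A") and a 9-point grid (0-44 h, "strain B"),
# 3 replicates per time point, planted URG1/URG2/URG3 classes, noise
# genes below the RPKM floor, and a realistic share of corrupted
# replicates. Writes counts, sample sheets, gene lengths and the planted
# truth under results/data/.

suppressPackageStartupMessages(library(urgflow))
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

grids <- list(strainA = seq(0L, 36L, 6L),
              strainB = c(seq(0L, 36L, 6L), 42L, 44L))
for (strain in names(grids)) {
  grid <- grids[[strain]]
  cfg <- sim_config(n_genes = 2000, time_grid = grid,
                    late = grid[grid >= 24L],
                    seed = if (strain == "strainA") 101L else 202L)
  sim <- simulate_counts(cfg)
  write_counts(sim$cm, file.path(out, paste0(strain, "_counts.tsv")))
  write_sample_sheet(sim$cm$samples, file.path(out, paste0(strain, "_samples.tsv")))
  write.table(sim$lengths, file.path(out, paste0(strain, "_lengths.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(out, paste0(strain, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$bad_samples, file.path(out, paste0(strain, "_bad_samples.txt")))
  cat(sprintf("%s: %d genes x %d samples, %d corrupted replicate(s): %s\n",
              strain, nrow(sim$cm$counts), ncol(sim$cm$counts),
              length(sim$bad_samples),
              paste(sim$bad_samples, collapse = ", ")))
}
cat("class totals (strain A):\n")
print(table(read.delim(file.path(out, "strainA_truth.tsv"))$class))
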