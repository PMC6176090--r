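#!/usr/bin/env Rscript
# Classify genes into the three upregulated stage groups by the
# intersection/sum conditions over significance-masked log2 fold changes,
# with the strict RPKM-maximum side conditions and the RPKM > 4 floor,
# then score the result against the planted truth.

suppressPackageStartupMessages(library(urgflow))
out <- "results/urg"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (strain in c("strainA", "strainB")) {
  cm <- read_counts(sprintf("results/qc/%s_counts_kept.tsv", strain),
                    sprintf("results/qc/%s_samples_kept.tsv", strain))
  lengths <- read_gene_lengths(sprintf("results/data/%s_lengths.tsv", strain))
  prof <- rpkm(cm, lengths)
  ctr <- build_contrast_set(cm, alpha = 1e-5, min_fold = 2)
  grid <- time_points(cm)
  urg <- assign_urg(ctr, prof, stage_partition(grid, early = c(6L, 12L, 18L)),
                    floor = 4)
  write.table(urg$trace, file.path(out, paste0(strain, "_assignment.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s URG sizes: URG1=%d URG2=%d URG3=%d none=%d (DEGs: %d)\n",
              strain, urg$counts["URG1"], urg$counts["URG2"],
              urg$counts["URG3"], urg$counts["none"], urg$n_deg))

  truth <- read.delim(sprintf("results/data/%s_truth.tsv", strain))
  for (k in 1:3) {
    lab <- paste0("URG", k); cl <- paste0("urg", k)
    tp <- sum(truth$class == cl & urg$labels[truth$gene_id] == lab)
    cat(sprintf("  %s recall %.3f precision %.3f\n", lab,
                tp / sum(truth$class == cl),
                tp / max(sum(urg$labels == lab), 1)))
  }
}
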