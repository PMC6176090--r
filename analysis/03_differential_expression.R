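#!/usr/bin/env Rscript
# All-vs-all pairwise negative-binomial differential expression on the
# QC-retained samples, with the study thresholds (BH-adjusted p < 1e-5,
# |fold change| > 2), plus RPKM profiles for downstream classification.

suppressPackageStartupMessages(library(urgflow))
out <- "results/de"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (strain in c("strainA", "strainB")) {
  cm <- read_counts(sprintf("results/qc/%s_counts_kept.tsv", strain),
                    sprintf("results/qc/%s_samples_kept.tsv", strain))
  lengths <- read_gene_lengths(sprintf("results/data/%s_lengths.tsv", strain))
  prof <- rpkm(cm, lengths)
  ctr <- build_contrast_set(cm, alpha = 1e-5, min_fold = 2)
  long <- contrast_long(ctr)
  write.table(long, file.path(out, paste0(strain, "_contrasts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rt <- prof$rpkm_time
  write.table(data.frame(gene_id = rownames(rt), round(rt, 4),
                         check.names = FALSE),
              file.path(out, paste0(strain, "_rpkm_time.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  n_deg <- sum(tapply(long$significant, long$gene, any))
  cat(sprintf("%s: %d contrasts, %d/%d genes DE in >= 1 contrast (%.0f%%)\n",
              strain, nrow(unique(long[, c("a", "b")])), n_deg,
              length(unique(long$gene)), 100 * n_deg / length(unique(long$gene))))
  per <- aggregate(significant ~ a + b, data = long, FUN = sum)
  cat(sprintf("  most separated pair: T%d vs T%d (%d DEGs)\n",
              per$a[which.max(per$significant)],
              per$b[which.max(per$significant)], max(per$significant)))
}
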