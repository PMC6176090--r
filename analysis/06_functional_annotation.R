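#!/usr/bin/env Rscript
# KO assignment by cumulative bit-score (e-value <= 1e-5, best KO plus any
# KO within 90% of the best) on a simulated homology hit table tied to the
# strain-A genes, followed by the BRITE level-B roll-up: per URG group and
# category, the sum of each member gene's characteristic-stage RPKM.

suppressPackageStartupMessages(library(urgflow))
out <- "results/annotation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

asg_urg <- read.delim("results/urg/strainA_assignment.tsv")
rt <- as.matrix(read.delim("results/de/strainA_rpkm_time.tsv",
                           row.names = 1, check.names = FALSE))

ht <- simulate_hit_table(n_query = 800, n_ko = 60, seed = 301L)
gene_ids <- asg_urg$gene
ht$hits$query <- gene_ids[as.integer(sub("q", "", ht$hits$query))]
ko <- assign_ko(ht$hits, ht$ko_map, e_max = 1e-5, retention = 0.9)
write.table(ko$assignments, file.path(out, "ko_assignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("KO terms assigned to %d genes (%.0f%% of %d); %d queries had no passing hit\n",
            length(unique(ko$assignments$query)),
            100 * length(unique(ko$assignments$query)) / length(gene_ids),
            length(gene_ids), ko$n_unassigned))

kos <- unique(ht$ko_map$ko)
brite_map <- data.frame(
  ko = kos,
  levelA = ifelse(seq_along(kos) %% 2 == 0, "09100 Metabolism",
                  "09120 Genetic Information Processing"),
  levelB = sprintf("category %02d", seq_along(kos) %% 10))
urg <- structure(list(labels = setNames(asg_urg$label, asg_urg$gene)),
                 class = "urg_assignment")
profile <- structure(list(rpkm_time = rt), class = "expression_profile")
grid <- as.integer(colnames(rt))
signal <- brite_rollup(ko, brite_map, urg, profile,
                       stage_partition(grid, early = c(6L, 12L, 18L)))
write.table(signal, file.path(out, "brite_signal.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- signal[order(-signal$signal), ]
cat("strongest category signals per URG group:\n")
for (g in unique(top$urg)) {
  r <- top[top$urg == g, ][1, ]
  cat(sprintf("  %s: %s / %s (summed RPKM %.0f over %d genes)\n",
              g, r$levelA, r$levelB, r$signal, r$n_genes))
}
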