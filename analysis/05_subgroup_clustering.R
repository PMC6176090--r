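#!/usr/bin/env Rscript
# Sub-cluster the URG2 and URG3 groups by Pearson correlation of RPKM
# profiles over the full time course: correlations with p <= 0.1 kept,
# complete-linkage clustering on d = 1 - r cut at 0.5, clusters validated
# when mean and median pairwise r exceed 0.5.

suppressPackageStartupMessages(library(urgflow))
out <- "results/subgroups"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (strain in c("strainA", "strainB")) {
  asg <- read.delim(sprintf("results/urg/%s_assignment.tsv", strain))
  rt <- as.matrix(read.delim(sprintf("results/de/%s_rpkm_time.tsv", strain),
                             row.names = 1, check.names = FALSE))
  for (group in c("URG2", "URG3")) {
    members <- asg$gene[asg$label == group]
    if (length(members) < 2) next
    tab <- filter_significant(correlate_profiles(rt, members), p_max = 0.1)
    sg <- cluster_subgroups(tab, rt, cut_height = 0.5)
    write.table(sg$clusters,
                file.path(out, sprintf("%s_%s_clusters.tsv", strain, group)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = names(sg$membership),
                           cluster = sg$membership),
                file.path(out, sprintf("%s_%s_members.tsv", strain, group)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    val <- sg$clusters[sg$clusters$validated, ]
    cat(sprintf("%s %s: %d genes -> %d clusters, %d validated (peaks at %s h)\n",
                strain, group, length(members), nrow(sg$clusters), nrow(val),
                paste(sort(unique(val$peak_time)), collapse = "/")))
  }
}
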