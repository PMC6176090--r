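#' Pairwise Pearson correlation of expression profiles
#'
#' Correlates every pair of genes on their RPKM values across time
#' points, with two-sided p-values from the t statistic on n - 2 degrees
#' of freedom. Constant profiles have undefined correlation; those
#' entries are recorded as missing and excluded downstream.
#'
#' @param rpkm_time genes x time points RPKM matrix (replicate means),
#'   with at least 3 time points.
#' @param genes optional subset of gene ids (default all rows).
#' @return List of class `correlation_table`: `r` and `p` (symmetric
#'   matrices), `n` (time points used).
#' @export
correlate_profiles <- function(rpkm_time, genes = rownames(rpkm_time)) {
  if (length(genes) == 0) stopf("gene subset is empty")
  x <- rpkm_time[genes, , drop = FALSE]
  n <- ncol(x)
  if (n < 3) stopf("need >= 3 time points for correlation p-values")
  r <- suppressWarnings(cor(t(x)))
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(p) <- 0
  structure(list(r = r, p = p, n = n), class = "correlation_table")
}

#' Mask non-significant correlations
#'
#' Pairs whose correlation p-value exceeds `p_max` (default 0.1) are
#' treated as uncorrelated: their r is set to 0 and the mask recorded.
#'
#' @param tab a `correlation_table`.
#' @param p_max maximum p-value to keep a pair (default 0.1).
#' @return The table with an additional `r_masked` matrix and logical
#'   `mask` (TRUE where a pair was zeroed).
#' @export
filter_significant <- function(tab, p_max = 0.1) {
  mask <- !is.na(tab$p) & tab$p > p_max
  r_masked <- tab$r
  r_masked[mask] <- 0
  tab$r_masked <- r_masked
  tab$mask <- mask
  tab$p_max <- p_max
  tab
}

#' Hierarchical sub-clustering of correlated genes
#'
#' Agglomerative clustering on the distance d = 1 - r over the masked
#' correlation matrix (masked or missing pairs enter at d = 1), cut at a
#' fixed height (default 0.5). Each resulting cluster is validated on the
#' raw (unmasked) correlations of its members: a cluster is validated
#' when its mean AND median pairwise r exceed 0.5 and it has at least two
#' members. Genes with constant profiles (undefined r) are excluded
#' before clustering, with a message.
#'
#' @param tab a `correlation_table`, ideally after [filter_significant()].
#' @param rpkm_time optional RPKM matrix to annotate each cluster's peak
#'   time point and mean RPKM at the peak.
#' @param cut_height tree cut height on d = 1 - r (default 0.5).
#' @param linkage hclust agglomeration method (default `"complete"`).
#' @param validation_r validation threshold on mean and median pairwise r
#'   (default 0.5).
#' @return List of class `subgroup_set`: `clusters` (data.frame: cluster,
#'   size, mean_r, median_r, validated, peak_time, mean_rpkm_peak),
#'   `membership` (named integer vector), `excluded` (constant genes).
#' @export
cluster_subgroups <- function(tab, rpkm_time = NULL, cut_height = 0.5,
                              linkage = "complete", validation_r = 0.5) {
  rm_ <- if (!is.null(tab$r_masked)) tab$r_masked else tab$r
  constant <- if (ncol(tab$r) > 1)
    rowSums(is.na(tab$r)) == ncol(tab$r) - 1
  else rep(FALSE, nrow(tab$r))
  if (any(constant)) {
    msgf("excluding %d constant profile(s) from clustering", sum(constant))
    rm_ <- rm_[!constant, !constant, drop = FALSE]
  }
  genes <- rownames(rm_)
  if (length(genes) == 0) stopf("no genes left to cluster")
  if (length(genes) == 1) {
    membership <- setNames(1L, genes)
  } else {
    d <- 1 - rm_
    d[is.na(d)] <- 1
    hc <- hclust(as.dist(d), method = linkage)
    membership <- cutree(hc, h = cut_height)
  }
  raw <- tab$r
  rows <- lapply(sort(unique(membership)), function(k) {
    members <- genes[membership == k]
    if (length(members) >= 2) {
      rr <- raw[members, members]
      vals <- rr[upper.tri(rr)]
      mean_r <- mean(vals, na.rm = TRUE)
      med_r <- median(vals, na.rm = TRUE)
    } else mean_r <- med_r <- NA_real_
    validated <- length(members) >= 2 && !is.na(mean_r) && !is.na(med_r) &&
      mean_r > validation_r && med_r > validation_r
    peak_time <- NA_integer_; mean_rpkm_peak <- NA_real_
    if (!is.null(rpkm_time)) {
      prof <- colMeans(rpkm_time[members, , drop = FALSE])
      peak_time <- as.integer(colnames(rpkm_time)[which.max(prof)])
      mean_rpkm_peak <- max(prof)
    }
    data.frame(cluster = k, size = length(members), mean_r = mean_r,
               median_r = med_r, validated = validated,
               peak_time = peak_time, mean_rpkm_peak = mean_rpkm_peak)
  })
  structure(list(clusters = do.call(rbind, rows), membership = membership,
                 excluded = rownames(tab$r)[constant],
                 cut_height = cut_height, linkage = linkage,
                 validation_r = validation_r),
            class = "subgroup_set")
}

#' @export
print.subgroup_set <- function(x, ...) {
  cat(sprintf("subgroup_set: %d cluster(s), %d validated (cut height %g, %s linkage)\n",
              nrow(x$clusters), sum(x$clusters$validated), x$cut_height,
              x$linkage))
  invisible(x)
}

#' Rectangular correlation between two gene sets
#'
#' Correlation matrix (with p-values) between the profiles of two gene
#' families, as used for family-vs-family co-expression heatmaps (e.g.
#' the anti-ROS gene families). Constant profiles give missing entries.
#'
#' @param rpkm_time genes x time points RPKM matrix.
#' @param set_a,set_b non-empty character vectors of gene ids.
#' @return List with `r` and `p` matrices (rows = `set_a`, columns =
#'   `set_b`) and `n` (time points used).
#' @export
correlate_gene_sets <- function(rpkm_time, set_a, set_b) {
  if (length(set_a) == 0 || length(set_b) == 0) stopf("gene sets must be non-empty")
  n <- ncol(rpkm_time)
  if (n < 3) stopf("need >= 3 time points for correlation p-values")
  r <- suppressWarnings(cor(t(rpkm_time[set_a, , drop = FALSE]),
                            t(rpkm_time[set_b, , drop = FALSE])))
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  list(r = r, p = p, n = n)
}
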