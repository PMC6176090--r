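#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed against the geometric-mean
#' reference gene-wise, as is conventional for count-based differential
#' expression; factors are rescaled to geometric mean 1. If no gene is
#' expressed in every sample the factors fall back to library-size
#' ratios, with a message.
#'
#' @param cm a [count_matrix] or plain counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    msgf("no gene expressed in all samples; using library-size factors")
    sf <- colSums(counts)
  } else {
    lg <- log(counts[allpos, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- apply(exp(lg - ref), 2, median)
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' RPKM expression profiles
#'
#' RPKM_gs = y_gs * 1e9 / (L_g * N_s), with N_s the sample's total counted
#' reads; the per-time-point profile is the arithmetic mean over retained
#' replicates.
#'
#' @param cm a [count_matrix].
#' @param lengths named integer vector of gene lengths (bp), covering all
#'   genes.
#' @return List of class `expression_profile`: `rpkm_sample` (genes x
#'   samples), `rpkm_time` (genes x time points, replicate means),
#'   `lengths`, `samples`.
#' @export
rpkm <- function(cm, lengths) {
  counts <- cm$counts
  if (!all(rownames(counts) %in% names(lengths)))
    stopf("gene length table does not cover all genes")
  L <- lengths[rownames(counts)]
  N <- colSums(counts)
  if (any(N == 0)) stopf("sample '%s' has zero total counts",
                         colnames(counts)[which(N == 0)[1]])
  r <- sweep(counts * 1e9 / L, 2, N, "/")
  tps <- sort(unique(cm$samples$time))
  rt <- sapply(tps, function(tp) {
    cols <- cm$samples$sample_id[cm$samples$time == tp]
    rowMeans(r[, cols, drop = FALSE])
  })
  colnames(rt) <- as.character(tps)
  structure(list(rpkm_sample = r, rpkm_time = rt, lengths = L,
                 samples = cm$samples), class = "expression_profile")
}

#' Pairwise negative-binomial Wald test
#'
#' Differential expression between two time points on normalized counts.
#' Per gene: group means of size-factor-normalized counts; moderated
#' log2 fold change log2((mu_b + c)/(mu_a + c)) with pseudo-mean c = 0.5;
#' gene-wise dispersion by method-of-moments pooled over the two groups,
#' floored at 0 and shrunk 50% toward a fitted mean-dispersion trend
#' (alpha ~ a0 + a1/mu); Wald z from the NB delta-method standard error
#' of the log2 fold change; two-sided normal p; BH adjustment within the
#' contrast. With a single replicate on either side p-values are
#' suppressed (NA) and only fold changes are reported, with a message.
#'
#' @param cm a [count_matrix].
#' @param sf named size factors covering the samples of both groups.
#' @param pair length-2 vector of time points `c(a, b)`; the fold change
#'   is of `b` relative to `a`.
#' @param pseudo_mean pseudo-mean c added to normalized group means.
#' @return data.frame: gene, log2fc, p, padj, mu_a, mu_b, dispersion.
#' @export
nb_pairwise_de <- function(cm, sf = size_factors(cm), pair,
                           pseudo_mean = 0.5) {
  a_cols <- cm$samples$sample_id[cm$samples$time == pair[1]]
  b_cols <- cm$samples$sample_id[cm$samples$time == pair[2]]
  if (length(a_cols) == 0 || length(b_cols) == 0)
    stopf("time point without retained replicates in pair (%s, %s)",
          pair[1], pair[2])
  qa <- sweep(cm$counts[, a_cols, drop = FALSE], 2, sf[a_cols], "/")
  qb <- sweep(cm$counts[, b_cols, drop = FALSE], 2, sf[b_cols], "/")
  mu_a <- rowMeans(qa); mu_b <- rowMeans(qb)
  lfc <- log2((mu_b + pseudo_mean) / (mu_a + pseudo_mean))
  na <- ncol(qa); nb <- ncol(qb)

  if (na < 2 && nb < 2) {
    msgf("single replicate on both sides of (%s, %s): p-values suppressed",
         pair[1], pair[2])
    p <- rep(NA_real_, length(lfc))
    return(data.frame(gene = rownames(cm$counts), log2fc = lfc, p = p,
                      padj = p, mu_a = mu_a, mu_b = mu_b,
                      dispersion = NA_real_))
  }
  if (na < 2 || nb < 2)
    msgf("single replicate on one side of (%s, %s): p-values suppressed",
         pair[1], pair[2])

  alpha <- nb_dispersion(qa, qb, mu_a, mu_b)
  if (na < 2 || nb < 2) {
    p <- rep(NA_real_, length(lfc))
  } else {
    var_a <- (mu_a %o% (1 / sf[a_cols])) |> rowSums()
    var_a <- (var_a + na * alpha * mu_a^2) / na^2
    var_b <- (mu_b %o% (1 / sf[b_cols])) |> rowSums()
    var_b <- (var_b + nb * alpha * mu_b^2) / nb^2
    se <- sqrt(var_a / (mu_a + pseudo_mean)^2 +
               var_b / (mu_b + pseudo_mean)^2) / log(2)
    z <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * pnorm(-abs(z))
    p[mu_a == 0 & mu_b == 0] <- 1
  }
  padj <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(cm$counts), log2fc = lfc, p = p, padj = padj,
             mu_a = mu_a, mu_b = mu_b, dispersion = alpha)
}

# Method-of-moments NB dispersion pooled over two groups, floored at 0
# and shrunk 50% toward the fitted mean-dispersion trend a0 + a1/mu.
nb_dispersion <- function(qa, qb, mu_a = rowMeans(qa), mu_b = rowMeans(qb)) {
  est_group <- function(q, mu) {
    if (ncol(q) < 2) return(rep(NA_real_, nrow(q)))
    v <- rowVars(q)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  }
  aa <- est_group(qa, mu_a); ab <- est_group(qb, mu_b)
  wa <- max(ncol(qa) - 1, 0); wb <- max(ncol(qb) - 1, 0)
  raw <- rowMeans(cbind(aa * wa, ab * wb), na.rm = TRUE) /
    rowMeans(cbind(ifelse(is.na(aa), NA, wa), ifelse(is.na(ab), NA, wb)),
             na.rm = TRUE)
  raw[is.nan(raw) | is.na(raw)] <- 0
  raw <- pmax(raw, 0)
  mu <- (mu_a + mu_b) / 2
  use <- mu > 1
  trend <- rep(mean(raw[use]), length(raw))
  if (sum(use) > 10) {
    fit <- tryCatch(lm(raw[use] ~ I(1 / mu[use])), error = function(e) NULL)
    if (!is.null(fit)) {
      co <- coef(fit)
      trend <- pmax(co[1] + co[2] / mu, 0)
    }
  }
  trend[!is.finite(trend)] <- 0
  pmax(0.5 * raw + 0.5 * trend, 1e-8)
}

#' All-vs-all pairwise differential expression
#'
#' Runs the NB Wald test for every unordered pair of time points and
#' stores antisymmetric log2 fold changes, p-values, BH-adjusted p-values
#' and the significance mask (adjusted p below `alpha` and absolute fold
#' change above `min_fold`, read as |log2FC| > log2(min_fold)).
#'
#' @param cm a [count_matrix] (after replicate QC).
#' @param alpha adjusted-p significance threshold (default 1e-5).
#' @param min_fold minimum fold change (default 2).
#' @param sf optional size factors (computed over all samples by default).
#' @return Object of class `contrast_set`: 3-d arrays `lfc`, `p`, `padj`,
#'   `sig` indexed \[gene, time a, time b\] (fold change of b relative to
#'   a), plus `time_points`, `alpha`, `min_fold`.
#' @export
build_contrast_set <- function(cm, alpha = 1e-5, min_fold = 2,
                               sf = size_factors(cm)) {
  tps <- sort(unique(cm$samples$time))
  if (length(tps) < 2) stopf("need at least 2 time points")
  genes <- rownames(cm$counts)
  dn <- list(genes, as.character(tps), as.character(tps))
  empty <- array(NA_real_, dim = c(length(genes), length(tps), length(tps)),
                 dimnames = dn)
  lfc <- empty; p <- empty; padj <- empty
  sig <- array(FALSE, dim = dim(empty), dimnames = dn)
  for (i in seq_along(tps)) for (j in seq_along(tps)) {
    if (j <= i) next
    de <- nb_pairwise_de(cm, sf, c(tps[i], tps[j]))
    lfc[, i, j] <- de$log2fc; lfc[, j, i] <- -de$log2fc
    p[, i, j] <- de$p;        p[, j, i] <- de$p
    padj[, i, j] <- de$padj;  padj[, j, i] <- de$padj
    s <- !is.na(de$padj) & de$padj < alpha & abs(de$log2fc) > log2(min_fold)
    sig[, i, j] <- s; sig[, j, i] <- s
  }
  for (i in seq_along(tps)) {
    lfc[, i, i] <- 0; p[, i, i] <- 1; padj[, i, i] <- 1
  }
  structure(list(lfc = lfc, p = p, padj = padj, sig = sig,
                 time_points = tps, alpha = alpha, min_fold = min_fold),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  n <- length(x$time_points)
  cat(sprintf("contrast_set: %d genes, %d time points (%d contrasts), alpha=%g, min fold=%g\n",
              dim(x$lfc)[1], n, n * (n - 1) / 2, x$alpha, x$min_fold))
  invisible(x)
}
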