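#' SERE replicate concordance statistic
#'
#' Simple Error Ratio Estimate for a pair of count vectors. With library
#' sizes \eqn{N_j = \sum_g y_{gj}}, the expected count is
#' \eqn{E_{gj} = (y_{gA}+y_{gB}) N_j / (N_A+N_B)} and
#' \deqn{SERE = \sqrt{ \sum_g \sum_j (y_{gj}-E_{gj})^2/E_{gj} \, / \, ((k-1) G') }}
#' over the \eqn{G'} genes with nonzero pair total, with \eqn{k = 2}
#' samples. The statistic is 0 for exact duplicates, close to 1 for
#' Poisson-distributed technical replicates, and grows with
#' overdispersion.
#'
#' @param a,b equal-length non-negative integer count vectors.
#' @return SERE value (non-negative scalar).
#' @export
sere <- function(a, b) {
  if (length(a) != length(b)) stopf("count vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stopf("counts must be non-negative")
  tot <- a + b
  keep <- tot > 0
  if (!any(keep)) stopf("no expressed genes")
  a <- a[keep]; b <- b[keep]; tot <- tot[keep]
  na <- sum(a); nb <- sum(b)
  ea <- tot * na / (na + nb)
  eb <- tot * nb / (na + nb)
  disp <- sum((a - ea)^2 / ea + (b - eb)^2 / eb)
  sqrt(disp / ((2 - 1) * length(tot)))
}

#' Replicate concordance QC and exclusion
#'
#' Within each time point, all pairwise SERE values are computed; a sample
#' is dropped when its SERE against every retained sibling is at or above
#' the threshold (default 1.7, the keep criterion SERE < 1.7). At least
#' one replicate is always retained per time point: if all replicates are
#' mutually discordant the one with the largest library is kept, with a
#' warning. Single-replicate time points pass through with a warning.
#' The report also records the pairwise Pearson and Spearman correlations
#' and per-sample count-distribution quantiles that accompany the SERE
#' inspection.
#'
#' @param cm a [count_matrix].
#' @param threshold SERE keep threshold (default 1.7).
#' @param force_keep sample ids exempt from dropping (override for
#'   deliberately retained discordant replicates).
#' @return List with `cm` (filtered [count_matrix]) and `report`:
#'   `pairs` (time, sample_a, sample_b, sere, pearson, spearman),
#'   `samples` (sample_id, time, library_size, count quartiles, kept,
#'   reason).
#' @export
qc_replicates <- function(cm, threshold = 1.7, force_keep = character()) {
  samples <- cm$samples
  pairs <- list()
  decisions <- data.frame(sample_id = samples$sample_id, time = samples$time,
                          library_size = colSums(cm$counts),
                          q25 = NA_real_, q50 = NA_real_, q75 = NA_real_,
                          kept = TRUE, reason = "concordant")
  for (i in seq_len(ncol(cm$counts))) {
    q <- quantile(cm$counts[, i], c(.25, .5, .75))
    decisions[i, c("q25", "q50", "q75")] <- q
  }
  for (tp in unique(samples$time)) {
    ids <- samples$sample_id[samples$time == tp]
    if (length(ids) < 2) {
      decisions$reason[decisions$sample_id %in% ids] <- "single replicate (passthrough)"
      warnf("time point %s has a single replicate; kept without QC", tp)
      next
    }
    cmb <- combn(ids, 2)
    sere_mat <- matrix(NA_real_, length(ids), length(ids),
                       dimnames = list(ids, ids))
    for (k in seq_len(ncol(cmb))) {
      x <- cm$counts[, cmb[1, k]]; y <- cm$counts[, cmb[2, k]]
      s <- sere(x, y)
      sere_mat[cmb[1, k], cmb[2, k]] <- s
      sere_mat[cmb[2, k], cmb[1, k]] <- s
      pairs[[length(pairs) + 1]] <- data.frame(
        time = tp, sample_a = cmb[1, k], sample_b = cmb[2, k], sere = s,
        pearson = cor(x, y), spearman = cor(x, y, method = "spearman"))
    }
    # iteratively drop the worst sample whose SERE to every retained
    # sibling fails the keep criterion
    retained <- ids
    repeat {
      if (length(retained) < 2) break
      sub <- sere_mat[retained, retained, drop = FALSE]
      min_sere <- apply(sub, 1, min, na.rm = TRUE)
      bad <- setdiff(retained[min_sere >= threshold], force_keep)
      if (length(bad) == 0) break
      if (length(bad) == length(retained)) {
        # no majority: keep the sample with the largest library
        libs <- decisions$library_size[match(retained, decisions$sample_id)]
        keep_one <- retained[which.max(libs)]
        drop_now <- setdiff(retained, keep_one)
        decisions$kept[decisions$sample_id %in% drop_now] <- FALSE
        decisions$reason[decisions$sample_id %in% drop_now] <-
          sprintf("SERE >= %g to all siblings", threshold)
        decisions$reason[decisions$sample_id == keep_one] <-
          "discordant but retained (largest library)"
        warnf("time point %s: all replicates mutually discordant; kept %s",
              tp, keep_one)
        retained <- keep_one
        break
      }
      worst <- bad[which.max(apply(sub[bad, , drop = FALSE], 1, min,
                                   na.rm = TRUE))]
      decisions$kept[decisions$sample_id == worst] <- FALSE
      decisions$reason[decisions$sample_id == worst] <-
        sprintf("SERE >= %g to all siblings", threshold)
      retained <- setdiff(retained, worst)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(time = integer(), sample_a = character(),
                           sample_b = character(), sere = numeric(),
                           pearson = numeric(), spearman = numeric())
  kept_ids <- decisions$sample_id[decisions$kept]
  list(cm = subset_samples(cm, kept_ids),
       report = list(pairs = pairs, samples = decisions,
                     threshold = threshold))
}
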