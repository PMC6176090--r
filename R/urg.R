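#' Stage partition of the infection time grid
#'
#' Splits the time grid into the dinospore/T0 point, the early
#' (beginning-of-infection) points and the late (end-of-infection)
#' points. Defaults follow the study design: early = 6/12/18 h, late =
#' everything from 24 h on (24-36 h on the 7-point grid, 24-44 h on the
#' 9-point grid).
#'
#' @param time_grid full ordered integer grid (hours).
#' @param t0 the dinospore/T0 label (default first grid point).
#' @param early,late disjoint subsets covering the rest of the grid.
#' @return List of class `stage_partition` (`t0`, `early`, `late`,
#'   `grid`).
#' @export
stage_partition <- function(time_grid, t0 = time_grid[1],
                            early = c(6L, 12L, 18L),
                            late = setdiff(time_grid, c(t0, early))) {
  time_grid <- as.integer(time_grid)
  t0 <- as.integer(t0); early <- as.integer(early); late <- as.integer(late)
  if (t0 %in% c(early, late)) stopf("t0 cannot be in early or late sets")
  if (length(intersect(early, late)) > 0) stopf("early and late must be disjoint")
  if (!setequal(c(t0, early, late), time_grid))
    stopf("t0, early and late must partition the time grid")
  structure(list(t0 = t0, early = sort(early), late = sort(late),
                 grid = sort(time_grid)), class = "stage_partition")
}

#' Per-gene D matrix from a contrast set
#'
#' D(Ta vs Tb) is the log2 fold change of the differential-expression
#' contrast between time points a and b. Under the default
#' `significant_only` masking, non-significant contrasts contribute
#' D = 0, so the sum conditions of the URG formulas read "at least one
#' significant change in the stated direction"; `raw` masking passes the
#' fold changes through unmasked.
#'
#' @param contrasts a `contrast_set` from [build_contrast_set()].
#' @param masking `"significant_only"` (default) or `"raw"`.
#' @return 3-d array D\[gene, a, b\], antisymmetric in (a, b).
#' @export
d_matrix <- function(contrasts, masking = c("significant_only", "raw")) {
  masking <- match.arg(masking)
  if (any(is.na(contrasts$lfc)))
    stopf("contrast set has missing fold changes")
  if (masking == "raw") return(contrasts$lfc)
  contrasts$lfc * contrasts$sig
}

# index helpers: D[, a, b] by time label; cbind of slices that keeps
# matrix shape even for a single gene
d_slice <- function(D, a, b) D[, as.character(a), as.character(b)]
d_cols <- function(D, pairs) {
  matrix(unlist(lapply(pairs, function(p) d_slice(D, p[1], p[2]))),
         nrow = dim(D)[1])
}

#' URG1 classifier: upregulated at the dinospore stage
#'
#' A gene is URG1 when every D(T0 vs Ti) over the non-T0 grid is <= 0,
#' their sum is nonzero, the T0 RPKM strictly exceeds the RPKM at every
#' other time point, and the RPKM floor is passed.
#'
#' @param D 3-d D array from [d_matrix()].
#' @param rpkm_time genes x time points RPKM matrix (replicate means).
#' @param partition a [stage_partition()].
#' @param floor_ok logical vector: per-gene RPKM floor status.
#' @return data.frame of per-gene condition traces and the `urg1` verdict.
#' @export
classify_urg1 <- function(D, rpkm_time, partition, floor_ok = TRUE) {
  others <- setdiff(partition$grid, partition$t0)
  dmat <- d_cols(D, lapply(others, function(ti) c(partition$t0, ti)))
  direction <- rowSums(dmat <= 0) == length(others)
  nonzero_sum <- rowSums(dmat) != 0
  r0 <- rpkm_time[, as.character(partition$t0)]
  rmax <- rowSums(r0 > rpkm_time[, as.character(others), drop = FALSE]) ==
    length(others)
  data.frame(direction = direction, nonzero_sum = nonzero_sum,
             rpkm_max = rmax, floor_ok = floor_ok,
             urg1 = direction & nonzero_sum & rmax & floor_ok)
}

#' URG2 classifier: upregulated at the beginning of infection
#'
#' A gene is URG2 when D(T0 vs Te) >= 0 for every early point, D(Te vs
#' Tl) <= 0 for every early/late pair, the sum of all those terms is
#' nonzero, the early-peak RPKM exceeds the RPKM at every non-early time
#' point, and the floor is passed. The RPKM rule defaults to
#' `any_early_max` (the maximum over early points must beat every
#' non-early point, matching "upregulated in at least one" of the early
#' points); `all_early_max` requires each early point to beat every
#' non-early point.
#'
#' @inheritParams classify_urg1
#' @param rpkm_rule `"any_early_max"` or `"all_early_max"`.
#' @return data.frame of per-gene condition traces and the `urg2` verdict.
#' @export
classify_urg2 <- function(D, rpkm_time, partition, floor_ok = TRUE,
                          rpkm_rule = c("any_early_max", "all_early_max")) {
  rpkm_rule <- match.arg(rpkm_rule)
  e <- partition$early; l <- partition$late
  d0e <- d_cols(D, lapply(e, function(ti) c(partition$t0, ti)))
  el_pairs <- unlist(lapply(e, function(ei) lapply(l, function(li) c(ei, li))),
                     recursive = FALSE)
  del <- d_cols(D, el_pairs)
  up_early <- rowSums(d0e >= 0) == length(e)
  down_late <- rowSums(del <= 0) == ncol(del)
  nonzero_sum <- (rowSums(d0e) + rowSums(del)) != 0
  re <- rpkm_time[, as.character(e), drop = FALSE]
  rother <- rpkm_time[, as.character(setdiff(partition$grid, e)), drop = FALSE]
  rmax <- if (rpkm_rule == "any_early_max") {
    apply(re, 1, max) > apply(rother, 1, max)
  } else {
    apply(re, 1, min) > apply(rother, 1, max)
  }
  data.frame(up_early = up_early, down_late = down_late,
             nonzero_sum = nonzero_sum, rpkm_max = rmax,
             floor_ok = floor_ok,
             urg2 = up_early & down_late & nonzero_sum & rmax & floor_ok)
}

#' URG3 classifier: upregulated at the end of infection
#'
#' A gene is URG3 when D(Ti vs Tl) >= 0 for every i in T0 plus the early
#' points and every late l, the sum is nonzero, the late-peak RPKM
#' exceeds the RPKM at every non-late time point, and the floor is
#' passed.
#'
#' @inheritParams classify_urg1
#' @return data.frame of per-gene condition traces and the `urg3` verdict.
#' @export
classify_urg3 <- function(D, rpkm_time, partition, floor_ok = TRUE) {
  pre <- c(partition$t0, partition$early); l <- partition$late
  il_pairs <- unlist(lapply(pre, function(ti) lapply(l, function(li) c(ti, li))),
                     recursive = FALSE)
  dil <- d_cols(D, il_pairs)
  up_late <- rowSums(dil >= 0) == ncol(dil)
  nonzero_sum <- rowSums(dil) != 0
  rl <- rpkm_time[, as.character(l), drop = FALSE]
  rother <- rpkm_time[, as.character(pre), drop = FALSE]
  rmax <- apply(rl, 1, max) > apply(rother, 1, max)
  data.frame(up_late = up_late, nonzero_sum = nonzero_sum, rpkm_max = rmax,
             floor_ok = floor_ok,
             urg3 = up_late & nonzero_sum & rmax & floor_ok)
}

#' Assign genes to URG stage groups
#'
#' Evaluates the three URG classifiers for every gene and returns the
#' label plus the full condition trace. The RPKM floor (default: RPKM > 4
#' at all time points) gates all three groups. The strict RPKM-maximum
#' side conditions make the three groups mutually exclusive by
#' construction; a double assignment is a hard error.
#'
#' @param contrasts a `contrast_set`.
#' @param profile an `expression_profile` from [rpkm()].
#' @param partition a [stage_partition()].
#' @param floor RPKM floor (default 4).
#' @param floor_rule `"all_timepoints"` (literal rule: every time point
#'   must exceed the floor) or `"any_timepoint"`.
#' @param rpkm_rule URG2 RPKM side-condition mode, see [classify_urg2()].
#' @param masking D-matrix masking, see [d_matrix()].
#' @return List of class `urg_assignment`: `labels` (named character:
#'   URG1/URG2/URG3/none), `trace` (per-gene condition data.frame),
#'   `counts` (table of label sizes), `n_deg` (genes significant in at
#'   least one contrast).
#' @export
assign_urg <- function(contrasts, profile, partition, floor = 4,
                       floor_rule = c("all_timepoints", "any_timepoint"),
                       rpkm_rule = "any_early_max",
                       masking = "significant_only") {
  floor_rule <- match.arg(floor_rule)
  D <- d_matrix(contrasts, masking)
  rt <- profile$rpkm_time[, as.character(partition$grid), drop = FALSE]
  floor_ok <- if (floor_rule == "all_timepoints") rowSums(rt > floor) == ncol(rt)
              else rowSums(rt > floor) > 0
  t1 <- classify_urg1(D, rt, partition, floor_ok)
  t2 <- classify_urg2(D, rt, partition, floor_ok, rpkm_rule)
  t3 <- classify_urg3(D, rt, partition, floor_ok)
  hits <- cbind(URG1 = t1$urg1, URG2 = t2$urg2, URG3 = t3$urg3)
  if (any(rowSums(hits) > 1)) {
    g <- rownames(rt)[which(rowSums(hits) > 1)[1]]
    stopf("gene '%s' satisfies more than one URG group; the strict RPKM maxima should forbid this", g)
  }
  labels <- rep("none", nrow(rt))
  for (k in colnames(hits)) labels[hits[, k]] <- k
  names(labels) <- rownames(rt)
  trace <- data.frame(gene = rownames(rt),
                      setNames(t1[1:3], paste0("urg1_", names(t1)[1:3])),
                      setNames(t2[1:4], paste0("urg2_", names(t2)[1:4])),
                      setNames(t3[1:3], paste0("urg3_", names(t3)[1:3])),
                      floor_ok = floor_ok, label = labels)
  n_deg <- sum(apply(contrasts$sig, 1, any))
  structure(list(labels = labels, trace = trace,
                 counts = table(factor(labels, c("URG1", "URG2", "URG3", "none"))),
                 n_deg = n_deg),
            class = "urg_assignment")
}

#' @export
print.urg_assignment <- function(x, ...) {
  cat("URG assignment:\n")
  print(x$counts)
  cat(sprintf("DEGs (significant in >= 1 contrast): %d\n", x$n_deg))
  invisible(x)
}
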