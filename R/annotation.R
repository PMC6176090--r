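#' KO assignment by cumulative bit-score
#'
#' Per query: hits are filtered by e-value, their bit-scores summed per
#' KO (a hit contributes to every KO its subject carries), and the KO
#' with the maximal cumulative bit-score is retained together with every
#' KO whose cumulative score reaches the retention fraction (default 90%)
#' of the best. Queries with no passing mapped hits receive no
#' assignment and are counted.
#'
#' @param hits hit table data.frame (query, subject, pident, length,
#'   evalue, bitscore), as from [read_hits()].
#' @param ko_map data.frame (subject, ko).
#' @param e_max e-value cutoff (default 1e-5).
#' @param retention fraction of the best cumulative score a KO must reach
#'   to be retained (default 0.9).
#' @return List of class `ko_assignment`: `assignments` (data.frame:
#'   query, ko, cum_score, best), `n_unassigned` (queries with hits but
#'   none passing/mapped), `n_unmapped_subjects`, parameters.
#' @export
assign_ko <- function(hits, ko_map, e_max = 1e-5, retention = 0.9) {
  if (retention < 0 || retention > 1) stopf("retention must lie in [0,1]")
  queries <- unique(hits$query)
  pass <- hits[hits$evalue <= e_max, , drop = FALSE]
  n_unmapped <- length(setdiff(pass$subject, ko_map$subject))
  m <- merge(pass, ko_map, by = "subject")
  if (nrow(m) == 0) {
    return(structure(list(
      assignments = data.frame(query = character(), ko = character(),
                               cum_score = numeric(), best = logical()),
      n_unassigned = length(queries), n_unmapped_subjects = n_unmapped,
      e_max = e_max, retention = retention), class = "ko_assignment"))
  }
  agg <- aggregate(bitscore ~ query + ko, data = m, FUN = sum)
  names(agg)[names(agg) == "bitscore"] <- "cum_score"
  out <- do.call(rbind, lapply(split(agg, agg$query), function(d) {
    best <- max(d$cum_score)
    d <- d[d$cum_score >= retention * best, , drop = FALSE]
    d$best <- d$cum_score == best
    d[order(-d$cum_score, d$ko), ]
  }))
  rownames(out) <- NULL
  structure(list(assignments = out,
                 n_unassigned = length(setdiff(queries, out$query)),
                 n_unmapped_subjects = n_unmapped,
                 e_max = e_max, retention = retention),
            class = "ko_assignment")
}

#' @export
print.ko_assignment <- function(x, ...) {
  cat(sprintf("ko_assignment: %d (query, KO) pairs over %d queries; %d queries unassigned\n",
              nrow(x$assignments), length(unique(x$assignments$query)),
              x$n_unassigned))
  invisible(x)
}

#' BRITE category roll-up of URG expression
#'
#' Sums, for each URG group and BRITE level-B category, the RPKM of the
#' member genes assigned to that category. Each gene contributes the
#' RPKM of its group's characteristic stage (URG1: dinospore/T0; URG2:
#' maximum over early points; URG3: maximum over late points), or, with
#' `rpkm_agg = "timecourse_sum"`, its RPKM summed over the whole time
#' course. A gene mapping to several categories contributes its full
#' RPKM to each (no splitting); KOs without a BRITE path roll up as
#' "unclassified".
#'
#' @param assignment a `ko_assignment` whose queries are gene ids.
#' @param brite_map data.frame (ko, levelA, levelB).
#' @param urg a `urg_assignment`.
#' @param profile an `expression_profile`.
#' @param partition a [stage_partition()].
#' @param rpkm_agg `"stage_peak"` (default) or `"timecourse_sum"`.
#' @return data.frame (urg, levelA, levelB, signal, n_genes) of summed
#'   RPKM per category and group.
#' @export
brite_rollup <- function(assignment, brite_map, urg, profile, partition,
                         rpkm_agg = c("stage_peak", "timecourse_sum")) {
  rpkm_agg <- match.arg(rpkm_agg)
  rt <- profile$rpkm_time
  stage_rpkm <- function(gene, group) {
    if (rpkm_agg == "timecourse_sum") return(sum(rt[gene, ]))
    cols <- switch(group,
                   URG1 = as.character(partition$t0),
                   URG2 = as.character(partition$early),
                   URG3 = as.character(partition$late))
    max(rt[gene, cols])
  }
  asg <- assignment$assignments
  rows <- list()
  for (group in c("URG1", "URG2", "URG3")) {
    members <- names(urg$labels)[urg$labels == group]
    sub <- asg[asg$query %in% members, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub <- merge(sub, brite_map, by = "ko", all.x = TRUE)
    sub$levelA[is.na(sub$levelA)] <- "unclassified"
    sub$levelB[is.na(sub$levelB)] <- "unclassified"
    # one contribution per gene per distinct category
    sub <- unique(sub[, c("query", "levelA", "levelB")])
    sub$signal <- vapply(sub$query, stage_rpkm, 0, group = group)
    agg <- aggregate(signal ~ levelA + levelB, data = sub, FUN = sum)
    ngene <- aggregate(query ~ levelA + levelB, data = sub,
                       FUN = function(q) length(unique(q)))
    agg$n_genes <- ngene$query[match(paste(agg$levelA, agg$levelB),
                                     paste(ngene$levelA, ngene$levelB))]
    agg$urg <- group
    rows[[group]] <- agg[, c("urg", "levelA", "levelB", "signal", "n_genes")]
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(urg = character(), levelA = character(),
                         levelB = character(), signal = numeric(),
                         n_genes = integer())
  rownames(out) <- NULL
  out
}
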