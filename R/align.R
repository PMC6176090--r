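#' BLOSUM62 scoring matrix
#'
#' The BLOSUM62 substitution matrix (from Biostrings' distributed data),
#' restricted to the 20 standard residues plus X.
#' @return Integer matrix with amino-acid row/column names.
#' @export
blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  keep <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], "X")
  storage.mode(m) <- "integer"
  m[keep, keep]
}

aa_index <- function(seq, alphabet) {
  if (nchar(seq) == 0) return(integer(0))
  idx <- match(strsplit(seq, "")[[1]], alphabet)
  if (any(is.na(idx)))
    stopf("sequence contains letters outside the scoring alphabet")
  idx - 1L
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment score under BLOSUM62 with affine gap
#' penalties: a gap of length L costs `gap_open + (L - 1) * gap_extend`
#' (gapo = 10, gape = 1 by default). The score is never negative; empty
#' sequences score 0.
#'
#' @param a,b amino-acid sequences (20 standard residues; X allowed and
#'   scored via the matrix's X column).
#' @param matrix substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend affine gap parameters (defaults 10 and 1).
#' @param traceback if TRUE, also return the aligned segments.
#' @return List of class `alignment_result`: `score`, and with
#'   `traceback` the aligned subsequences `a_aln`/`b_aln` (gaps as `-`)
#'   and 1-based segment bounds.
#' @export
smith_waterman <- function(a, b, matrix = blosum62(), gap_open = 10,
                           gap_extend = 1, traceback = FALSE) {
  alphabet <- rownames(matrix)
  ia <- aa_index(a, alphabet); ib <- aa_index(b, alphabet)
  if (!traceback) {
    return(structure(list(score = sw_score_c(ia, ib, matrix,
                                             as.integer(gap_open),
                                             as.integer(gap_extend))),
                     class = "alignment_result"))
  }
  res <- sw_align_c(ia, ib, matrix, as.integer(gap_open),
                    as.integer(gap_extend))
  ach <- strsplit(a, "")[[1]]; bch <- strsplit(b, "")[[1]]
  a_aln <- ifelse(is.na(res$a_pos), "-", ach[res$a_pos])
  b_aln <- ifelse(is.na(res$b_pos), "-", bch[res$b_pos])
  structure(list(score = res$score,
                 a_aln = paste(a_aln, collapse = ""),
                 b_aln = paste(b_aln, collapse = ""),
                 a_range = range(res$a_pos, na.rm = TRUE),
                 b_range = range(res$b_pos, na.rm = TRUE)),
            class = "alignment_result")
}

#' All-vs-all Smith-Waterman score matrix
#'
#' @param set_a,set_b named character vectors of peptide sequences.
#' @inheritParams smith_waterman
#' @return Integer matrix of local-alignment scores (rows = `set_a`).
#' @export
sw_score_matrix <- function(set_a, set_b, matrix = blosum62(),
                            gap_open = 10, gap_extend = 1) {
  alphabet <- rownames(matrix)
  ia <- lapply(set_a, aa_index, alphabet = alphabet)
  ib <- lapply(set_b, aa_index, alphabet = alphabet)
  s <- sw_matrix_c(ia, ib, matrix, as.integer(gap_open),
                   as.integer(gap_extend))
  dimnames(s) <- list(names(set_a), names(set_b))
  s
}

#' Reciprocal-best-hit orthology between two peptide sets
#'
#' A pair (a, b) is an ortholog call when b is the unique maximal-scoring
#' partner of a, a is the unique maximal-scoring partner of b, and their
#' Smith-Waterman score exceeds `min_score` (default 300). Ties produce
#' no pair (conservative: a false orthology call is worse than a miss);
#' tied genes are reported.
#'
#' @param set_a,set_b named character vectors of peptide sequences.
#' @param min_score minimum retained score (default 300; strictly
#'   greater-than).
#' @param scores optional precomputed score matrix from
#'   [sw_score_matrix()].
#' @inheritParams smith_waterman
#' @return List of class `ortholog_pairs`: `pairs` (data.frame: gene_a,
#'   gene_b, score), `ties` (genes skipped for tied best scores),
#'   `min_score`.
#' @export
reciprocal_best_hits <- function(set_a, set_b, min_score = 300,
                                 matrix = blosum62(), gap_open = 10,
                                 gap_extend = 1, scores = NULL) {
  if (length(set_a) == 0 || length(set_b) == 0)
    stopf("both peptide sets must be non-empty")
  if (is.null(scores))
    scores <- sw_score_matrix(set_a, set_b, matrix, gap_open, gap_extend)
  ties <- character()
  pairs <- list()
  best_b_of_a <- integer(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    mx <- max(scores[i, ])
    w <- which(scores[i, ] == mx)
    if (length(w) > 1) { ties <- c(ties, rownames(scores)[i]); best_b_of_a[i] <- NA
    } else best_b_of_a[i] <- w
  }
  for (j in seq_len(ncol(scores))) {
    mx <- max(scores[, j])
    w <- which(scores[, j] == mx)
    if (length(w) > 1) { ties <- c(ties, colnames(scores)[j]); next }
    i <- w
    if (!is.na(best_b_of_a[i]) && best_b_of_a[i] == j && scores[i, j] > min_score)
      pairs[[length(pairs) + 1]] <- data.frame(gene_a = rownames(scores)[i],
                                               gene_b = colnames(scores)[j],
                                               score = scores[i, j])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(gene_a = character(), gene_b = character(),
                           score = integer())
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, ties = unique(ties), min_score = min_score),
            class = "ortholog_pairs")
}

#' @export
print.ortholog_pairs <- function(x, ...) {
  cat(sprintf("ortholog_pairs: %d pair(s) above score %g; %d tie(s) skipped\n",
              nrow(x$pairs), x$min_score, length(x$ties)))
  invisible(x)
}
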