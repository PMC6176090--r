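#' Count matrix with sample metadata
#'
#' Container for a genes x samples matrix of non-negative integer read
#' counts together with the sample sheet (time point label in hours and
#' replicate index per sample). Time point labels are stored as integer
#' hours; the first point of the grid (0 h) is the free-living
#' dinospore / host-only reference condition.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `time` (integer
#'   hours), `replicate` (integer index), one row per column of `counts`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` and `samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("count matrix needs unique gene ids as rownames")
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts)))
    stopf("count matrix needs unique sample ids as colnames")
  if (any(is.na(counts)))
    stopf("count matrix contains NA entries")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("negative or non-integer count at gene '%s', sample '%s'",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  storage.mode(counts) <- "integer"
  samples <- as.data.frame(samples)
  need <- c("sample_id", "time", "replicate")
  if (!all(need %in% names(samples)))
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(counts)))
    stopf("sample sheet ids do not match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$time <- normalize_time_labels(samples$time)
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

# "T0"/"dinospore"-style labels are mapped to integer hours; the reserved
# first grid point is 0 h.
normalize_time_labels <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  x <- as.character(x)
  x[tolower(x) %in% c("dinospore", "dino", "t0")] <- "0"
  x <- sub("^[Tt]", "", x)
  out <- suppressWarnings(as.integer(x))
  if (any(is.na(out)))
    stopf("cannot interpret time label(s): %s",
          paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples, %d time points\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$samples$time))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Time grid of a count matrix
#' @param x a `count_matrix`.
#' @return Sorted unique integer time points (hours).
#' @export
time_points <- function(x) sort(unique(x$samples$time))

#' Subset a count matrix to a set of samples
#' @param x a `count_matrix`.
#' @param sample_ids character vector of sample ids to keep.
#' @return A `count_matrix` restricted to those samples, order preserved.
#' @export
subset_samples <- function(x, sample_ids) {
  keep <- colnames(x$counts) %in% sample_ids
  count_matrix(x$counts[, keep, drop = FALSE],
               x$samples[x$samples$sample_id %in% sample_ids, , drop = FALSE])
}
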