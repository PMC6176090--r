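#' @useDynLib urgflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cutree hclust as.dist median p.adjust pnorm pt
#'   quantile rbinom rnbinom rpois runif rlnorm rnorm setNames var sd lm coef
#'   aggregate
#' @importFrom utils read.table write.table combn head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf  <- function(fmt, ...) message(sprintf(fmt, ...))

is_count_scalar <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == round(x) && x >= 1
}

rowVars <- function(x) {
  if (ncol(x) < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (ncol(x) - 1)
}
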