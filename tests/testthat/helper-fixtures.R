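# Shared fixture builders for the test suite. Everything is generated in
# code; nothing binary is read from disk.

# Minimal count matrix from a plain matrix (one time point per column
# group is up to the caller via the sample sheet).
toy_cm <- function(counts, times, reps = NULL) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
  if (is.null(reps)) {
    reps <- integer(ncol(counts))
    for (tp in unique(times)) reps[times == tp] <- seq_len(sum(times == tp))
  }
  count_matrix(counts, data.frame(sample_id = colnames(counts),
                                  time = times, replicate = reps))
}

# Two planted correlation blocks (within-block r ~ 0.9) over a 7-point
# grid, plus the block labels.
make_block_profiles <- function(seed, n_per = 20, tp = 7, noise_var = 0.11) {
  set.seed(seed)
  s1 <- rnorm(tp); s2 <- rnorm(tp)
  x <- rbind(t(replicate(n_per, s1 + rnorm(tp, 0, sqrt(noise_var)))),
             t(replicate(n_per, s2 + rnorm(tp, 0, sqrt(noise_var)))))
  rownames(x) <- sprintf("g%02d", seq_len(2 * n_per))
  colnames(x) <- seq(0, by = 6, length.out = tp)
  list(x = x, block = rep(1:2, each = n_per))
}

# Random antisymmetric D tables with exact half-integer values plus RPKM
# tables, shaped like the outputs of build_contrast_set()/rpkm(), for
# oracle-equivalence checks.
make_random_tables <- function(seed, n_genes, grid) {
  set.seed(seed)
  tn <- as.character(grid)
  k <- length(grid)
  lfc <- array(0, dim = c(n_genes, k, k), dimnames = list(NULL, tn, tn))
  sig <- array(FALSE, dim = dim(lfc), dimnames = dimnames(lfc))
  vals <- c(-2, -1.5, -1, -0.5, 0, 0.5, 1, 1.5, 2)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    v <- sample(vals, n_genes, replace = TRUE)
    s <- runif(n_genes) < 0.6
    lfc[, i, j] <- v;  lfc[, j, i] <- -v
    sig[, i, j] <- s;  sig[, j, i] <- s
  }
  rpkm_time <- matrix(round(runif(n_genes * k, 0, 30), 1), n_genes, k,
                      dimnames = list(sprintf("g%04d", seq_len(n_genes)), tn))
  dimnames(lfc)[[1]] <- dimnames(sig)[[1]] <- rownames(rpkm_time)
  contrasts <- structure(list(lfc = lfc, p = NULL, padj = NULL, sig = sig,
                              time_points = grid, alpha = 1e-5,
                              min_fold = 2), class = "contrast_set")
  list(contrasts = contrasts, rpkm_time = rpkm_time)
}

# Literal brute-force evaluator of the three URG formulas: per-gene loops
# over every conjunct, written independently of the vectorized classifiers.
brute_force_urg <- function(D, rpkm_time, t0, early, late, floor = 4) {
  grid <- c(t0, early, late)
  n <- dim(D)[1]
  out <- character(n)
  for (g in seq_len(n)) {
    r <- rpkm_time[g, as.character(grid)]
    names(r) <- as.character(grid)
    floor_ok <- all(r > floor)
    d <- function(a, b) D[g, as.character(a), as.character(b)]

    # URG1: every D(T0 vs Ti) <= 0, sum != 0, T0 RPKM strictly maximal
    ok1 <- floor_ok
    s <- 0
    for (ti in c(early, late)) {
      if (!(d(t0, ti) <= 0)) ok1 <- FALSE
      s <- s + d(t0, ti)
    }
    if (s == 0) ok1 <- FALSE
    for (ti in c(early, late)) if (!(r[as.character(t0)] > r[as.character(ti)])) ok1 <- FALSE

    # URG2: D(T0 vs Te) >= 0, D(Te vs Tl) <= 0, total sum != 0,
    # early max strictly above every non-early point
    ok2 <- floor_ok
    s <- 0
    for (e in early) {
      if (!(d(t0, e) >= 0)) ok2 <- FALSE
      s <- s + d(t0, e)
      for (l in late) {
        if (!(d(e, l) <= 0)) ok2 <- FALSE
        s <- s + d(e, l)
      }
    }
    if (s == 0) ok2 <- FALSE
    if (!(max(r[as.character(early)]) > max(r[as.character(c(t0, late))]))) ok2 <- FALSE

    # URG3: D(Ti vs Tl) >= 0 for i in {T0, early}, sum != 0,
    # late max strictly above every non-late point
    ok3 <- floor_ok
    s <- 0
    for (ti in c(t0, early)) for (l in late) {
      if (!(d(ti, l) >= 0)) ok3 <- FALSE
      s <- s + d(ti, l)
    }
    if (s == 0) ok3 <- FALSE
    if (!(max(r[as.character(late)]) > max(r[as.character(c(t0, early))]))) ok3 <- FALSE

    out[g] <- if (ok1) "URG1" else if (ok2) "URG2" else if (ok3) "URG3" else "none"
  }
  setNames(out, rownames(rpkm_time))
}

# Brute-force affine-gap local alignment by exhaustive recursion: an
# alignment starts and ends on an aligned residue pair; between matches
# any combination of gap runs in either sequence is allowed, each run
# costing gap_open + (len - 1) * gap_extend. Exponential; tiny inputs only.
brute_force_sw <- function(a, b, S, gap_open = 10, gap_extend = 1) {
  ach <- strsplit(a, "")[[1]]; bch <- strsplit(b, "")[[1]]
  n <- length(ach); m <- length(bch)
  if (n == 0 || m == 0) return(0)
  gap_cost <- function(L) if (L == 0) 0 else gap_open + (L - 1) * gap_extend
  g <- function(i, j) {
    sc <- S[ach[i], bch[j]]
    best_cont <- 0
    for (da in 0:(n - i)) for (db in 0:(m - j)) {
      ni <- i + 1 + da; nj <- j + 1 + db
      if (ni > n || nj > m) next
      best_cont <- max(best_cont,
                       -gap_cost(da) - gap_cost(db) + g(ni, nj))
    }
    sc + best_cont
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, g(i, j))
  best
}

# All sequences over an alphabet up to a length.
all_seqs <- function(alphabet, max_len) {
  out <- character()
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(alphabet), L))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# Random peptide string.
random_pep <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Write a small SAM fixture; records is a character vector of alignment
# lines (tab-separated), header added here.
write_sam_fixture <- function(records, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:gene1\tLN:2000",
               "@SQ\tSN:gene2\tLN:5000",
               records), path)
  path
}

sam_line <- function(qname, flag, rname, cigar, nm = NULL, seq_len = NULL) {
  if (is.null(seq_len)) seq_len <- 101
  fields <- c(qname, flag, rname, "1", "60", cigar, "*", "0", "0",
              paste(rep("A", seq_len), collapse = ""),
              paste(rep("I", seq_len), collapse = ""))
  if (!is.null(nm)) fields <- c(fields, sprintf("NM:i:%d", nm))
  paste(fields, collapse = "\t")
}
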