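#' Read mapped alignment records from a SAM text file
#'
#' Parses the plain-text SAM fields needed by the identity/coverage filter:
#' read id, FLAG, reference id, CIGAR and the NM (edit distance) tag.
#' Unmapped records (FLAG bit 0x4) are skipped and counted; records
#' without an NM tag are yielded with `nm = NA` and tallied separately so
#' the filter can route them to a "no-identity-info" bin rather than
#' dropping them silently.
#'
#' @param path SAM file path (text, with `@` header lines).
#' @return data.frame (qname, flag, rname, cigar, nm) of mapped records,
#'   with attributes `n_unmapped` and `n_missing_nm`.
#' @export
read_sam_records <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@") & nzchar(ln)]
  n_unmapped <- 0L
  n_missing_nm <- 0L
  rows <- vector("list", length(ln))
  for (i in seq_along(ln)) {
    f <- strsplit(ln[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stopf("malformed SAM line %d: fewer than 11 fields", i)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) { n_unmapped <- n_unmapped + 1L; next }
    nm <- NA_integer_
    if (length(f) > 11) {
      tag <- grep("^NM:i:", f[12:length(f)], value = TRUE)
      if (length(tag) > 0) nm <- as.integer(sub("^NM:i:", "", tag[1]))
    }
    if (is.na(nm)) n_missing_nm <- n_missing_nm + 1L
    rows[[i]] <- data.frame(qname = f[1], flag = flag, rname = f[3],
                            cigar = f[6], nm = nm)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(qname = character(), flag = integer(),
                      rname = character(), cigar = character(),
                      nm = integer())
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  attr(out, "n_missing_nm") <- n_missing_nm
  out
}

# Sum of CIGAR operation lengths for the given operation characters.
cigar_sum <- function(cigar, ops) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) return(0L)
  parts <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  op <- substring(parts, nchar(parts), nchar(parts))
  len <- as.integer(substring(parts, 1, nchar(parts) - 1))
  sum(len[op %in% ops])
}
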