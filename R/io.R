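#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: header row of sample ids, first column gene ids. MTX layout:
#' a MatrixMarket file plus `<path>.genes` / `<path>.samples` sidecars with
#' one id per line. Entries must be non-negative integers; violations are
#' hard errors naming the offending cell.
#'
#' @param path file path.
#' @param samples sample sheet data.frame (`sample_id`, `time`,
#'   `replicate`) or path to a sample-sheet TSV.
#' @param format `"tsv"` or `"mtx"`.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, samples, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character")
    if (ncol(df) < 2) stopf("count TSV needs a gene-id column plus samples")
    gene_ids <- df[[1]]
    if (anyDuplicated(gene_ids))
      stopf("duplicate gene id '%s'", gene_ids[duplicated(gene_ids)][1])
    m <- as.matrix(df[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
    bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stopf("invalid count at gene '%s', sample '%s': '%s'",
            gene_ids[bad[1, 1]], colnames(m)[bad[1, 2]],
            m[bad[1, 1], bad[1, 2]])
    dimnames(num) <- list(gene_ids, colnames(m))
    count_matrix(num, samples)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(paste0(path, ".genes"))
    sample_ids <- readLines(paste0(path, ".samples"))
    dimnames(m) <- list(gene_ids, sample_ids)
    count_matrix(m, samples)
  }
}

#' Write a count matrix
#' @param cm a [count_matrix].
#' @param path output path.
#' @param format `"tsv"` or `"mtx"` (the latter writes `.genes`/`.samples`
#'   sidecars next to the MatrixMarket file).
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(rownames(cm$counts), paste0(path, ".genes"))
    writeLines(colnames(cm$counts), paste0(path, ".samples"))
  }
  invisible(path)
}

#' Read / write a sample sheet (sample_id, time, replicate)
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "replicate")
  if (!all(need %in% names(df)))
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @param samples sample sheet data.frame.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene length table
#'
#' Two-column TSV (`gene_id`, `length_bp`) with positive integer lengths.
#' @param path TSV path.
#' @return Named integer vector of lengths (bp).
#' @export
read_gene_lengths <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(df)))
    stopf("gene length table needs columns gene_id, length_bp")
  if (any(df$length_bp < 1 | df$length_bp != round(df$length_bp)))
    stopf("gene lengths must be positive integers (gene '%s')",
          df$gene_id[which(df$length_bp < 1)[1]])
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene id in length table")
  setNames(as.integer(df$length_bp), df$gene_id)
}

#' Extract gene lengths from a GFF3 file
#'
#' Minimal extractor: takes lines of the requested feature type and
#' returns end - start + 1 per ID attribute.
#' @param path GFF3 path.
#' @param feature feature type to use (default `"gene"`).
#' @return Named integer vector of lengths (bp).
#' @export
gene_lengths_from_gff3 <- function(path, feature = "gene") {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  f <- f[vapply(f, length, 0L) == 9]
  f <- f[vapply(f, `[`, "", 3) == feature]
  if (length(f) == 0) stopf("no '%s' features found in %s", feature, path)
  ids <- vapply(f, function(x) {
    m <- regmatches(x[9], regexec("ID=([^;]+)", x[9]))[[1]]
    if (length(m) < 2) stopf("GFF3 %s line without ID attribute", feature)
    m[2]
  }, "")
  lens <- vapply(f, function(x) as.integer(x[5]) - as.integer(x[4]) + 1L, 0L)
  setNames(lens, ids)
}

#' Read a homology hit table (BLAST outfmt 6)
#'
#' Accepts the standard 12-column tabular layout or a 6-column subset;
#' retains query, subject, percent identity, alignment length, e-value and
#' bit-score.
#' @param path tabular file path.
#' @return data.frame: query, subject, pident, length, evalue, bitscore.
#' @export
read_hits <- function(path) {
  df <- tryCatch(read.table(path, sep = "\t", stringsAsFactors = FALSE),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) {
    warnf("empty hit table: %s", path)
    return(data.frame(query = character(), subject = character(),
                      pident = numeric(), length = integer(),
                      evalue = numeric(), bitscore = numeric()))
  }
  if (ncol(df) == 12) df <- df[, c(1, 2, 3, 4, 11, 12)]
  if (ncol(df) != 6) stopf("hit table must have 6 or 12 tab-separated columns")
  names(df) <- c("query", "subject", "pident", "length", "evalue", "bitscore")
  if (any(df$evalue < 0)) stopf("negative e-value in hit table")
  if (any(!is.finite(df$bitscore))) stopf("non-finite bit-score in hit table")
  df
}

#' Read a subject-to-KO map
#'
#' Two-column TSV (subject, ko). Duplicate rows are merged with a message.
#' @param path TSV path.
#' @return data.frame: subject, ko.
#' @export
read_ko_map <- function(path) {
  df <- tryCatch(read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("subject", "ko")),
                 error = function(e) NULL)
  if (is.null(df)) {
    warnf("empty KO map: %s", path)
    return(data.frame(subject = character(), ko = character()))
  }
  if (any(!nzchar(df$ko))) stopf("empty KO term string in map")
  ndup <- sum(duplicated(df))
  if (ndup > 0) {
    msgf("KO map: merged %d duplicate row(s)", ndup)
    df <- unique(df)
  }
  rownames(df) <- NULL
  df
}

#' Read a flattened BRITE map
#'
#' Three-column TSV (ko, level A label, level B label). KO terms that are
#' never referenced by a KO map are allowed; a KO referenced downstream
#' but missing here rolls up as "unclassified".
#' @param path TSV path.
#' @param ko_map optional KO map; unknown KOs trigger a warning.
#' @return data.frame: ko, levelA, levelB.
#' @export
read_brite_map <- function(path, ko_map = NULL) {
  df <- tryCatch(read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("ko", "levelA", "levelB")),
                 error = function(e) NULL)
  if (is.null(df)) {
    warnf("empty BRITE map: %s", path)
    return(data.frame(ko = character(), levelA = character(),
                      levelB = character()))
  }
  if (any(!nzchar(df$levelA) | !nzchar(df$levelB)))
    stopf("empty BRITE category path")
  if (!is.null(ko_map)) {
    unknown <- setdiff(df$ko, ko_map$ko)
    if (length(unknown) > 0)
      warnf("BRITE map references %d KO(s) absent from the KO map",
            length(unknown))
  }
  ndup <- sum(duplicated(df))
  if (ndup > 0) df <- unique(df)
  rownames(df) <- NULL
  df
}

#' Write peptide sequences as FASTA
#' @param seqs named character vector of amino-acid sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read peptide sequences from FASTA
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
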