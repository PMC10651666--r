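#' Read a count matrix from TSV or MatrixMarket files
#'
#' TSV layout: first column gene IDs (header `gene`), remaining columns one
#' sample each. MatrixMarket layout: `<path>.mtx` plus `<path>.rows` (gene
#' IDs) and `<path>.cols` (sample IDs) sidecars; pass the `.mtx` path.
#' Counts must be non-negative integers; violations raise errors naming the
#' offending gene and sample.
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @param meta Sample metadata: a data.frame or the path of a TSV with
#'   columns `sample_id`, `sex`, `age_group`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, meta) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(sub("\\.mtx$", ".rows", path))
    cols <- readLines(sub("\\.mtx$", ".cols", path))
    if (nrow(m) != length(rows) || ncol(m) != length(cols)) {
      stopf("MTX dimensions do not match .rows/.cols sidecars")
    }
    dimnames(m) <- list(rows, cols)
  } else {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stopf("malformed counts TSV: %s", path)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stopf("non-numeric counts in %s", path)
    rownames(m) <- genes
  }
  if (is.character(meta)) {
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  }
  count_matrix(m, meta)
}

#' Write a count matrix (and its metadata) to disk
#'
#' @param cm A [count_matrix()].
#' @param path Output path: `.tsv` for tab-separated, `.mtx` for
#'   MatrixMarket (with `.rows`/`.cols` sidecars).
#' @param meta_path Optional path for the sample-metadata TSV.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, meta_path = NULL) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(cm$counts, sparse = TRUE), path)
    writeLines(rownames(cm$counts), sub("\\.mtx$", ".rows", path))
    writeLines(colnames(cm$counts), sub("\\.mtx$", ".cols", path))
  } else {
    df <- data.frame(gene = rownames(cm$counts), cm$counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(meta_path)) {
    utils::write.table(cm$meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write / read a differential-expression result as TSV
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @return `path` ([write_de()]) or a `de_result` ([read_de()]).
#' @export
write_de <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param sex Sex label to attach on read (written files do not carry it).
#' @rdname write_de
#' @export
read_de <- function(path, sex = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "log2fc", "p_value")
  if (!all(req %in% names(df))) {
    stopf("DE table %s lacks columns %s", path, paste(req, collapse = ", "))
  }
  if (is.null(df$neg_log10_p)) df$neg_log10_p <- -log10(df$p_value)
  attr(df, "sex") <- sex
  class(df) <- c("de_result", "data.frame")
  df
}

#' Read a per-probe statistics table (gene, probe, log2fc, p_value) from TSV
#'
#' @param path TSV path.
#' @return data.frame of class `probe_stats`.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "probe", "log2fc", "p_value")
  if (!all(req %in% names(df))) {
    stopf("probe table %s lacks columns %s", path, paste(req, collapse = ", "))
  }
  if (any(df$p_value <= 0 | df$p_value > 1)) {
    stopf("probe table %s: p-values must lie in (0, 1]", path)
  }
  class(df) <- c("probe_stats", "data.frame")
  df
}

#' Read a plain-text gene list (one symbol per line)
#'
#' Blank lines and lines starting with `#` are ignored; entries are
#' whitespace-trimmed.
#'
#' @param path Text file path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (length(x) == 0) stopf("gene list %s is empty", path)
  x
}
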