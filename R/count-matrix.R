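#' Construct a gene-by-sample count matrix with sample metadata
#'
#' The container used throughout the package: a non-negative integer matrix
#' of read counts per gene (rows) and sample (columns), together with a
#' metadata table assigning each sample a sex (`male`/`female`) and an age
#' group (`young`/`old`).
#'
#' @param counts Integer matrix, genes in rows (unique rownames), samples in
#'   columns (colnames matching `meta$sample_id`).
#' @param meta `data.frame` with columns `sample_id`, `sex`, `age_group`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `meta`.
#' @examples
#' cm <- count_matrix(
#'   matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   data.frame(sample_id = c("s1", "s2"),
#'              sex = "male", age_group = c("young", "old"))
#' )
#' @export
count_matrix <- function(counts, meta) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("'counts' must be a numeric matrix")
  }
  if (is.null(rownames(counts))) stopf("'counts' must have gene rownames")
  if (anyDuplicated(rownames(counts))) {
    stopf("duplicate gene identifiers: %s",
          paste(unique(rownames(counts)[duplicated(rownames(counts))])[1:3],
                collapse = ", "))
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)[1, ]
    stopf("negative or non-finite count at gene '%s', sample '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stopf("non-integer count at gene '%s', sample '%s'",
          rownames(counts)[bad[1]], colnames(counts)[bad[2]])
  }
  req <- c("sample_id", "sex", "age_group")
  if (!is.data.frame(meta) || !all(req %in% names(meta))) {
    stopf("'meta' must be a data.frame with columns %s",
          paste(req, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$sex <- as.character(meta$sex)
  meta$age_group <- as.character(meta$age_group)
  if (is.null(colnames(counts))) colnames(counts) <- meta$sample_id
  if (!identical(sort(colnames(counts)), sort(meta$sample_id))) {
    stopf("sample names of 'counts' do not match meta$sample_id")
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!all(meta$sex %in% c("male", "female"))) {
    stopf("meta$sex must be 'male' or 'female'")
  }
  if (!all(meta$age_group %in% c("young", "old"))) {
    stopf("meta$age_group must be 'young' or 'old'")
  }
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$meta$sex, x$meta$age_group)
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(tab)
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# Subset samples by metadata predicate; keeps genes.
subset_samples <- function(cm, keep) {
  count_matrix(cm$counts[, keep, drop = FALSE],
               cm$meta[keep, , drop = FALSE])
}
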