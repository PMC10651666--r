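#' Per-sex old-vs-young differential expression
#'
#' For the samples of one sex, computes for every gene the old-vs-young
#' log2 fold change on median-of-ratios-normalized counts and a two-sided
#' p-value from a negative-binomial Wald statistic. The per-gene NB
#' dispersion is estimated by method of moments, pooled across the two age
#' groups: `phi = max(sum_g (n_g-1)(s2_g - m_g) / sum_g (n_g-1) m_g^2, 1e-8)`,
#' giving group-mean variance `(m + phi m^2) / n`. The Wald statistic is
#' referred to a t distribution with `n_young + n_old - 2` degrees of freedom
#' as a finite-sample calibration. Genes with all-zero counts get
#' `log2fc = 0, p = 1`.
#'
#' @param counts A [count_matrix()] covering both sexes (size factors are
#'   computed on the full matrix) or only the requested sex.
#' @param sex `"male"` or `"female"`.
#' @param pseudo_count Added to both normalized group means before the log2
#'   ratio (default 0.5).
#' @return A data.frame of class `de_result` with columns `gene`, `log2fc`,
#'   `p_value`, `neg_log10_p`, `base_mean`, `p_adj` (Benjamini-Hochberg,
#'   reported but not used for DEG calls) and attribute `sex`.
#' @seealso [summarize_de()], [partition_degs()]
#' @export
de_test <- function(counts, sex = c("male", "female"), pseudo_count = 0.5) {
  sex <- match.arg(sex)
  if (!inherits(counts, "count_matrix")) stopf("'counts' must be a count_matrix")
  if (!sex %in% counts$meta$sex) stopf("sex '%s' not present in metadata", sex)
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  keep <- counts$meta$sex == sex
  norm <- norm[, keep, drop = FALSE]
  age <- counts$meta$age_group[keep]
  n_y <- sum(age == "young"); n_o <- sum(age == "old")
  if (n_y < 2 || n_o < 2) {
    stopf("need at least 2 young and 2 old samples of sex '%s' (have %d/%d)",
          sex, n_y, n_o)
  }
  y <- norm[, age == "young", drop = FALSE]
  o <- norm[, age == "old", drop = FALSE]
  m_y <- rowMeans(y); m_o <- rowMeans(o)
  v_y <- row_vars(y); v_o <- row_vars(o)

  num <- (n_y - 1) * (v_y - m_y) + (n_o - 1) * (v_o - m_o)
  den <- (n_y - 1) * m_y^2 + (n_o - 1) * m_o^2
  phi <- ifelse(den > 0, pmax(num / den, 1e-8), 1e-8)

  c0 <- pseudo_count
  lfc <- log2((m_o + c0) / (m_y + c0))
  var_my <- (m_y + phi * m_y^2) / n_y
  var_mo <- (m_o + phi * m_o^2) / n_o
  se <- sqrt(var_mo / (m_o + c0)^2 + var_my / (m_y + c0)^2) / log(2)
  tstat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df = n_y + n_o - 2)
  zero <- m_y == 0 & m_o == 0
  lfc[zero] <- 0; p[zero] <- 1
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  res <- data.frame(
    gene = rownames(counts$counts),
    log2fc = lfc,
    p_value = p,
    neg_log10_p = -log10(p),
    base_mean = (m_y * n_y + m_o * n_o) / (n_y + n_o),
    p_adj = stats::p.adjust(p, "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "sex") <- sex
  class(res) <- c("de_result", "data.frame")
  res
}

#' Count up- and downregulated DEGs
#'
#' A gene is a DEG when its raw p-value is below `alpha`; it is counted as
#' up (down) when its log2FC is positive (negative). Genes with log2FC
#' exactly 0 are counted in neither direction.
#'
#' @param de A `de_result`.
#' @param alpha Significance threshold in (0, 1); default 0.01.
#' @return Named integer vector `c(n_up, n_down)`.
#' @export
summarize_de <- function(de, alpha = 0.01) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("'alpha' must lie in (0, 1)")
  }
  sig <- de$p_value < alpha
  c(n_up = sum(sig & de$log2fc > 0), n_down = sum(sig & de$log2fc < 0))
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result (%s): %d genes; %d up / %d down at p < 0.01\n",
              attr(x, "sex") %||% "?", nrow(x),
              summarize_de(x)[1], summarize_de(x)[2]))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Volcano plot of a differential-expression result
#'
#' @param x A `de_result`.
#' @param alpha DEG threshold drawn as a horizontal line.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.de_result <- function(x, alpha = 0.01, ...) {
  graphics::plot(x$log2fc, x$neg_log10_p, pch = 16, cex = 0.4,
                 col = ifelse(x$p_value < alpha,
                              ifelse(x$log2fc > 0, "firebrick", "navy"),
                              "grey70"),
                 xlab = "log2 fold change (old vs young)",
                 ylab = "-log10 p", ...)
  graphics::abline(h = -log10(alpha), lty = 2)
  invisible(x)
}

#' PCA embedding of samples on the most variable genes
#'
#' Performs principal component analysis of samples on centered
#' `log2(normalized count + 1)` values restricted to the `n_top_genes` most
#' variable genes (default selector), or to the genes with the smallest
#' p-value in any of the supplied DE results (`selector = "significance"`).
#'
#' @param counts A [count_matrix()].
#' @param n_top_genes Number of genes to retain (capped at the gene count).
#' @param selector `"variance"` (default) or `"significance"`.
#' @param de_list List of `de_result` objects, required for the
#'   significance selector.
#' @return List with `coords` (samples x PCs), `explained` (non-increasing
#'   variance fractions summing to at most 1), `genes_used`, and the sample
#'   metadata.
#' @export
pca_embed <- function(counts, n_top_genes = 5000,
                      selector = c("variance", "significance"),
                      de_list = NULL) {
  selector <- match.arg(selector)
  if (!inherits(counts, "count_matrix")) stopf("'counts' must be a count_matrix")
  if (ncol(counts$counts) < 3) stopf("PCA requires at least 3 samples")
  if (n_top_genes > nrow(counts$counts)) {
    stopf("n_top_genes exceeds the number of genes")
  }
  lg <- log2(normalize_counts(counts) + 1)
  if (selector == "variance") {
    score <- row_vars(lg)
  } else {
    if (is.null(de_list)) stopf("selector 'significance' needs 'de_list'")
    pm <- sapply(de_list, function(d) d$p_value[match(rownames(lg), d$gene)])
    score <- -apply(pm, 1, min)
  }
  top <- order(score, decreasing = TRUE)[seq_len(n_top_genes)]
  x <- t(lg[top, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x, explained = expl,
       genes_used = rownames(lg)[top], meta = counts$meta)
}
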