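#' Partition genes into shared and sex-specific DEG sets
#'
#' Given the male and female old-vs-young DE results over the same gene
#' universe, classifies every gene as `shared` (p < alpha in both sexes),
#' `male_specific` (males only), `female_specific` (females only) or
#' `neither`. The four sets are disjoint and cover the universe.
#'
#' @param de_male,de_female `de_result` tables on the same gene universe.
#' @param alpha DEG threshold on the raw p-value (default 0.01).
#' @return An object of class `deg_partition`: list of the four gene-ID
#'   vectors plus `alpha` and a `counts` summary.
#' @export
partition_degs <- function(de_male, de_female, alpha = 0.01) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stopf("'alpha' must lie in (0, 1)")
  }
  gm <- de_male$gene; gf <- de_female$gene
  if (!setequal(gm, gf) || anyDuplicated(gm) || anyDuplicated(gf)) {
    diff <- length(union(setdiff(gm, gf), setdiff(gf, gm)))
    stopf("gene universes differ (symmetric difference: %d genes)", diff)
  }
  f <- de_female[match(gm, gf), ]
  sig_m <- de_male$p_value < alpha
  sig_f <- f$p_value < alpha
  out <- structure(list(
    shared = gm[sig_m & sig_f],
    male_specific = gm[sig_m & !sig_f],
    female_specific = gm[!sig_m & sig_f],
    neither = gm[!sig_m & !sig_f],
    alpha = alpha
  ), class = "deg_partition")
  out$counts <- vapply(out[1:4], length, integer(1))
  out
}

#' @export
print.deg_partition <- function(x, ...) {
  cat(sprintf("deg_partition (alpha = %g):\n", x$alpha))
  print(x$counts)
  invisible(x)
}

#' Cross-sex direction-of-regulation concordance statistics
#'
#' For paired per-gene log2 fold changes (male on x, female on y) computes
#' the percentage regulated in the same direction (both signs equal, zeros
#' excluded from the denominator and reported separately), the Pearson
#' correlation, and the ordinary least-squares regression of female on male
#' log2FC: slope `m`, intercept, and the two-sided p-value of the slope.
#'
#' @param lfc_male,lfc_female Numeric vectors of equal length (n >= 2).
#' @return Object of class `concordance_stats`: `n_pairs`,
#'   `pct_same_direction`, `pct_opposite`, `n_zero_excluded`, `pearson_R`,
#'   `slope_m`, `intercept`, `regression_p`.
#' @examples
#' concordance_stats(c(1, -2, 0.5), c(0.8, -1.5, 0.7))
#' @export
concordance_stats <- function(lfc_male, lfc_female) {
  x <- as.numeric(lfc_male); y <- as.numeric(lfc_female)
  if (length(x) != length(y)) stopf("paired vectors must have equal length")
  if (length(x) < 2) stopf("concordance undefined for fewer than 2 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stopf("non-finite log2FC values")
  }
  if (stats::var(x) == 0) stopf("zero variance in male log2FC; slope undefined")
  nz <- x != 0 & y != 0
  pct_same <- if (any(nz)) 100 * mean(sign(x[nz]) == sign(y[nz])) else NA_real_
  fit <- stats::lm(y ~ x)
  # exact linear pairs (e.g. noiseless truth) trigger a harmless
  # perfect-fit note in summary.lm; the estimates remain valid
  sm <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  structure(list(
    n_pairs = length(x),
    pct_same_direction = pct_same,
    pct_opposite = if (is.na(pct_same)) NA_real_ else 100 - pct_same,
    n_zero_excluded = sum(!nz),
    pearson_R = stats::cor(x, y),
    slope_m = unname(sm["x", "Estimate"]),
    intercept = unname(sm["(Intercept)", "Estimate"]),
    regression_p = unname(sm["x", "Pr(>|t|)"])
  ), class = "concordance_stats")
}

#' @export
print.concordance_stats <- function(x, ...) {
  cat(sprintf(
    "concordance_stats: n = %d | same direction %.1f%% | R = %.3f | m = %.3f (p = %.3g)\n",
    x$n_pairs, x$pct_same_direction, x$pearson_R, x$slope_m, x$regression_p))
  if (x$n_zero_excluded > 0) {
    cat(sprintf("  (%d pairs with a zero log2FC excluded from %%)\n",
                x$n_zero_excluded))
  }
  invisible(x)
}

#' Scatter plot of paired log2FC values with the fitted regression line
#'
#' @param x A `concordance_stats` object carrying `pairs` (attached by
#'   [geneset_concordance()]) or supply `lfc_male`/`lfc_female`.
#' @param lfc_male,lfc_female The paired values to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.concordance_stats <- function(x, lfc_male = NULL, lfc_female = NULL, ...) {
  xm <- lfc_male %||% attr(x, "pairs")$lfc_male
  yf <- lfc_female %||% attr(x, "pairs")$lfc_female
  if (is.null(xm)) stopf("no pairs to plot; pass lfc_male/lfc_female")
  graphics::plot(xm, yf, pch = 16, cex = 0.5, col = "grey30",
                 xlab = "male log2FC", ylab = "female log2FC", ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::abline(a = x$intercept, b = x$slope_m, col = "firebrick")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("R=%.2f m=%.2f same %.1f%%",
                                    x$pearson_R, x$slope_m,
                                    x$pct_same_direction))
  invisible(x)
}

# Case-insensitive match of a gene list against a gene universe.
match_gene_list <- function(gene_list, universe, list_name = "gene list") {
  idx <- match(toupper(gene_list), toupper(universe))
  unmatched <- gene_list[is.na(idx)]
  if (length(unmatched)) {
    message(sprintf("%s: %d of %d entries not found (e.g. %s)",
                    list_name, length(unmatched), length(gene_list),
                    paste(utils::head(unmatched, 3), collapse = ", ")))
  }
  idx[!is.na(idx)]
}

#' Concordance statistics restricted to a gene list
#'
#' Restricts the paired male/female log2FC values to a user-supplied gene
#' list (matched case-insensitively), optionally to its DEGs, then computes
#' [concordance_stats()].
#'
#' @param de_male,de_female `de_result` tables on the same gene universe.
#' @param gene_list Character vector of gene symbols.
#' @param selection `"all_in_list"` (every matched gene),
#'   `"degs_in_list_either_sex"` (matched genes significant in at least one
#'   sex) or `"degs_in_list_one_sex"` (significant in exactly one sex).
#' @param alpha DEG threshold used by the DEG-restricted selections.
#' @param list_name Label used in messages and errors.
#' @return `concordance_stats` with extra fields `n_listed` and `n_matched`
#'   and the pairs attached as attribute `pairs`.
#' @export
geneset_concordance <- function(de_male, de_female, gene_list,
                                selection = c("all_in_list",
                                              "degs_in_list_either_sex",
                                              "degs_in_list_one_sex"),
                                alpha = 0.01, list_name = "gene list") {
  selection <- match.arg(selection)
  if (length(gene_list) == 0) stopf("empty gene list '%s'", list_name)
  f <- de_female[match(de_male$gene, de_female$gene), ]
  idx <- match_gene_list(gene_list, de_male$gene, list_name)
  if (length(idx) == 0) stopf("no genes of '%s' found in the data", list_name)
  sig_m <- de_male$p_value[idx] < alpha
  sig_f <- f$p_value[idx] < alpha
  keep <- switch(selection,
    all_in_list = rep(TRUE, length(idx)),
    degs_in_list_either_sex = sig_m | sig_f,
    degs_in_list_one_sex = xor(sig_m, sig_f)
  )
  idx <- idx[keep]
  if (length(idx) < 2) {
    stopf("selection '%s' leaves %d genes of '%s'; need at least 2",
          selection, length(idx), list_name)
  }
  st <- concordance_stats(de_male$log2fc[idx], f$log2fc[idx])
  st$n_listed <- length(gene_list)
  st$n_matched <- length(idx)
  attr(st, "pairs") <- data.frame(gene = de_male$gene[idx],
                                  lfc_male = de_male$log2fc[idx],
                                  lfc_female = f$log2fc[idx])
  st
}

#' Genes ranked by average significance across the sexes
#'
#' Restricts to the listed genes and orders them by decreasing mean of the
#' male and female `-log10 p`; ties are broken lexicographically by gene ID.
#'
#' @inheritParams geneset_concordance
#' @return data.frame: gene, neg_log10_p_male, neg_log10_p_female,
#'   avg_neg_log10_p, sorted.
#' @export
ranked_logp_profile <- function(de_male, de_female, gene_list) {
  f <- de_female[match(de_male$gene, de_female$gene), ]
  idx <- match_gene_list(gene_list, de_male$gene)
  if (length(idx) == 0) stopf("no listed genes present in both DE tables")
  out <- data.frame(
    gene = de_male$gene[idx],
    neg_log10_p_male = de_male$neg_log10_p[idx],
    neg_log10_p_female = f$neg_log10_p[idx],
    stringsAsFactors = FALSE
  )
  out$avg_neg_log10_p <- (out$neg_log10_p_male + out$neg_log10_p_female) / 2
  out <- out[order(-out$avg_neg_log10_p, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Percentage of upregulated DEGs within a gene set
#'
#' Among the genes of `gene_set` that are DEGs at `alpha`, the percentage
#' with positive log2FC. Returns `NA` (with a warning) when the set contains
#' no DEGs.
#'
#' @param de A `de_result`.
#' @param gene_set Character vector of gene IDs.
#' @param alpha DEG threshold.
#' @return Percentage in [0, 100], or `NA_real_` if the set has no DEGs.
#' @export
pct_upregulated <- function(de, gene_set, alpha = 0.01) {
  if (length(gene_set) == 0) stopf("empty gene set")
  idx <- match_gene_list(gene_set, de$gene, "gene set")
  deg <- idx[de$p_value[idx] < alpha]
  if (length(deg) == 0) {
    warning("no DEGs in the gene set; percentage undefined", call. = FALSE)
    return(NA_real_)
  }
  100 * sum(de$log2fc[deg] > 0) / length(deg)
}
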