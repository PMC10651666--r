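#' Collapse per-probe statistics to one value per gene
#'
#' Applies the significant-probes-first averaging rule for microarray
#' cohorts: if at least one probe of a gene is significant (p < `alpha`),
#' the gene's `-log10 p` and log2FC are the arithmetic means over the
#' significant probes only (`collapse_mode = "significant_only"`); otherwise
#' the means over all probes (`"all_probes"`). Genes measured by a single
#' probe pass through unchanged (`"single"`).
#'
#' @param table data.frame with columns `gene`, `probe`, `log2fc`,
#'   `p_value` (p in (0, 1]).
#' @param alpha Probe-level significance threshold (default 0.01).
#' @return data.frame of class `gene_stats`: gene, neg_log10_p, log2fc,
#'   n_probes_used, collapse_mode.
#' @examples
#' tab <- data.frame(gene = c("G", "G"), probe = c("a", "b"),
#'                   log2fc = c(1.0, 0.2), p_value = c(0.005, 0.5))
#' collapse_probes(tab)  # uses the significant probe only
#' @export
collapse_probes <- function(table, alpha = 0.01) {
  req <- c("gene", "probe", "log2fc", "p_value")
  if (!is.data.frame(table) || !all(req %in% names(table))) {
    stopf("probe table must have columns %s", paste(req, collapse = ", "))
  }
  if (nrow(table) == 0) stopf("empty probe table")
  if (any(table$p_value <= 0 | table$p_value > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  key <- paste(table$gene, table$probe, sep = "\r")
  if (anyDuplicated(key)) {
    d <- table[duplicated(key), , drop = FALSE][1, ]
    stopf("duplicate (gene, probe) row: %s / %s", d$gene, d$probe)
  }
  nlp <- -log10(table$p_value)
  sig <- table$p_value < alpha
  idx <- split(seq_len(nrow(table)), table$gene)
  rows <- lapply(idx, function(i) {
    if (length(i) == 1L) {
      return(data.frame(gene = table$gene[i], neg_log10_p = nlp[i],
                        log2fc = table$log2fc[i], n_probes_used = 1L,
                        collapse_mode = "single", stringsAsFactors = FALSE))
    }
    use <- if (any(sig[i])) i[sig[i]] else i
    data.frame(gene = table$gene[i[1]],
               neg_log10_p = mean(nlp[use]),
               log2fc = mean(table$log2fc[use]),
               n_probes_used = length(use),
               collapse_mode = if (any(sig[i])) "significant_only" else "all_probes",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gene_stats", "data.frame")
  out
}

#' Per-probe old-vs-young statistics from a log2 expression matrix
#'
#' Computes, for each probe (row), Welch's two-sided t-test of old versus
#' young samples of one sex and the mean difference of log2 intensities as
#' the log2 fold change.
#'
#' @param expr Numeric probe-by-sample matrix of log2 intensities with probe
#'   rownames.
#' @param meta data.frame with `sample_id`, `sex`, `age_group` matching the
#'   columns of `expr`.
#' @param sex `"male"` or `"female"`.
#' @param gene_map Optional named character vector mapping probe IDs to gene
#'   symbols; unmapped probes keep their probe ID as gene.
#' @return data.frame of class `probe_stats`: gene, probe, log2fc, p_value.
#' @export
probe_de_from_expression <- function(expr, meta, sex = c("male", "female"),
                                     gene_map = NULL) {
  sex <- match.arg(sex)
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stopf("'expr' must be a numeric matrix")
  }
  if (is.null(rownames(expr))) stopf("'expr' must have probe rownames")
  m <- meta[match(colnames(expr), meta$sample_id), ]
  keep <- m$sex == sex
  age <- m$age_group[keep]
  x <- expr[, keep, drop = FALSE]
  n_y <- sum(age == "young"); n_o <- sum(age == "old")
  if (n_y < 2 || n_o < 2) stopf("need >= 2 samples per age group for '%s'", sex)
  y <- x[, age == "young", drop = FALSE]
  o <- x[, age == "old", drop = FALSE]
  m_y <- rowMeans(y); m_o <- rowMeans(o)
  v_y <- row_vars(y); v_o <- row_vars(o)
  se2 <- v_y / n_y + v_o / n_o
  tstat <- ifelse(se2 > 0, (m_o - m_y) / sqrt(se2), 0)
  df <- se2^2 / ((v_y / n_y)^2 / (n_y - 1) + (v_o / n_o)^2 / (n_o - 1))
  df[!is.finite(df)] <- n_y + n_o - 2
  p <- 2 * stats::pt(-abs(tstat), df = df)
  probes <- rownames(expr)
  gene <- if (is.null(gene_map)) probes else {
    g <- gene_map[probes]
    ifelse(is.na(g), probes, g)
  }
  out <- data.frame(gene = unname(gene), probe = probes,
                    log2fc = m_o - m_y,
                    p_value = pmin(pmax(p, .Machine$double.xmin), 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("probe_stats", "data.frame")
  out
}

#' Cross-cohort replication report
#'
#' For each external cohort (per-sex gene-level tables on a common gene
#' universe), calls DEGs at `-log10 p > -log10(alpha)`, partitions them into
#' shared and sex-specific sets, computes concordance statistics per set,
#' and the female-excess percentage `100 (n_f - n_m) / n_m`.
#'
#' @param cohorts Named list; each element a list with `male` and `female`
#'   `gene_stats` tables (from [collapse_probes()]).
#' @param alpha DEG threshold (default 0.01).
#' @return Object of class `replication_report`: per cohort the DEG counts,
#'   `female_excess_pct`, the `deg_partition`, and `concordance_stats` for
#'   the shared, male-specific and female-specific sets (NULL when a set has
#'   fewer than 2 genes).
#' @export
cohort_replication <- function(cohorts, alpha = 0.01) {
  if (!is.list(cohorts) || length(cohorts) == 0) stopf("no cohorts given")
  if (is.null(names(cohorts))) names(cohorts) <- paste0("cohort", seq_along(cohorts))
  res <- lapply(names(cohorts), function(nm) {
    co <- cohorts[[nm]]
    if (!all(c("male", "female") %in% names(co))) {
      stopf("cohort '%s' is missing a sex table", nm)
    }
    de_m <- gene_stats_as_de(co$male, "male")
    de_f <- gene_stats_as_de(co$female, "female")
    part <- partition_degs(de_m, de_f, alpha)
    n_m <- sum(de_m$p_value < alpha)
    n_f <- sum(de_f$p_value < alpha)
    conc <- lapply(list(shared = part$shared,
                        male_specific = part$male_specific,
                        female_specific = part$female_specific),
                   function(set) {
      if (length(set) < 2) return(NULL)
      i <- match(set, de_m$gene); j <- match(set, de_f$gene)
      tryCatch(concordance_stats(de_m$log2fc[i], de_f$log2fc[j]),
               error = function(e) NULL)
    })
    list(cohort = nm, n_degs_male = n_m, n_degs_female = n_f,
         female_excess_pct = if (n_m > 0) 100 * (n_f - n_m) / n_m else NA_real_,
         partition = part, concordance = conc)
  })
  names(res) <- names(cohorts)
  structure(res, class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  for (co in x) {
    cat(sprintf("%s: %d male / %d female DEGs (female excess %.1f%%)\n",
                co$cohort, co$n_degs_male, co$n_degs_female,
                co$female_excess_pct))
    for (set in names(co$concordance)) {
      st <- co$concordance[[set]]
      if (!is.null(st)) {
        cat(sprintf("  %s: n=%d, same direction %.1f%%, R=%.2f, m=%.2f\n",
                    set, st$n_pairs, st$pct_same_direction,
                    st$pearson_R, st$slope_m))
      }
    }
  }
  invisible(x)
}

# View a collapsed gene_stats table through the de_result interface.
gene_stats_as_de <- function(gs, sex) {
  res <- data.frame(gene = gs$gene, log2fc = gs$log2fc,
                    p_value = 10^(-gs$neg_log10_p),
                    neg_log10_p = gs$neg_log10_p,
                    base_mean = NA_real_, p_adj = NA_real_,
                    stringsAsFactors = FALSE)
  attr(res, "sex") <- sex
  class(res) <- c("de_result", "data.frame")
  res
}
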