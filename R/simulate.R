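#' Simulation configuration for two-sex, two-age-group count data
#'
#' Defines a synthetic transcriptome with four gene blocks: `shared` genes
#' carry an identical old-vs-young log2 fold change in both sexes;
#' `male_block` genes have the full effect in males and an attenuated effect
#' (factor `attenuation_male_block`) of the same sign in females;
#' `female_block` genes are the mirror image; `null` genes have no effect.
#' Counts are negative-binomial with variance `mu + dispersion * mu^2`.
#'
#' Default group sizes reproduce the study design this generator emulates:
#' 13 young / 28 old males and 13 young / 26 old females. Default
#' attenuations (0.4 male block, 0.52 female block) mirror the cross-sex
#' regression slopes observed for sex-specific genes in that study.
#'
#' @param n_genes_shared,n_genes_male_block,n_genes_female_block,n_genes_null
#'   Block sizes (non-negative integers).
#' @param group_sizes Named list with positive integer entries `male_young`,
#'   `male_old`, `female_young`, `female_old` (each at least 2).
#' @param lfc_magnitude_range Interval of |log2FC| for the dominant sex;
#'   magnitudes are drawn uniformly and given a random sign.
#' @param attenuation_male_block Factor in (0, 1] multiplying the male
#'   log2FC to obtain the female log2FC in the male-stronger block.
#' @param attenuation_female_block Factor in (0, 1] multiplying the female
#'   log2FC to obtain the male log2FC in the female-stronger block.
#' @param baseline_mean_range Interval of expected counts in young samples;
#'   baselines are drawn log-uniformly.
#' @param dispersion Negative-binomial dispersion phi >= 0 in
#'   `var = mu + phi * mu^2`; 0 gives Poisson counts.
#' @param size_factor_range Interval for per-sample library-size factors,
#'   drawn log-uniformly and multiplied into the NB means.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes_shared = 2000,
                       n_genes_male_block = 700,
                       n_genes_female_block = 2600,
                       n_genes_null = 7000,
                       group_sizes = list(male_young = 13, male_old = 28,
                                          female_young = 13, female_old = 26),
                       lfc_magnitude_range = c(0.5, 2),
                       attenuation_male_block = 0.4,
                       attenuation_female_block = 0.52,
                       baseline_mean_range = c(20, 2000),
                       dispersion = 0.05,
                       size_factor_range = c(0.7, 1.4),
                       seed = 1L) {
  cfg <- list(
    n_genes_shared = n_genes_shared,
    n_genes_male_block = n_genes_male_block,
    n_genes_female_block = n_genes_female_block,
    n_genes_null = n_genes_null,
    group_sizes = group_sizes,
    lfc_magnitude_range = as.numeric(lfc_magnitude_range),
    attenuation_male_block = attenuation_male_block,
    attenuation_female_block = attenuation_female_block,
    baseline_mean_range = as.numeric(baseline_mean_range),
    dispersion = dispersion,
    size_factor_range = as.numeric(size_factor_range),
    seed = as.integer(seed)
  )
  blocks <- c("n_genes_shared", "n_genes_male_block",
              "n_genes_female_block", "n_genes_null")
  for (b in blocks) {
    if (!is_count(cfg[[b]])) stopf("'%s' must be a non-negative integer", b)
  }
  if (sum(unlist(cfg[blocks])) < 1) stopf("at least one gene is required")
  grp <- c("male_young", "male_old", "female_young", "female_old")
  if (!all(grp %in% names(cfg$group_sizes))) {
    stopf("'group_sizes' must name %s", paste(grp, collapse = ", "))
  }
  for (g in grp) {
    if (!is_count(cfg$group_sizes[[g]]) || cfg$group_sizes[[g]] < 2) {
      stopf("group size '%s' must be an integer >= 2", g)
    }
  }
  chk_range <- function(r, nm, lo = 0) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] <= lo) {
      stopf("'%s' must be a finite increasing interval above %g", nm, lo)
    }
  }
  chk_range(cfg$lfc_magnitude_range, "lfc_magnitude_range")
  chk_range(cfg$baseline_mean_range, "baseline_mean_range")
  chk_range(cfg$size_factor_range, "size_factor_range")
  for (a in c("attenuation_male_block", "attenuation_female_block")) {
    if (!is.finite(cfg[[a]]) || cfg[[a]] <= 0 || cfg[[a]] > 1) {
      stopf("'%s' must lie in (0, 1]", a)
    }
  }
  if (!is.finite(cfg$dispersion) || cfg$dispersion < 0) {
    stopf("'dispersion' must be >= 0")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  cat(sprintf("  genes: %d shared, %d male-block, %d female-block, %d null\n",
              x$n_genes_shared, x$n_genes_male_block,
              x$n_genes_female_block, x$n_genes_null))
  cat(sprintf("  samples: M %d/%d, F %d/%d (young/old)\n",
              x$group_sizes$male_young, x$group_sizes$male_old,
              x$group_sizes$female_young, x$group_sizes$female_old))
  cat(sprintf("  |log2FC| in [%g, %g]; attenuation a_m=%g, a_f=%g; phi=%g\n",
              x$lfc_magnitude_range[1], x$lfc_magnitude_range[2],
              x$attenuation_male_block, x$attenuation_female_block,
              x$dispersion))
  invisible(x)
}

# Draw per-gene ground truth (block labels, signed log2FCs, baselines).
# Deterministic given config$seed; shared between count and probe simulators.
sim_truth <- function(config) {
  n <- c(shared = config$n_genes_shared,
         male_block = config$n_genes_male_block,
         female_block = config$n_genes_female_block,
         null = config$n_genes_null)
  total <- sum(n)
  block <- rep(names(n), n)
  gene <- sprintf("gene%05d", seq_len(total))
  with_seed(config$seed, {
    mag <- runif(total, config$lfc_magnitude_range[1],
                 config$lfc_magnitude_range[2])
    sgn <- sample(c(-1, 1), total, replace = TRUE)
    dom <- mag * sgn
    lfc_male <- numeric(total)
    lfc_female <- numeric(total)
    i <- block == "shared"
    lfc_male[i] <- dom[i]; lfc_female[i] <- dom[i]
    i <- block == "male_block"
    lfc_male[i] <- dom[i]
    lfc_female[i] <- config$attenuation_male_block * dom[i]
    i <- block == "female_block"
    lfc_female[i] <- dom[i]
    lfc_male[i] <- config$attenuation_female_block * dom[i]
    baseline <- exp(runif(total, log(config$baseline_mean_range[1]),
                          log(config$baseline_mean_range[2])))
    data.frame(gene = gene, block = block, lfc_male = lfc_male,
               lfc_female = lfc_female, baseline = baseline,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a two-sex, two-age-group count matrix with known truth
#'
#' Counts for sample j of sex s are drawn NB with mean
#' `baseline * 2^(lfc_s * I[old]) * size_factor_j` and variance
#' `mu + phi * mu^2` (Poisson when `dispersion = 0`). The returned truth
#' table records each gene's block, signed per-sex log2FC and baseline.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]), `truth`
#'   (data.frame: gene, block, lfc_male, lfc_female, baseline) and
#'   `size_factors` (the true per-sample library factors).
#' @examples
#' sim <- simulate_counts(sim_config(n_genes_shared = 5, n_genes_null = 5,
#'                                   n_genes_male_block = 0,
#'                                   n_genes_female_block = 0, seed = 7))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  truth <- sim_truth(config)
  gs <- config$group_sizes
  meta <- data.frame(
    sample_id = c(sprintf("M_young_%02d", seq_len(gs$male_young)),
                  sprintf("M_old_%02d", seq_len(gs$male_old)),
                  sprintf("F_young_%02d", seq_len(gs$female_young)),
                  sprintf("F_old_%02d", seq_len(gs$female_old))),
    sex = rep(c("male", "male", "female", "female"),
              c(gs$male_young, gs$male_old, gs$female_young, gs$female_old)),
    age_group = rep(c("young", "old", "young", "old"),
                    c(gs$male_young, gs$male_old,
                      gs$female_young, gs$female_old)),
    stringsAsFactors = FALSE
  )
  n_s <- nrow(meta)
  n_g <- nrow(truth)
  lfc <- ifelse(rep(meta$sex, each = n_g) == "male",
                truth$lfc_male, truth$lfc_female)
  old <- rep(meta$age_group == "old", each = n_g)
  counts <- with_seed(config$seed + 1L, {
    sf <- exp(runif(n_s, log(config$size_factor_range[1]),
                    log(config$size_factor_range[2])))
    mu <- truth$baseline * 2^(lfc * old) * rep(sf, each = n_g)
    x <- if (config$dispersion == 0) {
      stats::rpois(n_g * n_s, lambda = mu)
    } else {
      stats::rnbinom(n_g * n_s, mu = mu, size = 1 / config$dispersion)
    }
    attr(x, "sf") <- sf
    x
  })
  sf <- attr(counts, "sf")
  mat <- matrix(as.numeric(counts), nrow = n_g, ncol = n_s,
                dimnames = list(truth$gene, meta$sample_id))
  list(counts = count_matrix(mat, meta), truth = truth, size_factors = sf)
}

#' Simulate a per-probe microarray-style statistics table
#'
#' Emulates an external cohort in which each gene is measured by one or more
#' probes. Each probe's observed log2FC is the gene's true log2FC (for the
#' requested sex) plus Gaussian noise with standard deviation `probe_sd`;
#' its p-value is the two-sided tail of the standardized observation, so
#' probes of null genes have exactly uniform p-values.
#'
#' @param config A [sim_config()]; supplies the gene truth.
#' @param probes_per_gene_range Integer interval within [1, 10]; the number
#'   of probes per gene is drawn uniformly from it.
#' @param sex Which sex's true log2FC the cohort measures.
#' @param probe_sd Standard deviation of per-probe log2FC noise.
#' @param seed Seed for the probe-level randomness (gene truth still derives
#'   from `config$seed`).
#' @return data.frame of class `probe_stats`: gene, probe, log2fc, p_value.
#' @export
simulate_probe_table <- function(config, probes_per_gene_range = c(1, 4),
                                 sex = c("male", "female"),
                                 probe_sd = 0.25, seed = config$seed + 100L) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  sex <- match.arg(sex)
  r <- as.integer(probes_per_gene_range)
  if (length(r) != 2 || r[1] < 1 || r[2] > 10 || r[1] > r[2]) {
    stopf("'probes_per_gene_range' must be an integer interval within [1, 10]")
  }
  truth <- sim_truth(config)
  if (nrow(truth) == 0) stopf("empty gene set")
  true_lfc <- if (sex == "male") truth$lfc_male else truth$lfc_female
  tab <- with_seed(seed, {
    k <- sample(seq(r[1], r[2]), nrow(truth), replace = TRUE)
    gene <- rep(truth$gene, k)
    lfc0 <- rep(true_lfc, k)
    obs <- lfc0 + stats::rnorm(length(gene), sd = probe_sd)
    p <- 2 * stats::pnorm(-abs(obs) / probe_sd)
    probe <- paste0(gene, "_p", unlist(lapply(k, seq_len)))
    data.frame(gene = gene, probe = probe, log2fc = obs,
               p_value = pmax(p, .Machine$double.xmin),
               stringsAsFactors = FALSE)
  })
  class(tab) <- c("probe_stats", "data.frame")
  tab
}
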