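# Small shared fixtures built in code.

# Compact simulation config: same structure, fewer genes and samples.
small_config <- function(seed = 1L, ...) {
  args <- list(
    n_genes_shared = 150, n_genes_male_block = 50,
    n_genes_female_block = 150, n_genes_null = 400,
    group_sizes = list(male_young = 8, male_old = 10,
                       female_young = 8, female_old = 10),
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# Count matrix where only the last row varies; first rows are housekeeping
# genes constant across samples (size factors come out as 1).
toy_counts <- function(test_gene, age_groups, sex = "male") {
  n <- length(test_gene)
  hk <- matrix(rep(c(50, 80, 120, 200, 400, 1000), n), 6, n)
  m <- rbind(hk, test_gene)
  rownames(m) <- paste0("g", 1:7)
  colnames(m) <- paste0("s", seq_len(n))
  count_matrix(m, data.frame(sample_id = colnames(m), sex = sex,
                             age_group = age_groups))
}

# Minimal de_result-shaped table from explicit p-values and log2FCs.
toy_de <- function(gene, p, lfc, sex = "male") {
  res <- data.frame(gene = gene, log2fc = lfc, p_value = p,
                    neg_log10_p = -log10(p),
                    base_mean = rep(100, length(gene)),
                    p_adj = p, stringsAsFactors = FALSE)
  attr(res, "sex") <- sex
  class(res) <- c("de_result", "data.frame")
  res
}

# Brute-force minimal width: minimum over rotations (step degrees) of the
# projected extent; independent of the rotating-calipers implementation.
brute_min_width <- function(pts, step_deg = 0.1) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  w <- vapply(th, function(a) {
    proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
    diff(range(proj))
  }, numeric(1))
  min(w)
}

# Random convex polygon: convex hull of uniform points.
random_convex_polygon <- function(n_pts = 20, scale = 10) {
  pts <- matrix(stats::runif(2 * n_pts, -scale, scale), ncol = 2)
  pts[grDevices::chull(pts), , drop = FALSE]
}
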