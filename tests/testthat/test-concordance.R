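test_that("all-nonsignificant tables leave every gene in 'neither'", {
  g <- paste0("g", 1:8)
  dm <- toy_de(g, p = rep(1, 8), lfc = rnorm(8))
  df_ <- toy_de(g, p = rep(1, 8), lfc = rnorm(8), sex = "female")
  part <- partition_degs(dm, df_)
  expect_length(part$shared, 0)
  expect_length(part$male_specific, 0)
  expect_length(part$female_specific, 0)
  expect_setequal(part$neither, g)
})

test_that("partition matches exhaustive enumeration on a 6-gene toy", {
  g <- paste0("g", 1:6)
  pm <- c(0.001, 0.5, 0.005, 0.9, 0.0099, 0.011)
  pf <- c(0.002, 0.003, 0.8, 0.7, 0.0001, 0.009)
  part <- partition_degs(toy_de(g, pm, rep(1, 6)),
                         toy_de(g, pf, rep(1, 6), sex = "female"), 0.01)
  # brute-force set oracle
  expect_setequal(part$shared, g[pm < 0.01 & pf < 0.01])
  expect_setequal(part$male_specific, g[pm < 0.01 & pf >= 0.01])
  expect_setequal(part$female_specific, g[pm >= 0.01 & pf < 0.01])
  expect_setequal(part$neither, g[pm >= 0.01 & pf >= 0.01])
})

test_that("the four partition sets are disjoint and cover the universe", {
  set.seed(31)
  for (rep in 1:10) {
    g <- paste0("g", 1:50)
    part <- partition_degs(toy_de(g, runif(50), rnorm(50)),
                           toy_de(g, runif(50), rnorm(50), sex = "female"),
                           alpha = runif(1, 0.01, 0.5))
    all4 <- c(part$shared, part$male_specific, part$female_specific,
              part$neither)
    expect_equal(sort(all4), sort(g))  # no duplicates, full coverage
  }
})

test_that("mismatched gene universes are rejected with the difference size", {
  dm <- toy_de(paste0("g", 1:5), rep(0.5, 5), rnorm(5))
  df_ <- toy_de(paste0("g", 3:9), rep(0.5, 7), rnorm(7), sex = "female")
  expect_error(partition_degs(dm, df_), "symmetric difference: 6")
})

test_that("swapping the sexes transposes the partition", {
  set.seed(32)
  g <- paste0("g", 1:40)
  dm <- toy_de(g, runif(40), rnorm(40))
  df_ <- toy_de(g, runif(40), rnorm(40), sex = "female")
  a <- partition_degs(dm, df_, 0.2)
  b <- partition_degs(df_, dm, 0.2)
  expect_setequal(a$male_specific, b$female_specific)
  expect_setequal(a$female_specific, b$male_specific)
  expect_setequal(a$shared, b$shared)
})

test_that("identity and reflection lines give the expected statistics", {
  x <- seq(-2, 2, length.out = 10)
  st <- concordance_stats(x, x)
  expect_equal(st$pct_same_direction, 100)
  expect_equal(st$pearson_R, 1)
  expect_equal(st$slope_m, 1)
  expect_equal(st$intercept, 0)
  st2 <- concordance_stats(x, -x)
  expect_equal(st2$pct_same_direction, 0)
  expect_equal(st2$pct_opposite, 100)
  expect_equal(st2$pearson_R, -1)
  expect_equal(st2$slope_m, -1)
})

test_that("statistics match the closed-form OLS oracle on 5 pairs", {
  x <- c(-1.2, 0.4, 0.9, 1.7, -0.3)
  y <- c(-0.8, 0.9, 0.5, 2.1, 0.2)
  st <- concordance_stats(x, y)
  # textbook formulas
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx; a <- mean(y) - b * mean(x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  resid <- y - a - b * x
  se_b <- sqrt(sum(resid^2) / 3 / sxx)
  p <- 2 * pt(-abs(b / se_b), df = 3)
  expect_equal(st$slope_m, b, tolerance = 1e-10)
  expect_equal(st$intercept, a, tolerance = 1e-10)
  expect_equal(st$pearson_R, r, tolerance = 1e-10)
  expect_equal(st$regression_p, p, tolerance = 1e-10)
  expect_equal(st$pct_same_direction, 100 * 4 / 5)
})

test_that("pairs with a zero log2FC are excluded from the percentage", {
  st <- concordance_stats(c(1, -1, 0, 2), c(2, -3, 5, 0))
  expect_equal(st$n_zero_excluded, 2)
  expect_equal(st$pct_same_direction, 100)
})

test_that("degenerate concordance inputs are rejected", {
  expect_error(concordance_stats(1, 2), "fewer than 2")
  expect_error(concordance_stats(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(concordance_stats(c(1, NA), c(1, 2)), "non-finite")
})

test_that("noiseless truth gives 100% concordance and the exact attenuation slope", {
  tr <- simulate_counts(small_config(seed = 33))$truth
  nz <- tr$lfc_male != 0 & tr$lfc_female != 0
  st <- concordance_stats(tr$lfc_male[nz], tr$lfc_female[nz])
  expect_equal(st$pct_same_direction, 100)
  mb <- tr[tr$block == "male_block", ]
  st_mb <- concordance_stats(mb$lfc_male, mb$lfc_female)
  expect_equal(st_mb$slope_m, 0.4, tolerance = 1e-12)
  expect_equal(st_mb$intercept, 0, tolerance = 1e-12)
})

test_that("swapping regression axes obeys the OLS identity b_yx * b_xy = R^2", {
  set.seed(34)
  x <- rnorm(50); y <- 0.6 * x + rnorm(50, sd = 0.4)
  a <- concordance_stats(x, y)
  b <- concordance_stats(y, x)
  expect_equal(a$slope_m * b$slope_m, a$pearson_R^2, tolerance = 1e-10)
})

test_that("whole-universe gene list reproduces the unrestricted statistics", {
  set.seed(35)
  g <- paste0("g", 1:30)
  dm <- toy_de(g, runif(30), rnorm(30))
  df_ <- toy_de(g, runif(30), rnorm(30), sex = "female")
  st_all <- concordance_stats(dm$log2fc, df_$log2fc)
  st_list <- geneset_concordance(dm, df_, g, selection = "all_in_list")
  expect_equal(st_list$slope_m, st_all$slope_m)
  expect_equal(st_list$pearson_R, st_all$pearson_R)
  expect_equal(st_list$pct_same_direction, st_all$pct_same_direction)
})

test_that("gene-list restriction equals filter-then-compute, case-insensitively", {
  g <- c("Myh7", "Cox4i1", "Akt2", "Ppargc1a", "Igf1")
  dm <- toy_de(g, c(0.001, 0.5, 0.002, 0.9, 0.003), c(1, 0.5, -1, 0.2, 2))
  df_ <- toy_de(g, c(0.002, 0.6, 0.7, 0.8, 0.5), c(0.9, 0.4, -0.5, 0.1, 1.8),
                sex = "female")
  lst <- c("MYH7", "COX4I1", "AKT2")
  st <- geneset_concordance(dm, df_, lst, selection = "all_in_list")
  oracle <- concordance_stats(dm$log2fc[1:3], df_$log2fc[1:3])
  expect_equal(st$slope_m, oracle$slope_m)
  expect_equal(st$n_matched, 3)
  st2 <- geneset_concordance(dm, df_, g, selection = "degs_in_list_one_sex")
  # significant in exactly one sex: Akt2 (male only), Igf1-like pattern
  oracle2 <- concordance_stats(dm$log2fc[c(3, 5)], df_$log2fc[c(3, 5)])
  expect_equal(st2$slope_m, oracle2$slope_m)
  expect_error(geneset_concordance(dm, df_, c("NOPE1", "NOPE2"),
                                   list_name = "mystery"), "mystery")
  expect_message(geneset_concordance(dm, df_, c(lst, "NOPE"),
                                     selection = "all_in_list"), "not found")
})

test_that("ranked -log10 p profile sorts by average and breaks ties by gene", {
  g <- c("d", "a", "c", "b")
  dm <- toy_de(g, c(0.1, 0.001, 0.01, 0.01), rep(1, 4))
  df_ <- toy_de(g, c(0.1, 0.01, 0.1, 0.1), rep(1, 4), sex = "female")
  prof <- ranked_logp_profile(dm, df_, g)
  # averages: d=1, a=2.5, c=1.5, b=1.5 -> a, then b/c tie (lexicographic), d
  expect_equal(prof$gene, c("a", "b", "c", "d"))
  one <- ranked_logp_profile(dm, df_, "a")
  expect_equal(nrow(one), 1)
  dm2 <- toy_de(g, rep(0.05, 4), rep(1, 4))
  df2 <- toy_de(g, rep(0.05, 4), rep(1, 4), sex = "female")
  expect_equal(ranked_logp_profile(dm2, df2, g)$gene, sort(g))
  expect_error(ranked_logp_profile(dm, df_, "zzz"), "no listed genes")
})

test_that("percent upregulated counts DEGs only and flags empty sets", {
  de <- toy_de(paste0("g", 1:5), c(0.001, 0.002, 0.003, 0.004, 0.9),
               c(1, 2, 0.5, -1, -5))
  expect_equal(pct_upregulated(de, paste0("g", 1:5)), 75)
  de_up <- toy_de(c("a", "b"), c(0.001, 0.002), c(1, 2))
  expect_equal(pct_upregulated(de_up, c("a", "b")), 100)
  expect_warning(v <- pct_upregulated(de, "g5"), "no DEGs")
  expect_true(is.na(v))
})

test_that("shared-block DEGs are ~50% upregulated under symmetric signs", {
  vals <- vapply(1:25, function(s) {
    sim <- simulate_counts(sim_config(
      n_genes_shared = 300, n_genes_male_block = 0, n_genes_female_block = 0,
      n_genes_null = 100, seed = 300 + s))
    de <- de_test(sim$counts, "male")
    shared_genes <- sim$truth$gene[sim$truth$block == "shared"]
    pct_upregulated(de, shared_genes)
  }, numeric(1))
  expect_lt(abs(mean(vals) - 50), 5)
})
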