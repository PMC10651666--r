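test_that("minimal Feret diameter is exact on squares and discs", {
  sq <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
  expect_equal(as.numeric(min_feret(sq)), 4)
  # axis-aligned square mask of side s pixels measures s
  m <- matrix(FALSE, 30, 30); m[10:19, 6:15] <- TRUE
  expect_equal(as.numeric(min_feret(m)), 10)
  # disc of radius r: 2r within one pixel of discretization
  r <- 11
  xy <- expand.grid(x = 1:40, y = 1:40)
  d <- matrix((xy$x - 20)^2 + (xy$y - 20)^2 <= r^2, 40, 40)
  expect_lt(abs(as.numeric(min_feret(d)) - 2 * r), 1)
  # physical units scale linearly
  expect_equal(as.numeric(min_feret(sq, pixel_size = 0.5)), 2)
})

test_that("rotating calipers agrees with a 0.1-degree rotation scan", {
  set.seed(51)
  for (k in 1:50) {
    poly <- random_convex_polygon(sample(5:40, 1))
    mf <- as.numeric(min_feret(poly))
    bf <- brute_min_width(poly, step_deg = 0.1)
    expect_lt(abs(mf - bf) / bf, 0.001)
  }
})

test_that("min Feret is rotation invariant and hull invariant", {
  set.seed(52)
  poly <- random_convex_polygon(25)
  base <- as.numeric(min_feret(poly))
  for (deg in c(30, 45, 90)) {
    a <- deg * pi / 180
    rot <- poly %*% rbind(c(cos(a), sin(a)), c(-sin(a), cos(a)))
    expect_equal(as.numeric(min_feret(rot)), base, tolerance = 1e-9)
  }
  # a mask and its convex hull polygon measure the same
  m <- matrix(FALSE, 40, 40); m[10:25, 12:30] <- TRUE; m[8:12, 14:20] <- TRUE
  coords <- which(m, arr.ind = TRUE)
  corners <- rbind(cbind(coords[, 1] - 0.5, coords[, 2] - 0.5),
                   cbind(coords[, 1] + 0.5, coords[, 2] - 0.5),
                   cbind(coords[, 1] - 0.5, coords[, 2] + 0.5),
                   cbind(coords[, 1] + 0.5, coords[, 2] + 0.5))
  hull <- corners[grDevices::chull(corners), ]
  expect_equal(as.numeric(min_feret(m)), as.numeric(min_feret(hull)),
               tolerance = 1e-9)
})

test_that("collinear input yields a flagged zero width", {
  line <- cbind(1:5, 2 * (1:5))
  mf <- min_feret(line)
  expect_equal(as.numeric(mf), 0)
  expect_true(attr(mf, "degenerate"))
})

test_that("rendering is deterministic and respects type fractions", {
  a <- render_section(40, pct_type1 = 50, canvas_px = 220, seed = 5)
  b <- render_section(40, pct_type1 = 50, canvas_px = 220, seed = 5)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$types, b$truth$types)
  expect_equal(sum(a$truth$types == "type1"), 20)

  one <- render_section(1, pct_type1 = 100, canvas_px = 100, seed = 6)
  expect_length(one$truth$polygons, 1)
  expect_gt(mean(one$image[, , 1][one$truth$labels == 1]), 0.5)
  one2 <- render_section(1, pct_type1 = 0, canvas_px = 100, seed = 6)
  # absent marker: green channel is pure noise
  expect_lt(mean(one2$image[, , 1]), 0.05)
  expect_error(render_section(5000, canvas_px = 100), "infeasible")
})

test_that("noiseless segmentation recovers every fiber and type exactly", {
  sec <- render_section(60, pct_type1 = 50, canvas_px = 260,
                        noise_sd = 0, seed = 7)
  seg <- segment_fibers(sec$image, thresholds = list(green = 0.4, red = 0.4))
  n1 <- sum(sec$truth$types == "type1")
  expect_equal(max(seg$slow), n1)
  expect_equal(max(seg$fast), 60 - n1)
  # every segmented slow component sits on a single true type1 fiber
  for (i in seq_len(max(seg$slow))) {
    labs <- sec$truth$labels[seg$slow == i]
    labs <- labs[labs > 0]
    expect_equal(length(unique(labs)), 1)
    expect_equal(sec$truth$types[unique(labs)], "type1")
  }
  for (i in seq_len(max(seg$fast))) {
    labs <- sec$truth$labels[seg$fast == i]
    labs <- labs[labs > 0]
    expect_equal(length(unique(labs)), 1)
    expect_equal(sec$truth$types[unique(labs)], "type2")
  }
})

test_that("an all-type1 section leaves the fast set empty", {
  sec <- render_section(25, pct_type1 = 100, canvas_px = 200,
                        noise_sd = 0, seed = 8)
  seg <- segment_fibers(sec$image, thresholds = list(green = 0.4, red = 0.4))
  expect_equal(max(seg$fast), 0)
  expect_equal(max(seg$slow), 25)
})

test_that("type calls stay accurate under default noise (Otsu thresholds)", {
  acc <- vapply(1:5, function(s) {
    sec <- render_section(60, pct_type1 = 40, canvas_px = 260, seed = 60 + s)
    seg <- segment_fibers(sec$image)
    correct <- 0; total <- 0
    for (set in c("slow", "fast")) {
      lab <- seg[[set]]
      want <- if (set == "slow") "type1" else "type2"
      for (i in seq_len(max(lab))) {
        labs <- sec$truth$labels[lab == i]
        labs <- labs[labs > 0]
        if (length(labs) == 0) next
        tl <- names(sort(table(labs), decreasing = TRUE))[1]
        total <- total + 1
        if (sec$truth$types[as.integer(tl)] == want) correct <- correct + 1
      }
    }
    correct / total
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("section summaries compute proportions and the 70-fiber QC rule", {
  f69 <- data.frame(type = rep(c("type1", "type2"), c(30, 39)),
                    min_feret_um = runif(69, 30, 80))
  expect_false(summarize_section(f69)$qc_pass)
  f70 <- rbind(f69, data.frame(type = "type1", min_feret_um = 50))
  expect_true(summarize_section(f70)$qc_pass)
  f4 <- data.frame(type = c("type1", "type1", "type1", "type2"),
                   min_feret_um = c(10, 20, 30, 40))
  s <- summarize_section(f4)
  expect_equal(s$pct_type1, 75)
  expect_equal(unname(s$mean_min_feret["type1"]), 20)
  expect_equal(sum(s$size_hist$type1$count), 3)
})

test_that("summary of rendered truth reproduces the exact type percentage", {
  sec <- render_section(200, pct_type1 = 50, canvas_px = 420,
                        noise_sd = 0, seed = 9)
  seg <- segment_fibers(sec$image, thresholds = list(green = 0.4, red = 0.4))
  s <- summarize_section(fiber_records(seg))
  expect_equal(s$pct_type1, 50)
  expect_true(s$qc_pass)
})

test_that("mean tissue intensity: uniform value, mask correctness, gains", {
  u <- array(0.6, dim = c(20, 20, 2))
  expect_equal(mean_tissue_intensity(u, "green", 0.5), 0.6)
  half <- array(0, dim = c(20, 20, 2))
  half[1:10, , 1] <- 10 / 16  # half-plane high, half zero
  expect_equal(mean_tissue_intensity(half, "green", 5 / 16), 10 / 16)
  expect_error(mean_tissue_intensity(half, "red", 0.9), "no pixel")
  # recovered intensity ratio tracks the rendering gain ratio
  ratios <- vapply(1:10, function(s) {
    hi <- render_section(30, 100, canvas_px = 180, green_gain = 0.8,
                         seed = 100 + s)
    lo <- render_section(30, 100, canvas_px = 180, green_gain = 0.4,
                         seed = 100 + s)
    mean_tissue_intensity(hi$image, "green", 0.2) /
      mean_tissue_intensity(lo$image, "green", 0.2)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2), 0.15)
})
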