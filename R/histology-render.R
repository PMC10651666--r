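#' Render a synthetic two-channel muscle cross-section
#'
#' Builds a Voronoi mosaic of convex fiber polygons inside a disc-shaped
#' tissue region. Fiber interiors are separated by a boundary band of at
#' least `gap_px` pixels (the sarcolemma network). The green channel carries
#' interior signal for type-1 (slow, MYH7-positive) fibers only; the red
#' channel carries the boundary band around every fiber. Gaussian noise is
#' added to both channels and intensities are clamped to [0, 1].
#'
#' @param n_fibers Number of fibers (>= 1).
#' @param pct_type1 Percentage of type-1 fibers in [0, 100].
#' @param canvas_px Square canvas side in pixels.
#' @param gap_px Minimum boundary gap between fiber interiors, pixels.
#' @param pixel_size_um Physical pixel size in micrometres (default 0.5).
#' @param green_gain,red_gain Interior / boundary signal intensities on the
#'   [0, 1] scale.
#' @param noise_sd Gaussian noise standard deviation per channel.
#' @param lloyd_iters Lloyd relaxation iterations applied to the seed points
#'   (evens out fiber sizes).
#' @param seed Integer seed; the rendering is deterministic given it.
#' @return A list with `image` (canvas_px x canvas_px x 2 array, channels
#'   `green`, `red`) and `truth`, an object of class `section_truth`:
#'   per-fiber convex polygons (pixel coordinates), type labels, the label
#'   matrix, the tissue mask and the pixel size.
#' @export
render_section <- function(n_fibers, pct_type1 = 50, canvas_px = 480,
                           gap_px = 2, pixel_size_um = 0.5,
                           green_gain = 0.8, red_gain = 0.85,
                           noise_sd = 0.03, lloyd_iters = 2, seed = 1L) {
  if (!is_count(n_fibers) || n_fibers < 1) stopf("'n_fibers' must be >= 1")
  if (pct_type1 < 0 || pct_type1 > 100) stopf("'pct_type1' must be in [0, 100]")
  R <- 0.46 * canvas_px
  cx <- (canvas_px + 1) / 2
  # ~ area per fiber; refuse geometries that cannot hold measurable fibers
  if (pi * R^2 / n_fibers < 36) {
    stopf("infeasible geometry: %d fibers do not fit a %d px canvas",
          n_fibers, canvas_px)
  }
  with_seed(seed, {
    # seed points uniform in the disc, then Lloyd relaxation on a coarse grid
    th <- stats::runif(n_fibers, 0, 2 * pi)
    rr <- R * sqrt(stats::runif(n_fibers)) * 0.98
    pts <- cbind(cx + rr * cos(th), cx + rr * sin(th))
    g <- seq(1, canvas_px, by = 2)
    gx <- rep(g, length(g)); gy <- rep(g, each = length(g))
    ing <- (gx - cx)^2 + (gy - cx)^2 <= R^2
    gx <- gx[ing]; gy <- gy[ing]
    for (it in seq_len(lloyd_iters)) {
      a <- factor(nearest_two(gx, gy, pts)$i1, levels = seq_len(n_fibers))
      cnt <- as.numeric(table(a))
      pts <- cbind(as.numeric(tapply(gx, a, sum)),
                   as.numeric(tapply(gy, a, sum))) / cnt
      bad <- !is.finite(pts[, 1])
      if (any(bad)) {  # seed lost all grid points; resample inside disc
        th2 <- stats::runif(sum(bad), 0, 2 * pi)
        rr2 <- R * sqrt(stats::runif(sum(bad))) * 0.9
        pts[bad, ] <- cbind(cx + rr2 * cos(th2), cx + rr2 * sin(th2))
      }
    }
    px <- rep(seq_len(canvas_px), canvas_px)        # x varies fastest (rows)
    py <- rep(seq_len(canvas_px), each = canvas_px) # y per column
    dc <- sqrt((px - cx)^2 + (py - cx)^2)
    tissue <- dc <= R
    nn <- nearest_two(px, py, pts)
    interior <- tissue & (nn$d2 - nn$d1 > gap_px) & (R - dc > gap_px)
    labels <- matrix(0L, canvas_px, canvas_px)
    labels[cbind(px[interior], py[interior])] <- nn$i1[interior]
    sizes <- tabulate(labels[labels > 0L], nbins = n_fibers)
    if (any(sizes < 16)) {
      stopf("infeasible geometry: %d fibers leave interiors under 16 px",
            sum(sizes < 16))
    }
    n1 <- round(n_fibers * pct_type1 / 100)
    types <- sample(rep(c("type1", "type2"), c(n1, n_fibers - n1)))
    tissue_m <- matrix(FALSE, canvas_px, canvas_px)
    tissue_m[cbind(px[tissue], py[tissue])] <- TRUE
    boundary <- tissue_m & labels == 0L

    is1 <- matrix(types[pmax(labels, 1L)] == "type1" & labels > 0L,
                  canvas_px, canvas_px)
    green <- ifelse(is1, green_gain, 0) +
      stats::rnorm(canvas_px^2, sd = noise_sd)
    red <- ifelse(boundary, red_gain, 0) +
      stats::rnorm(canvas_px^2, sd = noise_sd)
    img <- array(c(pmin(pmax(green, 0), 1), pmin(pmax(red, 0), 1)),
                 dim = c(canvas_px, canvas_px, 2),
                 dimnames = list(NULL, NULL, c("green", "red")))
    polys <- lapply(seq_len(n_fibers), function(i) {
      co <- which(labels == i, arr.ind = TRUE)
      pixel_hull(co)
    })
    truth <- structure(list(polygons = polys, types = types,
                            labels = labels, tissue = tissue_m,
                            seeds = pts, pixel_size_um = pixel_size_um,
                            gains = c(green = green_gain, red = red_gain)),
                       class = "section_truth")
    list(image = img, truth = truth)
  })
}

#' @export
print.section_truth <- function(x, ...) {
  cat(sprintf("section_truth: %d fibers (%.1f%% type 1), %d x %d px, %.2g um/px\n",
              length(x$types), 100 * mean(x$types == "type1"),
              nrow(x$labels), ncol(x$labels), x$pixel_size_um))
  invisible(x)
}

# Indices and distances of the nearest and second-nearest seed per point,
# computed in chunks to bound memory.
nearest_two <- function(x, y, pts, chunk = 10000L) {
  n <- length(x); k <- nrow(pts)
  i1 <- integer(n); d1 <- numeric(n); d2 <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    D <- outer(x[s:e], pts[, 1], "-")^2 + outer(y[s:e], pts[, 2], "-")^2
    j1 <- max.col(-D, ties.method = "first")
    rows <- seq_len(e - s + 1L)
    dd1 <- D[cbind(rows, j1)]
    if (k > 1L) {
      D[cbind(rows, j1)] <- Inf
      j2 <- max.col(-D, ties.method = "first")
      dd2 <- D[cbind(rows, j2)]
    } else dd2 <- rep(Inf, length(rows))
    i1[s:e] <- j1; d1[s:e] <- sqrt(dd1); d2[s:e] <- sqrt(dd2)
  }
  list(i1 = i1, d1 = d1, d2 = d2)
}

# Convex hull of a set of pixels as a polygon over the pixel squares
# (each pixel contributes its four corners, so extent is not underestimated).
pixel_hull <- function(coords) {
  if (nrow(coords) == 0) return(NULL)
  h <- grDevices::chull(coords)
  hp <- coords[h, , drop = FALSE]
  corners <- rbind(cbind(hp[, 1] - 0.5, hp[, 2] - 0.5),
                   cbind(hp[, 1] + 0.5, hp[, 2] - 0.5),
                   cbind(hp[, 1] - 0.5, hp[, 2] + 0.5),
                   cbind(hp[, 1] + 0.5, hp[, 2] + 0.5))
  poly <- corners[grDevices::chull(corners), , drop = FALSE]
  colnames(poly) <- c("x", "y")
  poly
}
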