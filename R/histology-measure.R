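#' Minimal Feret diameter of a convex polygon or pixel mask
#'
#' The minimal Feret (caliper) diameter is the smallest width of the shape
#' over all orientations; it is computed on the convex hull by rotating
#' calipers (the minimal width is always attained flush with a hull edge).
#' Pixel masks are measured over the pixel squares, not the pixel centres,
#' so an axis-aligned square of side s pixels measures exactly s.
#'
#' @param x Either an n-by-2 numeric matrix of polygon vertices (columns
#'   x, y) or a logical matrix mask.
#' @param pixel_size Physical length of one pixel/coordinate unit; the
#'   returned diameter is in these units.
#' @return The minimal Feret diameter (numeric). Degenerate (collinear)
#'   inputs return 0 with attribute `degenerate = TRUE`.
#' @examples
#' sq <- cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))
#' min_feret(sq)  # 4
#' @export
min_feret <- function(x, pixel_size = 1) {
  if (is.logical(x) || (is.matrix(x) && !is.null(dim(x)) && ncol(x) != 2)) {
    coords <- which(x != 0, arr.ind = TRUE)
    if (nrow(coords) < 1) stopf("empty mask")
    pts <- pixel_hull(coords)
  } else {
    pts <- as.matrix(x)
    if (ncol(pts) != 2 || nrow(pts) < 3) {
      stopf("polygon must be an n-by-2 matrix with n >= 3")
    }
  }
  h <- grDevices::chull(pts)
  H <- pts[h, , drop = FALSE]
  n <- nrow(H)
  if (n < 3) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  w <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- H[j, ] - H[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nv <- c(-e[2], e[1]) / len
    proj <- (H[, 1] - H[i, 1]) * nv[1] + (H[, 2] - H[i, 2]) * nv[2]
    w <- min(w, diff(range(proj)))
  }
  if (!is.finite(w) || w < 1e-9) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  w * pixel_size
}

# 8-connected component labelling: 4-connected pass (EBImage::bwlabel),
# then union-find merging of labels that touch diagonally.
label_components <- function(mask, connectivity = 8L) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  k <- max(lab)
  if (connectivity == 4L || k < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
  a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment slow and fast fibers from a two-channel section image
#'
#' Slow (type-1) fibers are the connected components of the thresholded
#' green channel. Fast fibers are recovered from the red boundary network:
#' with `fast_mode = "filled_interior"` (default) the red mask is
#' hole-filled, the boundary is subtracted to expose all fiber interiors,
#' and interiors already claimed by the green (slow) mask are removed; with
#' `"raw_subtraction"` the green area is subtracted from the raw red mask.
#' Components are 8-connected and must reach `area_min` pixels.
#'
#' @param image canvas x canvas x 2 array as produced by [render_section()].
#' @param thresholds Optional list with elements `green` and/or `red`;
#'   missing thresholds are set automatically by Otsu's method.
#' @param area_min Minimum component area in pixels (default 50).
#' @param fast_mode `"filled_interior"` or `"raw_subtraction"`.
#' @return List of class `fiber_segmentation`: `slow` and `fast` labelled
#'   integer matrices and the `thresholds` used.
#' @export
segment_fibers <- function(image, thresholds = NULL, area_min = 50,
                           fast_mode = c("filled_interior", "raw_subtraction")) {
  fast_mode <- match.arg(fast_mode)
  if (length(dim(image)) != 3 || dim(image)[3] < 2) {
    stopf("'image' must be a two-channel array")
  }
  green <- image[, , 1]; red <- image[, , 2]
  th_g <- thresholds$green %||% EBImage::otsu(EBImage::Image(green))
  th_r <- thresholds$red %||% EBImage::otsu(EBImage::Image(red))
  mask_g <- green > th_g
  mask_r <- red > th_r
  if (!any(mask_g | mask_r)) stopf("no tissue above threshold")
  slow <- prune_small(label_components(mask_g), area_min)
  if (fast_mode == "filled_interior") {
    filled <- EBImage::fillHull(EBImage::Image(mask_r * 1)) > 0
    interiors <- matrix(as.logical(filled), nrow(mask_r)) & !mask_r
    lab <- prune_small(label_components(interiors), area_min)
    fast <- lab
    for (i in seq_len(max(lab))) {
      px <- lab == i
      if (mean(mask_g[px]) > 0.5) fast[px] <- 0L  # claimed by the slow mask
    }
    fast <- relabel(fast)
  } else {
    fast <- prune_small(label_components(mask_r & !mask_g), area_min)
  }
  structure(list(slow = slow, fast = fast,
                 thresholds = list(green = th_g, red = th_r),
                 area_min = area_min, fast_mode = fast_mode),
            class = "fiber_segmentation")
}

prune_small <- function(lab, area_min) {
  if (max(lab) == 0) return(lab)
  sz <- tabulate(lab[lab > 0], nbins = max(lab))
  drop <- which(sz < area_min)
  if (length(drop)) lab[lab %in% drop] <- 0L
  relabel(lab)
}

relabel <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (length(u) == 0) return(lab)
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

#' Per-fiber morphometry records from a segmentation
#'
#' @param seg A `fiber_segmentation`.
#' @param pixel_size_um Pixel size in micrometres.
#' @return data.frame: fiber_id, type (`type1` = slow, `type2` = fast),
#'   min_feret_um, area_um2.
#' @export
fiber_records <- function(seg, pixel_size_um = 0.5) {
  one <- function(lab, type) {
    k <- max(lab)
    if (k == 0) return(NULL)
    do.call(rbind, lapply(seq_len(k), function(i) {
      m <- lab == i
      data.frame(fiber_id = paste0(type, "_", i), type = type,
                 min_feret_um = as.numeric(min_feret(m, pixel_size_um)),
                 area_um2 = sum(m) * pixel_size_um^2,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one(seg$slow, "type1"), one(seg$fast, "type2"))
  if (is.null(out)) {
    out <- data.frame(fiber_id = character(), type = character(),
                      min_feret_um = numeric(), area_um2 = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Summarize fiber records for one section
#'
#' Counts fibers per type, the type-1 percentage, the per-type mean minimal
#' Feret diameter and a size histogram; sections with fewer than
#' `qc_min_fibers` fibers fail QC (`qc_pass = FALSE`).
#'
#' @param fibers data.frame as from [fiber_records()] (columns `type`,
#'   `min_feret_um`).
#' @param qc_min_fibers Minimum fiber count for QC (default 70).
#' @param bin_width_um Histogram bin width in micrometres (default 5).
#' @return Object of class `section_summary`.
#' @export
summarize_section <- function(fibers, qc_min_fibers = 70, bin_width_um = 5) {
  n1 <- sum(fibers$type == "type1")
  n2 <- sum(fibers$type == "type2")
  total <- n1 + n2
  mf <- function(t) {
    v <- fibers$min_feret_um[fibers$type == t]
    if (length(v)) mean(v) else NA_real_
  }
  hist1 <- size_hist(fibers$min_feret_um[fibers$type == "type1"], bin_width_um)
  hist2 <- size_hist(fibers$min_feret_um[fibers$type == "type2"], bin_width_um)
  structure(list(
    n_type1 = n1, n_type2 = n2,
    pct_type1 = if (total > 0) 100 * n1 / total else NA_real_,
    mean_min_feret = c(type1 = mf("type1"), type2 = mf("type2")),
    size_hist = list(type1 = hist1, type2 = hist2),
    bin_width_um = bin_width_um,
    qc_pass = total >= qc_min_fibers
  ), class = "section_summary")
}

size_hist <- function(v, bw) {
  if (length(v) == 0) return(data.frame(bin_lo = numeric(), count = integer()))
  br <- seq(0, (max(v) %/% bw + 1) * bw, by = bw)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  data.frame(bin_lo = h$breaks[-length(h$breaks)], count = h$counts)
}

#' @export
print.section_summary <- function(x, ...) {
  cat(sprintf("section_summary: %d type1 + %d type2 (%.1f%% type1); QC %s\n",
              x$n_type1, x$n_type2, x$pct_type1,
              if (x$qc_pass) "pass" else "FAIL (<70 fibers)"))
  cat(sprintf("  mean min Feret: type1 %.1f um, type2 %.1f um\n",
              x$mean_min_feret[1], x$mean_min_feret[2]))
  invisible(x)
}

#' Mean channel intensity over thresholded tissue
#'
#' @param image Two-channel array.
#' @param channel `"green"` or `"red"`.
#' @param tissue_threshold Fixed threshold selecting tissue pixels; keep it
#'   constant across a batch when comparing intensities.
#' @return Mean intensity of the channel over pixels at or above the
#'   threshold.
#' @export
mean_tissue_intensity <- function(image, channel = c("green", "red"),
                                  tissue_threshold) {
  channel <- match.arg(channel)
  m <- image[, , match(channel, c("green", "red"))]
  mask <- m >= tissue_threshold
  if (!any(mask)) stopf("no pixel at or above the tissue threshold")
  mean(m[mask])
}
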