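#' Read a leaf image from PNG or TIFF
#'
#' Reads an 8/16-bit grayscale (or RGB, converted by channel averaging)
#' image and returns it as a numeric matrix in [0, 1], origin top-left.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix.
#' @export
read_leaf_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' Binarize a leaf image into a single-leaf mask
#'
#' Thresholds a grayscale image and cleans the result so that exactly one
#' foreground connected component remains. For continuous grayscale input
#' the leaf is assumed darker than the scanner background and the
#' foreground is the below-threshold region (threshold from Otsu's method
#' when not given). Already-binary input is taken at face value (nonzero =
#' foreground), making the operation idempotent on masks. The largest
#' connected component is kept (with a warning when discarded components
#' exceed 10% of its area) and interior holes are filled.
#'
#' @param image Numeric matrix in [0, 1], or a [leaf_mask()].
#' @param threshold Optional gray threshold; Otsu's method when `NULL`.
#' @param dpi Resolution attached to the returned mask.
#' @param min_area Minimum foreground area in px (default 50).
#' @param leaf_id Identifier for the mask.
#' @return A cleaned [leaf_mask()].
#' @export
binarize <- function(image, threshold = NULL, dpi = 600, min_area = 50L,
                     leaf_id = "leaf") {
  if (inherits(image, "leaf_mask")) {
    dpi <- image$dpi
    leaf_id <- image$leaf_id
    image <- image$raster
  }
  if (!is.matrix(image)) stop("image must be a single-channel matrix")
  vals <- unique(as.vector(image))
  if (length(vals) <= 2L) {
    fg <- image != 0            # binary input: mask convention
  } else {
    if (is.null(threshold))
      threshold <- EBImage::otsu(EBImage::Image(image),
                                 range = range(image))
    fg <- image < threshold     # leaf darker than scanner background
  }
  if (!any(fg)) stop("empty foreground")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  if (length(sizes) > 1L) {
    second <- max(sizes[-keep])
    if (second > 0.1 * sizes[keep])
      warning(sprintf(
        "discarding %d secondary component(s); largest is %.0f%% of the kept leaf",
        length(sizes) - 1L, 100 * second / sizes[keep]))
  }
  fg <- lab == keep
  fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg * 1))) > 0
  fg <- matrix(fg, nrow = nrow(image))
  if (sum(fg) < min_area)
    stop(sprintf("foreground area %d px below minimum %d px", sum(fg),
                 as.integer(min_area)))
  leaf_mask(fg, dpi = dpi, leaf_id = leaf_id)
}

# Foreground pixel centers as (x = col, y = row) in px units.
fg_points <- function(mask) {
  idx <- which(mask$raster == 1L, arr.ind = TRUE)
  cbind(x = idx[, 2L], y = idx[, 1L])
}

#' Locate the base-to-tip axis of a leaf mask
#'
#' The midrib of a bilaterally symmetric single-vein leaf coincides with
#' the major principal axis of its silhouette, so the axis direction is
#' taken from the first principal component of the foreground pixel
#' coordinates — the noise-robust estimate of the longest chord, and exact
#' for any mask symmetric about its midrib. The base and tip are the
#' extreme foreground points projected onto that axis (among ties, the
#' pixel nearest the midline); leaf length is the projected extent plus one
#' pixel (n pixel centers span n pixels of material), converted to cm via
#' the dpi.
#'
#' The base is the endpoint whose terminal 10% window of the leaf is wider
#' — in single-vein leaves the blade broadens just above the petiole while
#' the apex tapers to an acute point. When the two terminal windows differ
#' by less than 5% the assignment is flagged ambiguous (e.g. a circle or a
#' symmetric ellipse).
#'
#' @param mask A [leaf_mask()].
#' @return A list with elements `base`, `tip` (length-2 xy vectors, px),
#'   `length_cm`, `length_px`, `direction` (unit vector base to tip) and
#'   `ambiguous`.
#' @export
find_axis <- function(mask) {
  stopifnot(inherits(mask, "leaf_mask"))
  pts <- fg_points(mask)
  if (nrow(pts) < 2L) stop("degenerate foreground: fewer than 2 pixels")
  ctr <- colMeans(pts)
  cx <- pts[, 1L] - ctr[1L]
  cy <- pts[, 2L] - ctr[2L]
  cov <- matrix(c(mean(cx * cx), mean(cx * cy),
                  mean(cx * cy), mean(cy * cy)), 2L)
  u <- eigen(cov, symmetric = TRUE)$vectors[, 1L]
  # canonical orientation: positive x (then positive y), for determinism
  if (u[1L] < 0 || (u[1L] == 0 && u[2L] < 0)) u <- -u
  t <- cx * u[1L] + cy * u[2L]
  len_px <- max(t) - min(t)
  if (len_px == 0) stop("degenerate foreground: zero extent along axis")
  mid_of <- function(idx) {       # extreme pixel nearest the midline
    w <- cx[idx] * -u[2L] + cy[idx] * u[1L]
    idx[order(abs(w), w)][1L]
  }
  e1 <- unname(pts[mid_of(which(t == min(t))), ])
  e2 <- unname(pts[mid_of(which(t == max(t))), ])
  lo <- t <= min(t) + 0.1 * len_px
  hi <- t >= max(t) - 0.1 * len_px
  # average width (px) of each terminal window = pixel count / window length
  w_lo <- sum(lo) / (0.1 * len_px)
  w_hi <- sum(hi) / (0.1 * len_px)
  ambiguous <- abs(w_lo - w_hi) < 0.05 * max(w_lo, w_hi)
  if (w_hi > w_lo && !ambiguous) {
    tmp <- e1; e1 <- e2; e2 <- tmp
    u <- -u
  }
  s <- 2.54 / mask$dpi
  list(base = e1, tip = e2,
       length_px = len_px, length_cm = (len_px + 1) * s,
       direction = unname(u), ambiguous = ambiguous)
}

#' Measure a width profile from a leaf mask
#'
#' Divides the base-to-tip axis into stations every `interval_cm` (0 at the
#' base) and, at each station, measures the full leaf width as the extent of
#' foreground along the direction perpendicular to the axis within a
#' one-pixel band around the station; the half-width is half of that, under
#' the bilateral-symmetry assumption. Stations with no foreground (extreme
#' tip) are retained with half-width 0.
#'
#' @param mask A [leaf_mask()].
#' @param interval_cm Station spacing (cm); the study convention is 0.1 or
#'   0.2 cm.
#' @param axis Optional precomputed result of [find_axis()].
#' @return A [width_profile()].
#' @export
measure_profile <- function(mask, interval_cm = 0.1, axis = NULL) {
  stopifnot(inherits(mask, "leaf_mask"))
  if (is.null(axis)) axis <- find_axis(mask)
  s <- 2.54 / mask$dpi
  if (interval_cm >= axis$length_cm)
    stop("interval must be smaller than the leaf length")
  pts <- fg_points(mask)
  u <- axis$direction
  v <- c(-u[2L], u[1L])
  t <- (pts[, 1L] - axis$base[1L]) * u[1L] + (pts[, 2L] - axis$base[2L]) * u[2L]
  w <- (pts[, 1L] - axis$base[1L]) * v[1L] + (pts[, 2L] - axis$base[2L]) * v[2L]
  t_rel <- t - min(t) + 0.5   # px; pixel material spans [t_rel - 0.5, t_rel + 0.5]
  positions <- seq(0, axis$length_cm, by = interval_cm)
  half <- vapply(positions, function(x) {
    sel <- abs(t_rel - x / s) <= 0.5
    if (!any(sel)) return(0)
    (max(w[sel]) - min(w[sel]) + 1) * s / 2
  }, numeric(1L))
  width_profile(positions, half, total_length_cm = axis$length_cm,
                leaf_id = mask$leaf_id, interval_cm = interval_cm)
}
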