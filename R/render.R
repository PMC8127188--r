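#' Binary leaf mask
#'
#' A raster with foreground 1 (leaf) and background 0, row-major with origin
#' at the top-left; `dpi` fixes the physical pixel size at 2.54/dpi cm.
#'
#' @param raster Matrix of 0/1 (or logical).
#' @param dpi Scan resolution in dots per inch, at least 50.
#' @param leaf_id Identifier.
#' @return An object of class `leaf_mask`.
#' @export
leaf_mask <- function(raster, dpi = 600, leaf_id = "leaf") {
  raster <- matrix(as.integer(raster != 0), nrow = nrow(raster))
  if (dpi < 50) stop("dpi must be at least 50")
  structure(list(raster = raster, dpi = as.integer(dpi),
                 leaf_id = as.character(leaf_id)),
            class = "leaf_mask")
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %s: %d x %d px at %d dpi, %d foreground px\n",
              x$leaf_id, nrow(x$raster), ncol(x$raster), x$dpi,
              sum(x$raster)))
  invisible(x)
}

#' Render a width profile as a binary mask
#'
#' Rasterizes a half-width profile into a binary image: at the pixel column
#' whose center lies at position \eqn{X} along the leaf, the foreground spans
#' \eqn{2\,\mathrm{half\_width}(X)} pixels symmetric about a straight
#' horizontal midrib. Half-widths between stations are interpolated
#' linearly; half-widths are converted to pixels by round-half-up. The
#' physical pixel size is 2.54/dpi cm.
#'
#' @param profile A [width_profile()].
#' @param dpi Output resolution (default 600, the study's scan setting).
#' @param margin_px Background margin added on every side (default 3).
#' @param max_px Cap on either raster dimension; rendering a mask larger
#'   than this is rejected.
#' @return A [leaf_mask()].
#' @examples
#' m <- render_mask(generate_profile(leaf_shape_spec("elliptic", 2)), dpi = 150)
#' dim(m$raster)
#' @export
render_mask <- function(profile, dpi = 600, margin_px = 3L, max_px = 8000L) {
  stopifnot(inherits(profile, "width_profile"))
  if (dpi < 50) stop("dpi must be at least 50")
  if (any(profile$half_widths_cm < 0)) stop("half-widths must be non-negative")
  s <- 2.54 / dpi
  L <- profile$total_length_cm
  n_cols <- floor(L / s + 0.5)
  x_centers <- (seq_len(n_cols) - 0.5) * s
  h <- approx(profile$positions_cm, profile$half_widths_cm,
              xout = x_centers, rule = 2)$y
  half_px <- floor(h / s + 0.5)  # round half up
  H <- 2L * max(half_px) + 2L * margin_px
  W <- n_cols + 2L * margin_px
  if (H > max_px || W > max_px)
    stop(sprintf("mask dimensions %d x %d exceed cap %d px", H, W, max_px))
  raster <- matrix(0L, nrow = H, ncol = W)
  r0 <- H %/% 2L  # midrib between rows r0 and r0 + 1
  for (j in seq_len(n_cols)) {
    k <- half_px[j]
    if (k > 0L)
      raster[(r0 - k + 1L):(r0 + k), j + margin_px] <- 1L
  }
  leaf_mask(raster, dpi = dpi, leaf_id = profile$leaf_id)
}

#' Write a leaf mask as an 8-bit PNG
#'
#' Foreground is written as 255 (white), background as 0.
#'
#' @param mask A [leaf_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(inherits(mask, "leaf_mask"))
  png::writePNG(mask$raster * 1.0, path)
  invisible(path)
}
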