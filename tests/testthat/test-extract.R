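# Mask cleanup, axis finding and perpendicular width measurement.

test_that("binarize is idempotent on binary masks and rejects empty images", {
  m <- render_mask(generate_profile(quadratic_spec(length_cm = 2)), dpi = 300)
  b <- binarize(m)
  expect_identical(b$raster, m$raster)
  expect_error(binarize(matrix(0, 50, 50)), "empty foreground")
})

test_that("grayscale scans binarize with the leaf darker than the background", {
  m <- render_mask(generate_profile(quadratic_spec(length_cm = 2)), dpi = 300)
  scan <- 0.9 - 0.7 * m$raster + 0.02 * sin(seq_len(length(m$raster)))
  scan <- matrix(scan, nrow(m$raster))
  b <- binarize(scan, dpi = 300)
  expect_gt(mean(b$raster == m$raster), 0.999)
})

test_that("salt noise is removed and the clean bounding box recovered", {
  m <- render_mask(generate_profile(quadratic_spec(length_cm = 3)), dpi = 300)
  noisy <- m$raster
  set.seed(42)
  bg <- which(noisy == 0L)
  noisy[sample(bg, round(0.01 * length(bg)))] <- 1L
  cleaned <- suppressWarnings(binarize(leaf_mask(noisy, dpi = 300)))
  bbox <- function(r) c(range(which(rowSums(r) > 0)),
                        range(which(colSums(r) > 0)))
  expect_lte(max(abs(bbox(cleaned$raster) - bbox(m$raster))), 2)
})

test_that("axis length matches the generated leaf and survives rotation", {
  p <- generate_profile(leaf_shape_spec("ovate", 4))
  m <- render_mask(p, dpi = 600)
  ax <- find_axis(binarize(m))
  expect_lt(abs(ax$length_cm - 4), 0.025)
  expect_false(ax$ambiguous)

  # 90 degree rotation: transpose the raster
  rot90 <- leaf_mask(t(m$raster), dpi = 600)
  ax90 <- find_axis(binarize(rot90))
  expect_lt(abs(ax90$length_px - ax$length_px), 1)

  # 30 degree rotation via nearest-neighbour resampling
  img <- EBImage::rotate(EBImage::Image(t(m$raster * 1.0)), 30,
                         filter = "none", bg.col = 0)
  rot30 <- leaf_mask(t(EBImage::imageData(img) > 0.5), dpi = 600)
  ax30 <- find_axis(binarize(rot30))
  expect_lt(abs(ax30$length_px - ax$length_px), 2)
})

test_that("a circle is measured across its diameter and flagged ambiguous", {
  d <- disc_mask(radius_px = 80)
  ax <- find_axis(d)
  expect_lt(abs(ax$length_px - 160), 2)
  expect_true(ax$ambiguous)
})

test_that("profiles are invariant under translation", {
  m <- render_mask(generate_profile(leaf_shape_spec("oblong", 3)), dpi = 300)
  pad <- matrix(0L, nrow(m$raster) + 40L, ncol(m$raster) + 60L)
  pad[21:(20 + nrow(m$raster)), 41:(40 + ncol(m$raster))] <- m$raster
  q1 <- measure_profile(m)
  q2 <- measure_profile(leaf_mask(pad, dpi = 300))
  expect_equal(q1$total_length_cm, q2$total_length_cm, tolerance = 1e-12)
  expect_equal(q1$half_widths_cm, q2$half_widths_cm, tolerance = 1e-12)
})

test_that("a rectangle yields 41 constant-width stations", {
  rect <- width_profile(seq(0, 4, 0.1), rep(0.15, 41), leaf_id = "rect")
  q <- measure_profile(binarize(render_mask(rect, dpi = 600)))
  expect_length(q$positions_cm, 41)
  expect_true(all(abs(q$half_widths_cm - 0.15) < 0.005))
})

test_that("width measurements respect symmetry and non-negativity", {
  # elliptic: widest stations centred at mid-length (rasterization flattens
  # the peak into a plateau, so use the plateau midpoint)
  pe <- generate_profile(leaf_shape_spec("elliptic", 4))
  qe <- measure_profile(binarize(render_mask(pe, dpi = 600)))
  plateau <- qe$positions_cm[qe$half_widths_cm == max(qe$half_widths_cm)]
  expect_lt(abs(mean(plateau) - qe$total_length_cm / 2), 0.1 + 1e-9)
  expect_true(all(qe$half_widths_cm >= 0))
  expect_lte(max(qe$half_widths_cm), 0.165 + 2.54 / 600)

  # ovate: downstream tipping ratio near the theoretical 2/5
  po <- generate_profile(leaf_shape_spec("ovate", 4))
  qo <- measure_profile(binarize(render_mask(po, dpi = 600)))
  expect_lt(abs(fit_taper(qo)$tipping_ratio - 0.4), 0.02)
})

test_that("degenerate masks raise errors", {
  expect_error(find_axis(leaf_mask(matrix(c(0L, 1L, 0L, 0L), 2L), dpi = 600)),
               "degenerate")
  m <- render_mask(generate_profile(quadratic_spec(length_cm = 2)), dpi = 300)
  expect_error(measure_profile(m, interval_cm = 10), "interval")
})
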