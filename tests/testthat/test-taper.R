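# Quadratic taper model: OLS fit, vertex, tipping ratio, batch behaviour.

test_that("noiseless quadratic samples are recovered exactly", {
  x <- seq(0, 4, 0.1)
  p <- width_profile(x, 0.12 + 0.04 * x - 0.014 * x^2)
  f <- fit_taper(p)
  expect_equal(f$C, 0.12, tolerance = 1e-9)
  expect_equal(f$B1, 0.04, tolerance = 1e-9)
  expect_equal(f$B2, -0.014, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$se_C, 0, tolerance = 1e-9)  # zero-residual fit, zero SEs
  expect_true(f$valid)
})

test_that("a constant profile is flagged B2_nonnegative, never an error", {
  p <- width_profile(seq(0, 4, 0.1), rep(0.15, 41))
  f <- fit_taper(p)
  expect_equal(f$B1, 0, tolerance = 1e-9)
  expect_equal(f$B2, 0, tolerance = 1e-9)
  expect_false(f$valid)
  expect_identical(f$invalid_reason, "B2_nonnegative")
})

test_that("too few stations or positions give a flagged fit", {
  f <- fit_taper(width_profile(c(0, 1, 2), c(0.1, 0.2, 0.1),
                               total_length_cm = 2))
  expect_identical(f$invalid_reason, "too_few_points")
  expect_false(f$valid)
})

test_that("the fit agrees with an explicit normal-equations solve", {
  set.seed(101)
  for (r in 1:25) {
    sp <- quadratic_spec(length_cm = runif(1, 3, 6),
                         coefficients = c(runif(1, 0.1, 0.2),
                                          runif(1, -0.03, 0.05),
                                          runif(1, -0.02, -0.002)),
                         noise_sd_cm = 0.01,
                         seed = sample.int(1e6, 1))
    p <- generate_profile(sp)
    f <- fit_taper(p)
    o <- ols_oracle(p$positions_cm, p$half_widths_cm)
    expect_equal(c(f$C, f$B1, f$B2), o, tolerance = 1e-8)
  }
})

test_that("the vertex closed form matches the published models", {
  expect_equal(taper_vertex(0.040, -0.014), 1.4285714286, tolerance = 1e-9)
  expect_equal(taper_vertex(0.020, -0.007), 1.4285714286, tolerance = 1e-9)
  expect_equal(taper_vertex(0, -0.01), 0)       # widest at the base
  expect_true(is.na(taper_vertex(0.04, 0)))     # undefined for B2 = 0
})

test_that("tipping ratio follows its definition and symmetry", {
  expect_equal(tipping_ratio(1.4286, 4.024), 1.4286 / 4.024, tolerance = 1e-12)
  expect_equal(round(tipping_ratio(1.4286, 4.024), 3), 0.355)
  expect_error(tipping_ratio(1, 0), "positive")
  # symmetric elliptic profile of any length -> 0.5
  for (L in c(2, 4, 7)) {
    f <- fit_taper(generate_profile(leaf_shape_spec("elliptic", L)))
    expect_equal(f$tipping_ratio, 0.5, tolerance = 1e-9)
  }
})

test_that("the ratio is scale equivariant", {
  p <- generate_profile(quadratic_spec(noise_sd_cm = 0.005, seed = 9L))
  f <- fit_taper(p)
  for (k in c(0.5, 2, 10)) {
    # stretch positions by k: ratio unchanged
    ps <- width_profile(p$positions_cm * k, p$half_widths_cm,
                        total_length_cm = p$total_length_cm * k)
    fs <- fit_taper(ps)
    expect_equal(fs$tipping_ratio, f$tipping_ratio, tolerance = 1e-8)
    # scale half-widths by k: X0 and ratio unchanged, coefficients scale
    pw <- width_profile(p$positions_cm, p$half_widths_cm * k,
                        total_length_cm = p$total_length_cm)
    fw <- fit_taper(pw)
    expect_equal(fw$X0, f$X0, tolerance = 1e-8)
    expect_equal(fw$tipping_ratio, f$tipping_ratio, tolerance = 1e-8)
    expect_equal(c(fw$C, fw$B1, fw$B2), c(f$C, f$B1, f$B2) * k,
                 tolerance = 1e-8)
  }
})

test_that("batch fitting keeps invalid fits with flags and is deterministic", {
  profs <- published_cohorts(n_per_group = 3L)
  fits <- batch_fit(profs)
  expect_identical(nrow(fits), 18L)
  expect_true(all(fits$invalid_reason[fits$group %in% c("5", "10", "13")] ==
                    "vertex_out_of_range"))
  expect_true(all(fits$valid[fits$group %in% c("2", "23", "30")]))
  # traits
  p1 <- profs[[1L]]
  expect_equal(fits$max_width_cm[1L], 2 * max(p1$half_widths_cm))
  expect_equal(fits$mean_width_cm[1L], 2 * mean(p1$half_widths_cm))
  # duplicated input -> duplicated identical fits
  fits2 <- batch_fit(c(profs[1], profs[1]))
  expect_equal(fits2[1, ], fits2[2, ])
})

test_that("an empty ratio set yields an n = 0 summary record", {
  fits <- batch_fit(published_cohorts(n_per_group = 3L))
  none <- fits$valid & fits$group == "13"
  s <- cohort_summary(fits$tipping_ratio[none], group = "13")
  expect_identical(s$n, 0L)
  expect_true(is.na(s$mean))
})

test_that("adjusted R2 uses two predictors", {
  sp <- quadratic_spec(noise_sd_cm = 0.02, seed = 12L)
  p <- generate_profile(sp)
  f <- fit_taper(p)
  n <- length(p$positions_cm)
  expect_equal(f$adj_r2, 1 - (1 - f$r2) * (n - 1) / (n - 3), tolerance = 1e-12)
  expect_lte(f$adj_r2, f$r2)
})

test_that("pooled group fits recover shared coefficients", {
  profs <- published_cohorts(n_per_group = 4L)
  thirty <- profs[vapply(profs, function(p) p$group == "30", logical(1))]
  pf <- pooled_fit(thirty, group = "30")
  expect_equal(c(pf$C, pf$B1, pf$B2), c(0.120, 0.040, -0.014),
               tolerance = 1e-9)
  expect_equal(pf$X0, 1.4285714286, tolerance = 1e-6)
})
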