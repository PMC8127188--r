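# Synthetic leaf generator: analytic curves, noise model, determinism,
# cohort structure.

test_that("quadratic profiles follow the analytic curve exactly when noise-free", {
  p <- generate_profile(quadratic_spec(length_cm = 4))
  # evaluate the 30-yr published polynomial at X = 1
  expect_equal(p$half_widths_cm[p$positions_cm == 1], 0.146, tolerance = 1e-12)
  expect_equal(p$half_widths_cm,
               pmax(0, 0.120 + 0.040 * p$positions_cm - 0.014 * p$positions_cm^2),
               tolerance = 1e-12)
  expect_equal(p$positions_cm, seq(0, 4, 0.1))
})

test_that("profiles are deterministic given the seed and vary across seeds", {
  sp <- quadratic_spec(noise_sd_cm = 0.01, seed = 7L)
  p1 <- generate_profile(sp)
  p2 <- generate_profile(sp)
  expect_identical(p1$half_widths_cm, p2$half_widths_cm)
  sp2 <- quadratic_spec(noise_sd_cm = 0.01, seed = 8L)
  expect_false(identical(generate_profile(sp2)$half_widths_cm,
                         p1$half_widths_cm))
})

test_that("noise is truncated at zero and zero-noise curves are exact", {
  sp <- leaf_shape_spec("elliptic", 4, max_half_width_cm = 0.01,
                        noise_sd_cm = 0.5, seed = 3L)
  p <- generate_profile(sp)
  expect_true(all(p$half_widths_cm >= 0))
  clean <- generate_profile(leaf_shape_spec("elliptic", 4))
  expect_equal(max(abs(clean$half_widths_cm -
                         0.165 * 2 * sqrt(pmax(0, (clean$positions_cm / 4) *
                                                  (1 - clean$positions_cm / 4))))),
               0, tolerance = 1e-12)
})

test_that("the elliptic family is symmetric about mid-length", {
  p <- generate_profile(leaf_shape_spec("elliptic", 5), interval_cm = 0.1)
  expect_equal(p$half_widths_cm, rev(p$half_widths_cm), tolerance = 1e-12)
})

test_that("family peak fractions default to the theoretical values", {
  expect_equal(leaf_shape_spec("ovate", 4)$true_ratio, 0.4)
  expect_equal(leaf_shape_spec("oblong", 4)$true_ratio, 1 / 3)
  expect_equal(leaf_shape_spec("elliptic", 4)$true_ratio, 0.5)
  # peaks actually sit there
  for (fam in c("ovate", "oblong", "elliptic")) {
    sp <- leaf_shape_spec(fam, 4)
    p <- generate_profile(sp, interval_cm = 0.01)
    expect_equal(p$positions_cm[which.max(p$half_widths_cm)] / 4,
                 sp$true_ratio, tolerance = 0.01)
  }
})

test_that("invalid shape specifications are rejected", {
  expect_error(leaf_shape_spec("quadratic", -1, coefficients = c(0.1, 0, -0.01)),
               "positive")
  expect_error(leaf_shape_spec("quadratic", 4), "coefficients")
  expect_error(leaf_shape_spec("quadratic", 4,
                               coefficients = c(-0.5, 0, -0.01)),
               "non-positive")
  expect_error(generate_profile(quadratic_spec(length_cm = 4),
                                interval_cm = 5), "interval")
  expect_error(leaf_shape_spec("ovate", 4, peak_fraction = 1.2), "peak_fraction")
})

test_that("ground-truth ratio metadata matches a taper fit of the noise-free profile", {
  m <- published_models
  for (i in seq_len(nrow(m))) {
    sp <- quadratic_spec(length_cm = m$length_mean_cm[i],
                         coefficients = c(m$C[i], m$B1[i], m$B2[i]))
    p <- generate_profile(sp)
    f <- fit_taper(p)
    expect_equal(f$X0 / f$Xmax, sp$true_ratio, tolerance = 1e-9)
  }
})

test_that("cohorts honour their length distribution and master seed", {
  tpl <- quadratic_spec()
  const <- generate_cohort(cohort_spec("g", 18, 4.2, 0, tpl, seed = 5L))
  expect_length(const, 18)
  expect_true(all(vapply(const, `[[`, numeric(1), "total_length_cm") == 4.2))

  big <- generate_cohort(cohort_spec("g", 1000, 4.368, 0.97, tpl, seed = 11L))
  lens <- vapply(big, `[[`, numeric(1), "total_length_cm")
  expect_lt(abs(mean(lens) - 4.368), 3 * 0.97 / sqrt(1000))  # CLT bound
  expect_true(all(lens > 0))

  again <- generate_cohort(cohort_spec("g", 18, 4.2, 0, tpl, seed = 5L))
  expect_identical(lapply(const, unclass), lapply(again, unclass))
})

test_that("profile CSV and ground-truth JSON round-trip", {
  co <- generate_cohort(cohort_spec("30", 3, 4.0, 0.2, quadratic_spec(),
                                    seed = 2L))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(co, csv)
  back <- read_profiles_csv(csv)
  expect_length(back, 3)
  p0 <- co[[1L]]
  expect_equal(back[[p0$leaf_id]]$half_widths_cm, p0$half_widths_cm)
  expect_equal(back[[p0$leaf_id]]$group, "30")

  js <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(co, js)
  gt <- jsonlite::read_json(js)
  expect_named(gt, vapply(co, `[[`, character(1), "leaf_id"))
  expect_equal(gt[[1L]]$true_ratio, attr(co[[1L]], "ground_truth")$true_ratio,
               tolerance = 1e-12)
})
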