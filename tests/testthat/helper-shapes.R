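# Shared fixtures, all generated in code.

# The six published age-group coefficient sets with their group mean lengths.
published_models <- cunninghamia_taper_models()

quadratic_spec <- function(length_cm = 4, coefficients = c(0.120, 0.040, -0.014),
                           noise_sd_cm = 0, seed = 1L) {
  leaf_shape_spec("quadratic", length_cm = length_cm,
                  coefficients = coefficients,
                  noise_sd_cm = noise_sd_cm, seed = seed)
}

# Independent OLS oracle: quadratic fit by explicit normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x, x^2)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Independent one-way ANOVA F oracle from between/within sums of squares.
anova_f_oracle <- function(values, groups) {
  groups <- factor(groups)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ssb <- sum(ns * (means - mean(values))^2)
  ssw <- sum((values - means[groups])^2)
  k <- nlevels(groups)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

# 108 noise-free leaves from the six published coefficient sets, lengths
# fixed at the group means (keeps every analytic curve positive in-domain).
published_cohorts <- function(n_per_group = 18L, interval_cm = 0.1) {
  m <- published_models
  out <- list()
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(n_per_group)) {
      sp <- quadratic_spec(length_cm = m$length_mean_cm[i],
                           coefficients = c(m$C[i], m$B1[i], m$B2[i]),
                           seed = i * 1000L + j)
      out[[length(out) + 1L]] <- generate_profile(
        sp, interval_cm,
        leaf_id = sprintf("%d_leaf%02d", m$age_yr[i], j),
        group = as.character(m$age_yr[i]))
    }
  }
  out
}

disc_mask <- function(radius_px = 100L, dpi = 600L) {
  n <- 2L * radius_px + 5L
  c0 <- (n + 1) / 2
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  m <- matrix(as.integer((g$r - c0)^2 + (g$c - c0)^2 <= radius_px^2), n, n)
  leaf_mask(m, dpi = dpi, leaf_id = "disc")
}
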