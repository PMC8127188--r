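#' Fit the quadratic taper model to a width profile
#'
#' Ordinary least squares of half-width on position and position squared,
#' \eqn{Y = C + B_1 X + B_2 X^2}, with classical coefficient standard
#' errors. The vertex \eqn{X_0 = -B_1/(2B_2)} and tipping leaf length ratio
#' \eqn{X_0 / X_{max}} are populated whenever defined; the fit is flagged
#' `valid` only when \eqn{B_2 < 0} and the vertex lies strictly inside
#' \eqn{(0, X_{max})}, i.e. the leaf genuinely widens and then tapers.
#'
#' Adjusted \eqn{R^2} uses the two predictors \eqn{X, X^2}:
#' \eqn{1 - (1 - R^2)(n - 1)/(n - 3)}. A perfect (zero-residual) fit yields
#' standard errors of 0; a rank-deficient design (fewer than 3 distinct
#' positions) or fewer than 5 stations is reported as `too_few_points`,
#' never raised as an error.
#'
#' @param profile A [width_profile()].
#' @param drop_trailing_zeros Drop zero-width stations at the extreme tip
#'   before fitting (default `FALSE`: they carry real shape information).
#' @return An object of class `taper_fit` with elements `C`, `B1`, `B2`,
#'   `se_C`, `se_B1`, `se_B2`, `r2`, `adj_r2`, `n_points`, `X0`, `Xmax`,
#'   `tipping_ratio`, `valid` and `invalid_reason` (one of `"none"`,
#'   `"B2_nonnegative"`, `"vertex_out_of_range"`, `"too_few_points"`).
#' @examples
#' p <- generate_profile(leaf_shape_spec("quadratic", 4,
#'                       coefficients = c(0.120, 0.040, -0.014)))
#' fit_taper(p)
#' @export
fit_taper <- function(profile, drop_trailing_zeros = FALSE) {
  stopifnot(inherits(profile, "width_profile"))
  x <- profile$positions_cm
  y <- profile$half_widths_cm
  if (drop_trailing_zeros) {
    nz <- which(y > 0)
    if (length(nz)) {
      keep <- seq_len(min(max(nz) + 1L, length(y)))
      x <- x[keep]; y <- y[keep]
    }
  }
  Xmax <- profile$total_length_cm
  empty <- function(reason) {
    structure(
      list(leaf_id = profile$leaf_id, group = profile$group,
           C = NA_real_, B1 = NA_real_, B2 = NA_real_,
           se_C = NA_real_, se_B1 = NA_real_, se_B2 = NA_real_,
           r2 = NA_real_, adj_r2 = NA_real_, n_points = length(x),
           X0 = NA_real_, Xmax = Xmax, tipping_ratio = NA_real_,
           valid = FALSE, invalid_reason = reason),
      class = "taper_fit")
  }
  if (length(x) < 5L || length(unique(x)) < 3L)
    return(empty("too_few_points"))
  fit <- lm(y ~ x + I(x^2))
  if (fit$rank < 3L) return(empty("too_few_points"))
  b <- unname(coef(fit))
  n <- length(x)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj_r2 <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - 3) else NA_real_
  sigma2 <- rss / (n - 3)
  piv <- fit$qr$pivot
  xtx_inv <- chol2inv(qr.R(fit$qr))[order(piv), order(piv)]
  ses <- sqrt(pmax(sigma2 * diag(xtx_inv), 0))
  # B2 indistinguishable from 0 at working precision (e.g. a constant or
  # linear profile) is treated as 0: no curvature, no vertex
  eps_b2 <- 1e-10 * (max(abs(y)) + .Machine$double.eps) / max(x)^2
  if (abs(b[3L]) < eps_b2) b[3L] <- 0
  X0 <- if (b[3L] != 0) taper_vertex(b[2L], b[3L]) else NA_real_
  ratio <- if (!is.na(X0)) X0 / Xmax else NA_real_
  if (b[3L] >= 0) {
    valid <- FALSE; reason <- "B2_nonnegative"
  } else if (is.na(X0) || X0 <= 0 || X0 >= Xmax) {
    valid <- FALSE; reason <- "vertex_out_of_range"
  } else {
    valid <- TRUE; reason <- "none"
  }
  structure(
    list(leaf_id = profile$leaf_id, group = profile$group,
         C = b[1L], B1 = b[2L], B2 = b[3L],
         se_C = ses[1L], se_B1 = ses[2L], se_B2 = ses[3L],
         r2 = r2, adj_r2 = adj_r2, n_points = n,
         X0 = X0, Xmax = Xmax, tipping_ratio = ratio,
         valid = valid, invalid_reason = reason),
    class = "taper_fit")
}

#' @export
print.taper_fit <- function(x, ...) {
  cat(sprintf("<taper_fit> %s: Y = %.4f + %.4f X + %.4f X^2 (R2 = %.3f)\n",
              x$leaf_id, x$C, x$B1, x$B2, x$r2))
  if (x$valid)
    cat(sprintf("  vertex X0 = %.4f cm, Xmax = %.4f cm, tipping ratio = %.4f\n",
                x$X0, x$Xmax, x$tipping_ratio))
  else
    cat(sprintf("  invalid: %s\n", x$invalid_reason))
  invisible(x)
}

#' Vertex of the quadratic taper curve
#'
#' The position of maximum half-width, \eqn{X_0 = -B_1 / (2 B_2)}; the
#' stationary point of \eqn{C + B_1 X + B_2 X^2}. Undefined (`NA`) when
#' \eqn{B_2 = 0}.
#'
#' @param b1 Linear coefficient (or a `taper_fit`, from which both
#'   coefficients are taken).
#' @param b2 Quadratic coefficient (1/cm).
#' @return Vertex position in cm.
#' @examples
#' taper_vertex(0.040, -0.014)  # 1.4286 cm
#' @export
taper_vertex <- function(b1, b2 = NULL) {
  if (inherits(b1, "taper_fit")) {
    b2 <- b1$B2; b1 <- b1$B1
  }
  ifelse(b2 == 0, NA_real_, -b1 / (2 * b2))
}

#' Tipping leaf length ratio
#'
#' The fraction of total leaf length at which the leaf is widest,
#' \eqn{X_0 / X_{max}}. Values outside (0, 1) indicate a vertex outside the
#' blade (the model places the widest point at/below the base or beyond the
#' tip) and are excluded from ratio summaries downstream.
#'
#' @param x0 Vertex position (cm), or a `taper_fit`.
#' @param xmax Total leaf length (cm), positive.
#' @return The ratio, possibly outside (0, 1).
#' @examples
#' tipping_ratio(1.4286, 4.024)
#' @export
tipping_ratio <- function(x0, xmax = NULL) {
  if (inherits(x0, "taper_fit")) {
    xmax <- x0$Xmax; x0 <- x0$X0
  }
  if (any(xmax <= 0)) stop("Xmax must be positive")
  x0 / xmax
}

#' Fit taper models to a batch of profiles
#'
#' Fits every profile and assembles one row per leaf with the fitted
#' coefficients and the scalar leaf traits used in cohort statistics:
#' total length, mean width (2 x mean half-width over stations) and maximum
#' width (2 x maximum half-width). Invalid fits are retained with their
#' flags — downstream ratio summaries exclude them — and per-leaf failures
#' are recorded, never raised.
#'
#' @param profiles A list of [width_profile()]s.
#' @param drop_trailing_zeros Passed to [fit_taper()].
#' @return A tibble with one row per leaf: identifiers, traits
#'   (`length_cm`, `mean_width_cm`, `max_width_cm`), coefficients and
#'   standard errors, `r2`, `adj_r2`, `n_points`, `X0`, `Xmax`,
#'   `tipping_ratio`, `valid`, `invalid_reason`.
#' @export
batch_fit <- function(profiles, drop_trailing_zeros = FALSE) {
  if (inherits(profiles, "width_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("empty profile list")
  rows <- lapply(profiles, function(p) {
    f <- fit_taper(p, drop_trailing_zeros = drop_trailing_zeros)
    tibble(
      leaf_id = p$leaf_id, group = p$group,
      length_cm = p$total_length_cm,
      mean_width_cm = 2 * mean(p$half_widths_cm),
      max_width_cm = 2 * max(p$half_widths_cm),
      C = f$C, B1 = f$B1, B2 = f$B2,
      se_C = f$se_C, se_B1 = f$se_B1, se_B2 = f$se_B2,
      r2 = f$r2, adj_r2 = f$adj_r2, n_points = f$n_points,
      X0 = f$X0, Xmax = f$Xmax, tipping_ratio = f$tipping_ratio,
      valid = f$valid, invalid_reason = f$invalid_reason)
  })
  do.call(rbind, rows)
}

#' Pool a group's stations into one taper model
#'
#' Stacks every station of every profile in a group and fits a single
#' quadratic by OLS — a pooled regression across the group's leaves, the
#' group-level analogue of the per-leaf fit. `Xmax` of the pooled fit is
#' the group's mean leaf length.
#'
#' @param profiles A list of [width_profile()]s belonging to one group.
#' @param group Group label attached to the result.
#' @return A `taper_fit` whose `leaf_id` is `"pooled:<group>"`.
#' @export
pooled_fit <- function(profiles, group = NA_character_) {
  if (inherits(profiles, "width_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("empty profile list")
  x <- unlist(lapply(profiles, `[[`, "positions_cm"))
  y <- unlist(lapply(profiles, `[[`, "half_widths_cm"))
  ord <- order(x)
  mean_len <- mean(vapply(profiles, `[[`, numeric(1L), "total_length_cm"))
  # positions repeat across leaves; jitter-free pooled profile built directly
  pooled <- structure(
    list(leaf_id = paste0("pooled:", group), group = as.character(group),
         positions_cm = x[ord], half_widths_cm = y[ord],
         total_length_cm = mean_len, interval_cm = NA_real_),
    class = "width_profile")
  fit_taper_pooled(pooled)
}

# fit_taper without the strictly-ascending position requirement (pooled
# stations repeat positions across leaves).
fit_taper_pooled <- function(profile) {
  fit_taper(structure(profile, class = "width_profile"))
}
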