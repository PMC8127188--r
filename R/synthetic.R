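#' Specify a synthetic single-vein leaf shape
#'
#' Defines the analytic half-width curve of a synthetic leaf, used as ground
#' truth for validating extraction and model fitting. Four families are
#' available:
#' \describe{
#'   \item{quadratic}{\eqn{Y = C + B_1 X + B_2 X^2}, truncated at 0. The
#'     family the taper model assumes; `coefficients` is required.}
#'   \item{ovate}{a parabolic arc with its apex at `peak_fraction` of the
#'     length (default 2/5, the theoretical ovate value), half-width 0 at the
#'     tip and a blunt base.}
#'   \item{oblong}{as ovate with default peak at 1/3 of the length.}
#'   \item{elliptic}{a true half-ellipse, widest at 1/2 of the length.}
#' }
#' The ovate/oblong arc is
#' \eqn{Y(X) = W\,[1 - ((X/L - p)/(1 - p))^2]} with \eqn{p} the peak
#' fraction, \eqn{L} the length and \eqn{W} the maximum half-width; it is the
#' idealization consistent with the quadratic taper model, so the ground-truth
#' tipping ratio of every family is recovered exactly by a quadratic fit of
#' the noise-free curve.
#'
#' @param family One of `"quadratic"`, `"ovate"`, `"oblong"`, `"elliptic"`.
#' @param length_cm Leaf length (cm), positive.
#' @param coefficients Numeric `c(C, B1, B2)` (cm, dimensionless, 1/cm);
#'   quadratic family only.
#' @param peak_fraction Position of maximum width as a fraction of length,
#'   in (0, 1); non-quadratic families. Defaults: ovate 0.4, oblong 1/3,
#'   elliptic 0.5.
#' @param max_half_width_cm Maximum half-width (cm) for non-quadratic
#'   families. Default 0.165 cm, a typical conifer half-width at the apex.
#' @param noise_sd_cm SD of additive Gaussian measurement noise on
#'   half-width (cm); sampled half-widths are truncated at 0. Default 0.
#' @param seed Integer seed making every profile drawn from this spec
#'   reproducible.
#' @return An object of class `leaf_shape_spec`. Its `true_ratio` element is
#'   the analytic tipping leaf length ratio: \eqn{-B_1/(2 B_2)/L} for the
#'   quadratic family (possibly outside (0, 1) when the printed model places
#'   the apex at or below the base), `peak_fraction` otherwise.
#' @examples
#' spec <- leaf_shape_spec("quadratic", length_cm = 4,
#'                         coefficients = c(0.120, 0.040, -0.014))
#' spec$true_ratio
#' @export
leaf_shape_spec <- function(family = c("quadratic", "ovate", "oblong", "elliptic"),
                            length_cm,
                            coefficients = NULL,
                            peak_fraction = NULL,
                            max_half_width_cm = 0.165,
                            noise_sd_cm = 0,
                            seed = 1L) {
  family <- match.arg(family)
  if (!is.numeric(length_cm) || length_cm <= 0)
    stop("length_cm must be a positive real")
  if (noise_sd_cm < 0) stop("noise_sd_cm must be non-negative")
  if (family == "quadratic") {
    if (is.null(coefficients) || length(coefficients) != 3L)
      stop("quadratic family requires coefficients = c(C, B1, B2)")
    coefficients <- as.numeric(coefficients)
    # reject curves that are negative over the entire domain
    xs <- seq(0, length_cm, length.out = 201L)
    ys <- coefficients[1L] + coefficients[2L] * xs + coefficients[3L] * xs^2
    if (all(ys <= 0))
      stop("quadratic curve is non-positive over the whole leaf")
    true_ratio <- if (coefficients[3L] != 0)
      -coefficients[2L] / (2 * coefficients[3L]) / length_cm else NA_real_
    peak_fraction <- NA_real_
  } else {
    default_peak <- c(ovate = 0.4, oblong = 1 / 3, elliptic = 0.5)[[family]]
    peak_fraction <- peak_fraction %||% default_peak
    if (peak_fraction <= 0 || peak_fraction >= 1)
      stop("peak_fraction must lie in (0, 1)")
    if (max_half_width_cm <= 0) stop("max_half_width_cm must be positive")
    coefficients <- NULL
    true_ratio <- peak_fraction
  }
  structure(
    list(family = family, length_cm = length_cm,
         coefficients = coefficients, peak_fraction = peak_fraction,
         max_half_width_cm = max_half_width_cm,
         noise_sd_cm = noise_sd_cm, seed = as.integer(seed),
         true_ratio = true_ratio),
    class = "leaf_shape_spec")
}

#' @export
print.leaf_shape_spec <- function(x, ...) {
  cat(sprintf("<leaf_shape_spec> %s, length %.3f cm, noise sd %.4f cm\n",
              x$family, x$length_cm, x$noise_sd_cm))
  invisible(x)
}

# Analytic (noise-free) half-width curve of a shape spec, truncated at 0.
half_width_curve <- function(spec, x) {
  L <- spec$length_cm
  y <- switch(spec$family,
    quadratic = {
      b <- spec$coefficients
      b[1L] + b[2L] * x + b[3L] * x^2
    },
    elliptic = {
      u <- x / L
      spec$max_half_width_cm * 2 * sqrt(pmax(0, u * (1 - u)))
    },
    { # ovate / oblong parabolic arc: apex at p*L, zero at the tip
      p <- spec$peak_fraction
      u <- x / L
      spec$max_half_width_cm * (1 - ((u - p) / (1 - p))^2)
    })
  pmax(y, 0)
}

#' Generate a width profile from a shape specification
#'
#' Samples the analytic half-width curve at a fixed interval from the base
#' (position 0) to the leaf length, adds iid Gaussian measurement noise of
#' SD `noise_sd_cm` and truncates negative samples at 0. Deterministic given
#' the spec's seed.
#'
#' @param spec A [leaf_shape_spec()].
#' @param interval_cm Sampling interval (cm), positive and smaller than the
#'   leaf length. The study convention is 0.1 or 0.2 cm.
#' @param leaf_id,group Identifiers attached to the profile.
#' @return A [width_profile()] carrying the spec and its ground-truth ratio
#'   in attribute `"ground_truth"`.
#' @examples
#' p <- generate_profile(leaf_shape_spec("elliptic", length_cm = 4))
#' max(p$half_widths_cm)
#' @export
generate_profile <- function(spec, interval_cm = 0.1,
                             leaf_id = "synthetic", group = NA_character_) {
  stopifnot(inherits(spec, "leaf_shape_spec"))
  if (interval_cm <= 0) stop("interval must be positive")
  if (interval_cm >= spec$length_cm)
    stop("interval must be smaller than the leaf length")
  x <- seq(0, spec$length_cm, by = interval_cm)
  y <- half_width_curve(spec, x)
  if (spec$noise_sd_cm > 0) {
    y <- with_seed(spec$seed, y + rnorm(length(y), 0, spec$noise_sd_cm))
    y <- pmax(y, 0)
  }
  prof <- width_profile(x, y, total_length_cm = spec$length_cm,
                        leaf_id = leaf_id, group = group,
                        interval_cm = interval_cm)
  attr(prof, "ground_truth") <- list(
    family = spec$family, coefficients = spec$coefficients,
    peak_fraction = spec$peak_fraction, true_ratio = spec$true_ratio,
    length_cm = spec$length_cm, noise_sd_cm = spec$noise_sd_cm,
    seed = spec$seed)
  prof
}

#' Specify a cohort of synthetic leaves
#'
#' A cohort emulates one stand (e.g. one tree-age group): `n_leaves` leaves
#' whose lengths are drawn from a Normal distribution truncated to positive
#' values, all sharing one shape template. Per-leaf seeds are derived
#' deterministically from the cohort's master seed, so a cohort is fully
#' reproducible from `seed` alone.
#'
#' @param group_label Cohort label (e.g. stand age in years).
#' @param n_leaves Number of leaves, at least 2.
#' @param length_mean_cm,length_sd_cm Mean and SD of leaf length (cm);
#'   `length_sd_cm >= 0`.
#' @param template A [leaf_shape_spec()] whose length is replaced per leaf.
#' @param length_max_cm Optional upper truncation for the length draw
#'   (default `Inf`). Useful when every leaf must follow the template's
#'   analytic curve exactly: a quadratic blade closes (half-width reaches 0)
#'   at the curve's positive root, so lengths beyond it are infeasible for
#'   that model.
#' @param seed Master seed for the cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_label, n_leaves, length_mean_cm,
                        length_sd_cm, template, length_max_cm = Inf,
                        seed = 1L) {
  stopifnot(inherits(template, "leaf_shape_spec"))
  if (n_leaves < 2) stop("n_leaves must be at least 2")
  if (length_sd_cm < 0) stop("length_sd_cm must be non-negative")
  if (length_mean_cm <= 0) stop("length_mean_cm must be positive")
  if (length_max_cm <= 0) stop("length_max_cm must be positive")
  structure(
    list(group_label = as.character(group_label),
         n_leaves = as.integer(n_leaves),
         length_mean_cm = length_mean_cm, length_sd_cm = length_sd_cm,
         length_max_cm = length_max_cm,
         template = template, seed = as.integer(seed)),
    class = "cohort_spec")
}

#' Generate a cohort of width profiles
#'
#' @param spec A [cohort_spec()].
#' @param interval_cm Sampling interval passed to [generate_profile()].
#' @return A list of [width_profile()]s with attribute `"ground_truth"`: a
#'   tibble of per-leaf ground-truth parameters (leaf id, group, length,
#'   true tipping ratio, sub-seed).
#' @export
generate_cohort <- function(spec, interval_cm = 0.1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_leaves
  seeds <- derive_seeds(spec$seed, n)
  lmax <- spec$length_max_cm %||% Inf
  lengths <- with_seed(spec$seed + 1L, {
    out <- numeric(n)
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        l <- rnorm(1L, spec$length_mean_cm, spec$length_sd_cm)
        if (l > interval_cm && l <= lmax) break
        tries <- tries + 1L
        if (tries > 10000L)
          stop("length distribution incompatible with (interval, length_max_cm]")
      }
      out[i] <- l
    }
    out
  })
  profiles <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    li <- spec$template
    li$length_cm <- lengths[i]
    li$seed <- seeds[i]
    if (li$family == "quadratic" && !is.null(li$coefficients) &&
        li$coefficients[3L] != 0) {
      li$true_ratio <- -li$coefficients[2L] / (2 * li$coefficients[3L]) /
        li$length_cm
    }
    id <- sprintf("%s_leaf%03d", spec$group_label, i)
    profiles[[i]] <- generate_profile(li, interval_cm, leaf_id = id,
                                      group = spec$group_label)
    truths[[i]] <- tibble(
      leaf_id = id, group = spec$group_label, length_cm = lengths[i],
      true_ratio = li$true_ratio, seed = seeds[i])
  }
  attr(profiles, "ground_truth") <- do.call(rbind, truths)
  profiles
}

#' Write per-leaf ground-truth parameters as JSON
#'
#' Sidecar metadata for a generated cohort or profile, so rendered masks can
#' be traced back to their generating parameters.
#'
#' @param profiles Output of [generate_cohort()] or a single profile.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(profiles, path) {
  if (inherits(profiles, "width_profile")) profiles <- list(profiles)
  gt <- lapply(profiles, function(p) attr(p, "ground_truth"))
  names(gt) <- vapply(profiles, function(p) p$leaf_id, character(1L))
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
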