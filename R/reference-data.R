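#' Published group-level taper models for Cunninghamia lanceolata
#'
#' The six age-group half-leaf taper models reported for *Cunninghamia
#' lanceolata* (Chinese fir) stands aged 2 to 30 years: coefficients (with
#' standard errors) of \eqn{Y = C + B_1 X + B_2 X^2}, the model \eqn{R^2},
#' and the group's leaf-length mean and SD (cm) from the accompanying trait
#' table. These published figures are the inputs for the package's demo
#' cohorts and internal-consistency checks. Note that three groups (5-,
#' 10- and 13-yr) have \eqn{B_1 \le 0}: their group-level vertex lies at or
#' below the leaf base, so no in-blade tipping ratio exists for the pooled
#' model even though per-leaf ratios were reported.
#'
#' @return A tibble with one row per age group: `age_yr`, `C`, `B1`, `B2`,
#'   `se_C`, `se_B1`, `se_B2`, `r2`, `length_mean_cm`, `length_sd_cm`,
#'   `n_leaves`.
#' @examples
#' m <- cunninghamia_taper_models()
#' taper_vertex(m$B1[m$age_yr == 30], m$B2[m$age_yr == 30])
#' @export
cunninghamia_taper_models <- function() {
  tibble(
    age_yr = c(2L, 5L, 10L, 13L, 23L, 30L),
    C   = c(0.142, 0.147, 0.142, 0.138, 0.119, 0.120),
    B1  = c(0.005, -0.008, -0.006, -0.001, 0.020, 0.040),
    B2  = c(-0.005, -0.002, -0.005, -0.002, -0.007, -0.014),
    se_C  = c(0.005, 0.005, 0.003, 0.004, 0.003, 0.003),
    se_B1 = c(0.004, 0.005, 0.003, 0.003, 0.002, 0.003),
    se_B2 = c(0.0008, 0.0009, 0.0005, 0.0004, 0.0004, 0.0007),
    r2  = c(0.357, 0.275, 0.498, 0.376, 0.542, 0.583),
    length_mean_cm = c(4.32, 3.977, 4.518, 4.887, 4.484, 4.024),
    length_sd_cm   = c(1.075, 0.904, 0.99, 1.169, 0.899, 0.424),
    n_leaves = rep(18L, 6L))
}

# Published trait table, built from the printed strings so that each cell's
# decimal precision is preserved for rounding-aware consistency checks.
trait_rows <- function(trait, rows) {
  parse1 <- function(r) {
    tibble(trait = trait, group = r[[1L]], n = as.integer(r[[2L]]),
           mean_chr = r[[3L]], sd_chr = r[[4L]], letters = r[[5L]],
           se_chr = r[[6L]], cv_chr = r[[7L]],
           ci_low = as.numeric(r[[8L]]), ci_high = as.numeric(r[[9L]]),
           median = as.numeric(r[[10L]]), min = as.numeric(r[[11L]]),
           max = as.numeric(r[[12L]]))
  }
  do.call(rbind, lapply(rows, parse1))
}

#' Published trait summary table for Cunninghamia lanceolata
#'
#' The published per-age-group descriptive statistics for four leaf traits
#' of *C. lanceolata*: width (all station measurements), maximum leaf
#' width, leaf length and the half-leaf tipping length ratio. Each row
#' carries n, mean, SD, Fisher-LSD letters, SE, CV%, the 95% confidence
#' interval of the mean, median, minimum and maximum as printed; numeric
#' columns `mean`, `sd`, `se`, `cv_percent` are parsed from the printed
#' strings, and `*_dp` columns record the printed decimal places so
#' rounding-aware checks can propagate the display precision.
#'
#' @return A tibble with 28 rows (4 traits x 6 age groups + totals).
#' @seealso [check_summary_consistency()]
#' @export
cunninghamia_trait_table <- function() {
  w <- trait_rows("width_cm", list(
    list("2", 386, "0.241", "0.098", "ab", "0.005", "40.664", 0.231, 0.251, 0.252, 0.002, 0.473),
    list("5", 367, "0.234", "0.093", "ab", "0.005", "39.744", 0.225, 0.244, 0.24, 0.004, 0.437),
    list("10", 804, "0.234", "0.09", "a", "0.003", "38.462", 0.228, 0.24, 0.246, 0.01, 0.434),
    list("13", 452, "0.23", "0.081", "ac", "0.004", "35.217", 0.223, 0.238, 0.247, 0.005, 0.361),
    list("23", 861, "0.222", "0.08", "c", "0.003", "36.036", 0.217, 0.228, 0.236, 0.012, 0.388),
    list("30", 740, "0.242", "0.084", "b", "0.003", "34.711", 0.236, 0.249, 0.258, 0.013, 0.387),
    list("Total", 3610, "0.233", "0.087", "", "0.001", "37.339", 0.23, 0.236, 0.246, 0.002, 0.473)))
  mw <- trait_rows("max_width_cm", list(
    list("2", 18, "0.346", "0.055", "a", "0.013", "16.021", 0.319, 0.374, 0.335, 0.277, 0.473),
    list("5", 18, "0.330", "0.042", "ab", "0.010", "12.699", 0.310, 0.351, 0.326, 0.277, 0.437),
    list("10", 18, "0.331", "0.048", "ab", "0.011", "14.628", 0.307, 0.356, 0.326, 0.262, 0.434),
    list("13", 18, "0.320", "0.026", "ab", "0.006", "8.096", 0.307, 0.333, 0.328, 0.266, 0.361),
    list("23", 18, "0.334", "0.034", "ab", "0.008", "10.176", 0.317, 0.351, 0.334, 0.278, 0.387),
    list("30", 18, "0.310", "0.040", "b", "0.009", "12.925", 0.290, 0.330, 0.311, 0.204, 0.388),
    list("Total", 108, "0.329", "0.043", "", "0.004", "12.970", 0.321, 0.337, 0.327, 0.204, 0.473)))
  ln <- trait_rows("length_cm", list(
    list("2", 18, "4.32", "1.075", "ab", "0.253", "24.884", 3.785, 4.854, 4.240, 2.881, 6.823),
    list("5", 18, "3.977", "0.904", "a", "0.213", "22.731", 3.527, 4.426, 3.95, 2.433, 6.421),
    list("10", 18, "4.518", "0.99", "ab", "0.233", "21.912", 4.025, 5.01, 4.311, 2.76, 6.158),
    list("13", 18, "4.887", "1.169", "b", "0.276", "23.921", 4.306, 5.469, 4.430, 3.702, 7.826),
    list("23", 18, "4.484", "0.899", "ab", "0.212", "20.049", 4.036, 4.931, 4.690, 2.879, 6.092),
    list("30", 18, "4.024", "0.424", "a", "0.100", "10.537", 3.814, 4.235, 4.110, 3.225, 4.887),
    list("Total", 108, "4.368", "0.97", "", "0.093", "22.207", 4.183, 4.553, 4.243, 2.433, 7.826)))
  tr <- trait_rows("tipping_ratio", list(
    list("2", 18, "0.34", "0.051", "ab", "0.012", "15.000", 0.315, 0.366, 0.348, 0.191, 0.425),
    list("5", 18, "0.328", "0.075", "ab", "0.018", "22.866", 0.291, 0.365, 0.345, 0.183, 0.41),
    list("10", 18, "0.303", "0.08", "a", "0.019", "26.403", 0.264, 0.343, 0.319, 0.123, 0.409),
    list("13", 18, "0.365", "0.051", "bc", "0.012", "13.973", 0.34, 0.391, 0.362, 0.272, 0.441),
    list("23", 18, "0.381", "0.104", "c", "0.024", "27.297", 0.33, 0.433, 0.408, 0.1, 0.525),
    list("30", 18, "0.361", "0.106", "c", "0.025", "29.363", 0.308, 0.414, 0.358, 0.155, 0.593),
    list("Total", 108, "0.347", "0.083", "", "0.008", "23.919", 0.331, 0.362, 0.352, 0.1, 0.593)))
  tab <- rbind(w, mw, ln, tr)
  dp <- function(chr) {
    ifelse(grepl("\\.", chr), nchar(sub("^[^.]*\\.", "", chr)), 0L)
  }
  tab$mean <- as.numeric(tab$mean_chr)
  tab$sd <- as.numeric(tab$sd_chr)
  tab$se <- as.numeric(tab$se_chr)
  tab$cv_percent <- as.numeric(tab$cv_chr)
  tab$mean_dp <- dp(tab$mean_chr)
  tab$sd_dp <- dp(tab$sd_chr)
  tab$se_dp <- dp(tab$se_chr)
  tab$cv_dp <- dp(tab$cv_chr)
  tab[, c("trait", "group", "n", "mean", "sd", "letters", "se",
          "cv_percent", "ci_low", "ci_high", "median", "min", "max",
          "mean_dp", "sd_dp", "se_dp", "cv_dp")]
}

#' Check internal consistency of a printed trait table
#'
#' Recomputes SE = SD/sqrt(n) and CV% = 100 SD/mean from a summary table's
#' own mean, SD and n columns and compares them with the table's printed SE
#' and CV cells. Because the inputs are themselves rounded for display, the
#' comparison tolerance propagates a half unit in the last printed place of
#' each input plus a half unit of the printed target cell.
#'
#' @param tab A table in the shape of [cunninghamia_trait_table()].
#' @return `tab` augmented with `se_calc`, `cv_calc`, `se_tol`, `cv_tol`,
#'   `se_match` and `cv_match`.
#' @examples
#' all(check_summary_consistency()$se_match)
#' @export
check_summary_consistency <- function(tab = cunninghamia_trait_table()) {
  half_ulp <- function(d) 0.5 * 10^(-d)
  dm <- half_ulp(tab$mean_dp)
  ds <- half_ulp(tab$sd_dp)
  tab$se_calc <- tab$sd / sqrt(tab$n)
  tab$cv_calc <- 100 * tab$sd / tab$mean
  tab$se_tol <- half_ulp(tab$se_dp) + ds / sqrt(tab$n)
  tab$cv_tol <- half_ulp(tab$cv_dp) +
    100 * ((tab$sd + ds) / (tab$mean - dm) - tab$sd / tab$mean)
  tab$se_match <- abs(tab$se_calc - tab$se) <= tab$se_tol
  tab$cv_match <- abs(tab$cv_calc - tab$cv_percent) <= tab$cv_tol
  tab
}
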