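#' Descriptive summary of one cohort
#'
#' Summary-table row for one trait in one group: n, mean, SD (n-1
#' denominator), SE = SD/sqrt(n), CV% = 100 SD/mean, a t-based confidence
#' interval for the mean, median, minimum and maximum. With n < 2 the
#' dispersion fields are `NA`.
#'
#' @param values Numeric trait values.
#' @param group Group label for the row.
#' @param confidence Confidence level for the interval (default 0.95).
#' @return A one-row tibble with columns `group`, `n`, `mean`, `sd`, `se`,
#'   `cv_percent`, `ci_low`, `ci_high`, `median`, `min`, `max`.
#' @examples
#' cohort_summary(rnorm(18, 4.0, 0.4), group = "30")
#' @export
cohort_summary <- function(values, group = "all", confidence = 0.95) {
  values <- as.numeric(values[!is.na(values)])
  n <- length(values)
  if (n == 0L)
    return(tibble(group = as.character(group), n = 0L, mean = NA_real_,
                  sd = NA_real_, se = NA_real_, cv_percent = NA_real_,
                  ci_low = NA_real_, ci_high = NA_real_, median = NA_real_,
                  min = NA_real_, max = NA_real_))
  m <- mean(values)
  if (n < 2L) {
    s <- se <- cv <- lo <- hi <- NA_real_
  } else {
    s <- sd(values)
    se <- s / sqrt(n)
    cv <- if (m != 0) 100 * s / m else NA_real_
    tq <- qt(1 - (1 - confidence) / 2, df = n - 1)
    lo <- m - tq * se
    hi <- m + tq * se
  }
  tibble(group = as.character(group), n = n, mean = m, sd = s, se = se,
         cv_percent = cv, ci_low = lo, ci_high = hi,
         median = median(values), min = min(values), max = max(values))
}

#' Summarize a trait by group
#'
#' Applies [cohort_summary()] to each group and appends a pooled `Total`
#' row, mirroring a per-trait block of a descriptive trait table.
#'
#' @param values Numeric trait values.
#' @param groups Group labels, same length as `values`.
#' @param confidence Confidence level for the mean's interval.
#' @param total_label Label for the pooled row (`NULL` to omit).
#' @return A tibble with one row per group plus the pooled row.
#' @export
summarize_by_group <- function(values, groups, confidence = 0.95,
                               total_label = "Total") {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  out <- lapply(sort(unique(groups)), function(g)
    cohort_summary(values[groups == g], group = g, confidence = confidence))
  if (!is.null(total_label))
    out <- c(out, list(cohort_summary(values, group = total_label,
                                      confidence = confidence)))
  do.call(rbind, out)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around [stats::shapiro.test()] returning the W statistic
#' and p-value; requires 3 <= n <= 5000 non-degenerate values.
#'
#' @param values Numeric sample.
#' @return A list with elements `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 3L) stop("normality check requires at least 3 values")
  ht <- shapiro.test(values)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}

#' Log10-transform tipping ratios
#'
#' The ratio is log10-transformed before the group comparison (its raw
#' distribution is right-skewed and bounded); descriptive summaries stay on
#' the raw scale. Non-positive values are rejected with the offending ids
#' named.
#'
#' @param values Positive ratios.
#' @param ids Optional identifiers used in the error message.
#' @return `log10(values)`.
#' @examples
#' log10_ratio(c(1, 10, 100))
#' @export
log10_ratio <- function(values, ids = NULL) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    lab <- if (!is.null(ids)) paste(ids[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("non-positive ratio for: ", lab)
  }
  log10(values)
}

# Insert-and-absorb compact letter display. `sig` is a logical matrix
# (TRUE = significantly different) over groups ordered by descending mean.
# Guarantees: significant pairs share no letter; non-significant pairs share
# at least one.
cld_insert_absorb <- function(sig) {
  k <- nrow(sig)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      if (!sig[i, j]) next
      hit <- which(vapply(cols, function(cl) i %in% cl && j %in% cl,
                          logical(1L)))
      for (h in hit) {
        cl <- cols[[h]]
        cols[[h]] <- setdiff(cl, i)
        cols[[length(cols) + 1L]] <- setdiff(cl, j)
      }
      # absorb: drop duplicates and columns contained in another column
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a == b || drop[a] || drop[b]) next
          if (all(cols[[a]] %in% cols[[b]])) {
            if (all(cols[[b]] %in% cols[[a]])) {
              if (a > b) drop[a] <- TRUE
            } else drop[a] <- TRUE
          }
        }
      }
      cols <- cols[!drop]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1L)))]
  letters_out <- vapply(seq_len(k), function(g)
    paste0(letters[which(vapply(cols, function(cl) g %in% cl, logical(1L)))],
           collapse = ""),
    character(1L))
  letters_out
}

#' One-way ANOVA with Fisher LSD compact letters
#'
#' Classical one-way ANOVA (omnibus F against the pooled within-group mean
#' square) followed by unprotected Fisher LSD pairwise t-tests — every pair
#' is tested with the pooled MSE and its error degrees of freedom,
#' regardless of the omnibus result, matching common statistical-software
#' behaviour of the "LSD" option. Groups are assigned compact letters by
#' the insert-and-absorb algorithm in descending-mean order: groups sharing
#' no letter differ at level `alpha`.
#'
#' @param values Numeric observations.
#' @param groups Group labels, same length as `values`; at least two groups
#'   with n >= 2 each.
#' @param alpha Significance level for the pairwise decisions (default 0.05).
#' @return An object of class `anova_lsd`: `F`, `p`, `df_between`,
#'   `df_within`, `mse`, `alpha`, `groups` (tibble with `group`, `n`,
#'   `mean`, `letters`, ordered by descending mean) and `pairwise`
#'   (matrix of LSD p-values).
#' @examples
#' set.seed(1)
#' anova_lsd(c(rnorm(18, 0), rnorm(18, 1)), rep(c("a", "b"), each = 18))
#' @export
anova_lsd <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values)
  values <- as.numeric(values[keep])
  groups <- factor(as.character(groups)[keep])
  k <- nlevels(groups)
  if (k < 2L) stop("at least two groups are required")
  ns <- table(groups)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[groups])^2)
  df_between <- k - 1L
  df_within <- N - k
  mse <- ss_within / df_within
  if (ss_within == 0) {
    # all observations identical, or perfect group separation
    Fstat <- if (ss_between == 0) 0 else Inf
    pval <- if (ss_between == 0) 1 else 0
  } else {
    ht <- oneway.test(values ~ groups, var.equal = TRUE)
    Fstat <- unname(ht$statistic)
    pval <- unname(ht$p.value)
  }
  ord <- order(means, decreasing = TRUE)
  lev <- levels(groups)[ord]
  mo <- means[ord]; no <- ns[ord]
  pmat <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { pmat[i, j] <- 1; next }
      se_ij <- sqrt(mse * (1 / no[i] + 1 / no[j]))
      d <- mo[i] - mo[j]
      pmat[i, j] <- if (se_ij == 0) as.numeric(d == 0)
                    else 2 * pt(-abs(d / se_ij), df_within)
    }
  }
  sig <- pmat < alpha
  letts <- cld_insert_absorb(sig)
  structure(
    list(F = Fstat, p = pval, df_between = df_between,
         df_within = df_within, mse = mse, alpha = alpha,
         groups = tibble(group = lev, n = as.integer(no),
                         mean = as.numeric(mo), letters = letts),
         pairwise = pmat),
    class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("<anova_lsd> F(%d, %d) = %.4f, p = %.4g (alpha = %g)\n",
              x$df_between, x$df_within, x$F, x$p, x$alpha))
  print(as.data.frame(x$groups))
  invisible(x)
}
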