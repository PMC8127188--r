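#' Width profile of a single leaf
#'
#' A width profile holds ordered samples of leaf half-width against position
#' along the midrib, measured from the base (position 0), together with the
#' total leaf length \eqn{X_{max}}. All units are cm.
#'
#' @param positions_cm Ascending positions along the midrib, starting at 0.
#' @param half_widths_cm Non-negative half-widths, one per position.
#' @param total_length_cm Total leaf length \eqn{X_{max}}; defaults to the
#'   last position.
#' @param leaf_id Identifier for the leaf.
#' @param group Optional cohort label (e.g. stand age).
#' @param interval_cm Sampling interval; inferred from positions when absent.
#' @return An object of class `width_profile`.
#' @export
width_profile <- function(positions_cm, half_widths_cm,
                          total_length_cm = NULL,
                          leaf_id = "leaf", group = NA_character_,
                          interval_cm = NULL) {
  positions_cm <- as.numeric(positions_cm)
  half_widths_cm <- as.numeric(half_widths_cm)
  if (length(positions_cm) != length(half_widths_cm))
    stop("positions and half-widths must have equal length")
  if (length(positions_cm) < 1L) stop("empty profile")
  if (is.unsorted(positions_cm, strictly = TRUE))
    stop("positions must be strictly ascending")
  if (abs(positions_cm[1L]) > 1e-9)
    stop("profile must start at position 0")
  if (any(half_widths_cm < 0)) stop("half-widths must be non-negative")
  total_length_cm <- total_length_cm %||% max(positions_cm)
  if (total_length_cm <= 0) stop("total length must be positive")
  if (max(positions_cm) > total_length_cm + 1e-9)
    stop("positions exceed total length")
  if (is.null(interval_cm)) {
    interval_cm <- if (length(positions_cm) > 1L)
      median(diff(positions_cm)) else NA_real_
  }
  structure(
    list(leaf_id = as.character(leaf_id), group = as.character(group),
         positions_cm = positions_cm, half_widths_cm = half_widths_cm,
         total_length_cm = as.numeric(total_length_cm),
         interval_cm = interval_cm),
    class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf(
    "<width_profile> %s%s: %d stations, length %.3f cm, max half-width %.3f cm\n",
    x$leaf_id, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    length(x$positions_cm), x$total_length_cm, max(x$half_widths_cm)))
  invisible(x)
}

#' @export
as.data.frame.width_profile <- function(x, ...) {
  data.frame(leaf_id = x$leaf_id, group = x$group,
             position_cm = x$positions_cm,
             half_width_cm = x$half_widths_cm,
             total_length_cm = x$total_length_cm,
             stringsAsFactors = FALSE)
}

#' Write width profiles to CSV
#'
#' One row per station with columns `leaf_id`, `group`, `position_cm`,
#' `half_width_cm`, `total_length_cm`.
#'
#' @param profiles A `width_profile` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  if (inherits(profiles, "width_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read width profiles from CSV
#'
#' Inverse of [write_profiles_csv()].
#'
#' @param path CSV path with the profile schema.
#' @return A list of `width_profile` objects, one per `leaf_id`.
#' @export
read_profiles_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("leaf_id", "position_cm", "half_width_cm")
  if (!all(need %in% names(df)))
    stop("profile CSV must contain columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$leaf_id), function(d) {
    d <- d[order(d$position_cm), , drop = FALSE]
    width_profile(
      d$position_cm, d$half_width_cm,
      total_length_cm = if ("total_length_cm" %in% names(d))
        d$total_length_cm[1L] else NULL,
      leaf_id = d$leaf_id[1L],
      group = if ("group" %in% names(d)) as.character(d$group[1L])
              else NA_character_)
  })
}
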