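#' Read and validate a pipeline run configuration
#'
#' A run configuration describes an end-to-end analysis: which stages to
#' run (`simulate`, `extract`, `fit`, `stats`, `report`), measurement
#' settings (`dpi`, `interval_cm`), statistical settings (`alpha`,
#' `confidence`, `transform`), the master `seed`, and either synthetic
#' group definitions (`groups`) or an `input_dir` of leaf images.
#' Configurations may be given as an R list or as a JSON/YAML file.
#'
#' @param config A list, or path to a `.json`/`.yaml`/`.yml` file.
#' @return A validated config list with defaults filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      json = jsonlite::read_json(config, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE),
      yaml = ,
      yml = yaml::read_yaml(config),
      stop("unsupported config format: ", ext))
  }
  stopifnot(is.list(config))
  cfg <- list(
    stages = config$stages %||% c("simulate", "fit", "stats", "report"),
    dpi = config$dpi %||% 600L,
    interval_cm = config$interval_cm %||% 0.1,
    alpha = config$alpha %||% 0.05,
    confidence = config$confidence %||% 0.95,
    transform = config$transform %||% "log10",
    rasterize = isTRUE(config$rasterize),
    seed = config$seed,
    input_dir = config$input_dir,
    groups = config$groups)
  known <- c("simulate", "extract", "fit", "stats", "report")
  if (!all(cfg$stages %in% known))
    stop("unknown stage(s): ",
         paste(setdiff(cfg$stages, known), collapse = ", "))
  if (!cfg$transform %in% c("none", "log10"))
    stop("transform must be 'none' or 'log10'")
  simulating <- "simulate" %in% cfg$stages
  if (simulating) {
    if (is.null(cfg$seed)) stop("seed is mandatory when simulating")
    if (is.null(cfg$groups) || !length(cfg$groups))
      stop("simulate stage requires group definitions")
  }
  if (!is.null(cfg$groups) && length(cfg$groups)) {
    labs <- vapply(cfg$groups, function(g) as.character(g$label),
                   character(1L))
    if (anyDuplicated(labs)) stop("duplicated group labels")
    # canonical group order, so per-group sub-seeds attach to labels and
    # shuffled input order yields identical reports
    cfg$groups <- cfg$groups[match(sort_group_labels(labs), labs)]
  }
  if ("extract" %in% cfg$stages && !simulating) {
    if (is.null(cfg$input_dir))
      stop("extract stage requires input_dir with leaf images")
    if (!dir.exists(cfg$input_dir))
      stop("input_dir does not exist: ", cfg$input_dir)
    imgs <- list.files(cfg$input_dir, "\\.(png|tif|tiff)$",
                       ignore.case = TRUE, recursive = TRUE)
    if (!length(imgs))
      stop("no PNG/TIFF images found in ", cfg$input_dir)
  }
  cfg
}

#' Demo configuration: six published age-group cohorts
#'
#' A ready-made synthetic study: six cohorts of 18 leaves whose half-width
#' curves follow the six published group-level taper models
#' ([cunninghamia_taper_models()]), with leaf lengths drawn from each
#' group's published mean and SD and no measurement noise, so the fits
#' recover the published coefficients exactly. Lengths are capped at each
#' group's blade-closure point (the positive root of its quadratic): a leaf
#' longer than that cannot follow its model, its half-width having already
#' reached 0. The same configuration ships as `demo-config.json` in the
#' package's `extdata`.
#'
#' @param seed Master seed.
#' @param noise_sd_cm Measurement noise SD (cm); default 0.
#' @param n_leaves Leaves per cohort; default 18, the published per-group n.
#' @return A config list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, noise_sd_cm = 0, n_leaves = 18L) {
  m <- cunninghamia_taper_models()
  groups <- lapply(seq_len(nrow(m)), function(i) {
    list(label = as.character(m$age_yr[i]),
         n_leaves = n_leaves,
         length_mean_cm = m$length_mean_cm[i],
         length_sd_cm = m$length_sd_cm[i],
         length_max_cm = quadratic_blade_limit(m$C[i], m$B1[i], m$B2[i]),
         family = "quadratic",
         coefficients = c(m$C[i], m$B1[i], m$B2[i]),
         noise_sd_cm = noise_sd_cm)
  })
  list(seed = as.integer(seed), groups = groups,
       stages = c("simulate", "fit", "stats", "report"))
}

# Positive root of C + B1 x + B2 x^2 for a concave curve: the position at
# which the blade closes (half-width 0); Inf when the curve never closes.
quadratic_blade_limit <- function(C, B1, B2) {
  if (B2 >= 0) return(Inf)
  disc <- B1^2 - 4 * B2 * C
  if (disc <= 0) return(Inf)
  (-B1 - sqrt(disc)) / (2 * B2)
}

group_shape_spec <- function(g, seed) {
  leaf_shape_spec(
    family = g$family %||% "quadratic",
    length_cm = g$length_mean_cm,
    coefficients = g$coefficients,
    peak_fraction = g$peak_fraction,
    max_half_width_cm = g$max_half_width_cm %||% 0.165,
    noise_sd_cm = g$noise_sd_cm %||% 0,
    seed = seed)
}

# canonical group order: numeric when all labels parse as numbers
sort_group_labels <- function(labels) {
  u <- unique(labels)
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' Run the leaf-taper pipeline
#'
#' Executes the requested stages in order — simulate (or read images and
#' extract), fit, stats, report — and returns a run report. Synthetic
#' cohorts are generated with per-group sub-seeds derived from the master
#' seed, so a run is fully reproducible from its configuration; with
#' `rasterize = TRUE` each simulated profile additionally passes through
#' the full image round trip (render to a binary mask at `dpi`, then
#' re-extract the profile) before fitting.
#'
#' The report contains the per-leaf fits (trait-table analogue of the
#' per-leaf regressions), per-group pooled taper models, descriptive
#' summaries of the four leaf traits (length, mean width, maximum width,
#' tipping ratio — ratio summaries use valid fits only), ANOVA with Fisher
#' LSD letters per trait (the ratio is compared on the log10 scale by
#' default and also on the raw scale), a QC table counting invalid fits by
#' reason, and a structured per-leaf log.
#'
#' @param config A config list or path; see [read_run_config()].
#' @param output_dir Optional directory; when given, all report tables are
#'   written there as CSV (plus the run log and the echoed config as JSON).
#' @return An object of class `leaf_run_report`.
#' @examples
#' \donttest{
#' rep <- run_pipeline(demo_config(seed = 1))
#' rep$group_models
#' }
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- read_run_config(config)
  log <- list()
  note <- function(stage, msg, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage, message = msg),
                                  list(...))
  }
  profiles <- list()
  truths <- NULL

  if ("simulate" %in% cfg$stages) {
    seeds <- derive_seeds(cfg$seed, length(cfg$groups))
    for (i in seq_along(cfg$groups)) {
      g <- cfg$groups[[i]]
      cs <- cohort_spec(g$label, g$n_leaves, g$length_mean_cm,
                        g$length_sd_cm %||% 0,
                        template = group_shape_spec(g, seeds[i]),
                        length_max_cm = g$length_max_cm %||% Inf,
                        seed = seeds[i])
      cohort <- generate_cohort(cs, interval_cm = cfg$interval_cm)
      truths <- rbind(truths, attr(cohort, "ground_truth"))
      profiles <- c(profiles, cohort)
      note("simulate", sprintf("group %s: %d leaves", g$label, length(cohort)))
    }
    if (cfg$rasterize) {
      profiles <- lapply(profiles, function(p) {
        mask <- render_mask(p, dpi = cfg$dpi)
        q <- measure_profile(binarize(mask), interval_cm = cfg$interval_cm)
        q$group <- p$group
        q$leaf_id <- p$leaf_id
        q
      })
      note("simulate", sprintf("rasterized %d leaves at %d dpi",
                               length(profiles), cfg$dpi))
    }
  } else if ("extract" %in% cfg$stages) {
    paths <- list.files(cfg$input_dir, "\\.(png|tif|tiff)$",
                        full.names = TRUE, ignore.case = TRUE,
                        recursive = TRUE)
    for (pth in paths) {
      id <- tools::file_path_sans_ext(basename(pth))
      mask <- tryCatch(
        binarize(read_leaf_image(pth), dpi = cfg$dpi, leaf_id = id),
        error = function(e)
          stop("extract failed for ", pth, ": ", conditionMessage(e)))
      prof <- measure_profile(mask, interval_cm = cfg$interval_cm)
      # images carry no cohort label; group by the immediate parent folder
      prof$group <- basename(dirname(pth))
      profiles[[length(profiles) + 1L]] <- prof
      note("extract", "measured profile", leaf_id = id)
    }
  }
  if (!length(profiles)) stop("no profiles to analyse")

  fits <- NULL
  if ("fit" %in% cfg$stages) {
    fits <- batch_fit(profiles)
    for (i in seq_len(nrow(fits)))
      note("fit", fits$invalid_reason[i], leaf_id = fits$leaf_id[i],
           valid = fits$valid[i])
  }

  qc <- summaries <- anova_results <- group_models <- NULL
  if (!is.null(fits)) {
    glab <- sort_group_labels(fits$group)
    qc <- do.call(rbind, lapply(glab, function(g) {
      f <- fits[fits$group == g, ]
      tibble(group = g, n_leaves = nrow(f), n_valid = sum(f$valid),
             n_B2_nonnegative = sum(f$invalid_reason == "B2_nonnegative"),
             n_vertex_out_of_range =
               sum(f$invalid_reason == "vertex_out_of_range"),
             n_too_few_points = sum(f$invalid_reason == "too_few_points"))
    }))
    group_models <- do.call(rbind, lapply(glab, function(g) {
      pf <- pooled_fit(profiles[vapply(profiles, function(p)
        identical(p$group, g), logical(1L))], group = g)
      tibble(group = g, C = pf$C, B1 = pf$B1, B2 = pf$B2,
             r2 = pf$r2, adj_r2 = pf$adj_r2, n_points = pf$n_points,
             X0 = pf$X0, Xmax = pf$Xmax, tipping_ratio = pf$tipping_ratio,
             valid = pf$valid)
    }))
  }

  if ("stats" %in% cfg$stages && !is.null(fits)) {
    traits <- list(length_cm = fits$length_cm,
                   mean_width_cm = fits$mean_width_cm,
                   max_width_cm = fits$max_width_cm)
    ok <- fits$valid & !is.na(fits$tipping_ratio)
    summaries <- do.call(rbind, lapply(names(traits), function(tr) {
      s <- summarize_by_group(traits[[tr]], fits$group,
                              confidence = cfg$confidence)
      s <- cbind(tibble(trait = tr), s)
      s
    }))
    if (any(ok)) {
      sr <- summarize_by_group(fits$tipping_ratio[ok], fits$group[ok],
                               confidence = cfg$confidence)
      summaries <- rbind(summaries, cbind(tibble(trait = "tipping_ratio"), sr))
    }
    anova_results <- list()
    for (tr in names(traits)) {
      if (length(unique(fits$group)) >= 2L)
        anova_results[[tr]] <- anova_lsd(traits[[tr]], fits$group,
                                         alpha = cfg$alpha)
    }
    if (any(ok) && length(unique(fits$group[ok])) >= 2L &&
        all(table(fits$group[ok]) >= 2L)) {
      anova_results$tipping_ratio_raw <-
        anova_lsd(fits$tipping_ratio[ok], fits$group[ok], alpha = cfg$alpha)
      if (cfg$transform == "log10")
        anova_results$tipping_ratio_log10 <-
          anova_lsd(log10_ratio(fits$tipping_ratio[ok], fits$leaf_id[ok]),
                    fits$group[ok], alpha = cfg$alpha)
    }
    note("stats", sprintf("summarized %d traits", length(traits) + any(ok)))
  }

  report <- structure(
    list(config = cfg, profiles = profiles, ground_truth = truths,
         fits = fits, qc = qc, group_models = group_models,
         summaries = summaries, anova = anova_results, log = log),
    class = "leaf_run_report")

  if ("report" %in% cfg$stages && !is.null(output_dir))
    report_tables(report, output_dir)
  report
}

#' @export
print.leaf_run_report <- function(x, ...) {
  cat(sprintf("<leaf_run_report> %d leaves", length(x$profiles)))
  if (!is.null(x$fits))
    cat(sprintf(", %d fits (%d valid)", nrow(x$fits), sum(x$fits$valid)))
  cat("\n")
  if (!is.null(x$qc)) print(as.data.frame(x$qc))
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) round(v, digits))
  df
}

#' Write the report tables of a pipeline run
#'
#' Writes deterministic CSV artifacts: `fits.csv` (one row per leaf, the
#' per-leaf regression table), `trait_summary.csv` (one row per group per
#' trait, with a pooled Total row), `group_models.csv` (pooled per-group
#' taper models), `anova_letters.csv` (F, p and compact letters per trait),
#' `qc.csv`, per-group density tables for maximum width and tipping ratio,
#' `run_log.jsonl` and `config.json`. Groups are written in canonical
#' order and numeric report columns are rounded (3 decimals for traits and
#' ratios, 6 for regression coefficients), so identical runs produce
#' byte-identical files. An empty fits table yields headers-only outputs
#' with a warning.
#'
#' @param report A `leaf_run_report` from [run_pipeline()].
#' @param output_dir Directory to write into (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_tables <- function(report, output_dir) {
  stopifnot(inherits(report, "leaf_run_report"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(df, name, digits = 3L) {
    p <- file.path(output_dir, name)
    if (is.null(df) || !nrow(df)) {
      warning("empty table: ", name, " written headers-only")
      if (is.null(df)) df <- tibble()
    }
    write.csv(round_df(as.data.frame(df), digits), p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  fits <- report$fits
  if (!is.null(fits) && nrow(fits)) {
    fits <- fits[order(match(fits$group, sort_group_labels(fits$group)),
                       fits$leaf_id), ]
    stopifnot(!anyDuplicated(fits$leaf_id))  # id accounting: one row per leaf
  }
  emit(fits, "fits.csv", digits = 6L)
  emit(report$summaries, "trait_summary.csv", digits = 3L)
  emit(report$group_models, "group_models.csv", digits = 6L)
  emit(report$qc, "qc.csv")
  if (!is.null(report$anova)) {
    an <- do.call(rbind, lapply(names(report$anova), function(tr) {
      a <- report$anova[[tr]]
      cbind(tibble(trait = tr), a$groups,
            tibble(F = a$F, p = a$p,
                   df_between = a$df_between, df_within = a$df_within))
    }))
    emit(an, "anova_letters.csv", digits = 6L)
  }
  if (!is.null(fits) && nrow(fits)) {
    dens <- function(values, groups) {
      do.call(rbind, lapply(sort_group_labels(groups), function(g) {
        v <- values[groups == g & !is.na(values)]
        if (length(v) < 2L || sd(v) == 0) return(NULL)
        d <- density(v, n = 128L)
        tibble(group = g, x = d$x, density = d$y)
      }))
    }
    emit(dens(fits$max_width_cm, fits$group), "density_max_width.csv",
         digits = 6L)
    ok <- fits$valid & !is.na(fits$tipping_ratio)
    if (any(ok))
      emit(dens(fits$tipping_ratio[ok], fits$group[ok]),
           "density_tipping_ratio.csv", digits = 6L)
  }
  logp <- file.path(output_dir, "run_log.jsonl")
  writeLines(vapply(report$log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE), character(1L)), logp)
  cfgp <- file.path(output_dir, "config.json")
  jsonlite::write_json(report$config, cfgp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, logp, cfgp))
}
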