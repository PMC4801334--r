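#' Run the full foraging analysis
#'
#' Orchestrates an end-to-end run from a single configuration: load (or
#' generate) the three survey tables, cross-validate them, estimate
#' availability per territory and per site, test dietary selectivity and
#' compute selection ratios per site class, compare live cover between the
#' low and high sites, fit the territory-size power law and the Spearman
#' correlations, and summarise feeding rates.
#'
#' `config` is a list (or path to a JSON file) with either an `input` block —
#' `list(points = , bites = , territories = )` file paths — or a `synthetic`
#' block of [synthetic_config()] arguments, but not both. Optional elements:
#' `alpha` (default 0.05), `pooling` (availability pooling mode), `unit`
#' (sampling unit for the use matrix), `seed` (overrides the synthetic seed),
#' `out_dir` (when given, all stage outputs, `report.json` and `report.txt`
#' are written there).
#'
#' Validation findings never abort silently: hard errors raise a classed
#' condition (`coralforage_validation_error`) carrying the report.
#'
#' @param config List or JSON file path, as above.
#' @return A `foraging_analysis` object (list of all stage results), with a
#'   Table-style text rendering via `print()` / [report_text()].
#' @export
run_analysis <- function(config) {
  cfg <- load_run_config(config)
  sch <- cfg$scheme

  if (!is.null(cfg$synthetic)) {
    sim <- generate_survey(cfg$synthetic)
    points <- sim$points; bites <- sim$bites; territories <- sim$territories
    truth <- sim$truth
  } else {
    points <- read_point_counts(cfg$input$points, sch)
    bites <- read_bite_records(cfg$input$bites, sch, n_periods = cfg$n_periods)
    territories <- read_territories(cfg$input$territories)
    truth <- NULL
  }

  expected_points <- cfg$photos_per_territory * cfg$points_per_photo
  validation <- validate_dataset(points, bites, territories, sch,
                                 expected_points = expected_points,
                                 n_periods = cfg$n_periods)
  if (length(validation$errors)) {
    rlang::abort(
      c("Dataset failed validation:", validation$errors),
      class = "coralforage_validation_error",
      report = validation
    )
  }

  profiles <- availability_profiles(points, sch)

  site_classes <- intersect(c("low", "intermediate", "high"),
                            unique(territories$site_class))
  avail <- list(); selectivity <- list(); rsf <- list()
  for (s in site_classes) {
    tids <- territories$territory_id[territories$site_class == s]
    if (!any(bites$territory_id %in% tids)) next
    avail[[s]] <- site_availability(points, tids, sch, site_class = s,
                                    pooling = cfg$pooling)
    use <- build_use_matrix(bites, sch, territory_ids = tids, unit = cfg$unit)
    selectivity[[s]] <- suppressWarnings(chi2_log_likelihood(use, avail[[s]]))
    rsf[[s]] <- selection_functions(use, avail[[s]], alpha = cfg$alpha)
  }

  covers <- dplyr::inner_join(
    profiles[c("territory_id", "live_cover")], territories, by = "territory_id"
  )
  cover_comparison <- NULL
  if (sum(covers$site_class == "low") >= 2 && sum(covers$site_class == "high") >= 2) {
    cover_comparison <- compare_cover(
      100 * covers$live_cover[covers$site_class == "low"],
      100 * covers$live_cover[covers$site_class == "high"]
    )
  }

  rates <- feeding_rates(bites, n_periods = cfg$n_periods)
  terr_rates <- rates |>
    dplyr::group_by(.data$territory_id) |>
    dplyr::summarise(mean_rate = mean(.data$mean_rate), .groups = "drop")
  terr_stats <- covers |>
    dplyr::left_join(terr_rates, by = "territory_id") |>
    dplyr::mutate(cover_pct = 100 * .data$live_cover)

  power_fit <- NULL; spearman <- NULL
  if (nrow(terr_stats) >= 3L && all(terr_stats$cover_pct > 0)) {
    power_fit <- fit_power_law(terr_stats$cover_pct, terr_stats$perimeter_m)
    sp <- list(
      cover_vs_size = spearman_correlation(terr_stats$cover_pct, terr_stats$perimeter_m)
    )
    ok_rate <- !is.na(terr_stats$mean_rate)
    if (sum(ok_rate) >= 3L) {
      sp$cover_vs_rate <- spearman_correlation(
        terr_stats$cover_pct[ok_rate], terr_stats$mean_rate[ok_rate]
      )
      sp$rate_vs_size <- spearman_correlation(
        terr_stats$mean_rate[ok_rate], terr_stats$perimeter_m[ok_rate]
      )
    }
    spearman <- dplyr::bind_rows(sp, .id = "relationship")
  }

  result <- structure(
    list(
      validation = validation,
      profiles = profiles,
      site_availability = avail,
      selectivity = selectivity,
      rsf = rsf,
      cover_comparison = cover_comparison,
      territory_stats = terr_stats,
      power_fit = power_fit,
      spearman = spearman,
      feeding_rates = rates,
      truth = truth,
      config = cfg
    ),
    class = "foraging_analysis"
  )
  if (!is.null(cfg$out_dir)) write_analysis_outputs(result, cfg$out_dir)
  result
}

#' Table-style text report of an analysis
#'
#' One row per site with the unit count, the selectivity statistic (3
#' significant figures), its p-value, and the selection ratio of every prey
#' category (2 decimals) — the conventional compact layout for dietary
#' selectivity results — followed by the cover comparison and size-law
#' summaries.
#'
#' @param x A `foraging_analysis`.
#' @return Character vector of report lines.
#' @export
report_text <- function(x) {
  lines <- character()
  push <- function(...) lines <<- c(lines, sprintf(...))
  push("Dietary selectivity and prey preferences")
  if (length(x$selectivity)) {
    cats <- x$rsf[[1L]]$category
    push(paste(c(sprintf("%-13s %4s %10s %8s", "site", "n", "chi2_L2", "P"),
                 sprintf("%12s", cats)), collapse = ""))
    for (s in names(x$selectivity)) {
      st <- x$selectivity[[s]]
      w <- x$rsf[[s]]$w[match(cats, x$rsf[[s]]$category)]
      push(paste(c(sprintf("%-13s %4d %10s %8.2g", s, st$n_units,
                           formatC(st$chi2_l2, format = "g", digits = 3),
                           st$p_value),
                   sprintf("%12.2f", w)), collapse = ""))
    }
  }
  if (!is.null(x$cover_comparison)) {
    cc <- x$cover_comparison
    push("")
    push("Live cover, low vs high sites: %.2f +/- %.2f%% (n=%d) vs %.2f +/- %.2f%% (n=%d)",
         cc$group_means[["a"]], cc$group_ses[["a"]], cc$n[["a"]],
         cc$group_means[["b"]], cc$group_ses[["b"]], cc$n[["b"]])
    push("  pooled t = %.2f, df = %d, p = %.3g; F = %.2f, p = %.3g",
         cc$t_statistic, cc$df, cc$p_value_t, cc$f_statistic, cc$p_value_f)
  }
  if (!is.null(x$power_fit)) {
    pf <- x$power_fit
    push("")
    push("Territory size vs cover: y = %.2f x^%.3f, r2(log10) = %.3f, F(%d,%d) = %.2f, p = %.3g",
         pf$coefficient_a, pf$exponent_b, pf$r2_log,
         pf$anova_df[1L], pf$anova_df[2L], pf$anova_f, pf$p_value)
  }
  if (!is.null(x$spearman)) {
    for (k in seq_len(nrow(x$spearman))) {
      push("Spearman %s: rho = %.3f, n = %d, p = %.3g",
           x$spearman$relationship[k], x$spearman$rho[k],
           x$spearman$n[k], x$spearman$p_value[k])
    }
  }
  lines
}

#' @export
print.foraging_analysis <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Machine-readable summary of an analysis
#'
#' Everything the text report shows, as a nested list suitable for JSON
#' serialisation; numbers are unrounded.
#'
#' @param x A `foraging_analysis`.
#' @return A named list.
#' @export
report_list <- function(x) {
  out <- list()
  out$selectivity <- lapply(x$selectivity, function(st) {
    list(chi2_l2 = st$chi2_l2, df = st$df, p_value = st$p_value, n = st$n_units)
  })
  out$selection_ratios <- lapply(x$rsf, function(tab) {
    as.list(tibble::as_tibble(tab))
  })
  if (!is.null(x$cover_comparison)) {
    out$cover_comparison <- as.list(tidy.cover_comparison(x$cover_comparison))
  }
  if (!is.null(x$power_fit)) {
    out$power_fit <- as.list(glance.power_fit(x$power_fit))
  }
  if (!is.null(x$spearman)) out$spearman <- as.list(x$spearman)
  out$validation <- list(
    errors = x$validation$errors, warnings = x$validation$warnings,
    counts = x$validation$counts
  )
  out
}

write_analysis_outputs <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$profiles, file.path(out_dir, "availability_territories.csv"))
  if (length(x$site_availability)) {
    readr::write_csv(dplyr::bind_rows(lapply(x$site_availability, tibble::as_tibble)),
                     file.path(out_dir, "availability_sites.csv"))
  }
  if (length(x$rsf)) {
    readr::write_csv(
      dplyr::bind_rows(lapply(names(x$rsf), function(s) {
        dplyr::mutate(tibble::as_tibble(x$rsf[[s]]), site_class = s, .before = 1L)
      })),
      file.path(out_dir, "selection_functions.csv")
    )
  }
  readr::write_csv(x$territory_stats, file.path(out_dir, "territory_stats.csv"))
  readr::write_csv(x$feeding_rates, file.path(out_dir, "feeding_rates.csv"))
  jsonlite::write_json(report_list(x), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_text(x), file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' Run a replicated simulation study from a config
#'
#' Delegates to [recovery_experiment()] for a config with a `synthetic`
#' block; optionally writes the per-replicate estimates as CSV and the
#' summary as JSON.
#'
#' @param config List or JSON path with a `synthetic` block (see
#'   [run_analysis()]).
#' @param n_replicates Number of replicates (>= 1).
#' @param out_dir Optional output directory.
#' @return The `recovery_report`.
#' @export
run_simulation_study <- function(config, n_replicates = 100L, out_dir = NULL) {
  cfg <- load_run_config(config)
  if (is.null(cfg$synthetic)) {
    rlang::abort("`run_simulation_study()` requires a synthetic block in the config.")
  }
  rep <- recovery_experiment(cfg$synthetic, n_replicates = n_replicates,
                             alpha = cfg$alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(rep$ratios, file.path(out_dir, "replicate_estimates.csv"))
    readr::write_csv(rep$tests, file.path(out_dir, "replicate_tests.csv"))
    if (nrow(rep$sizes)) readr::write_csv(rep$sizes, file.path(out_dir, "replicate_sizes.csv"))
    jsonlite::write_json(lapply(rep$summary, as.list),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

# Normalise a run config (list or JSON path) and apply defaults.
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) rlang::abort("`config` must be a list or a JSON file path.")
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  if (has_input == has_synth) {
    rlang::abort("Exactly one of `input` and `synthetic` must be present in the config.")
  }
  if (has_input) {
    need <- setdiff(c("points", "bites", "territories"), names(config$input))
    if (length(need)) {
      rlang::abort(sprintf("`input` is missing path(s): %s.", paste(need, collapse = ", ")))
    }
  }
  scheme <- config$scheme %||% default_scheme(aliases = unlist(config$aliases) %||% character())
  synth <- NULL
  if (has_synth) {
    args <- config$synthetic
    if (inherits(args, "synthetic_config")) {
      synth <- args
    } else {
      args$scheme <- scheme
      if (!is.null(config$seed)) args$seed <- config$seed
      synth <- do.call(synthetic_config, args)
    }
    if (!is.null(config$seed)) synth$seed <- as.integer(config$seed)
  }
  list(
    input = config$input,
    synthetic = synth,
    scheme = scheme,
    alpha = config$alpha %||% 0.05,
    pooling = config$pooling %||% "counts",
    unit = config$unit %||% (if (has_synth) synth$unit else "pair"),
    n_periods = config$n_periods %||% (if (has_synth) synth$n_periods else 10L),
    photos_per_territory = config$photos_per_territory %||%
      (if (has_synth) synth$photos_per_territory else 50L),
    points_per_photo = config$points_per_photo %||%
      (if (has_synth) synth$points_per_photo else 10L),
    out_dir = config$out_dir
  )
}
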