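#' Configuration for the synthetic reef-survey generator
#'
#' Bundles every parameter of the simulated study: how many territories per
#' site class, the live-cover range each class spans, the mean coral
#' composition of each class (a probability vector over the prey categories),
#' how tightly territory compositions scatter around that mean, the true
#' selection ratios that drive bite allocation, the bite-rate and observation
#' design, and the territory-size power law.
#'
#' Defaults emulate a two-site contrast on a shallow reef flat: eight
#' low-cover territories (< 25% live coral, Acropora about half of the live
#' coral), nine high-cover territories (> 40%, Acropora-dominated at ~85% of
#' live coral) plus six intermediate ones; 50 photos x 10 points = 500
#' point-intercept samples per territory; 10 consecutive observation periods
#' per focal pair; and a declining size-versus-cover power law. True
#' selection at high cover is strong (Pocillopora taken at ~4x its
#' availability); at low cover the same preferences are relaxed (square root
#' of the high-cover ratios), reflecting diminished selectivity where
#' preferred prey are scarce.
#'
#' @param n_territories Named integer vector, territories per site class.
#' @param cover_range Named list of percent intervals per site class.
#' @param composition_mean Named list of per-site probability vectors over
#'   the scheme's prey categories (fractions of live coral).
#' @param composition_concentration Dirichlet concentration for territory
#'   compositions about the site mean; `Inf` makes every territory identical
#'   to its site mean.
#' @param true_w Named list of per-site true selection ratios (length =
#'   number of prey categories, entries >= 0, not all zero). Bite
#'   probabilities are proportional to `true_w * composition`, renormalised.
#' @param bite_rate Mean bites per observation period (Poisson).
#' @param n_periods Observation periods per unit.
#' @param photos_per_territory,points_per_photo Point-intercept design.
#' @param unit `"pair"` (one observation unit per territory, the focal pair)
#'   or `"individual"` (two units per territory).
#' @param power_a,power_b Territory-size law `perimeter = a * cover_pct^b`.
#' @param size_noise_sd_log10 SD of multiplicative log10-normal size noise.
#' @param noncoral_split Probability split of non-coral points over the
#'   scheme's substrate categories (default equal shares).
#' @param scheme A [category_scheme()].
#' @param seed Integer master seed; all generators split per-territory
#'   substreams from it, so regenerating with more territories leaves
#'   existing ones unchanged.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_territories = c(low = 8L, intermediate = 6L, high = 9L),
                             cover_range = list(
                               low = c(5, 24.9),
                               intermediate = c(26, 39),
                               high = c(40, 62)
                             ),
                             composition_mean = list(
                               low = c(0.54, 0.05, 0.15, 0.04, 0.03, 0.04, 0.15),
                               intermediate = c(0.695, 0.045, 0.0865, 0.03, 0.025, 0.0265, 0.092),
                               high = c(0.85, 0.04, 0.023, 0.02, 0.02, 0.013, 0.034)
                             ),
                             composition_concentration = 100,
                             true_w = list(
                               low = sqrt(c(0.90, 4.38, 0.63, 1.57, 0.72, 0.58, 0.18)),
                               intermediate = sqrt(c(0.90, 4.38, 0.63, 1.57, 0.72, 0.58, 0.18)),
                               high = c(0.90, 4.38, 0.63, 1.57, 0.72, 0.58, 0.18)
                             ),
                             bite_rate = 20,
                             n_periods = 10L,
                             photos_per_territory = 50L,
                             points_per_photo = 10L,
                             unit = c("pair", "individual"),
                             power_a = 369.76,
                             power_b = -0.713,
                             size_noise_sd_log10 = 0.12,
                             noncoral_split = NULL,
                             scheme = default_scheme(),
                             seed = 1L) {
  unit <- match.arg(unit)
  sites <- c("low", "intermediate", "high")
  n_territories <- n_territories[sites]
  n_territories[is.na(n_territories)] <- 0L
  names(n_territories) <- sites
  ncat <- length(scheme$prey_categories)
  for (s in sites) {
    if (n_territories[[s]] == 0L) next
    cm <- composition_mean[[s]]
    if (length(cm) != ncat || any(cm < 0) || abs(sum(cm) - 1) > 1e-8) {
      rlang::abort(sprintf(
        "composition_mean$%s must be a probability vector of length %d.", s, ncat
      ))
    }
    tw <- true_w[[s]]
    if (length(tw) != ncat || any(tw < 0) || all(tw == 0)) {
      rlang::abort(sprintf(
        "true_w$%s must be length %d, non-negative, not all zero.", s, ncat
      ))
    }
    rng <- cover_range[[s]]
    if (length(rng) != 2L || rng[1L] <= 0 || rng[2L] > 100 || rng[1L] > rng[2L]) {
      rlang::abort(sprintf("cover_range$%s must be an increasing interval in (0, 100].", s))
    }
  }
  if (is.null(noncoral_split)) {
    k <- length(scheme$substrate_categories)
    noncoral_split <- rep(1 / k, k)
  }
  if (length(noncoral_split) != length(scheme$substrate_categories) ||
      any(noncoral_split < 0) || abs(sum(noncoral_split) - 1) > 1e-8) {
    rlang::abort("noncoral_split must be a probability vector over the substrate categories.")
  }
  structure(
    list(
      n_territories = n_territories,
      cover_range = cover_range,
      composition_mean = composition_mean,
      composition_concentration = composition_concentration,
      true_w = true_w,
      bite_rate = bite_rate,
      n_periods = as.integer(n_periods),
      photos_per_territory = as.integer(photos_per_territory),
      points_per_photo = as.integer(points_per_photo),
      unit = unit,
      power_a = power_a,
      power_b = power_b,
      size_noise_sd_log10 = size_noise_sd_log10,
      noncoral_split = noncoral_split,
      scheme = scheme,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Deterministic substream seed from (master seed, territory key, purpose).
# Multipliers kept small enough that all arithmetic stays exact in doubles.
substream_seed <- function(seed, key, purpose) {
  as.integer((as.numeric(seed) * 48271 + key * 16807 + purpose * 69621) %% 2147483646) + 1L
}

territory_keys <- function(config) {
  sites <- names(config$n_territories)
  out <- list()
  for (si in seq_along(sites)) {
    s <- sites[si]
    n <- config$n_territories[[s]]
    if (n == 0L) next
    code <- c(low = "L", intermediate = "M", high = "H")[[s]]
    out[[s]] <- tibble::tibble(
      territory_id = sprintf("%s%02d", code, seq_len(n)),
      site_class = s,
      key = si * 1000 + seq_len(n)
    )
  }
  dplyr::bind_rows(out)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate synthetic territories with known ground truth
#'
#' Draws, per territory: a live-cover fraction uniform within its site
#' class's range; a coral composition from a Dirichlet perturbation of the
#' site mean; and a perimeter on the configured power law with multiplicative
#' log10-normal noise. Each territory uses its own random substream derived
#' from the master seed.
#'
#' @param config A [synthetic_config()].
#' @return A list: `territories` (tibble `territory_id`, `site_class`,
#'   `perimeter_m`) and `truth` (a `ground_truth` list holding true cover,
#'   composition matrix, true selection ratios and the config).
#' @export
generate_territories <- function(config = synthetic_config()) {
  keys <- territory_keys(config)
  ncat <- length(config$scheme$prey_categories)
  cover <- numeric(nrow(keys))
  comp <- matrix(NA_real_, nrow(keys), ncat,
                 dimnames = list(keys$territory_id, config$scheme$prey_categories))
  perim <- numeric(nrow(keys))
  for (k in seq_len(nrow(keys))) {
    s <- keys$site_class[k]
    withr::with_seed(substream_seed(config$seed, keys$key[k], 1L), {
      rng <- config$cover_range[[s]]
      cover_pct <- stats::runif(1, rng[1L], rng[2L])
      cm <- config$composition_mean[[s]]
      comp[k, ] <- if (is.infinite(config$composition_concentration)) cm else {
        rdirichlet1(cm * config$composition_concentration)
      }
      noise <- stats::rnorm(1, 0, config$size_noise_sd_log10)
      perim[k] <- config$power_a * cover_pct^config$power_b * 10^noise
      cover[k] <- cover_pct / 100
    })
  }
  territories <- tibble::tibble(
    territory_id = keys$territory_id,
    site_class = keys$site_class,
    perimeter_m = perim
  )
  truth <- structure(
    list(
      territories = tibble::tibble(
        territory_id = keys$territory_id,
        site_class = keys$site_class,
        key = keys$key,
        cover = cover,
        perimeter_m = perim
      ),
      composition = comp,
      true_w = config$true_w,
      config = config
    ),
    class = "ground_truth"
  )
  list(territories = territories, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d territories (%s)\n",
              nrow(x$territories),
              paste(sprintf("%s: %d", names(table(x$territories$site_class)),
                            table(x$territories$site_class)), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic point-intercept survey
#'
#' For every territory, draws `photos_per_territory * points_per_photo`
#' substrate points independently: a point lands on coral prey category `i`
#' with probability `cover * composition_i` and on each non-coral substrate
#' category with probability `(1 - cover) * split`. Points are labelled with
#' photo and within-photo indices matching the survey design.
#'
#' @param truth A `ground_truth` from [generate_territories()].
#' @param config The same [synthetic_config()] (defaults to the one stored in
#'   `truth`).
#' @return A point-count tibble, as [read_point_counts()] would return.
#' @export
generate_point_counts <- function(truth, config = truth$config) {
  sch <- config$scheme
  labs <- scheme_labels(sch)
  npts <- config$photos_per_territory * config$points_per_photo
  out <- vector("list", nrow(truth$territories))
  for (k in seq_len(nrow(truth$territories))) {
    tr <- truth$territories[k, ]
    probs <- c(tr$cover * truth$composition[k, ],
               (1 - tr$cover) * config$noncoral_split)
    cats <- withr::with_seed(
      substream_seed(config$seed, tr$key, 2L),
      sample(labs, npts, replace = TRUE, prob = probs)
    )
    out[[k]] <- tibble::tibble(
      territory_id = tr$territory_id,
      photo_index = rep(seq_len(config$photos_per_territory),
                        each = config$points_per_photo),
      point_index = rep(seq_len(config$points_per_photo),
                        times = config$photos_per_territory),
      category = cats
    )
  }
  dplyr::bind_rows(out)
}

#' Generate synthetic bite records
#'
#' For each observation unit (the focal pair, or two individuals per
#' territory) and each observation period, draws a Poisson total bite count
#' and allocates it multinomially over the prey categories with probability
#' proportional to `true_w * composition` (renormalised) for the unit's
#' territory. Only positive counts are emitted; absent combinations mean
#' zero bites.
#'
#' @inheritParams generate_point_counts
#' @return A bite tibble, as [read_bite_records()] would return.
#' @export
generate_bites <- function(truth, config = truth$config) {
  sch <- config$scheme
  out <- list()
  for (k in seq_len(nrow(truth$territories))) {
    tr <- truth$territories[k, ]
    w <- config$true_w[[tr$site_class]]
    q <- w * truth$composition[k, ]
    if (sum(q) == 0) rlang::abort("true_w x composition is all zero; no prey can be bitten.")
    q <- q / sum(q)
    inds <- if (config$unit == "pair") "pair" else c("ind1", "ind2")
    rows <- withr::with_seed(substream_seed(config$seed, tr$key, 3L), {
      rr <- list()
      for (ind in inds) {
        totals <- stats::rpois(config$n_periods, config$bite_rate)
        counts <- sapply(totals, function(b) {
          if (b == 0) rep(0L, length(q)) else as.integer(stats::rmultinom(1, b, q))
        })
        # counts: categories x periods
        idx <- which(counts > 0, arr.ind = TRUE)
        if (nrow(idx)) {
          rr[[ind]] <- tibble::tibble(
            territory_id = tr$territory_id,
            individual_id = ind,
            period_index = as.integer(idx[, "col"]),
            category = sch$prey_categories[idx[, "row"]],
            bites = as.integer(counts[idx])
          )
        }
      }
      dplyr::bind_rows(rr)
    })
    out[[k]] <- rows
  }
  res <- dplyr::bind_rows(out)
  dplyr::arrange(res, .data$territory_id, .data$individual_id,
                 .data$period_index, .data$category)
}

#' Generate a complete synthetic survey
#'
#' Convenience wrapper: territories + ground truth, point counts and bites
#' in one call.
#'
#' @param config A [synthetic_config()].
#' @return A list with `points`, `bites`, `territories` and `truth`.
#' @export
generate_survey <- function(config = synthetic_config()) {
  g <- generate_territories(config)
  list(
    points = generate_point_counts(g$truth, config),
    bites = generate_bites(g$truth, config),
    territories = g$territories,
    truth = g$truth
  )
}

#' Site-level expected availability and effective selection ratios
#'
#' From the ground truth, computes for each site class the expected pooled
#' proportional availability `p_i` (territory compositions weighted by true
#' cover, since each territory contributes points in proportion to its coral
#' cover) and the *effective* site-level selection ratio: the mean over
#' territories of expected proportional use divided by pooled availability.
#' Renormalising `true_w * composition` into bite probabilities means the
#' estimable site-level ratios are a scaled version of `true_w`; this
#' function returns exactly the quantity the analysis pipeline estimates,
#' which is the correct target for recovery scoring.
#'
#' @param truth A `ground_truth`.
#' @return Tibble: `site_class`, `category`, `p_true`, `w_eff`.
#' @export
true_site_summary <- function(truth) {
  config <- truth$config
  out <- list()
  for (s in unique(truth$territories$site_class)) {
    sel <- truth$territories$site_class == s
    cover <- truth$territories$cover[sel]
    comp <- truth$composition[sel, , drop = FALSE]
    p <- colSums(comp * cover) / sum(cover)
    w <- config$true_w[[s]]
    qmat <- sweep(comp, 2L, w, "*")
    qmat <- qmat / rowSums(qmat)
    w_eff <- colMeans(qmat) / p
    out[[s]] <- tibble::tibble(
      site_class = s,
      category = config$scheme$prey_categories,
      p_true = as.numeric(p),
      w_eff = as.numeric(w_eff)
    )
  }
  dplyr::bind_rows(out)
}

#' Simulation study: parameter recovery and test calibration
#'
#' Repeatedly generates a survey under `config`, runs the full analysis
#' pipeline (availability estimation from the simulated points, use-matrix
#' construction, selectivity test, selection ratios, territory-size fit), and
#' scores the results against the ground truth: bias and RMSE of the
#' selection ratios, empirical coverage of the Bonferroni intervals,
#' rejection rate of the selectivity test, and recovery of the size-law
#' exponent.
#'
#' @param config A [synthetic_config()]; each replicate uses a fresh
#'   substream split from `config$seed`.
#' @param n_replicates Number of replicates.
#' @param sites Site classes to analyse (default: those with territories).
#' @param alpha Significance level for the selectivity test and CIs.
#' @param availability `"estimated"` (default) runs the full pipeline,
#'   re-estimating availability from the simulated point survey each
#'   replicate; `"true"` scores against the known pooled availability,
#'   isolating the bite-sampling properties of the estimators. The Manly
#'   standard error treats availability as known, so its nominal CI coverage
#'   is a conditional-on-availability statement and is assessed with
#'   `availability = "true"`; with `"estimated"`, shared availability noise
#'   moves all units' ratios together and true coverage falls below nominal.
#' @param fit_sizes Also fit the territory-size power law per replicate?
#' @return A `recovery_report`: list with `ratios` (per replicate x site x
#'   category tibble), `tests` (per replicate x site), `sizes` (per
#'   replicate, if requested) and `summary` (aggregated tibbles).
#' @export
recovery_experiment <- function(config = synthetic_config(), n_replicates = 100L,
                                sites = NULL, alpha = 0.05,
                                availability = c("estimated", "true"),
                                fit_sizes = TRUE) {
  if (n_replicates < 1L) rlang::abort("`n_replicates` must be >= 1.")
  availability <- match.arg(availability)
  sites <- sites %||% names(config$n_territories)[config$n_territories > 0]
  ratios <- vector("list", n_replicates)
  tests <- vector("list", n_replicates)
  sizes <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, r, 4L)
    if (availability == "true" && !fit_sizes) {
      # point survey not needed: availability comes from ground truth
      g <- generate_territories(cfg)
      sim <- list(points = NULL, bites = generate_bites(g$truth, cfg),
                  territories = g$territories, truth = g$truth)
    } else {
      sim <- generate_survey(cfg)
    }
    truth_site <- true_site_summary(sim$truth)
    rr <- list(); tt <- list()
    for (s in sites) {
      tids <- sim$territories$territory_id[sim$territories$site_class == s]
      avail <- if (availability == "estimated") {
        suppressWarnings(
          site_availability(sim$points, tids, cfg$scheme, site_class = s)
        )
      } else {
        tw0 <- truth_site[truth_site$site_class == s, ]
        tibble::tibble(site_class = s, category = tw0$category, p = tw0$p_true)
      }
      use <- suppressWarnings(
        build_use_matrix(sim$bites, cfg$scheme, territory_ids = tids, unit = cfg$unit)
      )
      st <- suppressWarnings(chi2_log_likelihood(use, avail))
      rsf <- suppressWarnings(selection_functions(use, avail, alpha = alpha))
      tw <- truth_site[truth_site$site_class == s, ]
      joined <- dplyr::left_join(
        tibble::as_tibble(rsf), tw[c("category", "p_true", "w_eff")],
        by = "category"
      )
      rr[[s]] <- tibble::tibble(
        replicate = r, site_class = s,
        category = joined$category,
        w_hat = joined$w, se = joined$se,
        ci_low = joined$ci_low, ci_high = joined$ci_high,
        w_true = joined$w_eff,
        covered = joined$ci_low <= joined$w_eff & joined$w_eff <= joined$ci_high
      )
      tt[[s]] <- tibble::tibble(
        replicate = r, site_class = s,
        chi2_l2 = st$chi2_l2, df = st$df, p_value = st$p_value,
        reject = st$p_value < alpha
      )
    }
    ratios[[r]] <- dplyr::bind_rows(rr)
    tests[[r]] <- dplyr::bind_rows(tt)
    if (fit_sizes && nrow(sim$territories) >= 3L) {
      cov_pct <- 100 * sim$truth$territories$cover
      pf <- fit_power_law(cov_pct, sim$territories$perimeter_m)
      rho <- spearman_correlation(cov_pct, sim$territories$perimeter_m)
      sizes[[r]] <- tibble::tibble(
        replicate = r,
        exponent_b = pf$exponent_b, coefficient_a = pf$coefficient_a,
        r2_log = pf$r2_log, spearman_rho = rho$rho
      )
    }
  }
  ratios <- dplyr::bind_rows(ratios)
  tests <- dplyr::bind_rows(tests)
  sizes <- dplyr::bind_rows(sizes)

  ratio_summary <- ratios |>
    dplyr::group_by(.data$site_class, .data$category) |>
    dplyr::summarise(
      w_true = .data$w_true[1L],
      mean_w_hat = mean(.data$w_hat),
      bias = mean(.data$w_hat - .data$w_true),
      rmse = sqrt(mean((.data$w_hat - .data$w_true)^2)),
      coverage = mean(.data$covered),
      .groups = "drop"
    )
  family_coverage <- ratios |>
    dplyr::group_by(.data$site_class, .data$replicate) |>
    dplyr::summarise(all_covered = all(.data$covered), .groups = "drop") |>
    dplyr::group_by(.data$site_class) |>
    dplyr::summarise(family_coverage = mean(.data$all_covered), .groups = "drop")
  test_summary <- tests |>
    dplyr::group_by(.data$site_class) |>
    dplyr::summarise(
      rejection_rate = mean(.data$reject),
      mean_chi2 = mean(.data$chi2_l2),
      .groups = "drop"
    )
  size_summary <- if (nrow(sizes)) {
    tibble::tibble(
      mean_exponent = mean(sizes$exponent_b),
      sd_exponent = stats::sd(sizes$exponent_b),
      prop_negative_rho = mean(sizes$spearman_rho < 0)
    )
  } else tibble::tibble()

  structure(
    list(
      ratios = ratios, tests = tests, sizes = sizes,
      summary = list(
        ratios = ratio_summary,
        family_coverage = family_coverage,
        tests = test_summary,
        sizes = size_summary
      ),
      n_replicates = n_replicates, alpha = alpha
    ),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d replicates, alpha = %g\n", x$n_replicates, x$alpha))
  cat("-- selectivity test --\n"); print(x$summary$tests)
  cat("-- selection ratios --\n"); print(x$summary$ratios, n = Inf)
  cat("-- simultaneous CI coverage --\n"); print(x$summary$family_coverage)
  if (nrow(x$summary$sizes)) {
    cat("-- territory size law --\n"); print(x$summary$sizes)
  }
  invisible(x)
}
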