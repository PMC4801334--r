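#' Per-territory availability profiles from point-intercept data
#'
#' Converts a point-count table to, per territory: the total number of points,
#' the live-coral cover fraction (points falling on any coral prey category
#' divided by all points), and the coral composition — each prey category's
#' share of the coral points. Composition is normalised over the coral prey
#' categories only, i.e. it is a fraction *of live coral*, not of total
#' substrate; this is the availability basis the selection ratios use.
#'
#' A territory whose points hit no coral at all has `live_cover = 0` and an
#' undefined composition (`composition_defined = FALSE`, composition columns
#' `NA`); selectivity analyses must exclude such territories.
#'
#' @param points Point-count tibble ([read_point_counts()]).
#' @param scheme A [category_scheme()].
#' @return A tibble with one row per territory: `territory_id`, `point_total`,
#'   `coral_points`, `live_cover` (fraction in 0..1), `composition_defined`,
#'   then one composition column per prey category.
#' @export
availability_profiles <- function(points, scheme = default_scheme()) {
  if (nrow(points) == 0L) {
    rlang::abort("`points` is empty: no territories to profile.")
  }
  prey <- scheme$prey_categories
  counts <- points |>
    dplyr::count(.data$territory_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n", values_fill = 0L)
  for (lab in setdiff(scheme_labels(scheme), names(counts))) counts[[lab]] <- 0L

  prey_mat <- as.matrix(counts[prey])
  point_total <- rowSums(as.matrix(counts[scheme_labels(scheme)]))
  coral_points <- rowSums(prey_mat)
  comp <- prey_mat / ifelse(coral_points > 0, coral_points, NA_real_)

  out <- tibble::tibble(
    territory_id = counts$territory_id,
    point_total = as.integer(point_total),
    coral_points = as.integer(coral_points),
    live_cover = coral_points / point_total,
    composition_defined = coral_points > 0
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(comp))
  dplyr::arrange(out, .data$territory_id)
}

#' Raw per-category point counts by territory
#'
#' Convenience view of the same tally as [availability_profiles()] but as raw
#' counts over all categories (prey and substrate), one row per territory.
#'
#' @inheritParams availability_profiles
#' @return A tibble: `territory_id`, then one count column per scheme label.
#' @export
point_count_summary <- function(points, scheme = default_scheme()) {
  counts <- points |>
    dplyr::count(.data$territory_id, .data$category) |>
    tidyr::pivot_wider(names_from = "category", values_from = "n", values_fill = 0L)
  for (lab in setdiff(scheme_labels(scheme), names(counts))) counts[[lab]] <- 0L
  counts[c("territory_id", scheme_labels(scheme))]
}

#' Pooled proportional availability for a site
#'
#' Pools the member territories of a site into one proportional-availability
#' vector over the prey categories. The default (`pooling = "counts"`) sums
#' the coral point counts across territories and renormalises — the
#' maximum-likelihood pooled estimate. `pooling = "mean_of_territories"`
#' instead averages the per-territory compositions unweighted, which treats
#' each territory as one sampling unit regardless of its coral abundance.
#'
#' @param points Point-count tibble.
#' @param territory_ids Territories belonging to the site.
#' @param scheme A [category_scheme()].
#' @param site_class Optional label stored with the result.
#' @param pooling `"counts"` (default) or `"mean_of_territories"`.
#' @return A tibble with one row per prey category: `site_class`, `category`,
#'   `p` (proportional availability, sums to 1), plus attributes
#'   `pooled_point_total` and `territory_ids`.
#' @export
site_availability <- function(points, territory_ids, scheme = default_scheme(),
                              site_class = NA_character_,
                              pooling = c("counts", "mean_of_territories")) {
  pooling <- match.arg(pooling)
  if (length(territory_ids) == 0L) {
    rlang::abort("`territory_ids` is empty.")
  }
  prof <- availability_profiles(
    dplyr::filter(points, .data$territory_id %in% territory_ids), scheme
  )
  prey <- scheme$prey_categories
  usable <- prof[prof$composition_defined, , drop = FALSE]
  if (nrow(usable) == 0L) {
    rlang::abort("No territory in this site has any coral points; availability undefined.")
  }
  if (nrow(usable) < nrow(prof)) {
    rlang::warn(sprintf(
      "%d territorie(s) with zero coral points excluded from site availability.",
      nrow(prof) - nrow(usable)
    ))
  }
  if (pooling == "counts") {
    coral_counts <- as.matrix(usable[prey]) * usable$coral_points
    p <- colSums(coral_counts) / sum(usable$coral_points)
  } else {
    p <- colMeans(as.matrix(usable[prey]))
  }
  out <- tibble::tibble(
    site_class = site_class,
    category = prey,
    p = as.numeric(p)
  )
  attr(out, "pooled_point_total") <- sum(usable$point_total)
  attr(out, "pooled_coral_points") <- sum(usable$coral_points)
  attr(out, "territory_ids") <- usable$territory_id
  class(out) <- c("site_availability", class(out))
  out
}

#' Compare live coral cover between two groups of territories
#'
#' Classical two-sample comparison of percent live cover: pooled-variance
#' Student's t-test (df = n1 + n2 - 2), a variance-ratio F statistic
#' (group a variance over group b variance), and a Lilliefors-corrected
#' Kolmogorov-Smirnov normality check per group (the correction is needed
#' because the normal parameters are estimated from the same data).
#'
#' @param covers_a,covers_b Numeric vectors of percent live cover, one value
#'   per territory, each of length >= 2.
#' @return A `cover_comparison` object; see [tidy.cover_comparison()] and
#'   [glance.cover_comparison()].
#' @examples
#' compare_cover(c(12, 15, 19, 16), c(45, 52, 48, 51))
#' @export
compare_cover <- function(covers_a, covers_b) {
  covers_a <- as.numeric(covers_a)
  covers_b <- as.numeric(covers_b)
  n1 <- length(covers_a); n2 <- length(covers_b)
  if (n1 < 2L || n2 < 2L) {
    rlang::abort("Each group needs at least 2 territories (variance undefined otherwise).")
  }
  v1 <- stats::var(covers_a); v2 <- stats::var(covers_b)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  t_stat <- (mean(covers_a) - mean(covers_b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_t <- 2 * stats::pt(-abs(t_stat), df)
  f_stat <- v1 / v2
  p_f <- 2 * min(stats::pf(f_stat, n1 - 1, n2 - 1),
                 stats::pf(f_stat, n1 - 1, n2 - 1, lower.tail = FALSE))
  lil <- function(x) {
    if (length(x) >= 5 && stats::sd(x) > 0) nortest::lillie.test(x)$p.value else NA_real_
  }
  structure(
    list(
      t_statistic = t_stat, df = df, p_value_t = p_t,
      f_statistic = f_stat, p_value_f = p_f,
      normality_p = c(a = lil(covers_a), b = lil(covers_b)),
      group_means = c(a = mean(covers_a), b = mean(covers_b)),
      group_ses = c(a = stats::sd(covers_a) / sqrt(n1), b = stats::sd(covers_b) / sqrt(n2)),
      n = c(a = n1, b = n2)
    ),
    class = "cover_comparison"
  )
}

#' @export
print.cover_comparison <- function(x, ...) {
  cat("<cover_comparison>\n")
  cat(sprintf("  group a: mean %.2f +/- %.2f SE (n = %d)\n",
              x$group_means[["a"]], x$group_ses[["a"]], x$n[["a"]]))
  cat(sprintf("  group b: mean %.2f +/- %.2f SE (n = %d)\n",
              x$group_means[["b"]], x$group_ses[["b"]], x$n[["b"]]))
  cat(sprintf("  pooled t = %.3f, df = %d, p = %.3g\n", x$t_statistic, x$df, x$p_value_t))
  cat(sprintf("  variance ratio F = %.3f, p = %.3g\n", x$f_statistic, x$p_value_f))
  cat(sprintf("  normality (Lilliefors) p: a = %.3g, b = %.3g\n",
              x$normality_p[["a"]], x$normality_p[["b"]]))
  invisible(x)
}

#' Tidy a cover comparison
#' @param x A `cover_comparison`.
#' @param ... Unused.
#' @return One-row tibble of the test statistics.
#' @export
tidy.cover_comparison <- function(x, ...) {
  tibble::tibble(
    t_statistic = x$t_statistic,
    df = x$df,
    p_value_t = x$p_value_t,
    f_statistic = x$f_statistic,
    p_value_f = x$p_value_f,
    mean_a = x$group_means[["a"]],
    mean_b = x$group_means[["b"]],
    se_a = x$group_ses[["a"]],
    se_b = x$group_ses[["b"]],
    normality_p_a = x$normality_p[["a"]],
    normality_p_b = x$normality_p[["b"]]
  )
}

#' @rdname tidy.cover_comparison
#' @export
glance.cover_comparison <- function(x, ...) {
  tidy.cover_comparison(x)[c("t_statistic", "df", "p_value_t", "f_statistic", "p_value_f")]
}
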