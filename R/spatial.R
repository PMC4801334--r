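#' Fit a power law by least squares on log10-log10 scale
#'
#' Fits `y = a * x^b` by ordinary least squares on the log10-transformed
#' variables, `log10(y) = log10(a) + b log10(x)` — the standard treatment for
#' territory-size versus resource-density relationships, where sizes are
#' right-skewed and multiplicative noise is the natural error model. The
#' variance explained (`r2_log`) and regression ANOVA are reported on the
#' log scale; no nonlinear fit on the original scale is attempted.
#'
#' @param cover_pct Predictor, typically percent live coral cover (> 0).
#' @param size_m Response, typically territory perimeter in metres (> 0).
#' @return A `power_fit`: list with `coefficient_a` (size at x = 1),
#'   `exponent_b`, `r2_log`, `anova_f`, `anova_df` (c(1, n - 2)), `p_value`,
#'   `n`, and the underlying `lm` fit.
#' @examples
#' fit_power_law(c(10, 20, 40, 60), 369.76 * c(10, 20, 40, 60)^-0.713)
#' @export
fit_power_law <- function(cover_pct, size_m) {
  x <- as.numeric(cover_pct); y <- as.numeric(size_m)
  if (length(x) != length(y)) rlang::abort("`cover_pct` and `size_m` must have equal length.")
  if (length(x) < 3L) rlang::abort("At least 3 observations are required.")
  if (any(x <= 0) || any(y <= 0)) {
    rlang::abort("All values must be positive (log10 undefined otherwise).")
  }
  fit <- stats::lm(log10(y) ~ log10(x))
  n <- length(x)
  ss_tot <- sum((log10(y) - mean(log10(y)))^2)
  if (ss_tot == 0) {
    # flat response: slope 0, nothing to explain
    r2 <- 0; f <- 0; p <- 1
  } else {
    sm <- suppressWarnings(summary(fit)) # "essentially perfect fit" is expected on exact data
    r2 <- sm$r.squared
    f <- unname(sm$fstatistic[1L])
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  structure(
    list(
      coefficient_a = 10^unname(stats::coef(fit)[1L]),
      exponent_b = unname(stats::coef(fit)[2L]),
      r2_log = r2,
      anova_f = f,
      anova_df = c(1L, n - 2L),
      p_value = p,
      n = n,
      fit = fit,
      data = tibble::tibble(x = x, y = y)
    ),
    class = "power_fit"
  )
}

#' @export
print.power_fit <- function(x, ...) {
  cat("<power_fit>\n")
  cat(sprintf("  y = %.4g * x^%.4g   (n = %d)\n", x$coefficient_a, x$exponent_b, x$n))
  cat(sprintf("  r2 (log10 scale) = %.3f; ANOVA F(%d, %d) = %.3f, p = %.3g\n",
              x$r2_log, x$anova_df[1L], x$anova_df[2L], x$anova_f, x$p_value))
  invisible(x)
}

#' Tidy / glance methods for power-law fits
#' @param x A `power_fit`.
#' @param ... Unused.
#' @return A tibble of coefficients (`tidy`) or fit summary (`glance`).
#' @export
tidy.power_fit <- function(x, ...) {
  tibble::tibble(
    term = c("coefficient_a", "exponent_b"),
    estimate = c(x$coefficient_a, x$exponent_b)
  )
}

#' @rdname tidy.power_fit
#' @export
glance.power_fit <- function(x, ...) {
  tibble::tibble(
    coefficient_a = x$coefficient_a,
    exponent_b = x$exponent_b,
    r2_log = x$r2_log,
    anova_f = x$anova_f,
    df1 = x$anova_df[1L],
    df2 = x$anova_df[2L],
    p_value = x$p_value,
    n = x$n
  )
}

#' Plot a power-law fit
#'
#' Scatter of the data with the fitted curve, on log10-log10 axes.
#'
#' @param object A `power_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = exp(seq(log(min(object$data$x)), log(max(object$data$x)), length.out = 100))
  )
  grid$y <- object$coefficient_a * grid$x^object$exponent_b
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "live coral cover (%)", y = "territory perimeter (m)",
      title = sprintf("y = %.2f x^%.3f (r2 = %.2f, log10 scale)",
                      object$coefficient_a, object$exponent_b, object$r2_log)
    ) +
    ggplot2::theme_minimal()
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average-ranked data (ties receive mean ranks),
#' with a two-sided p-value: exact for small samples without ties (n <= 10),
#' and the t-approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return One-row tibble: `rho`, `n`, `p_value`, `method`.
#' @examples
#' spearman_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
spearman_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3L) rlang::abort("At least 3 pairs are required.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Spearman correlation undefined for a constant vector.")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10L && !ties) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    )
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(t_stat), n - 2)
    }
    method <- "t-approximation"
  }
  tibble::tibble(rho = rho, n = n, p_value = p, method = method)
}

#' Per-individual feeding rates
#'
#' Mean number of bites per observation period for each individual, counting
#' all recorded bites (coral and non-coral alike; behavioural exclusions are
#' applied before the data reach this point). The denominator is the
#' configured number of observation periods, so unrecorded periods count as
#' zero-bite periods.
#'
#' @param bites Bite tibble ([read_bite_records()]).
#' @param n_periods Observation periods per individual (default 10).
#' @return A tibble ordered by id: `territory_id`, `individual_id`,
#'   `total_bites`, `n_periods`, `mean_rate` (bites per period).
#' @export
feeding_rates <- function(bites, n_periods = 10L) {
  if (nrow(bites) == 0L) rlang::abort("`bites` is empty.")
  bites |>
    dplyr::group_by(.data$territory_id, .data$individual_id) |>
    dplyr::summarise(total_bites = sum(.data$bites), .groups = "drop") |>
    dplyr::mutate(
      n_periods = as.integer(n_periods),
      mean_rate = .data$total_bites / n_periods
    ) |>
    dplyr::arrange(.data$territory_id, .data$individual_id)
}
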