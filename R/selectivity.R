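#' Build a use matrix from bite records
#'
#' Aggregates bite counts over observation periods into one row per sampling
#' unit and one column per coral prey category. Non-coral bite categories
#' (mucus, dead coral, substrate labels) are excluded before aggregation:
#' the use-versus-availability analysis is defined over live coral prey only.
#'
#' The sampling unit is either the individual as observed (`unit =
#' "individual"`) or the territory's focal pair (`unit = "pair"`), in which
#' case both members' counts are summed. Field protocols that alternate
#' observation between pair members make the pair the natural unit.
#'
#' Units with zero total coral bites carry no information about prey choice
#' among corals and are dropped with a warning.
#'
#' @param bites Bite tibble ([read_bite_records()]).
#' @param scheme A [category_scheme()].
#' @param territory_ids Optional: restrict to these territories (a site).
#' @param unit `"pair"` (default; one unit per territory) or `"individual"`.
#' @return A `use_matrix`: list with `counts` (units x categories integer
#'   matrix), `units` (row ids), `categories` (prey labels) and `totals`
#'   (per-unit total coral bites).
#' @export
build_use_matrix <- function(bites, scheme = default_scheme(),
                             territory_ids = NULL,
                             unit = c("pair", "individual")) {
  unit <- match.arg(unit)
  if (!is.null(territory_ids)) {
    bites <- dplyr::filter(bites, .data$territory_id %in% territory_ids)
  }
  bites <- dplyr::filter(bites, is_prey_category(.data$category, scheme))
  if (nrow(bites) == 0L) {
    rlang::abort("No coral bite records available to build a use matrix.")
  }
  bites$unit_id <- if (unit == "pair") bites$territory_id else {
    paste(bites$territory_id, bites$individual_id, sep = "/")
  }
  agg <- bites |>
    dplyr::group_by(.data$unit_id, .data$category) |>
    dplyr::summarise(bites = sum(.data$bites), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category", values_from = "bites", values_fill = 0L)
  for (lab in setdiff(scheme$prey_categories, names(agg))) agg[[lab]] <- 0L
  m <- as.matrix(agg[scheme$prey_categories])
  rownames(m) <- agg$unit_id
  totals <- rowSums(m)
  if (any(totals == 0)) {
    rlang::warn(sprintf(
      "Dropping %d unit(s) with zero coral bites: %s.",
      sum(totals == 0), paste(rownames(m)[totals == 0], collapse = ", ")
    ))
    m <- m[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (nrow(m) == 0L) {
    rlang::abort("All units have zero coral bites; no use matrix can be built.")
  }
  structure(
    list(
      counts = m,
      units = rownames(m),
      categories = colnames(m),
      totals = as.numeric(totals)
    ),
    class = "use_matrix"
  )
}

#' Construct a use matrix directly from counts
#'
#' Escape hatch for simulation and testing: wrap an already-aggregated
#' units-by-categories bite count matrix as a `use_matrix`.
#'
#' @param counts Numeric matrix, one row per sampling unit, one column per
#'   prey category (column names required; row names optional).
#' @return A `use_matrix`.
#' @export
use_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) rlang::abort("`counts` needs category column names.")
  if (any(counts < 0)) rlang::abort("Bite counts must be non-negative.")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("unit", seq_len(nrow(counts)))
  totals <- rowSums(counts)
  if (any(totals == 0)) rlang::abort("Every unit must have a positive total bite count.")
  structure(
    list(
      counts = counts,
      units = rownames(counts),
      categories = colnames(counts),
      totals = as.numeric(totals)
    ),
    class = "use_matrix"
  )
}

#' @export
print.use_matrix <- function(x, ...) {
  cat(sprintf("<use_matrix> %d unit(s) x %d prey categories, %d bites total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Log-likelihood chi-square test of dietary selectivity
#'
#' Tests whether bite allocation deviates from proportionality to prey
#' availability, pooled over sampling units. With `u_ij` the bite count of
#' unit `j` on category `i`, `b_j = sum_i u_ij`, and `p_i` the site's pooled
#' proportional availability, the statistic is
#'
#' \deqn{\chi^2_{L2} = 2 \sum_j \sum_i u_{ij} \ln\{u_{ij} / E(u_{ij})\},
#'       \quad E(u_{ij}) = b_j p_i,}
#'
#' a G-type log-likelihood-ratio statistic referred to the chi-square
#' distribution with `n (I - 1)` degrees of freedom, where `n` is the number
#' of units and `I` the number of categories with positive availability.
#' Zero counts contribute nothing (`0 ln 0 = 0` by convention). Larger values
#' indicate stronger dietary specialisation.
#'
#' Categories with zero availability and zero use are uninformative and are
#' dropped (reducing `I`). A category with zero availability but positive use
#' is incompatible with the model: the statistic is `+Inf` and the result is
#' flagged. A warning is emitted when any expected count falls below 5, where
#' the chi-square approximation weakens.
#'
#' @param use A [build_use_matrix()] result.
#' @param avail A [site_availability()] tibble (or any tibble with `category`
#'   and `p` columns matching the use categories).
#' @return A `selectivity_test`: list with `chi2_l2`, `df`, `p_value`,
#'   `n_units`, `expected` (matrix of `E(u_ij)`), `incompatible` flag and the
#'   category set actually used.
#' @export
chi2_log_likelihood <- function(use, avail) {
  stopifnot(inherits(use, "use_matrix"))
  p <- align_availability(avail, use$categories)
  m <- use$counts
  if (all(p == 0)) rlang::abort("All availabilities are zero.")

  drop <- p == 0 & colSums(m) == 0
  if (any(drop)) {
    rlang::warn(sprintf(
      "Dropping unavailable, unused categorie(s): %s.",
      paste(use$categories[drop], collapse = ", ")
    ))
    m <- m[, !drop, drop = FALSE]
    p <- p[!drop]
  }
  incompatible <- any(p == 0 & colSums(m) > 0)

  b <- rowSums(m)
  if (any(b == 0)) rlang::abort("Every unit must have a positive total bite count.")
  expected <- outer(b, p)
  dimnames(expected) <- dimnames(m)

  if (incompatible) {
    chi2 <- Inf
  } else {
    term <- m * log(ifelse(m > 0, m / expected, 1))
    chi2 <- 2 * sum(term)
  }
  n <- nrow(m)
  df <- n * (ncol(m) - 1L)
  if (!incompatible && any(expected < 5)) {
    rlang::warn(sprintf(
      "%d expected count(s) below 5; the chi-square approximation may be unreliable.",
      sum(expected < 5)
    ))
  }
  structure(
    list(
      chi2_l2 = chi2,
      df = df,
      p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
      n_units = n,
      expected = expected,
      incompatible = incompatible,
      categories = colnames(m)
    ),
    class = "selectivity_test"
  )
}

#' @export
print.selectivity_test <- function(x, ...) {
  cat("<selectivity_test>\n")
  cat(sprintf("  chi2_L2 = %.4g, df = %d, p = %.3g (n = %d units)\n",
              x$chi2_l2, x$df, x$p_value, x$n_units))
  if (x$incompatible) {
    cat("  NOTE: observed use of an unavailable category; statistic is +Inf\n")
  }
  invisible(x)
}

#' Tidy / glance methods for selectivity tests
#' @param x A `selectivity_test`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.selectivity_test <- function(x, ...) {
  tibble::tibble(
    chi2_l2 = x$chi2_l2, df = x$df, p_value = x$p_value,
    n_units = x$n_units, incompatible = x$incompatible
  )
}

#' @rdname glance.selectivity_test
#' @export
tidy.selectivity_test <- function(x, ...) glance.selectivity_test(x, ...)

#' Manly resource selection ratios with Bonferroni confidence intervals
#'
#' For each prey category `i`, the selection ratio is the mean over sampling
#' units of proportional use over proportional availability:
#'
#' \deqn{w_i = \frac{1}{n} \sum_j \frac{u_{ij}/b_j}{p_i}.}
#'
#' `w = 1` means use proportional to availability; `w > 1` preference;
#' `w < 1` avoidance. The standard error is the between-unit standard
#' deviation of the per-unit ratios divided by `sqrt(n)` (0 when `n = 1`,
#' giving a degenerate interval). Simultaneous confidence intervals use the
#' Bonferroni-corrected normal quantile `z[1 - alpha/(2 I)]`, with `I` the
#' number of categories in the family, and each category is classified as
#' `preference` (lower bound > 1), `avoidance` (upper bound < 1) or
#' `proportional` otherwise.
#'
#' Because every unit's use proportions and the pooled availability each sum
#' to one, the availability-weighted mean of the ratios is exactly one:
#' `sum_i p_i w_i = 1`.
#'
#' @param use A [build_use_matrix()] result.
#' @param avail A [site_availability()] tibble (columns `category`, `p`).
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_categories_for_correction Size `I` of the Bonferroni family;
#'   defaults to the number of categories analysed.
#' @return An `rsf_table` tibble, one row per category: `category`, `p`, `w`,
#'   `se`, `ci_low`, `ci_high`, `classification`, `n`.
#' @export
selection_functions <- function(use, avail, alpha = 0.05,
                                n_categories_for_correction = NULL) {
  stopifnot(inherits(use, "use_matrix"))
  p <- align_availability(avail, use$categories)
  m <- use$counts
  cats <- use$categories

  drop <- p == 0 & colSums(m) == 0
  if (any(drop)) {
    rlang::warn(sprintf(
      "Dropping unavailable, unused categorie(s) from the selection table: %s.",
      paste(cats[drop], collapse = ", ")
    ))
    m <- m[, !drop, drop = FALSE]
    p <- p[!drop]
    cats <- cats[!drop]
  }
  bad <- p == 0 & colSums(m) > 0
  if (any(bad)) {
    rlang::abort(sprintf(
      "Category with zero availability but observed use: %s.",
      paste(cats[bad], collapse = ", ")
    ))
  }
  n <- nrow(m)
  if (n < 1L) rlang::abort("At least one sampling unit is required.")
  b <- rowSums(m)
  ratios <- sweep(m / b, 2L, p, "/") # r_ij = (u_ij / b_j) / p_i
  w <- colMeans(ratios)
  se <- if (n > 1L) apply(ratios, 2L, stats::sd) / sqrt(n) else rep(0, length(w))
  I <- n_categories_for_correction %||% length(cats)
  z <- stats::qnorm(1 - alpha / (2 * I))
  ci_low <- w - z * se
  ci_high <- w + z * se

  out <- tibble::tibble(
    category = cats,
    p = as.numeric(p),
    w = as.numeric(w),
    se = as.numeric(se),
    ci_low = as.numeric(ci_low),
    ci_high = as.numeric(ci_high),
    classification = classify_selection(ci_low, ci_high),
    n = n
  )
  attr(out, "alpha") <- alpha
  attr(out, "bonferroni_I") <- I
  attr(out, "z") <- z
  class(out) <- c("rsf_table", class(out))
  out
}

#' Classify selection from simultaneous confidence bounds
#'
#' A category is preferred when even the lower confidence bound of its
#' selection ratio exceeds 1, avoided when the upper bound is below 1, and
#' used in proportion to availability otherwise.
#'
#' @param ci_low,ci_high Numeric vectors of interval bounds.
#' @return Character vector: `"preference"`, `"avoidance"` or `"proportional"`.
#' @examples
#' classify_selection(c(1.4, 0.1, 0.8), c(2.6, 0.5, 1.4))
#' @export
classify_selection <- function(ci_low, ci_high) {
  stopifnot(length(ci_low) == length(ci_high), all(is.finite(ci_low)), all(is.finite(ci_high)))
  dplyr::case_when(
    ci_low > 1 ~ "preference",
    ci_high < 1 ~ "avoidance",
    .default = "proportional"
  )
}

#' Plot a selection-ratio table
#'
#' Point estimates with Bonferroni simultaneous confidence intervals and the
#' neutral-use reference line at `w = 1`.
#'
#' @param object An `rsf_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsf_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$w)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high), width = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$classification), size = 2.5) +
    ggplot2::labs(
      x = NULL, y = "selection ratio w",
      colour = NULL,
      title = "Resource selection ratios with Bonferroni 95% intervals"
    ) +
    ggplot2::theme_minimal()
}

# Align an availability table (category, p) to the use-matrix category order.
align_availability <- function(avail, categories) {
  if (!all(c("category", "p") %in% names(avail))) {
    rlang::abort("`avail` must have `category` and `p` columns.")
  }
  idx <- match(categories, avail$category)
  if (anyNA(idx)) {
    rlang::abort(sprintf(
      "Availability is missing categorie(s): %s.",
      paste(categories[is.na(idx)], collapse = ", ")
    ))
  }
  p <- as.numeric(avail$p[idx])
  if (any(p < 0) || any(!is.finite(p))) {
    rlang::abort("Availabilities must be finite and non-negative.")
  }
  p
}
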