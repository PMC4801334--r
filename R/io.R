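#' Read a point-intercept (photoquadrat) survey table
#'
#' One row per sampled point: the territory it belongs to, the photograph
#' index along the transect, the point index within the photograph, and the
#' substrate category recorded beneath the point. Category labels are
#' normalised against `scheme` (trimmed, case-folded, aliases applied).
#'
#' @param path Path to a CSV file with columns `territory_id`, `photo_index`,
#'   `point_index`, `category`.
#' @param scheme A [category_scheme()]; defaults to [default_scheme()].
#' @return A tibble with the four columns above, categories canonicalised.
#' @export
read_point_counts <- function(path, scheme = default_scheme()) {
  df <- read_table_checked(path, c("territory_id", "photo_index", "point_index", "category"))
  df <- tibble::tibble(
    territory_id = as.character(df$territory_id),
    photo_index = as.integer(df$photo_index),
    point_index = as.integer(df$point_index),
    category = as.character(df$category)
  )
  if (nrow(df) == 0L) return(df)
  df$category <- check_categories(df$category, scheme, path)
  dup <- duplicated(df[c("territory_id", "photo_index", "point_index")])
  if (any(dup)) {
    k <- df[which(dup)[1L], ]
    rlang::abort(sprintf(
      "Duplicate point key in %s: (territory_id=%s, photo_index=%d, point_index=%d).",
      path, k$territory_id, k$photo_index, k$point_index
    ))
  }
  df
}

#' Read a bite-record table
#'
#' One row per (territory, individual, observation period, prey category) with
#' a non-negative bite count. Absent combinations are implicitly zero bites;
#' explicit zero rows are retained. Non-coral categories (e.g. mucus, dead
#' coral) are allowed here and excluded later by [build_use_matrix()].
#'
#' @param path Path to a CSV file with columns `territory_id`, `individual_id`,
#'   `period_index`, `category`, `bites`.
#' @param scheme A [category_scheme()]. Bite categories may be any scheme
#'   label or any extra label listed in `extra_categories`.
#' @param n_periods Number of observation periods per individual (default 10);
#'   `period_index` must lie in `1..n_periods`.
#' @param extra_categories Additional non-scheme labels tolerated in the bite
#'   data (recorded non-prey items such as `"mucus"`).
#' @return A tibble with the five columns above.
#' @export
read_bite_records <- function(path, scheme = default_scheme(), n_periods = 10L,
                              extra_categories = c("mucus", "dead coral")) {
  df <- read_table_checked(
    path, c("territory_id", "individual_id", "period_index", "category", "bites")
  )
  df <- tibble::tibble(
    territory_id = as.character(df$territory_id),
    individual_id = as.character(df$individual_id),
    period_index = as.integer(df$period_index),
    category = as.character(df$category),
    bites = as.integer(df$bites)
  )
  if (nrow(df) == 0L) return(df)
  if (any(df$bites < 0L | is.na(df$bites))) {
    rows <- which(df$bites < 0L | is.na(df$bites))
    rlang::abort(sprintf(
      "Negative or missing bite count in %s at data row(s): %s.",
      path, paste(utils::head(rows, 5L), collapse = ", ")
    ))
  }
  bad_period <- which(df$period_index < 1L | df$period_index > n_periods | is.na(df$period_index))
  if (length(bad_period)) {
    rlang::abort(sprintf(
      "period_index outside 1..%d in %s at data row(s): %s.",
      n_periods, path, paste(utils::head(bad_period, 5L), collapse = ", ")
    ))
  }
  df$category <- check_categories(df$category, scheme, path, extra = extra_categories)
  key <- df[c("territory_id", "individual_id", "period_index", "category")]
  if (anyDuplicated(key)) {
    k <- df[which(duplicated(key))[1L], ]
    rlang::abort(sprintf(
      "Duplicate bite key in %s: (%s, %s, period %d, %s).",
      path, k$territory_id, k$individual_id, k$period_index, k$category
    ))
  }
  df
}

#' Read a territory metadata table
#'
#' @param path Path to a CSV file with columns `territory_id`, `site_class`
#'   (one of `low`, `intermediate`, `high`) and `perimeter_m` (metres, > 0).
#' @return A tibble with the three columns above.
#' @export
read_territories <- function(path) {
  df <- read_table_checked(path, c("territory_id", "site_class", "perimeter_m"))
  df <- tibble::tibble(
    territory_id = as.character(df$territory_id),
    site_class = tolower(trimws(as.character(df$site_class))),
    perimeter_m = as.numeric(df$perimeter_m)
  )
  if (nrow(df) == 0L) return(df)
  if (anyDuplicated(df$territory_id)) {
    rlang::abort(sprintf(
      "Duplicate territory_id in %s: %s.",
      path, paste(unique(df$territory_id[duplicated(df$territory_id)]), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(df$site_class), c("low", "intermediate", "high"))
  if (length(bad)) {
    rlang::abort(sprintf("Unknown site_class in %s: %s.", path, paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(df$perimeter_m) | df$perimeter_m <= 0)) {
    rlang::abort(sprintf("perimeter_m must be positive and finite in %s.", path))
  }
  df
}

#' Write survey tables back to CSV
#'
#' Plain comma-separated UTF-8 with a header row and no row names, the same
#' dialect the readers expect, so write-then-read round-trips.
#'
#' @param x A tibble as returned by one of the readers or generators.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' Cross-validate a full survey dataset
#'
#' Checks referential integrity and design expectations across the three
#' tables before analysis. Findings are reported, never raised: hard problems
#' (unknown territory references, unknown categories, negative counts) go to
#' `errors`; departures from the survey design (a territory without the
#' expected number of points, an individual observed for fewer than the
#' configured periods, a site-class label inconsistent with measured cover) go
#' to `warnings`.
#'
#' Cover/site-class consistency uses the conventional banding: low < 25%
#' live coral, intermediate 26-39%, high > 40%; values on a band boundary
#' only ever warn.
#'
#' @param points Point-count tibble ([read_point_counts()]).
#' @param bites Bite tibble ([read_bite_records()]).
#' @param territories Territory tibble ([read_territories()]).
#' @param scheme A [category_scheme()].
#' @param expected_points Expected points per territory (survey design:
#'   50 photos x 10 points = 500).
#' @param n_periods Configured observation periods per individual.
#' @param extra_bite_categories Non-scheme bite labels to tolerate.
#' @return A `validation_report`: list with `errors`, `warnings` (character
#'   vectors) and `counts` (named list). The dataset is admissible for
#'   analysis iff `errors` is empty.
#' @export
validate_dataset <- function(points, bites, territories,
                             scheme = default_scheme(),
                             expected_points = 500L,
                             n_periods = 10L,
                             extra_bite_categories = c("mucus", "dead coral")) {
  errors <- character()
  warnings <- character()

  known_t <- unique(territories$territory_id)
  miss_p <- setdiff(unique(points$territory_id), known_t)
  if (length(miss_p)) {
    errors <- c(errors, sprintf(
      "Point rows reference unknown territory_id: %s.", paste(miss_p, collapse = ", ")
    ))
  }
  miss_b <- setdiff(unique(bites$territory_id), known_t)
  if (length(miss_b)) {
    errors <- c(errors, sprintf(
      "Bite rows reference unknown territory_id: %s.", paste(miss_b, collapse = ", ")
    ))
  }
  ok_cat <- c(scheme_labels(scheme), extra_bite_categories)
  bad_cat <- setdiff(unique(bites$category), ok_cat)
  if (length(bad_cat)) {
    errors <- c(errors, sprintf(
      "Bite categories absent from scheme: %s.", paste(bad_cat, collapse = ", ")
    ))
  }
  bad_pcat <- setdiff(unique(points$category), scheme_labels(scheme))
  if (length(bad_pcat)) {
    errors <- c(errors, sprintf(
      "Point categories absent from scheme: %s.", paste(bad_pcat, collapse = ", ")
    ))
  }

  if (nrow(points)) {
    per_t <- table(points$territory_id)
    off <- per_t[per_t != expected_points]
    for (id in names(off)) {
      warnings <- c(warnings, sprintf(
        "Territory %s has %d points; survey design expects %d.",
        id, as.integer(off[[id]]), expected_points
      ))
    }
  }
  if (nrow(bites)) {
    per_i <- tapply(bites$period_index, bites$individual_id,
                    function(p) length(unique(p)))
    short <- per_i[per_i < n_periods]
    for (id in names(short)) {
      warnings <- c(warnings, sprintf(
        "Individual %s observed in %d of %d periods.",
        id, as.integer(short[[id]]), n_periods
      ))
    }
  }

  # site class vs measured cover (banding: low < 25, intermediate 26-39, high > 40)
  if (nrow(points) && nrow(territories)) {
    prof <- availability_profiles(points, scheme)
    joined <- dplyr::inner_join(prof[c("territory_id", "live_cover")],
                                territories, by = "territory_id")
    for (k in seq_len(nrow(joined))) {
      pct <- 100 * joined$live_cover[k]
      cls <- joined$site_class[k]
      ok <- switch(cls,
        low = pct < 25,
        intermediate = pct >= 25 && pct <= 40,
        high = pct > 40
      )
      if (!isTRUE(ok)) {
        warnings <- c(warnings, sprintf(
          "Territory %s: measured live cover %.1f%% is inconsistent with site_class '%s'.",
          joined$territory_id[k], pct, cls
        ))
      }
    }
  }

  structure(
    list(
      errors = errors,
      warnings = warnings,
      counts = list(
        territories = length(known_t),
        individuals = length(unique(bites$individual_id)),
        points = nrow(points),
        bites = sum(bites$bites)
      )
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat(sprintf(
    "  %d territories, %d individuals, %d points, %d bites\n",
    x$counts$territories, x$counts$individuals, x$counts$points, x$counts$bites
  ))
  cat(sprintf("  errors: %d\n", length(x$errors)))
  for (e in x$errors) cat("    - ", e, "\n", sep = "")
  cat(sprintf("  warnings: %d\n", length(x$warnings)))
  for (w in x$warnings) cat("    - ", w, "\n", sep = "")
  invisible(x)
}

# --- internal helpers ---------------------------------------------------

read_table_checked <- function(path, required_cols) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("File not found: %s", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s.", path, paste(missing, collapse = ", ")
    ))
  }
  df[required_cols]
}

check_categories <- function(x, scheme, path, extra = character()) {
  canon <- normalise_categories(x, scheme)
  if (length(extra)) {
    key <- tolower(trimws(x))
    hit <- match(key, tolower(trimws(extra)))
    canon[is.na(canon) & !is.na(hit)] <- extra[hit[is.na(canon) & !is.na(hit)]]
  }
  if (anyNA(canon)) {
    bad <- which(is.na(canon))
    rlang::abort(sprintf(
      "Unknown category label(s) in %s: %s (data row(s) %s).",
      path,
      paste(unique(x[bad]), collapse = ", "),
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  canon
}
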