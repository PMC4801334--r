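# Fixture writers and independent brute-force oracles used across the suite.

write_fixture <- function(df) {
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  path
}

points_fixture <- function(territory_id, photo_index, point_index, category) {
  tibble::tibble(
    territory_id = territory_id, photo_index = photo_index,
    point_index = point_index, category = category
  )
}

bites_fixture <- function(territory_id, individual_id, period_index, category, bites) {
  tibble::tibble(
    territory_id = territory_id, individual_id = individual_id,
    period_index = period_index, category = category, bites = bites
  )
}

# Term-by-term double-loop computation of the log-likelihood statistic,
# written independently of the vectorised implementation.
chi2_oracle <- function(counts, p) {
  total <- 0
  for (j in seq_len(nrow(counts))) {
    b <- sum(counts[j, ])
    for (i in seq_len(ncol(counts))) {
      u <- counts[j, i]
      if (u > 0) total <- total + u * log(u / (b * unname(p[i])))
    }
  }
  unname(2 * total)
}

# Textbook pooled-variance two-sample t.
pooled_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Per-point tally of pooled site availability: count points per prey
# category across the member territories, one point at a time.
site_availability_oracle <- function(points, territory_ids, scheme) {
  tal <- stats::setNames(numeric(length(scheme$prey_categories)),
                         scheme$prey_categories)
  for (k in seq_len(nrow(points))) {
    if (!points$territory_id[k] %in% territory_ids) next
    cat_k <- points$category[k]
    if (cat_k %in% scheme$prey_categories) tal[cat_k] <- tal[cat_k] + 1
  }
  tal / sum(tal)
}

# Construct a vector with exactly the requested mean and standard deviation.
vector_with_moments <- function(n, mean, sd) {
  base <- seq_len(n)
  mean + sd * (base - mean(base)) / stats::sd(base)
}

# A small fully consistent hand-built dataset: 2 territories, 100 points
# each, 1 pair per territory with bites over 2 periods.
tiny_dataset <- function() {
  sch <- default_scheme()
  pts <- dplyr::bind_rows(
    points_fixture("T1", rep(1:10, each = 10), rep(1:10, 10),
                   rep(c("Acropora", "Pocillopora", "rock", "sand"), 25)),
    points_fixture("T2", rep(1:10, each = 10), rep(1:10, 10),
                   rep(c("Acropora", "Porites", "rubble", "rock"), 25))
  )
  bt <- dplyr::bind_rows(
    bites_fixture("T1", "pair", c(1, 1, 2), c("Acropora", "Pocillopora", "Acropora"),
                  c(12, 5, 9)),
    bites_fixture("T2", "pair", c(1, 2, 2), c("Acropora", "Porites", "Acropora"),
                  c(7, 4, 11))
  )
  terr <- tibble::tibble(
    territory_id = c("T1", "T2"),
    site_class = c("high", "high"),
    perimeter_m = c(35, 42)
  )
  list(points = pts, bites = bt, territories = terr, scheme = sch)
}
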