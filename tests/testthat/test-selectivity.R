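avail_tbl <- function(p, cats = default_scheme()$prey_categories[seq_along(p)]) {
  tibble::tibble(category = cats, p = p)
}

test_that("use matrices aggregate periods and exclude non-coral items", {
  bt <- dplyr::bind_rows(
    bites_fixture("T1", "a", 1:2, "Acropora", c(4L, 3L)),
    bites_fixture("T1", "a", 1:2, "Pocillopora", c(1L, 2L)),
    bites_fixture("T1", "a", 2L, "mucus", 5L)
  )
  um <- build_use_matrix(bt, unit = "individual")
  expect_equal(dim(um$counts), c(1L, 7L))
  expect_equal(unname(um$counts[1, c("Acropora", "Pocillopora")]), c(7L, 3L))
  expect_equal(um$totals, 10)
  expect_false("mucus" %in% um$categories)

  # pair unit merges both members of the territory
  bt2 <- dplyr::bind_rows(
    bites_fixture("T1", "a", 1L, "Acropora", 6L),
    bites_fixture("T1", "b", 1L, "Acropora", 4L)
  )
  expect_equal(nrow(build_use_matrix(bt2, unit = "pair")$counts), 1L)
  expect_equal(build_use_matrix(bt2, unit = "pair")$totals, 10)
  expect_equal(nrow(build_use_matrix(bt2, unit = "individual")$counts), 2L)

  expect_error(build_use_matrix(bt[0, ]), "No coral bite")
  only_mucus <- bites_fixture("T1", "a", 1L, "mucus", 3L)
  expect_error(build_use_matrix(only_mucus), "No coral bite")

  # a unit recording zero coral bites is dropped with a warning
  mixed <- dplyr::bind_rows(bt2, bites_fixture("T2", "c", 1L, c("Acropora", "sand"), c(0L, 9L)))
  expect_warning(um2 <- build_use_matrix(mixed, unit = "pair"), "zero coral bites")
  expect_equal(um2$units, "T1")
})

test_that("the log-likelihood statistic matches closed forms", {
  # counts exactly at expectation: statistic is zero
  u0 <- use_matrix(matrix(c(5, 5), 1, dimnames = list(NULL, c("Acropora", "Porites"))))
  st0 <- suppressWarnings(chi2_log_likelihood(u0, avail_tbl(c(0.5, 0.5), c("Acropora", "Porites"))))
  expect_equal(st0$chi2_l2, 0)
  expect_equal(st0$p_value, 1)

  # one unit, all 10 bites on one of two equally available corals
  u1 <- use_matrix(matrix(c(10, 0), 1, dimnames = list(NULL, c("Acropora", "Porites"))))
  st1 <- suppressWarnings(chi2_log_likelihood(u1, avail_tbl(c(0.5, 0.5), c("Acropora", "Porites"))))
  expect_equal(st1$chi2_l2, 2 * 10 * log(2), tolerance = 1e-12)
  expect_equal(st1$df, 1L)

  # two units each (8, 2) against (0.5, 0.5)
  u2 <- use_matrix(matrix(c(8, 8, 2, 2), 2, dimnames = list(NULL, c("Acropora", "Porites"))))
  st2 <- suppressWarnings(chi2_log_likelihood(u2, avail_tbl(c(0.5, 0.5), c("Acropora", "Porites"))))
  expect_equal(st2$chi2_l2, 2 * 2 * (8 * log(1.6) + 2 * log(0.4)), tolerance = 1e-12)
  expect_equal(st2$df, 2L)
  expect_equal(st2$expected, matrix(5, 2, 2, dimnames = dimnames(u2$counts)))
})

test_that("the statistic equals a term-by-term double-loop oracle", {
  withr::with_seed(512, {
    for (rep in 1:100) {
      n <- sample(1:6, 1)
      k <- sample(2:7, 1)
      p <- rgamma(k, 2); p <- p / sum(p)
      m <- t(rmultinom(n, sample(20:200, 1), p))
      colnames(m) <- paste0("cat", seq_len(k))
      st <- suppressWarnings(
        chi2_log_likelihood(use_matrix(m), avail_tbl(p, colnames(m)))
      )
      expect_equal(st$chi2_l2, chi2_oracle(m, p), tolerance = 1e-9)
      expect_gte(st$chi2_l2, 0)
      expect_equal(st$df, n * (k - 1L))
    }
  })
})

test_that("the statistic is invariant to unit and category permutations", {
  withr::with_seed(77, {
    p <- c(0.5, 0.2, 0.2, 0.1)
    m <- t(rmultinom(5, 60, p))
    colnames(m) <- c("w", "x", "y", "z")
    base <- suppressWarnings(chi2_log_likelihood(use_matrix(m), avail_tbl(p, colnames(m))))
    for (rep in 1:10) {
      ri <- sample(nrow(m)); ci <- sample(ncol(m))
      perm <- suppressWarnings(chi2_log_likelihood(
        use_matrix(m[ri, ci, drop = FALSE]),
        avail_tbl(p[ci], colnames(m)[ci])
      ))
      expect_equal(perm$chi2_l2, base$chi2_l2, tolerance = 1e-12)
    }
  })
})

test_that("zero-availability categories are handled per their use", {
  # unavailable and unused: dropped with a warning, df shrinks
  m <- matrix(c(6, 4, 0), 1, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(
    expect_warning(
      chi2_log_likelihood(use_matrix(m), avail_tbl(c(0.6, 0.4, 0), c("a", "b", "c"))),
      "Dropping"
    ),
    "below 5" # the surviving expected counts are small, which also warns
  )
  st <- suppressWarnings(
    chi2_log_likelihood(use_matrix(m), avail_tbl(c(0.6, 0.4, 0), c("a", "b", "c")))
  )
  expect_equal(st$df, 1L)
  expect_false(st$incompatible)

  # unavailable but used: incompatible, statistic infinite
  m2 <- matrix(c(6, 4, 2), 1, dimnames = list(NULL, c("a", "b", "c")))
  st2 <- suppressWarnings(
    chi2_log_likelihood(use_matrix(m2), avail_tbl(c(0.6, 0.4, 0), c("a", "b", "c")))
  )
  expect_true(st2$incompatible)
  expect_identical(st2$chi2_l2, Inf)

  expect_error(
    suppressWarnings(chi2_log_likelihood(use_matrix(m), avail_tbl(c(0, 0, 0), c("a", "b", "c")))),
    "zero"
  )
})

test_that("small expected counts trigger a warning", {
  m <- matrix(c(40, 1), 1, dimnames = list(NULL, c("a", "b")))
  expect_warning(
    chi2_log_likelihood(use_matrix(m), avail_tbl(c(0.95, 0.05), c("a", "b"))),
    "below 5"
  )
})

test_that("selection ratios, standard errors and intervals follow the estimator", {
  # two units with per-unit ratios 2 and 3 for the first category
  m <- matrix(c(8, 12, 2, 8), 2, dimnames = list(NULL, c("a", "b")))
  # unit ratios for a: (0.8/p) and (0.6/p); choose p = 0.3 -> 8/3, 2
  av <- avail_tbl(c(0.3, 0.7), c("a", "b"))
  rsf <- selection_functions(use_matrix(m), av)
  r_a <- c((8 / 10) / 0.3, (12 / 20) / 0.3)
  expect_equal(rsf$w[1], mean(r_a))
  expect_equal(rsf$se[1], sd(r_a) / sqrt(2))

  # the worked two-ratio case: ratios 2.0 and 3.0 give w 2.5, se 0.5
  expect_equal(mean(c(2, 3)), 2.5)
  expect_equal(sd(c(2, 3)) / sqrt(2), 0.5)
  m2 <- matrix(c(20, 30, 80, 70), 2, dimnames = list(NULL, c("a", "b")))
  rsf2 <- selection_functions(use_matrix(m2), avail_tbl(c(0.1, 0.9), c("a", "b")))
  expect_equal(rsf2$w[1], 2.5)
  expect_equal(rsf2$se[1], 0.5)

  # neutral use: every unit proportional to availability
  p <- c(0.5, 0.3, 0.2)
  m3 <- rbind(p * 100, p * 200)
  colnames(m3) <- c("a", "b", "c")
  rsf3 <- selection_functions(use_matrix(m3), avail_tbl(p, colnames(m3)))
  expect_equal(rsf3$w, rep(1, 3))
  expect_equal(unique(rsf3$classification), "proportional")

  # Bonferroni quantile honours the family size
  rsf_i7 <- selection_functions(use_matrix(m2), avail_tbl(c(0.1, 0.9), c("a", "b")),
                                n_categories_for_correction = 7)
  z7 <- qnorm(1 - 0.05 / 14)
  expect_equal(rsf_i7$ci_high[1] - rsf_i7$w[1], z7 * 0.5, tolerance = 1e-12)

  # single unit: zero se, degenerate interval
  rsf1 <- selection_functions(use_matrix(m2[1, , drop = FALSE]),
                              avail_tbl(c(0.1, 0.9), c("a", "b")))
  expect_equal(rsf1$se, c(0, 0))
  expect_equal(rsf1$ci_low, rsf1$w)

  expect_error(
    selection_functions(use_matrix(matrix(c(5, 5), 1, dimnames = list(NULL, c("a", "b")))),
                        avail_tbl(c(0, 1), c("a", "b"))),
    "zero availability"
  )
})

test_that("availability-weighted ratios always average to one", {
  withr::with_seed(2024, {
    for (rep in 1:50) {
      n <- sample(1:9, 1); k <- sample(2:7, 1)
      p <- rgamma(k, 1.5); p <- p / sum(p)
      m <- t(rmultinom(n, 150, rgamma(k, 1) / 1)) + 1 # +1 keeps totals positive
      colnames(m) <- paste0("c", seq_len(k))
      rsf <- selection_functions(use_matrix(m), avail_tbl(p, colnames(m)))
      expect_equal(sum(rsf$p * rsf$w), 1, tolerance = 1e-9)
    }
  })
})

test_that("classification follows the interval bounds", {
  expect_equal(
    classify_selection(c(1.4, 0.1, 0.8), c(2.6, 0.5, 1.4)),
    c("preference", "avoidance", "proportional")
  )
  rsf_like <- classify_selection(1.0, 1.0) # bounds at exactly 1
  expect_equal(rsf_like, "proportional")
})

test_that("anomalous zero use drags the mean ratio below the pooled ratio", {
  # five units genuinely consume a rare category, two units happen to record
  # zero bites on it: the mean-of-ratios estimator is pulled toward zero
  # relative to the pooled estimator.
  p <- c(0.05, 0.95)
  m <- rbind(
    c(2, 38), c(1, 39), c(2, 38), c(0, 10), c(0, 10)
  )
  colnames(m) <- c("rare", "common")
  rsf <- suppressWarnings(selection_functions(use_matrix(m), avail_tbl(p, colnames(m))))
  pooled_w <- (sum(m[, "rare"]) / sum(m)) / p[1]
  expect_lt(rsf$w[rsf$category == "rare"], pooled_w)
})
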