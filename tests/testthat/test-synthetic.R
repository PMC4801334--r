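test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(seed = 7)
  s1 <- generate_survey(cfg)
  s2 <- generate_survey(cfg)
  expect_identical(s1$territories, s2$territories)
  expect_identical(s1$points, s2$points)
  expect_identical(s1$bites, s2$bites)

  s3 <- generate_survey(synthetic_config(seed = 8))
  expect_false(identical(s1$bites, s3$bites))
})

test_that("defaults reproduce the survey design constants", {
  sim <- generate_survey(synthetic_config(seed = 2))
  expect_equal(nrow(sim$territories), 23L) # 8 low + 6 intermediate + 9 high
  expect_equal(
    as.integer(table(sim$territories$site_class)[c("low", "intermediate", "high")]),
    c(8L, 6L, 9L)
  )
  per_t <- table(sim$points$territory_id)
  expect_true(all(per_t == 500L)) # 50 photos x 10 points
  expect_lte(max(sim$bites$period_index), 10L)
  # pair unit: one observation unit per territory
  expect_equal(dplyr::n_distinct(sim$bites$individual_id), 1L)
  ind <- generate_survey(synthetic_config(unit = "individual", seed = 2))
  expect_setequal(unique(ind$bites$individual_id), c("ind1", "ind2"))
})

test_that("noise-free territories sit exactly on the size law", {
  cfg <- synthetic_config(size_noise_sd_log10 = 0, seed = 5)
  g <- generate_territories(cfg)
  cover_pct <- 100 * g$truth$territories$cover
  expect_equal(g$territories$perimeter_m,
               cfg$power_a * cover_pct^cfg$power_b, tolerance = 1e-12)
  fit <- fit_power_law(cover_pct, g$territories$perimeter_m)
  expect_equal(fit$exponent_b, cfg$power_b, tolerance = 1e-9)
  expect_equal(fit$coefficient_a, cfg$power_a, tolerance = 1e-6)

  # covers respect their site class bands
  tt <- g$truth$territories
  rng <- cfg$cover_range
  for (s in unique(tt$site_class)) {
    pct <- 100 * tt$cover[tt$site_class == s]
    expect_true(all(pct >= rng[[s]][1] & pct <= rng[[s]][2]))
  }
})

test_that("empirical cover tracks true cover within binomial error", {
  hits <- 0L; total <- 0L
  for (seed in c(3, 4)) {
    sim <- generate_survey(synthetic_config(seed = seed))
    prof <- availability_profiles(sim$points)
    j <- dplyr::inner_join(prof, sim$truth$territories, by = "territory_id")
    total <- total + nrow(j)
    hits <- hits + sum(abs(j$live_cover - j$cover) <= 0.05)
  }
  # binomial se over 500 points is at most ~0.022, so 5 points of cover is >2 se
  expect_gte(hits / total, 0.95)
})

test_that("degenerate composition and selection configs are rejected", {
  expect_error(
    synthetic_config(composition_mean = list(
      low = c(0.5, 0.5, 0, 0, 0, 0, 0.5),
      intermediate = rep(1 / 7, 7), high = rep(1 / 7, 7)
    )),
    "probability vector"
  )
  expect_error(
    synthetic_config(true_w = list(
      low = rep(0, 7), intermediate = rep(1, 7), high = rep(1, 7)
    )),
    "true_w"
  )
  expect_error(
    synthetic_config(cover_range = list(low = c(30, 20), intermediate = c(26, 39),
                                        high = c(40, 62))),
    "cover_range"
  )
})

test_that("single-category cover generates only that category", {
  cfg <- synthetic_config(
    n_territories = c(low = 0, intermediate = 0, high = 2),
    cover_range = list(low = c(1, 2), intermediate = c(1, 2), high = c(99.99, 100)),
    composition_mean = list(
      low = rep(1 / 7, 7), intermediate = rep(1 / 7, 7),
      high = c(1, 0, 0, 0, 0, 0, 0)
    ),
    composition_concentration = Inf,
    seed = 6
  )
  pts <- generate_point_counts(generate_territories(cfg)$truth, cfg)
  expect_gte(mean(pts$category == "Acropora"), 0.999)
})

test_that("generated datasets validate with zero errors", {
  for (seed in c(10, 20)) {
    sim <- generate_survey(synthetic_config(seed = seed))
    rep <- validate_dataset(sim$points, sim$bites, sim$territories)
    expect_length(rep$errors, 0)
  }
})

test_that("per-territory substreams leave existing territories unchanged", {
  small <- generate_survey(synthetic_config(
    n_territories = c(low = 3, intermediate = 0, high = 4), seed = 12
  ))
  big <- generate_survey(synthetic_config(
    n_territories = c(low = 5, intermediate = 2, high = 6), seed = 12
  ))
  keep <- small$territories$territory_id
  expect_identical(
    small$territories,
    dplyr::filter(big$territories, territory_id %in% keep)
  )
  expect_identical(
    small$bites,
    dplyr::filter(big$bites, territory_id %in% keep)
  )
})

test_that("empirical margins converge to the configured distributions", {
  # one massive territory: composition of points converges to truth
  cfg <- synthetic_config(
    n_territories = c(low = 0, intermediate = 0, high = 1),
    photos_per_territory = 10000L, # 1e5 points
    composition_concentration = Inf,
    bite_rate = 10000, # 1e5 bites over 10 periods
    seed = 17
  )
  g <- generate_territories(cfg)
  pts <- generate_point_counts(g$truth, cfg)
  prof <- availability_profiles(pts)
  expect_equal(prof$live_cover, g$truth$territories$cover, tolerance = 0.01)
  comp_hat <- as.numeric(prof[1, cfg$scheme$prey_categories])
  expect_equal(comp_hat, as.numeric(g$truth$composition[1, ]), tolerance = 0.01)

  # bite allocation converges to w * p renormalised
  bt <- generate_bites(g$truth, cfg)
  um <- build_use_matrix(bt, cfg$scheme, unit = "pair")
  q <- cfg$true_w$high * g$truth$composition[1, ]
  q <- q / sum(q)
  expect_equal(as.numeric(um$counts / um$totals), as.numeric(q), tolerance = 0.01)
})

test_that("true selection drives estimated selection in large samples", {
  # 4-fold preference for the first category is recovered as w > 1 there
  cfg <- synthetic_config(
    n_territories = c(low = 0, intermediate = 0, high = 5),
    composition_mean = list(low = rep(1 / 7, 7), intermediate = rep(1 / 7, 7),
                            high = rep(1 / 7, 7)),
    composition_concentration = Inf,
    true_w = list(low = rep(1, 7), intermediate = rep(1, 7),
                  high = c(4, 1, 1, 1, 1, 1, 1)),
    bite_rate = 200,
    seed = 19
  )
  sim <- generate_survey(cfg)
  avail <- site_availability(sim$points, sim$territories$territory_id)
  um <- build_use_matrix(sim$bites)
  rsf <- selection_functions(um, avail)
  expect_gt(rsf$w[rsf$category == "Acropora"], 1)
  expect_equal(which.max(rsf$w), which(rsf$category == "Acropora"))
})

test_that("the recovery experiment scores unbiasedness and coverage", {
  cfg <- synthetic_config(
    n_territories = c(low = 0, intermediate = 0, high = 9),
    composition_concentration = Inf, seed = 11
  )
  rep <- recovery_experiment(cfg, 30, availability = "true", fit_sizes = FALSE)
  expect_equal(nrow(rep$tests), 30L)
  expect_equal(nrow(rep$ratios), 30L * 7L)
  s <- rep$summary$ratios
  expect_true(all(abs(s$bias) < 0.5))
  expect_true(all(s$coverage > 0.8))
  # strong selection should essentially always be detected at this scale
  expect_gt(rep$summary$tests$rejection_rate, 0.9)
})
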