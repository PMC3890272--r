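test_that("size-spectrum slope matches exact log-log lines", {
  expect_equal(size_spectra_slope(c(5, 5, 5, 5), c(1, 2, 4, 8)), 0,
               tolerance = 1e-12)
  s <- c(1, 2, 4, 8)
  expect_equal(size_spectra_slope(s^-2, s), -2, tolerance = 1e-12)
  expect_true(is.na(size_spectra_slope(c(3), c(10))))
  expect_true(is.na(size_spectra_slope(c(3, 0, 0, 1), c(1, 2, 3, 4))))
})

test_that("Shannon diversity has its closed-form values and limits", {
  expect_equal(shannon_diversity(rep(10, 4)), log(4))
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_lt(shannon_diversity(c(1e6, 1, 1)), 0.01)
  expect_true(is.na(shannon_diversity(c(0, 0))))
})

test_that("inversion and normalisation follow the best-equals-one rule", {
  tab <- data.frame(
    strategy = rep(c("A", "B", "C"), 2),
    year = 1,
    indicator = rep(c("up", "down"), each = 3),
    class = "economic",
    starred = rep(c(FALSE, TRUE), each = 3),
    value = c(2, 4, 8, 2, 4, 8))
  ut <- invert_and_normalize(tab)
  expect_equal(ut$value[ut$indicator == "up"], c(0.25, 0.5, 1.0))
  expect_equal(ut$value[ut$indicator == "down"], c(1.0, 4 / 6, 0.0))
  # constant series map to 1 everywhere
  tab2 <- tab[1:3, ]; tab2$value <- 5
  expect_equal(invert_and_normalize(tab2)$value, rep(1, 3))
})

test_that("normalisation contract holds for random tables", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 8
    tab <- data.frame(strategy = rep(c("A", "B"), each = n / 2),
                      year = rep(1:2, n / 2),
                      indicator = sample(c("i1", "i2"), n, TRUE),
                      class = "social",
                      starred = FALSE,
                      value = stats::rnorm(n))
    tab$starred <- tab$indicator == "i2"
    ut <- invert_and_normalize(tab)
    expect_true(all(ut$value >= 0 & ut$value <= 1 + 1e-12))
    for (ind in unique(ut$indicator))
      expect_equal(max(ut$value[ut$indicator == ind]), 1)
  }
})

test_that("starred indicators reverse direction (more discards, lower score)", {
  tab <- data.frame(strategy = c("A", "B"), year = 1, indicator = "discards",
                    class = "industry", starred = TRUE, value = c(100, 300))
  ut <- invert_and_normalize(tab)
  expect_gt(ut$value[1], ut$value[2])
})

test_that("composite scores are weighted means with the stated properties", {
  tab <- data.frame(strategy = "A", year = 1,
                    indicator = c("i1", "i2"), class = "economic",
                    starred = FALSE, value = c(1.0, 0.5))
  expect_equal(composite_scores(tab)$score, 0.75)
  tabw <- tab; tabw$value <- c(1, 0)
  expect_equal(composite_scores(tabw, weights = c(i1 = 0.75, i2 = 0.25))$score,
               0.75)
  expect_equal(composite_scores(transform(tab, value = c(1, 1)))$score, 1)
  # permutation invariance and monotonicity
  expect_equal(composite_scores(tab[2:1, ])$score, 0.75)
  tab_up <- tab; tab_up$value[2] <- 0.6
  expect_gt(composite_scores(tab_up)$score, 0.75)
  expect_error(composite_scores(tab[0, ]), "empty")
})

test_that("indicator catalogue covers every class with correct stars", {
  cat <- indicator_catalogue()
  expect_setequal(unique(cat$class),
                  c("industry", "operator", "management_cost", "social",
                    "economic", "ecological"))
  starred <- cat$indicator[cat$starred]
  expect_true(all(c("discards", "habitat_impact", "tep_interactions",
                    "total_effort", "catch_composition", "gear_conflict",
                    "operating_costs", "microfaunal_biomass",
                    "size_spectra_change") %in% starred))
  expect_true(all(cat$indicator[cat$class == "management_cost"] %in% starred))
  expect_false(any(c("total_landings", "gvp", "public_image",
                     "biomass_target") %in% starred))
})

test_that("indicator table is complete and a pure function of the run", {
  res <- ref_run("S1_status_quo")
  cfg <- ref_cfg()
  it1 <- compute_indicator_table(res, cfg)
  it2 <- compute_indicator_table(res, cfg)
  expect_identical(it1, it2)
  expect_setequal(setdiff(unique(it1$indicator),
                          c("cpue_low_tl", "cpue_high_tl", "diversity",
                            "trip_length")),
                  indicator_catalogue()$indicator)
  yrs <- sort(unique(res$annual$year))
  expect_equal(sort(unique(it1$year)), yrs)
  # catch composition equals the max single-group landings share
  y <- 15
  lg <- res$annual_raw[[y]]$landings_by_group
  expect_equal(it1$value[it1$indicator == "catch_composition" & it1$year == y],
               max(lg) / sum(lg))
})

test_that("quartile bands use the linear-interpolation rule", {
  expect_equal(shelfmse:::band_quantile(c(1, 2, 3, 4), 0.25), 1.75)
  expect_equal(shelfmse:::band_quantile(c(1, 2, 3, 4), 0.75), 3.25)
  ind <- data.frame(strategy = "A", year = 1, indicator = "x",
                    class = "economic", starred = FALSE,
                    value = c(1, 2, 3, 4), member = 0:3)
  b <- quartile_bands(ind)
  expect_equal(b$lower, 1.75)
  expect_equal(b$upper, 3.25)
  expect_equal(b$best_fit, 1)
  # identical members collapse the band onto the trajectory
  ind2 <- ind; ind2$value <- 2
  b2 <- quartile_bands(ind2)
  expect_equal(b2$lower, 2)
  expect_equal(b2$upper, 2)
})
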