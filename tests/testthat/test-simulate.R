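test_that("group matrices draw cells uniformly within the count range", {
  set.seed(101)
  m <- random_group_matrix(50, 5, c(0, 250))
  expect_equal(dim(m), c(5, 50))
  expect_true(all(m >= 0 & m <= 250))
  # uniform moment: mean near (low + high) / 2
  big <- random_group_matrix(200, 50, c(0, 250))
  expect_lt(abs(mean(big) - 125), 3)
  # degenerate range: constant matrix, perfectly consistent
  m3 <- random_group_matrix(1, 2, c(3, 3))
  expect_true(all(m3 == 3))
  expect_identical(dc(m3)$dc, 1)
  expect_error(random_group_matrix(5, 5, c(10, 2)), "low <= high")
})

test_that("territorial matrices place N holders on N distinct territories", {
  set.seed(102)
  m <- random_territorial_matrix(100, 5, c(25, 75))
  expect_equal(dim(m), c(5, 100))
  expect_true(all(m %in% c(0L, 1L)))
  expect_true(all(rowSums(m) >= 25 & rowSums(m) <= 75))
  sat <- random_territorial_matrix(10, 2, c(10, 10))
  expect_true(all(sat == 1))
  expect_identical(dc(sat)$dc, 1)
  expect_error(random_territorial_matrix(10, 2, c(5, 11)), "cannot place")
})

test_that("survey error thins each time step by exactly round(rate * N)", {
  m <- dc_example_matrix("groups")
  expect_identical(apply_survey_error(m, 0), m)
  # all individuals at one site: removals are forced there
  row1 <- rbind(c(4, 0, 0), c(4, 0, 0))
  thinned <- apply_survey_error(row1, 0.5)
  expect_equal(rowSums(thinned), c(2, 2), ignore_attr = TRUE)
  expect_equal(thinned[, 1], c(2L, 2L), ignore_attr = TRUE)
  set.seed(103)
  for (i in 1:20) {
    mm <- random_nonzero_survey(4, 8, 6)
    rate <- runif(1, 0.05, 0.9)
    obs <- apply_survey_error(mm, rate)
    expect_true(all(obs >= 0))
    expect_true(all(obs <= mm))
    n_t <- rowSums(mm)
    expect_equal(rowSums(obs), n_t - floor(rate * n_t + 0.5),
                 ignore_attr = TRUE)
  }
  expect_error(apply_survey_error(m, 1), "\\[0, 1\\)")
  expect_error(apply_survey_error(m, -0.1), "\\[0, 1\\)")
})

test_that("thinning removes individuals evenly across sites on average", {
  # expected observed count at each site is (1 - rate) * true count
  m <- rbind(c(40, 10, 50), c(20, 30, 50))
  rate <- 0.4
  set.seed(104)
  tot <- matrix(0, 2, 3)
  reps <- 400
  for (i in seq_len(reps)) tot <- tot + apply_survey_error(m, rate)
  expect_equal(unname(tot / reps), unname(m * (1 - rate)), tolerance = 0.05)
})

test_that("error studies are reproducible and quiet at low error rates", {
  cfg <- list(n_patterns = 6, n_sites = 20, error_rates = c(0.05, 0.5),
              n_error_reps = 3, seed = 9)
  a <- do.call(run_group_error_study, cfg)
  b <- do.call(run_group_error_study, cfg)
  expect_identical(a$results, b$results)
  expect_equal(nrow(a$results), 6 * 2 * 3)
  expect_true(all(a$results$rel_change >= 0))
  # smaller error, smaller distortion
  expect_lt(a$summary$mean_rel_change[a$summary$error_rate == 0.05],
            a$summary$mean_rel_change[a$summary$error_rate == 0.5] + 1e-12)
  expect_lt(a$summary$mean_rel_change[1], 0.05)
  expect_error(run_group_error_study(error_rates = c(0, 0.5)),
               "within \\(0, 1\\)")
})

test_that("territorial error is predictable and correctable", {
  st <- run_territorial_error_study(
    n_patterns = 12, n_sites = 60, pop_range = c(15, 45),
    error_rates = seq(0.1, 0.7, by = 0.1), n_error_reps = 4, seed = 21
  )
  expect_gt(st$correction$r_squared, 0.9)
  # near-zero error leaves DC nearly unchanged
  tiny <- run_territorial_error_study(
    n_patterns = 6, n_sites = 60, pop_range = c(15, 45),
    error_rates = 0.02, n_error_reps = 4, seed = 22, fit_correction = FALSE
  )
  expect_lt(mean(tiny$results$rel_change), 0.1)
  # correction shrinks the bias of the raw observed DC
  corrected <- correct_dc(st, st$results$observed_dc, st$results$error_rate)
  raw_bias <- mean(abs(st$results$observed_dc - st$results$true_dc))
  corr_bias <- mean(abs(corrected - st$results$true_dc))
  expect_lt(corr_bias, raw_bias)
  expect_error(correct_dc(list(), 0.5, 0.1), "dc_error_study")
})

test_that("dispersal simulation links movement rate to DC", {
  # no movement: every individual stays put, DC is exactly 1
  still <- simulate_dispersal(n_individuals = 20, n_sites = 30,
                              n_steps = 6, dc_window = 4,
                              dispersal_rates = c(0, 0.5), n_reps = 2,
                              seed = 5)
  expect_true(all(still$samples$dc[still$samples$rate == 0] == 1))
  # determinism
  again <- simulate_dispersal(n_individuals = 20, n_sites = 30,
                              n_steps = 6, dc_window = 4,
                              dispersal_rates = c(0, 0.5), n_reps = 2,
                              seed = 5)
  expect_identical(still$samples, again$samples)
  # more dispersal, less consistency (means over a modest replicate count)
  sim <- simulate_dispersal(n_individuals = 60, n_sites = 60,
                            n_steps = 12, dc_window = 6,
                            dispersal_rates = c(0.1, 0.5, 0.9),
                            n_reps = 10, seed = 6)
  mu <- tapply(sim$samples$dc, sim$samples$rate, mean)
  expect_true(all(diff(mu) < 0))
  expect_true(all(sim$samples$dc > 0 & sim$samples$dc <= 1))
  # 1/DC is close to linear in rate even at this small size
  expect_gt(sim$r_squared, 0.8)
  # inverting the regression recovers the simulated rates roughly
  est <- predict(sim, mu)
  expect_lt(mean(abs(est - c(0.1, 0.5, 0.9))), 0.15)
  expect_error(predict(sim, 0), "\\(0, 1\\]")
  expect_error(simulate_dispersal(dispersal_rates = 1.2), "\\[0, 1\\]")
  expect_error(simulate_dispersal(n_steps = 5, dc_window = 6),
               "cannot exceed")
})

test_that("dispersers can be barred from their current site", {
  sim <- simulate_dispersal(n_individuals = 15, n_sites = 4, n_steps = 5,
                            dc_window = 3, dispersal_rates = 0.8,
                            n_reps = 2, seed = 8, exclude_current = TRUE)
  expect_true(all(sim$samples$dc > 0 & sim$samples$dc <= 1))
})
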