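test_that("per-site consistency counts follow the sorted-differencing rule", {
  cases <- list(
    # counts, expected k = 2..y
    list(c(3, 2, 1, 0), c(`2` = 1L, `3` = 1L, `4` = 0L)),
    list(c(1, 2, 0, 0), c(`2` = 1L, `3` = 0L, `4` = 0L)),
    list(c(3, 3, 3, 3), c(`2` = 0L, `3` = 0L, `4` = 3L)),
    list(c(5, 0, 0, 0), c(`2` = 0L, `3` = 0L, `4` = 0L)),
    list(c(0, 0, 0, 0), c(`2` = 0L, `3` = 0L, `4` = 0L)),
    list(c(2, 2), c(`2` = 2L))
  )
  for (cs in cases) {
    expect_identical(site_observed_consistency(cs[[1]]), cs[[2]])
  }
  expect_error(site_observed_consistency(c(1, -1)), "non-negative")
  expect_error(site_observed_consistency(c(1.5, 1)), "whole numbers")
  expect_error(site_observed_consistency(3), "at least 2 time steps")
})

test_that("regional observed consistency reproduces both worked summaries", {
  o1 <- observed_consistency(dc_example_matrix("territorial"))
  expect_equal(as.vector(o1), c(7L, 4L, 1L))
  o5 <- observed_consistency(dc_example_matrix("groups"))
  expect_equal(as.vector(o5), c(11L, 6L, 3L))
  # per-site contributions sum to O_k, and match the per-site rule
  m <- dc_example_matrix("groups")
  ps <- attr(o5, "per_site")
  expect_equal(rowSums(ps), as.vector(o5), ignore_attr = TRUE)
  for (s in seq_len(ncol(m))) {
    expect_equal(as.vector(ps[, s]),
                 as.vector(site_observed_consistency(m[, s])))
  }
  zero2 <- matrix(0, 3, 4)
  expect_equal(as.vector(observed_consistency(zero2)), c(0L, 0L))
})

test_that("nesting adjustment applies binomial weights over higher levels", {
  expect_equal(adjust_observed(c(`2` = 7, `3` = 4, `4` = 1), y = 4),
               c(`2` = 25, `3` = 8, `4` = 1))
  # P individuals fully consistent over all 4 steps
  for (P in c(1, 3, 10)) {
    expect_equal(adjust_observed(c(`2` = 0, `3` = 0, `4` = P), y = 4),
                 c(`2` = 6 * P, `3` = 4 * P, `4` = P))
  }
  expect_error(adjust_observed(c(`2` = 1), y = 4), "covering levels")
})

test_that("the full decomposition reproduces the worked example", {
  fit <- dc(dc_example_matrix("territorial"))
  expect_equal(as.vector(fit$M), c(49, 32, 8))
  expect_equal(as.vector(fit$O), c(7L, 4L, 1L))
  expect_equal(as.vector(fit$O_adj), c(25, 8, 1))
  expect_equal(as.vector(fit$R), c(25 / 49, 0.25, 0.125))
  expect_equal(fit$dc, (25 / 49 + 0.25 + 0.125) / 3)
  expect_equal(fit$pop_sizes, c(9, 9, 8, 8))
  expect_length(fit$levels_excluded, 0)
})

test_that("fully consistent and fully inconsistent matrices hit the bounds", {
  expect_equal(dc(dc_example_matrix("consistent"))$dc, 1)
  expect_equal(dc(dc_example_matrix("inconsistent"))$dc, 0)
})

test_that("group-occupancy matrices use the same code path as binary ones", {
  fit <- dc(dc_example_matrix("groups"))
  # cross-checked against the brute-force subset-minimum oracle
  m <- dc_example_matrix("groups")
  expect_equal(as.vector(fit$M),
               vapply(2:4, function(k) brute_M(m, k), numeric(1)))
  expect_equal(as.vector(fit$O_adj),
               vapply(2:4, function(k) brute_adjusted(m, k), numeric(1)))
  expect_equal(fit$dc, brute_dc(m))
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(dc(matrix(0, 3, 4)), "no individuals")
  expect_error(dc(matrix(1, 1, 4)), "at least 2 time steps")
  expect_error(dc(matrix(c(1, 2.5, 0, 1), 2, 2)), "whole numbers")
  expect_error(dc(matrix(c(1, -1, 0, 1), 2, 2)), "non-negative")
  expect_error(as_survey_matrix(matrix(c(1, NA, 0, 1), 2, 2)), "finite")
  big <- matrix(1L, 26, 2)
  expect_error(dc(big), "max_steps")
  expect_s3_class(dc(big, max_steps = 26), "dc")
})

test_that("levels where no consistency was possible are excluded", {
  # one empty year: every subset containing it has minimum 0
  m <- rbind(c(2, 1, 0), c(0, 0, 0), c(2, 0, 1))
  fit <- dc(m)
  expect_equal(fit$levels_excluded, 3L)
  expect_true(is.na(fit$R["3"]))
  expect_equal(fit$dc, fit$R[["2"]])
  expect_equal(fit$dc, brute_dc(m))
})

test_that("dc methods expose the decomposition consistently", {
  fit <- dc(dc_example_matrix("territorial"))
  s <- summary(fit)
  expect_equal(s$table$R, as.vector(fit$R))
  cf <- coef(fit)
  expect_named(cf, c("R2", "R3", "R4", "DC"))
  expect_equal(cf[["DC"]], fit$dc)
  df <- as.data.frame(fit)
  expect_equal(df$k, 2:4)
  expect_output(print(fit), "DC = 0.2951")
  expect_output(print(s), "O_adj")
})
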