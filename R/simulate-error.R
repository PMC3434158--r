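# Draw one sub-seed per stochastic unit so studies are reproducible from a
# single root seed and units are independent of one another.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

run_error_study <- function(type, n_patterns, n_sites, n_steps, range,
                            error_rates, n_error_reps, seed) {
  if (any(error_rates <= 0 | error_rates >= 1)) {
    stop("error_rates must lie strictly within (0, 1)")
  }
  if (n_error_reps < 1) stop("n_error_reps must be at least 1")
  n_rates <- length(error_rates)
  all_seeds <- derive_seeds(seed, n_patterns * (1 + n_rates * n_error_reps))
  seed_mat <- matrix(all_seeds, nrow = n_patterns)

  n_regenerated <- 0L
  rows <- vector("list", n_patterns)
  for (p in seq_len(n_patterns)) {
    set.seed(seed_mat[p, 1])
    repeat {
      m <- if (type == "group") {
        random_group_matrix(n_sites, n_steps, range)
      } else {
        random_territorial_matrix(n_sites, n_steps, range)
      }
      fit <- tryCatch(dc(m), error = function(e) NULL)
      if (!is.null(fit) && fit$dc > 0) break
      n_regenerated <- n_regenerated + 1L # degenerate pattern, redraw
    }
    true_dc <- fit$dc
    obs <- matrix(NA_real_, nrow = n_rates, ncol = n_error_reps)
    for (ri in seq_len(n_rates)) {
      for (rep_i in seq_len(n_error_reps)) {
        set.seed(seed_mat[p, 1 + (ri - 1) * n_error_reps + rep_i])
        noisy <- apply_survey_error(m, error_rates[ri])
        obs[ri, rep_i] <- tryCatch(dc(noisy)$dc,
                                   error = function(e) NA_real_)
      }
    }
    rows[[p]] <- data.frame(
      pattern = p,
      error_rate = rep(error_rates, each = n_error_reps),
      rep = rep(seq_len(n_error_reps), times = n_rates),
      true_dc = true_dc,
      observed_dc = as.vector(t(obs))
    )
  }
  results <- do.call(rbind, rows)
  results$rel_change <- abs(results$observed_dc - results$true_dc) /
    results$true_dc

  summarise_at <- function(v) {
    agg_m <- tapply(v, results$error_rate, mean, na.rm = TRUE)
    agg_s <- tapply(v, results$error_rate, stats::sd, na.rm = TRUE)
    list(mean = as.numeric(agg_m), sd = as.numeric(agg_s))
  }
  rc <- summarise_at(results$rel_change)
  od <- summarise_at(results$observed_dc)
  summary <- data.frame(
    error_rate = sort(unique(results$error_rate)),
    mean_rel_change = rc$mean,
    sd_rel_change = rc$sd,
    mean_observed_dc = od$mean,
    sd_observed_dc = od$sd
  )

  structure(
    list(results = results, summary = summary, type = type,
         n_regenerated = n_regenerated,
         config = list(n_patterns = n_patterns, n_sites = n_sites,
                       n_steps = n_steps, range = range,
                       error_rates = error_rates,
                       n_error_reps = n_error_reps, seed = seed)),
    class = "dc_error_study"
  )
}

#' Robustness of DC to survey error for group-occupied sites
#'
#' Monte Carlo study of how survey error distorts DC when sites hold counts
#' of individuals. `n_patterns` random distribution patterns are generated
#' with [random_group_matrix]; for each pattern and each error rate,
#' [apply_survey_error] is applied `n_error_reps` times and DC of the
#' thinned matrix is compared with DC of the true pattern via the relative
#' change `|DC_obs - DC_true| / DC_true`. Because DC evaluates only the
#' individuals actually observed, the distortion stays small even at severe
#' error rates (under the default configuration, below 5% mean relative
#' change at 80% error).
#'
#' Defaults are the study conditions: fifty 5-step patterns over 50 sites
#' with per-cell counts uniform on 0--250, five error replicates per rate,
#' error rates 5--90% in 5% steps. Patterns whose DC is degenerate (no
#' individuals, or DC = 0 so relative change is undefined) are redrawn and
#' counted in `n_regenerated`.
#'
#' @param n_patterns Number of true distribution patterns.
#' @param n_sites,n_steps Dimensions of each pattern.
#' @param count_range Per-cell count bounds, passed to
#'   [random_group_matrix].
#' @param error_rates Survey error rates, each strictly within (0, 1).
#' @param n_error_reps Error randomisations per pattern and rate.
#' @param seed Root seed; one sub-seed is derived per pattern and per
#'   (pattern, rate, replicate), so results are bit-reproducible.
#' @return A `"dc_error_study"` object: `results` (one row per pattern x
#'   rate x replicate, with `true_dc`, `observed_dc`, `rel_change`),
#'   `summary` (per-rate mean and sd), `type`, `config`, `n_regenerated`.
#' @examples
#' st <- run_group_error_study(n_patterns = 4, error_rates = c(0.2, 0.8),
#'                             seed = 1)
#' st$summary
#' @export
run_group_error_study <- function(n_patterns = 50, n_sites = 50, n_steps = 5,
                                  count_range = c(0, 250),
                                  error_rates = seq(0.05, 0.90, by = 0.05),
                                  n_error_reps = 5, seed = 1) {
  run_error_study("group", n_patterns, n_sites, n_steps, count_range,
                  error_rates, n_error_reps, seed)
}

#' Survey-error predictability for territorial presence/absence data
#'
#' As [run_group_error_study], but for a territorial species surveyed as
#' presence/absence: patterns come from [random_territorial_matrix], where
#' a missed territory holder blanks its site entirely. Here survey error
#' does shift DC substantially, but in a highly predictable way, so the
#' study additionally fits a correction model regressing observed DC on
#' true DC and error rate (linear in true DC, polynomial of degree at most
#' 2 in error rate, the degree chosen by adjusted R-squared). Inverting
#' the fit with [correct_dc] recovers an approximately unbiased DC from an
#' error-contaminated survey with known error rate.
#'
#' Defaults are the study conditions: one hundred 5-step patterns over 100
#' territories with per-step population uniform on 25--75, fifteen error
#' replicates per rate, error rates 1--90% in 1% steps.
#'
#' @inheritParams run_group_error_study
#' @param pop_range Per-step population bounds, passed to
#'   [random_territorial_matrix].
#' @param fit_correction Whether to fit the correction model.
#' @return A `"dc_error_study"` object as in [run_group_error_study], with
#'   an additional `correction` element: the fitted [stats::lm] model, the
#'   selected polynomial degree, and its R-squared.
#' @examples
#' st <- run_territorial_error_study(n_patterns = 5, n_error_reps = 2,
#'                                   error_rates = c(0.1, 0.3, 0.5),
#'                                   seed = 1)
#' st$correction$r_squared
#' @export
run_territorial_error_study <- function(n_patterns = 100, n_sites = 100,
                                        n_steps = 5, pop_range = c(25, 75),
                                        error_rates = seq(0.01, 0.90,
                                                          by = 0.01),
                                        n_error_reps = 15, seed = 1,
                                        fit_correction = TRUE) {
  st <- run_error_study("territorial", n_patterns, n_sites, n_steps,
                        pop_range, error_rates, n_error_reps, seed)
  if (fit_correction) {
    st$correction <- fit_error_correction(st$results)
  }
  st
}

# Observed DC as a function of true DC and error rate: linear in true DC,
# polynomial (degree <= 2) in error rate, degree selected by adjusted R^2.
fit_error_correction <- function(results) {
  d <- results[stats::complete.cases(results[c("observed_dc", "true_dc",
                                               "error_rate")]), ]
  m1 <- stats::lm(observed_dc ~ true_dc + error_rate + true_dc:error_rate,
                  data = d)
  m2 <- stats::lm(observed_dc ~ true_dc + error_rate + I(error_rate^2) +
                    true_dc:error_rate + true_dc:I(error_rate^2),
                  data = d)
  s1 <- summary(m1)
  s2 <- summary(m2)
  if (s2$adj.r.squared > s1$adj.r.squared) {
    list(model = m2, degree = 2L, r_squared = s2$r.squared)
  } else {
    list(model = m1, degree = 1L, r_squared = s1$r.squared)
  }
}

#' Correct a DC estimate for known survey error
#'
#' Inverts the correction model fitted by [run_territorial_error_study]:
#' given a DC value measured from an error-contaminated presence/absence
#' survey and the survey's error rate, returns the model's estimate of the
#' error-free DC, clamped to \[0, 1\].
#'
#' @param study A `"dc_error_study"` object with a fitted `correction`.
#' @param observed_dc Numeric vector of measured DC values.
#' @param error_rate Matching survey error rate(s).
#' @return Corrected DC estimate(s).
#' @export
correct_dc <- function(study, observed_dc, error_rate) {
  if (!inherits(study, "dc_error_study") || is.null(study$correction)) {
    stop("study must be a dc_error_study with a fitted correction model")
  }
  co <- stats::coef(study$correction$model)
  pick <- function(nm) if (nm %in% names(co)) co[[nm]] else 0
  a <- pick("(Intercept)") + pick("error_rate") * error_rate +
    pick("I(error_rate^2)") * error_rate^2
  b <- pick("true_dc") + pick("true_dc:error_rate") * error_rate +
    pick("true_dc:I(error_rate^2)") * error_rate^2
  pmin(1, pmax(0, (observed_dc - a) / b))
}

#' @export
print.dc_error_study <- function(x, ...) {
  cat("DC survey-error study (", x$type, " occupancy)\n", sep = "")
  cfg <- x$config
  cat("  ", cfg$n_patterns, " patterns, ", cfg$n_steps, " steps x ",
      cfg$n_sites, " sites, ", cfg$n_error_reps,
      " error reps, ", length(cfg$error_rates), " rates in [",
      min(cfg$error_rates), ", ", max(cfg$error_rates), "]\n", sep = "")
  if (x$n_regenerated > 0) {
    cat("  degenerate patterns redrawn:", x$n_regenerated, "\n")
  }
  i <- which.max(x$summary$error_rate)
  cat("  mean relative DC change at rate ", x$summary$error_rate[i], ": ",
      round(100 * x$summary$mean_rel_change[i], 2), "%\n", sep = "")
  if (!is.null(x$correction)) {
    cat("  correction model: degree ", x$correction$degree,
        " in error rate, R^2 = ", round(x$correction$r_squared, 4), "\n",
        sep = "")
  }
  invisible(x)
}

#' Plot a survey-error study
#'
#' Mean per-rate effect of survey error with standard-deviation error bars:
#' relative DC change for group studies, observed DC for territorial
#' studies.
#'
#' @param x A `"dc_error_study"` object.
#' @param ... Passed to [graphics::plot].
#' @export
plot.dc_error_study <- function(x, ...) {
  s <- x$summary
  if (x$type == "group") {
    y <- 100 * s$mean_rel_change
    e <- 100 * s$sd_rel_change
    ylab <- "relative change in DC (%)"
  } else {
    y <- s$mean_observed_dc
    e <- s$sd_observed_dc
    ylab <- "observed DC"
  }
  graphics::plot(s$error_rate, y, type = "b", xlab = "survey error rate",
                 ylab = ylab, ylim = range(c(y - e, y + e), finite = TRUE),
                 ...)
  graphics::arrows(s$error_rate, y - e, s$error_rate, y + e,
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
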