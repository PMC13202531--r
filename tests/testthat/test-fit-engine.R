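test_that("curve stripping recovers well-separated rates from clean curves", {
  set.seed(7)
  for (i in 1:50) {
    beta <- exp(runif(1, log(0.005), log(0.03)))
    alpha <- beta * exp(runif(1, log(12), log(40)))
    hp <- hybrid_params(A = runif(1, 10, 60), alpha = alpha, beta = beta)
    ie <- initial_estimates(noise_free_curve(hp))
    expect_lt(abs(ie$alpha - alpha) / alpha, 0.25)
    expect_lt(abs(ie$beta - beta) / beta, 0.25)
  }
})

test_that("stripping falls back gracefully on monoexponential input", {
  sched <- study_schedule()
  mono <- tibble::tibble(time_h = sched, activity_pct = 100 * exp(-0.0147 * sched))
  ie <- initial_estimates(mono)
  expect_true(attr(ie, "fallback"))
  fit <- suppressWarnings(fit_two_compartment(mono))
  expect_equal(fit$params$beta, 0.0147, tolerance = 1e-3)
})

test_that("a flat curve cannot initialise the fit", {
  flat <- tibble::tibble(time_h = study_schedule(), activity_pct = rep(100, 16))
  expect_error(initial_estimates(flat), "not decreasing")
})

test_that("curve validation rejects malformed input", {
  sched <- study_schedule()
  good <- noise_free_curve(control_mean_params())
  expect_error(fit_two_compartment(good[1:5, ]), "6 time points")
  bad0 <- good; bad0$activity_pct[1] <- 90
  expect_error(fit_two_compartment(bad0), "100")
  negy <- good; negy$activity_pct[3] <- -1
  expect_error(fit_two_compartment(negy), "negative")
})

test_that("noise-free curves at the group-mean constants are recovered exactly", {
  for (hp in list(control_mean_params(), amd_mean_params())) {
    for (w in c("1/yhat2", "1/yhat", "none")) {
      fit <- fit_two_compartment(noise_free_curve(hp), weighting = w)
      expect_lt(abs(fit$params$alpha - hp$alpha) / hp$alpha, 1e-6)
      expect_lt(abs(fit$params$beta - hp$beta) / hp$beta, 1e-6)
      expect_lt(abs(fit$params$A - hp$A) / hp$A, 1e-6)
      expect_true(fit$converged)
    }
  }
})

test_that("noise-free recovery holds across random admissible parameters", {
  set.seed(11)
  for (i in 1:40) {
    hp <- random_admissible_params()
    fit <- fit_two_compartment(noise_free_curve(hp))
    expect_lt(abs(fit$params$alpha - hp$alpha) / hp$alpha, 1e-6)
    expect_lt(abs(fit$params$beta - hp$beta) / hp$beta, 1e-6)
    expect_lt(abs(fit$params$A - hp$A) / hp$A, 1e-6)
  }
})

test_that("refitting a fit's own predictions is a fixed point", {
  hp <- control_mean_params()
  noisy <- generate_curve(hp, noise_cv = 0.1, seed = 5)
  fit1 <- suppressWarnings(fit_two_compartment(noisy))
  refit <- fit_two_compartment(noise_free_curve(fit1$params))
  expect_equal(refit$params$alpha, fit1$params$alpha, tolerance = 1e-6)
  expect_equal(refit$params$beta, fit1$params$beta, tolerance = 1e-6)
})

test_that("the weighted objective never increases within an outer iteration", {
  set.seed(21)
  for (i in 1:10) {
    hp <- random_admissible_params()
    noisy <- generate_curve(hp, noise_cv = 0.1, seed = 100 + i)
    fit <- suppressWarnings(fit_two_compartment(noisy))
    expect_true(all(fit$trace[, "obj_after"] <= fit$trace[, "obj_before"] + 1e-12))
  }
})

test_that("terminal-phase estimation is accurate at 10% noise across eyes", {
  hp <- control_mean_params()
  errs <- vapply(1:100, function(s) {
    fit <- suppressWarnings(
      fit_two_compartment(generate_curve(hp, noise_cv = 0.1, seed = 9000 + s),
                          n_starts = 1))
    abs(fit$params$beta - hp$beta) / hp$beta
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("weighting matched to the error structure lowers the beta error", {
  hp <- control_mean_params()
  sched <- study_schedule()
  yh <- predict_eye_activity(hp, sched)
  one_rep <- function(s, noise) {
    set.seed(s)
    y <- if (noise == "additive") pmax(yh + rnorm(length(yh), 0, 3), 0.1)
         else yh * rlnorm(length(yh), -log(1 + 0.1^2) / 2, sqrt(log(1 + 0.1^2)))
    y[1] <- 100
    cv <- tibble::tibble(time_h = sched, activity_pct = y)
    fn <- suppressWarnings(fit_two_compartment(cv, weighting = "none", n_starts = 1))
    fw <- suppressWarnings(fit_two_compartment(cv, weighting = "1/yhat2", n_starts = 1))
    abs(fn$params$beta - hp$beta) < abs(fw$params$beta - hp$beta)
  }
  wins_homo <- sum(vapply(1:120, one_rep, logical(1), noise = "additive"))
  wins_mult <- sum(vapply(1:120, one_rep, logical(1), noise = "multiplicative"))
  # homoscedastic noise: unweighted wins; CV-proportional noise: reversed
  expect_lt(binom.test(wins_homo, 120, alternative = "greater")$p.value, 0.05)
  expect_lt(binom.test(120 - wins_mult, 120, alternative = "greater")$p.value, 0.05)
})

test_that("goodness-of-fit formulas match hand computation on the toy vector", {
  obs <- c(1, -1, 1, -1, 1, -1, 1, -1)
  gof <- goodness_of_fit(obs + 10, rep(10, 8), n_params = 3)
  expect_equal(gof$rmse, 1)
  expect_equal(gof$sy_x, sqrt(8 / 5))
  expect_equal(gof$aicc, 8 * log(1) + 8 + 40 / 3)
  expect_equal(gof$aic, 8)
})

test_that("degenerate goodness-of-fit inputs are handled explicitly", {
  perfect <- goodness_of_fit(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6), n_params = 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_true(perfect$ss_floored)
  expect_true(is.finite(perfect$aicc))
  expect_error(goodness_of_fit(rep(5, 8), rep(4, 8), n_params = 3), "SStot")
  expect_error(goodness_of_fit(1:5, 1:5, n_params = 3), "AICc")
})

test_that("parameter CV% follows its definition and vanishes for exact fits", {
  est <- c(A = 14, alpha = 0.27, beta = 0.015)
  cv <- parameter_cv(diag(0.01 * est^2), est)
  expect_equal(unname(cv), rep(10, 3))
  expect_true(is.na(parameter_cv(diag(3), c(a = 1, b = 0, c = 2))[2]))
  fit <- fit_two_compartment(noise_free_curve(control_mean_params()))
  expect_true(all(fit$cv_percent < 1e-3))
})

test_that("asymptotic beta CV% agrees with a parametric bootstrap", {
  hp <- control_mean_params()
  fits <- lapply(1:150, function(s) {
    bc <- generate_curve(hp, noise_cv = 0.1, seed = 5000 + s)
    suppressWarnings(fit_two_compartment(bc, n_starts = 1))
  })
  betas <- vapply(fits, function(f) f$params$beta, numeric(1))
  asym <- vapply(fits, function(f) f$cv_percent[["beta"]], numeric(1))
  # robust spread: replicates whose fast phase is swallowed by noise leave a
  # heavy tail that the asymptotic formula does not describe
  boot_cv <- 100 * mad(betas) / median(betas)
  ratio <- median(asym, na.rm = TRUE) / boot_cv
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("tidy and glance expose the full parameter and fit battery", {
  fit <- fit_two_compartment(noise_free_curve(control_mean_params()))
  td <- tidy(fit)
  expect_setequal(
    td$term,
    c("A", "alpha", "beta", "k12", "k21", "k20", "t_half_alpha",
      "t_half_beta", "auc_inf", "aumc_inf", "mrt"))
  gl <- glance(fit)
  expect_equal(gl$alpha, 0.2714, tolerance = 1e-6)
  expect_true(all(c("r2", "sy_x", "rmse", "aicc", "converged") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
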