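#' Curve-stripping initial estimates for the biexponential model
#'
#' Classical feathering initialiser. The terminal (elimination) rate `beta`
#' and intercept are obtained by log-linear regression on the last
#' `ceiling(n/3)` points; the extrapolated terminal phase is subtracted from
#' the early points and a second log-linear regression on the positive
#' residuals yields `alpha` and the fast coefficient `A` (clamped to
#' `(0.01 D, 0.99 D)`). If stripping fails (too few positive residuals, or an
#' ill-ordered pair), the fallback `A = 0.2 D`, `alpha = 10 * beta` is used.
#'
#' @param data a data frame with columns `time_h` (hours, strictly
#'   increasing, first 0) and `activity_pct` (percent of initial uptake).
#' @param D administered activity (percent); default 100.
#' @return A [hybrid_params()] object of admissible starting values, with an
#'   attribute `"fallback"` flagging whether the stripped estimate failed.
#' @export
initial_estimates <- function(data, D = 100) {
  curve <- check_curve_data(data)
  t <- curve$time_h
  y <- curve$activity_pct
  n <- length(t)

  m <- ceiling(n / 3)
  tail_idx <- seq.int(n - m + 1L, n)
  yt <- y[tail_idx]
  if (any(yt <= 0)) {
    stop("terminal-phase activities must be positive for log-linear stripping",
         call. = FALSE)
  }
  fit_tail <- stats::lm.fit(cbind(1, t[tail_idx]), log(yt))
  beta0 <- -fit_tail$coefficients[2]
  if (!is.finite(beta0) || beta0 <= 0) {
    stop("terminal phase is not decreasing; cannot initialise the fit",
         call. = FALSE)
  }
  B0 <- exp(fit_tail$coefficients[1])

  early_idx <- setdiff(seq_len(n), tail_idx)
  resid <- y[early_idx] - B0 * exp(-beta0 * t[early_idx])
  keep <- resid > 0
  fallback <- FALSE
  if (sum(keep) >= 2L) {
    fit_early <- stats::lm.fit(
      cbind(1, t[early_idx][keep]), log(resid[keep])
    )
    alpha0 <- -fit_early$coefficients[2]
    A0 <- exp(fit_early$coefficients[1])
    if (!is.finite(alpha0) || alpha0 <= beta0 || !is.finite(A0)) {
      fallback <- TRUE
    }
  } else {
    fallback <- TRUE
  }
  if (fallback) {
    alpha0 <- 10 * beta0
    A0 <- 0.2 * D
  }
  A0 <- min(max(A0, 0.01 * D), 0.99 * D)
  beta0 <- min(beta0, alpha0 / 2)  # keep ordering with margin
  out <- hybrid_params(A = A0, alpha = alpha0, beta = beta0, D = D)
  attr(out, "fallback") <- fallback
  out
}

# natural -> unconstrained transform used inside the optimiser:
#   theta = (logit(A/D), log(alpha - beta), log(beta))
theta_from_params <- function(hp) {
  c(
    stats::qlogis(hp$A / hp$D),
    log(hp$alpha - hp$beta),
    log(hp$beta)
  )
}

params_from_theta <- function(theta, D = 100) {
  beta <- exp(theta[3])
  alpha <- beta + exp(theta[2])
  A <- D * stats::plogis(theta[1])
  list(D = D, A = A, B = D - A, alpha = alpha, beta = beta)
}

model_predict <- function(p, t) {
  p$A * exp(-p$alpha * t) + p$B * exp(-p$beta * t)
}

# Jacobian of X1 wrt the natural parameters (A, alpha, beta); B = D - A.
model_jacobian <- function(p, t) {
  ea <- exp(-p$alpha * t)
  eb <- exp(-p$beta * t)
  cbind(A = ea - eb, alpha = -p$A * t * ea, beta = -p$B * t * eb)
}

resolve_weighting <- function(weighting) {
  weighting <- match.arg(weighting, c("1/yhat2", "1/yhat", "none"))
  weighting
}

weights_for <- function(yhat, weighting) {
  switch(weighting,
    "none" = rep(1, length(yhat)),
    "1/yhat" = 1 / pmax(yhat, 1e-12),
    "1/yhat2" = 1 / pmax(yhat, 1e-12)^2
  )
}

#' Fit the two-compartment intravitreal model to one time-activity curve
#'
#' Weighted nonlinear least squares for the biexponential eye-activity model
#' with `D` fixed at 100 (curves normalised to the first post-injection
#' frame). The objective \eqn{\sum_i w_i (y_i - X_1(t_i))^2} is minimised by
#' Levenberg-Marquardt on transformed parameters
#' (`logit(A/D)`, `log(alpha - beta)`, `log(beta)`), which enforces
#' `alpha > beta > 0` and `0 < A < D` by construction. For the
#' predicted-concentration weighting schemes (`1/yhat`, `1/yhat2`) the
#' weights are recomputed from the current predictions and the solve is
#' repeated until the parameters change by less than `1e-8` relative
#' (at most 50 outer iterations). Five deterministic starts jittered around
#' the curve-stripping initialiser guard against the shallow trough in the
#' fast phase.
#'
#' @param data a data frame with columns `time_h` and `activity_pct` for a
#'   single eye (use [fit_cohort()] for a multi-eye table).
#' @param weighting `"1/yhat2"` (default; standard for radioactivity data
#'   spanning decades), `"1/yhat"` or `"none"`.
#' @param D administered activity (percent); fixed, not estimated.
#' @param n_starts number of deterministic multi-starts (default 5).
#' @param outer_max,outer_tol reweighting loop controls.
#' @return An object of class `ivt_fit`: a list with elements `params`
#'   ([hybrid_params()]), `micro`, `derived`, `cv_percent` (named, percent),
#'   `gof` (tibble from [goodness_of_fit()]), `residuals`, `fitted`, `data`,
#'   `weighting`, `weights`, `trace` (per-outer-iteration objective before
#'   and after each fixed-weight solve), `at_bound`, `converged`, `n_obs`,
#'   `n_params`. A solution on the boundary of the admissible parameter box
#'   (in particular a fast rate too large to be resolved by the first
#'   post-baseline sample) means the biexponential is not identifiable from
#'   that curve; such fits are flagged `converged = FALSE` and are excluded
#'   from group summaries. Use [tidy()] and [glance()] to extract results
#'   as tibbles.
#' @export
#' @examples
#' hp <- hybrid_params(A = 13.7515, alpha = 0.2714, beta = 0.0147)
#' sched <- study_schedule()
#' curve <- tibble::tibble(
#'   time_h = sched,
#'   activity_pct = predict_eye_activity(hp, sched)
#' )
#' fit <- fit_two_compartment(curve)
#' glance(fit)
fit_two_compartment <- function(data, weighting = c("1/yhat2", "1/yhat", "none"),
                                D = 100, n_starts = 5,
                                outer_max = 50, outer_tol = 1e-8) {
  weighting <- resolve_weighting(weighting)
  curve <- check_curve_data(data)
  t <- curve$time_h
  y <- curve$activity_pct
  n <- length(t)

  start <- initial_estimates(curve, D = D)
  theta0 <- theta_from_params(start)
  # deterministic jitters around the stripped start (logit-A, log-spread, log-beta)
  jitters <- list(
    c(0, 0, 0),
    c(1, 0.7, 0),
    c(-1, -0.7, 0),
    c(0.5, 0, 0.3),
    c(-0.5, 0, -0.3),
    c(1.5, 1.2, -0.2),
    c(-1.5, -1.2, 0.2)
  )
  jitters <- jitters[seq_len(max(1L, min(n_starts, length(jitters))))]

  # box constraints on the transformed parameters: rates far faster than the
  # first post-baseline sample (or absurdly slow) are not identifiable from
  # this design, and letting them run away destabilises the weighted fit
  t1 <- t[2]
  lower <- c(-12, log(1e-5), log(1e-6))
  upper <- c(12, log(20 / t1), log(2))

  solve_at_weights <- function(theta, w) {
    sw <- sqrt(w)
    res_fn <- function(th) {
      p <- params_from_theta(th, D = D)
      sw * (y - model_predict(p, t))
    }
    minpack.lm::nls.lm(
      par = pmin(pmax(theta, lower), upper), fn = res_fn,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-10, ptol = 1e-10
      )
    )
  }

  obj_at <- function(theta, w) {
    sum(w * (y - model_predict(params_from_theta(theta, D), t))^2)
  }

  run_start <- function(theta) {
    theta <- pmin(pmax(theta, lower), upper)
    w <- rep(1, n)
    if (weighting != "none") {
      w <- weights_for(model_predict(params_from_theta(theta, D), t), weighting)
    }
    converged <- TRUE
    trace <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("obj_before", "obj_after")))
    for (it in seq_len(outer_max)) {
      before <- obj_at(theta, w)
      lm_fit <- solve_at_weights(theta, w)
      theta_new <- lm_fit$par
      trace <- rbind(trace, c(before, obj_at(theta_new, w)))
      rel <- max(abs(theta_new - theta) / pmax(abs(theta), 1e-8))
      theta <- theta_new
      if (weighting == "none") break
      w_new <- weights_for(model_predict(params_from_theta(theta, D), t), weighting)
      w <- w_new
      if (rel < outer_tol) break
      if (it == outer_max) converged <- FALSE
    }
    p <- params_from_theta(theta, D = D)
    obj <- sum(w * (y - model_predict(p, t))^2)
    at_bound <- any(theta <= lower + 1e-6) || any(theta >= upper - 1e-6)
    list(theta = theta, weights = w, objective = obj, trace = trace,
         at_bound = at_bound,
         converged = converged && lm_fit$info %in% 1:4)
  }

  candidates <- lapply(jitters, function(j) {
    tryCatch(run_start(theta0 + j), error = function(e) NULL)
  })
  candidates <- Filter(Negate(is.null), candidates)
  if (length(candidates) == 0L) {
    stop("all optimisation starts failed", call. = FALSE)
  }
  best <- candidates[[which.min(vapply(candidates, `[[`, numeric(1), "objective"))]]

  p <- params_from_theta(best$theta, D = D)
  hp <- hybrid_params(A = p$A, alpha = p$alpha, beta = p$beta, D = D)
  yhat <- model_predict(p, t)
  resid <- y - yhat
  w <- best$weights
  n_params <- 3L

  # asymptotic covariance in natural parameter space: s^2 (J' W J)^{-1}
  J <- model_jacobian(p, t)
  JtWJ <- crossprod(J * sqrt(w))
  s2 <- sum(w * resid^2) / (n - n_params)
  cov_nat <- tryCatch(s2 * solve(JtWJ), error = function(e) NULL)
  est <- c(A = p$A, alpha = p$alpha, beta = p$beta)
  if (is.null(cov_nat)) {
    cv <- stats::setNames(rep(NA_real_, 3), names(est))
    warning("singular normal matrix: parameter CV% undefined", call. = FALSE)
  } else {
    cv <- parameter_cv(cov_nat, est)
  }

  gof <- goodness_of_fit(y, yhat, n_params = n_params, weights = w)

  structure(
    list(
      params = hp,
      micro = hybrid_to_micro(hp),
      derived = derived_parameters(hp),
      cv_percent = cv,
      gof = gof,
      residuals = resid,
      fitted = yhat,
      data = curve,
      weighting = weighting,
      weights = w,
      trace = best$trace,
      at_bound = isTRUE(best$at_bound),
      converged = isTRUE(best$converged) && !isTRUE(best$at_bound),
      n_obs = n,
      n_params = n_params
    ),
    class = "ivt_fit"
  )
}

#' Goodness-of-fit battery for a nonlinear regression
#'
#' Computes the fit-quality metrics reported for each eye: the coefficient
#' of determination `r2 = 1 - SSres/SStot` (on unweighted residuals), the
#' standard error of the estimate `sy_x = sqrt(SSres/(n - p))`, the root
#' mean square error `rmse = sqrt(SSres/n)`, and the small-sample corrected
#' Akaike criterion
#' \deqn{AICc = n \ln(SS_{res}/n) + 2K + \frac{2K(K+1)}{n-K-1},}
#' with `K = n_params + 1` (the error variance counts as a parameter). The
#' plain `aic` (first two terms) and, when weights are supplied, a weighted
#' `r2_weighted` are also returned.
#'
#' @param observed,predicted equal-length numeric vectors (percent units).
#' @param n_params number of fitted model parameters `p` (3 for the
#'   biexponential with fixed `D`).
#' @param weights optional fit weights for the weighted R2.
#' @return A one-row tibble with columns `r2`, `sy_x`, `rmse`, `aic`,
#'   `aicc`, `r2_weighted`, `ss_res`, `ss_floored`.
#' @export
#' @examples
#' goodness_of_fit(c(1, -1, 1, -1, 1, -1, 1, -1), rep(0, 8), n_params = 3)
goodness_of_fit <- function(observed, predicted, n_params, weights = NULL) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  n <- length(observed)
  K <- n_params + 1L
  if (n <= K + 1L) {
    stop("AICc undefined: need n > n_params + 2 observations", call. = FALSE)
  }
  resid <- observed - predicted
  ss_res <- sum(resid^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("constant observations: R2 undefined (SStot = 0)", call. = FALSE)
  }
  ss_floored <- ss_res < 1e-30
  ss_res_f <- max(ss_res, 1e-30)

  r2w <- NA_real_
  if (!is.null(weights)) {
    wres <- weights * resid^2
    wbar <- sum(weights * observed) / sum(weights)
    wtot <- sum(weights * (observed - wbar)^2)
    if (wtot > 0) r2w <- 1 - sum(wres) / wtot
  }

  tibble::tibble(
    r2 = 1 - ss_res / ss_tot,
    sy_x = sqrt(ss_res / (n - n_params)),
    rmse = sqrt(ss_res / n),
    aic = n * log(ss_res_f / n) + 2 * K,
    aicc = n * log(ss_res_f / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1),
    r2_weighted = r2w,
    ss_res = ss_res,
    ss_floored = ss_floored
  )
}

#' Percentage coefficient of variation of fitted parameters
#'
#' `CV% = 100 * sqrt(diag(covariance)) / |estimate|`, the asymptotic
#' parameter precision from the covariance of the fit.
#'
#' @param covariance parameter covariance matrix (natural scale).
#' @param estimates named vector of parameter estimates.
#' @return Named numeric vector of CV percentages (NA where the estimate is
#'   zero).
#' @export
parameter_cv <- function(covariance, estimates) {
  d <- diag(as.matrix(covariance))
  if (length(d) != length(estimates)) {
    stop("covariance dimension does not match the estimates", call. = FALSE)
  }
  d <- pmax(d, 0)  # clip tiny negatives from finite-precision inversion
  cv <- 100 * sqrt(d) / abs(estimates)
  cv[estimates == 0] <- NA_real_
  stats::setNames(cv, names(estimates))
}

#' @export
print.ivt_fit <- function(x, ...) {
  cat("<ivt_fit>  two-compartment intravitreal model, weighting =",
      x$weighting, "\n")
  cat(sprintf("  A = %.4f  alpha = %.4f /h  beta = %.4f /h  (D = %g)\n",
              x$params$A, x$params$alpha, x$params$beta, x$params$D))
  cat(sprintf("  R2 = %.4f  Sy.x = %.3f  RMSE = %.3f  AICc = %.3f  converged: %s\n",
              x$gof$r2, x$gof$sy_x, x$gof$rmse, x$gof$aicc, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-compartment fit into a one-row-per-parameter tibble
#'
#' @param x an `ivt_fit` object.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `cv_percent`.
#' @exportS3Method generics::tidy
#' @export
tidy.ivt_fit <- function(x, ...) {
  est <- c(
    A = x$params$A, alpha = x$params$alpha, beta = x$params$beta,
    k12 = x$micro$k12, k21 = x$micro$k21, k20 = x$micro$k20,
    t_half_alpha = x$derived$t_half_alpha,
    t_half_beta = x$derived$t_half_beta,
    auc_inf = x$derived$auc_inf,
    aumc_inf = x$derived$aumc_inf,
    mrt = x$derived$mrt
  )
  cv <- x$cv_percent[match(names(est), names(x$cv_percent))]
  tibble::tibble(
    term = names(est),
    estimate = unname(unlist(est)),
    cv_percent = unname(cv)
  )
}

#' One-row fit summary
#'
#' @param x an `ivt_fit` object.
#' @param ... unused.
#' @return A one-row tibble with parameter estimates, derived quantities and
#'   the goodness-of-fit battery.
#' @exportS3Method generics::glance
#' @export
glance.ivt_fit <- function(x, ...) {
  tibble::tibble(
    A = x$params$A, alpha = x$params$alpha, beta = x$params$beta,
    k12 = x$micro$k12, k21 = x$micro$k21, k20 = x$micro$k20,
    t_half_alpha = x$derived$t_half_alpha,
    t_half_beta = x$derived$t_half_beta,
    auc_inf = x$derived$auc_inf,
    mrt = x$derived$mrt,
    cv_A = unname(x$cv_percent["A"]),
    cv_alpha = unname(x$cv_percent["alpha"]),
    cv_beta = unname(x$cv_percent["beta"]),
    r2 = x$gof$r2, sy_x = x$gof$sy_x, rmse = x$gof$rmse,
    aicc = x$gof$aicc,
    weighting = x$weighting,
    converged = x$converged,
    n_obs = x$n_obs, n_params = x$n_params
  )
}

#' Plot observed points and the fitted biexponential curve
#'
#' @param object an `ivt_fit` object.
#' @param log_y plot activity on a log scale (default TRUE, the conventional
#'   display for multiexponential decay).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ivt_fit <- function(object, log_y = TRUE, ...) {
  tgrid <- seq(0, max(object$data$time_h), length.out = 200)
  pred <- tibble::tibble(
    time_h = tgrid,
    activity_pct = predict_eye_activity(object$params, tgrid)
  )
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$time_h, y = .data$activity_pct)) +
    ggplot2::geom_line(data = pred, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Time after injection (h)",
      y = "Activity (% of initial ocular uptake)",
      title = "Two-compartment fit"
    )
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# validate / coerce a single-curve data frame; returns a tibble sorted by time
check_curve_data <- function(data) {
  if (inherits(data, "hybrid_params")) {
    stop("`data` must be a data frame of observations, not parameters",
         call. = FALSE)
  }
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  need <- c("time_h", "activity_pct")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  curve <- tibble::as_tibble(data)[, need]
  curve <- dplyr::arrange(curve, .data$time_h)
  if (nrow(curve) < 6L) {
    stop("at least 6 time points are required for a 3-parameter fit",
         call. = FALSE)
  }
  if (anyDuplicated(curve$time_h)) {
    stop("duplicate time points in the curve", call. = FALSE)
  }
  if (curve$time_h[1] != 0) {
    stop("the curve must start at time 0 (normalised first frame)", call. = FALSE)
  }
  if (any(curve$activity_pct < 0)) {
    stop("negative activities are not allowed", call. = FALSE)
  }
  if (abs(curve$activity_pct[1] - 100) > 1e-6) {
    stop("activity at t = 0 must equal 100 (normalise with ",
         "`normalize_to_first_frame()` first)", call. = FALSE)
  }
  curve
}
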