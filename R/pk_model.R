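#' Hybrid (macro) parameters of the open two-compartment intravitreal model
#'
#' The decline of decay-corrected activity in the eye after an intravitreal
#' injection follows a biexponential (two-compartment) law
#' \deqn{X_1(t) = A e^{-\alpha t} + B e^{-\beta t}, \qquad A + B = D,}
#' where compartment 1 is the eye (observed) and compartment 2 the blood and
#' well-perfused organs. `hybrid_params()` builds and validates the macro
#' parameterisation: the administered dose `D` (fixed at 100 when curves are
#' normalised to the first post-injection frame), the fast-phase coefficient
#' `A`, and the hybrid rate constants `alpha` (distribution) and `beta`
#' (elimination), both in 1/hour.
#'
#' Invariants enforced: `alpha > beta > 0`, `0 < A < D` (so the slow
#' coefficient `B = D - A` is positive), and hence `X1(0) = A + B = D`.
#'
#' @param A fast-phase coefficient, percent units, in `(0, D)`.
#' @param alpha distribution hybrid rate constant (1/hour), `> beta`.
#' @param beta elimination hybrid rate constant (1/hour), `> 0`.
#' @param D administered activity in percent units; default 100.
#' @return An object of class `hybrid_params`: a list with elements `D`, `A`,
#'   `B`, `alpha`, `beta`.
#' @seealso [micro_constants()], [hybrid_to_micro()], [micro_to_hybrid()],
#'   [predict_eye_activity()], [derived_parameters()]
#' @export
#' @examples
#' hp <- hybrid_params(A = 13.7515, alpha = 0.2714, beta = 0.0147)
#' predict_eye_activity(hp, t = c(0, 24, 240))
hybrid_params <- function(A, alpha, beta, D = 100) {
  stop_if_not_scalar_finite(A = A, alpha = alpha, beta = beta, D = D)
  if (beta <= 0) stop("`beta` must be > 0 (elimination rate constant)", call. = FALSE)
  if (alpha <= beta) stop("`alpha` must exceed `beta` (alpha > beta > 0)", call. = FALSE)
  if (A <= 0 || A >= D) {
    stop("`A` must lie strictly between 0 and D = ", D,
         " (got ", format(A), ")", call. = FALSE)
  }
  structure(
    list(D = unname(D), A = unname(A), B = unname(D - A),
         alpha = unname(alpha), beta = unname(beta)),
    class = "hybrid_params"
  )
}

#' @export
print.hybrid_params <- function(x, ...) {
  cat("<hybrid_params>  D =", format(x$D),
      " A =", format(x$A), " B =", format(x$B),
      " alpha =", format(x$alpha), "/h  beta =", format(x$beta), "/h\n")
  invisible(x)
}

#' Micro rate constants of the two-compartment intravitreal model
#'
#' First-order transfer rates of the compartment system
#' \deqn{dX_1/dt = -k_{12} X_1 + k_{21} X_2, \qquad
#'       dX_2/dt = k_{12} X_1 - (k_{21} + k_{20}) X_2,}
#' with `k12` the eye-to-peripheral distribution constant, `k21` the return
#' constant and `k20` elimination from the peripheral compartment, all in
#' 1/hour. The matching hybrid constants satisfy
#' `k12 + k21 + k20 = alpha + beta` and `k12 * k20 = alpha * beta`
#' (sum and determinant of the rate matrix).
#'
#' @param k12 eye to peripheral distribution micro-constant (1/hour), `> 0`.
#' @param k21 peripheral to eye micro-constant (1/hour), `>= 0`.
#' @param k20 elimination from the peripheral compartment (1/hour), `> 0`.
#' @return An object of class `micro_constants`.
#' @export
#' @examples
#' micro_constants(k12 = 0.05, k21 = 0.1563, k20 = 0.0798)
micro_constants <- function(k12, k21, k20) {
  stop_if_not_scalar_finite(k12 = k12, k21 = k21, k20 = k20)
  if (k12 <= 0) stop("`k12` must be > 0", call. = FALSE)
  if (k20 <= 0) stop("`k20` must be > 0", call. = FALSE)
  if (k21 < 0) stop("`k21` must be >= 0", call. = FALSE)
  structure(list(k12 = unname(k12), k21 = unname(k21), k20 = unname(k20)),
            class = "micro_constants")
}

#' @export
print.micro_constants <- function(x, ...) {
  cat("<micro_constants>  k12 =", format(x$k12),
      " k21 =", format(x$k21), " k20 =", format(x$k20), "/h\n")
  invisible(x)
}

# Resolve the (D, A, B, alpha, beta, k12) set from either parameterisation.
# `params` is a hybrid_params (k12 derived by inversion) or micro_constants
# (converted with the given D).
resolve_params <- function(params, D = 100) {
  if (inherits(params, "micro_constants")) {
    hp <- micro_to_hybrid(params, D = D)
    mc <- params
  } else if (inherits(params, "hybrid_params")) {
    hp <- params
    mc <- hybrid_to_micro(params)
  } else {
    stop("`params` must be a `hybrid_params` or `micro_constants` object",
         call. = FALSE)
  }
  list(hybrid = hp, micro = mc)
}

#' Predicted activity in the eye compartment
#'
#' Closed-form solution for the observed (eye) compartment:
#' \deqn{X_1(t) = D\frac{\beta - k_{12}}{\beta - \alpha} e^{-\alpha t}
#'              + D\frac{\alpha - k_{12}}{\alpha - \beta} e^{-\beta t},}
#' so that `X1(0) = D` exactly, `X1` is strictly decreasing and tends to 0.
#' Admissibility requires `beta < k12 < alpha`, which is equivalent to the
#' fast coefficient `A = D (k12 - beta)/(alpha - beta)` lying in `(0, D)`.
#'
#' @param params a [hybrid_params()] or [micro_constants()] object.
#' @param t time(s) after injection, hours, `>= 0`.
#' @param D administered activity (percent); used only when `params` is a
#'   `micro_constants` object.
#' @return Numeric vector of eye activity in percent units, same length as `t`.
#' @export
#' @examples
#' hp <- hybrid_params(A = 13.7515, alpha = 0.2714, beta = 0.0147)
#' predict_eye_activity(hp, t = 24)  # ~ 60.6 % of the injected activity
predict_eye_activity <- function(params, t, D = 100) {
  check_times(t)
  hp <- resolve_params(params, D = D)$hybrid
  hp$A * exp(-hp$alpha * t) + hp$B * exp(-hp$beta * t)
}

#' Predicted activity in the peripheral compartment
#'
#' Closed-form solution for the unobserved peripheral (blood and
#' well-perfused organs) compartment:
#' \deqn{X_2(t) = D\frac{k_{12}}{\beta - \alpha}
#'   \left(e^{-\alpha t} - e^{-\beta t}\right),}
#' which starts at 0, rises to a single interior maximum and decays back to 0.
#'
#' @inheritParams predict_eye_activity
#' @return Numeric vector of peripheral activity in percent units.
#' @export
predict_peripheral_activity <- function(params, t, D = 100) {
  check_times(t)
  p <- resolve_params(params, D = D)
  hp <- p$hybrid
  k12 <- p$micro$k12
  hp$D * k12 / (hp$beta - hp$alpha) * (exp(-hp$alpha * t) - exp(-hp$beta * t))
}

#' Convert hybrid (macro) parameters to micro rate constants
#'
#' Inverts the macro parameterisation: from `(D, A, alpha, beta)`,
#' `k12 = beta + (A/D)(alpha - beta)`, `k20 = alpha * beta / k12`, and
#' `k21 = alpha + beta - k12 - k20`. The returned constants satisfy the sum
#' identity `k12 + k21 + k20 = alpha + beta` and the determinant identity
#' `k12 * k20 = alpha * beta`; `k21 = (alpha - k12)(k12 - beta)/k12 >= 0`
#' holds automatically for any valid `hybrid_params`.
#'
#' @param params a [hybrid_params()] object.
#' @return A [micro_constants()] object.
#' @export
#' @examples
#' hybrid_to_micro(hybrid_params(A = 13.7515, alpha = 0.2714, beta = 0.0147))
hybrid_to_micro <- function(params) {
  if (!inherits(params, "hybrid_params")) {
    stop("`params` must be a `hybrid_params` object", call. = FALSE)
  }
  k12 <- params$beta + (params$A / params$D) * (params$alpha - params$beta)
  k20 <- params$alpha * params$beta / k12
  k21 <- params$alpha + params$beta - k12 - k20
  # guard against tiny negative k21 from floating-point cancellation
  if (k21 < 0 && k21 > -1e-12 * (params$alpha + params$beta)) k21 <- 0
  if (k12 <= 0 || k20 <= 0 || k21 < 0) {
    stop("parameter set inconsistent with the two-compartment model: ",
         "inversion gives k12 = ", format(k12), ", k21 = ", format(k21),
         ", k20 = ", format(k20), "; all must be non-negative ",
         "(k12, k20 strictly positive)", call. = FALSE)
  }
  micro_constants(k12 = k12, k21 = k21, k20 = k20)
}

#' Convert micro rate constants to hybrid (macro) parameters
#'
#' `alpha` and `beta` are the roots of
#' \eqn{\lambda^2 - (k_{12}+k_{21}+k_{20})\lambda + k_{12} k_{20} = 0}
#' (the characteristic polynomial of the rate matrix), ordered
#' `alpha > beta`; the fast coefficient is `A = D (k12 - beta)/(alpha - beta)`.
#'
#' @param micro a [micro_constants()] object.
#' @param D administered activity (percent units); default 100.
#' @return A [hybrid_params()] object.
#' @export
#' @examples
#' micro_to_hybrid(micro_constants(0.05, 0.1563, 0.0798))
micro_to_hybrid <- function(micro, D = 100) {
  if (!inherits(micro, "micro_constants")) {
    stop("`micro` must be a `micro_constants` object", call. = FALSE)
  }
  s <- micro$k12 + micro$k21 + micro$k20
  p <- micro$k12 * micro$k20
  disc <- s^2 - 4 * p
  if (disc <= 0) {
    stop("degenerate system: alpha = beta (discriminant <= 0)", call. = FALSE)
  }
  alpha <- (s + sqrt(disc)) / 2
  beta <- p / alpha  # numerically stable companion root
  A <- D * (micro$k12 - beta) / (alpha - beta)
  hybrid_params(A = A, alpha = alpha, beta = beta, D = D)
}

#' Derived pharmacokinetic quantities
#'
#' Phase half-lives, exposure and residence time implied by the macro
#' parameters: `t_half_alpha = ln2/alpha`, `t_half_beta = ln2/beta`,
#' `auc_inf = A/alpha + B/beta` (percent-hours),
#' `aumc_inf = A/alpha^2 + B/beta^2` (percent-hours squared), and
#' `mrt = aumc_inf / auc_inf` (hours).
#'
#' @param params a [hybrid_params()] object.
#' @return A one-row tibble with columns `t_half_alpha`, `t_half_beta`,
#'   `auc_inf`, `aumc_inf`, `mrt`.
#' @export
#' @examples
#' derived_parameters(hybrid_params(A = 13.7515, alpha = 0.2714, beta = 0.0147))
derived_parameters <- function(params) {
  if (!inherits(params, "hybrid_params")) {
    stop("`params` must be a `hybrid_params` object", call. = FALSE)
  }
  auc <- params$A / params$alpha + params$B / params$beta
  aumc <- params$A / params$alpha^2 + params$B / params$beta^2
  tibble::tibble(
    t_half_alpha = log(2) / params$alpha,
    t_half_beta = log(2) / params$beta,
    auc_inf = auc,
    aumc_inf = aumc,
    mrt = aumc / auc
  )
}

#' High-accuracy ODE integration of the two-compartment system
#'
#' Numerically integrates
#' \deqn{dX_1/dt = -k_{12} X_1 + k_{21} X_2, \quad
#'       dX_2/dt = k_{12} X_1 - (k_{21}+k_{20}) X_2}
#' from `X1(0) = D`, `X2(0) = 0`, together with the cumulative eliminated
#' amount `E(t) = k20 * integral of X2`, at tight tolerances. This is an
#' independent check on the closed-form predictions (and of mass balance
#' `X1 + X2 + E = D`); it is deliberately not used by the fitting code.
#'
#' @param micro a [micro_constants()] object.
#' @param times sorted, non-negative output times (hours); 0 is prepended if
#'   absent.
#' @param D administered activity (percent units); default 100.
#' @param rtol,atol integration tolerances passed to [deSolve::ode()].
#' @param method integrator; the default high-order explicit Runge-Kutta
#'   pair resolves this stiff-free linear system to ~1e-10 relative.
#' @return A tibble with columns `time`, `X1`, `X2`, `eliminated`.
#' @export
ode_oracle <- function(micro, times, D = 100, rtol = 1e-12, atol = 1e-12,
                       method = "ode45") {
  if (!inherits(micro, "micro_constants")) {
    stop("`micro` must be a `micro_constants` object", call. = FALSE)
  }
  check_times(times)
  if (is.unsorted(times)) stop("`times` must be sorted increasing", call. = FALSE)
  tt <- if (times[1] == 0) times else c(0, times)
  deriv <- function(t, y, p) {
    list(c(
      -p$k12 * y[1] + p$k21 * y[2],
      p$k12 * y[1] - (p$k21 + p$k20) * y[2],
      p$k20 * y[2]
    ))
  }
  sol <- deSolve::ode(
    y = c(X1 = D, X2 = 0, eliminated = 0), times = tt, func = deriv,
    parms = micro, method = method, rtol = rtol, atol = atol
  )
  istate <- attr(sol, "istate")
  if (!is.null(istate) && istate[1L] < 0) {
    stop("ODE integration failed", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time"
  out[match(times, out$time), ]
}

# ---- shared validators ----

stop_if_not_scalar_finite <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  invisible(TRUE)
}

check_times <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t))) {
    stop("`t` must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(t < 0)) stop("negative times are not allowed", call. = FALSE)
  invisible(TRUE)
}
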