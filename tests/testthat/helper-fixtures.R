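# Canonical parameter sets used across tests: group-mean hybrid constants
# with the default fixed k12 = 0.05/h.
control_mean_params <- function() {
  hybrid_params(A = 100 * (0.05 - 0.0147) / (0.2714 - 0.0147),
                alpha = 0.2714, beta = 0.0147)
}

amd_mean_params <- function() {
  hybrid_params(A = 100 * (0.05 - 0.0191) / (0.1837 - 0.0191),
                alpha = 0.1837, beta = 0.0191)
}

# random admissible parameter draw: alpha > 2 beta, beta < k12 < alpha
random_admissible_params <- function() {
  beta <- exp(stats::runif(1, log(0.003), log(0.05)))
  alpha <- beta * exp(stats::runif(1, log(2.5), log(50)))
  k12 <- exp(stats::runif(1, log(beta * 1.1), log(alpha / 1.1)))
  A <- 100 * (k12 - beta) / (alpha - beta)
  hybrid_params(A = A, alpha = alpha, beta = beta)
}

noise_free_curve <- function(params, schedule = study_schedule()) {
  tibble::tibble(time_h = schedule,
                 activity_pct = predict_eye_activity(params, schedule))
}
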