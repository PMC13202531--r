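#' The longitudinal imaging schedule
#'
#' Imaging time points used throughout: 0, 2, 4, 8, 12, 24 and 36 hours
#' post-injection, then daily to day 10 (16 points in total).
#'
#' @return Numeric vector of hours.
#' @export
study_schedule <- function() {
  c(0, 2, 4, 8, 12, 24, 36, 48, 72, 96, 120, 144, 168, 192, 216, 240)
}

#' Configuration of a simulated cohort of eyes
#'
#' Defines the group-level distribution the simulator draws per-eye hybrid
#' rate constants from, the measurement-noise level and the imaging
#' schedule. `alpha` and `beta` are drawn log-normally with the given
#' arithmetic mean and SD (moment-matched); draws are rejected until
#' `alpha > 2 beta` and the implied micro-constants are admissible for the
#' chosen `k12` (which requires `beta < k12 < alpha`).
#'
#' The named configurations [control_config()] and [amd_config()] carry the
#' study conditions: healthy controls (6 eyes, mean alpha 0.2714/h SD
#' 0.2099, mean beta 0.0147/h SD 0.0029) and the laser-induced neovascular
#' AMD model (8 eyes, mean alpha 0.1837/h SD 0.1245, mean beta 0.0191/h SD
#' 0.0073), both measured with ~10% multiplicative noise on the 16-point
#' schedule.
#'
#' @param group group label, e.g. `"control"` or `"amd"`.
#' @param n_eyes number of eyes to simulate.
#' @param alpha_mean,alpha_sd arithmetic mean and SD of the distribution
#'   rate constant (1/hour).
#' @param beta_mean,beta_sd arithmetic mean and SD of the elimination rate
#'   constant (1/hour).
#' @param k12 fixed eye-to-peripheral distribution constant (1/hour).
#' @param noise_cv fractional multiplicative measurement noise (0.10 = 10%).
#' @param schedule sampling times in hours, starting at 0, strictly
#'   increasing.
#' @return An object of class `cohort_config` (a list).
#' @export
cohort_config <- function(group, n_eyes,
                          alpha_mean, alpha_sd,
                          beta_mean, beta_sd,
                          k12 = 0.05, noise_cv = 0.10,
                          schedule = study_schedule()) {
  if (!is.character(group) || length(group) != 1L) {
    stop("`group` must be a single label", call. = FALSE)
  }
  if (!is.numeric(n_eyes) || n_eyes < 1 || n_eyes != round(n_eyes)) {
    stop("`n_eyes` must be a positive integer", call. = FALSE)
  }
  if (alpha_mean <= 0 || beta_mean <= 0) stop("means must be > 0", call. = FALSE)
  if (alpha_sd < 0 || beta_sd < 0) stop("SDs must be >= 0", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  if (k12 <= 0) stop("`k12` must be > 0", call. = FALSE)
  if (schedule[1] != 0 || is.unsorted(schedule, strictly = TRUE)) {
    stop("`schedule` must start at 0 and be strictly increasing", call. = FALSE)
  }
  structure(
    list(group = group, n_eyes = as.integer(n_eyes),
         alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         beta_mean = beta_mean, beta_sd = beta_sd,
         k12 = k12, noise_cv = noise_cv, schedule = schedule),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @param ... overrides passed to [cohort_config()].
#' @export
control_config <- function(...) {
  args <- utils::modifyList(
    list(group = "control", n_eyes = 6,
         alpha_mean = 0.2714, alpha_sd = 0.2099,
         beta_mean = 0.0147, beta_sd = 0.0029),
    list(...)
  )
  do.call(cohort_config, args)
}

#' @rdname cohort_config
#' @export
amd_config <- function(...) {
  args <- utils::modifyList(
    list(group = "amd", n_eyes = 8,
         alpha_mean = 0.1837, alpha_sd = 0.1245,
         beta_mean = 0.0191, beta_sd = 0.0073),
    list(...)
  )
  do.call(cohort_config, args)
}

# moment-matched log-normal draw: arithmetic mean m, arithmetic sd s
rlnorm_moments <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# sub-seeds, one per named purpose, derived from the master seed; the first
# k per-eye seeds are unchanged when more eyes are added
derive_seeds <- function(seed, n, purpose = c("params", "noise", "phantom")) {
  purpose <- match.arg(purpose)
  offset <- c(params = 1L, noise = 2L, phantom = 3L)[[purpose]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed((seed %% 599999L) * 3571L + offset * 7919L)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw admissible per-eye model parameters
#'
#' Samples one eye's hybrid rate constants from the cohort distribution
#' (log-normal, moment-matched to the configured mean/SD), rejecting draws
#' until `alpha > 2 beta` and `beta < k12 < alpha` (so the implied
#' micro-constants are admissible). With zero SDs every eye receives the
#' configured means exactly.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed for this draw.
#' @param max_tries rejection-sampling cap; exceeded means the
#'   configuration is infeasible.
#' @return A list with `params` ([hybrid_params()]), `micro`
#'   ([micro_constants()]) and the drawn `alpha`, `beta`, `k12`.
#' @export
sample_eye_params <- function(config, seed, max_tries = 1000) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  for (i in seq_len(max_tries)) {
    alpha <- rlnorm_moments(1, config$alpha_mean, config$alpha_sd)
    beta <- rlnorm_moments(1, config$beta_mean, config$beta_sd)
    if (alpha <= 2 * beta) next
    if (!(beta < config$k12 && config$k12 < alpha)) next
    A <- 100 * (config$k12 - beta) / (alpha - beta)
    hp <- hybrid_params(A = A, alpha = alpha, beta = beta, D = 100)
    return(list(params = hp, micro = hybrid_to_micro(hp),
                alpha = alpha, beta = beta, k12 = config$k12))
  }
  stop("cohort configuration infeasible: ", max_tries,
       " consecutive inadmissible parameter draws", call. = FALSE)
}

#' Simulate one time-activity curve
#'
#' Evaluates the closed-form eye activity on the schedule and applies
#' multiplicative log-normal measurement noise with unit mean and the given
#' CV to every point after time 0; the first point is fixed at exactly 100
#' (normalisation to the first frame is exact by construction).
#'
#' @param params a [hybrid_params()] object (the eye's truth).
#' @param schedule sampling times (hours), first must be 0.
#' @param noise_cv fractional noise CV (0 gives the noise-free model curve).
#' @param seed integer seed for the noise draw.
#' @return A tibble with columns `time_h`, `activity_pct`.
#' @export
generate_curve <- function(params, schedule = study_schedule(),
                           noise_cv = 0.10, seed = 1L) {
  stopifnot(inherits(params, "hybrid_params"))
  if (schedule[1] != 0) stop("`schedule` must start at 0", call. = FALSE)
  if (noise_cv < 0) stop("`noise_cv` must be >= 0", call. = FALSE)
  y <- predict_eye_activity(params, schedule)
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    eps <- stats::rlnorm(length(schedule), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    y <- y * eps
  }
  y[1] <- 100
  tibble::tibble(time_h = schedule, activity_pct = y)
}

#' Simulate a cohort of eyes with known ground truth
#'
#' Draws per-eye parameters from the cohort distribution and generates a
#' noisy time-activity curve for each eye. All randomness derives from the
#' single `seed` through named sub-streams (one for parameters, one for
#' noise), with per-eye sub-seeds, so the same seed reproduces the cohort
#' exactly and adding eyes does not perturb earlier draws.
#'
#' @param config a [cohort_config()] (see [control_config()],
#'   [amd_config()]).
#' @param seed master integer seed.
#' @return A list with two tibbles: `curves` (columns `subject_id`, `eye`,
#'   `group`, `time_h`, `activity_pct`) and `truth` (one row per eye with
#'   the generating `A`, `alpha`, `beta`, `k12`, `k21`, `k20` and derived
#'   quantities).
#' @export
#' @examples
#' sim <- simulate_cohort(control_config(noise_cv = 0), seed = 7)
#' dplyr::count(sim$curves, subject_id)
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_eyes
  param_seeds <- derive_seeds(seed, n, "params")
  noise_seeds <- derive_seeds(seed, n, "noise")
  eyes <- purrr::map(seq_len(n), function(i) {
    truth <- sample_eye_params(config, seed = param_seeds[i])
    curve <- generate_curve(truth$params, schedule = config$schedule,
                            noise_cv = config$noise_cv,
                            seed = noise_seeds[i])
    id <- sprintf("%s_%02d", config$group, i)
    list(
      curve = dplyr::mutate(curve, subject_id = id, eye = "OD",
                            group = config$group, .before = 1),
      truth = tibble::tibble(
        subject_id = id, eye = "OD", group = config$group,
        A = truth$params$A, alpha = truth$alpha, beta = truth$beta,
        k12 = truth$micro$k12, k21 = truth$micro$k21, k20 = truth$micro$k20
      ) |>
        dplyr::bind_cols(derived_parameters(truth$params))
    )
  })
  list(
    curves = purrr::list_rbind(purrr::map(eyes, "curve")),
    truth = purrr::list_rbind(purrr::map(eyes, "truth"))
  )
}

#' Generate a spherical-eye voxel phantom with known truth
#'
#' A uniform sphere of activity (the eye) on a uniform background, rendered
#' on a regular voxel grid by centre-inclusion. The truth record carries the
#' analytic sphere integral and the exact voxelised total, the known-truth
#' targets for [extract_ellipsoid_roi()].
#'
#' @param eye_center mm coordinates of the sphere centre (length 3 or
#'   scalar).
#' @param eye_radius_mm sphere radius in mm.
#' @param eye_activity activity concentration inside the sphere (units/mL).
#' @param background background concentration (default 0).
#' @param spacing voxel size in mm (default 0.5, the PET reconstruction
#'   grid).
#' @param grid_shape number of voxels along each axis (length 3 or scalar).
#' @return A list with `volume` ([activity_volume()]) and `truth` (a tibble
#'   with the analytic and voxelised totals and sphere geometry).
#' @export
generate_eye_phantom <- function(eye_center, eye_radius_mm, eye_activity = 1,
                                 background = 0, spacing = 0.5,
                                 grid_shape = 48) {
  eye_center <- rep_len(as.numeric(eye_center), 3L)
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (eye_radius_mm <= 0) stop("`eye_radius_mm` must be > 0", call. = FALSE)
  if (eye_activity < 0 || background < 0) {
    stop("activities must be non-negative", call. = FALSE)
  }
  extent <- grid_shape * spacing
  if (any(eye_center - eye_radius_mm < 0) ||
      any(eye_center + eye_radius_mm > extent)) {
    stop("sphere does not fit inside the grid", call. = FALSE)
  }
  cx <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  cy <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  cz <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  q <- outer(outer((cx - eye_center[1])^2, (cy - eye_center[2])^2, `+`),
             (cz - eye_center[3])^2, `+`)
  inside <- q <= eye_radius_mm^2
  vox <- array(background, dim = grid_shape)
  vox[inside] <- eye_activity
  vol <- activity_volume(vox, spacing = spacing, origin = 0)
  vox_vol <- prod(spacing)
  truth <- tibble::tibble(
    analytic_total = 4 / 3 * pi * eye_radius_mm^3 * eye_activity +
      background * (prod(extent) - 4 / 3 * pi * eye_radius_mm^3),
    voxelized_total = sum(vox) * vox_vol,
    n_sphere_voxels = sum(inside),
    eye_radius_mm = eye_radius_mm,
    eye_activity = eye_activity,
    background = background
  )
  list(volume = vol, truth = truth)
}

#' Generate a synthetic autoradiograph with a known anterior fraction
#'
#' Builds a 2-D activity image split at a straight boundary orthogonal to
#' the anterior-posterior axis (rows): the anterior block (rows up to the
#' boundary) carries exactly `anterior_fraction` of the total activity
#' before noise. Optional multiplicative log-normal noise (unit mean) is
#' applied per pixel.
#'
#' @param shape image dimensions `c(rows, cols)`.
#' @param anterior_fraction target anterior share in `(0, 1)`.
#' @param noise_cv fractional multiplicative pixel noise (default 0).
#' @param seed integer seed for the noise draw.
#' @return A list with `image` (matrix), `boundary_row` (truth boundary)
#'   and `anterior_fraction` (the noise-free truth).
#' @export
generate_autoradiograph <- function(shape = c(64, 64), anterior_fraction,
                                    noise_cv = 0, seed = 1L) {
  if (anterior_fraction <= 0 || anterior_fraction >= 1) {
    stop("`anterior_fraction` must lie in (0, 1)", call. = FALSE)
  }
  shape <- rep_len(as.integer(shape), 2L)
  if (any(shape < 2L)) stop("image must be at least 2 x 2", call. = FALSE)
  nr <- shape[1]; nc <- shape[2]
  b <- min(max(round(anterior_fraction * nr), 1L), nr - 1L)
  total <- 1000
  img <- matrix(0, nr, nc)
  img[seq_len(b), ] <- anterior_fraction * total / (b * nc)
  img[seq.int(b + 1L, nr), ] <- (1 - anterior_fraction) * total / ((nr - b) * nc)
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    sdlog <- sqrt(log(1 + noise_cv^2))
    img <- img * matrix(
      stats::rlnorm(nr * nc, meanlog = -sdlog^2 / 2, sdlog = sdlog), nr, nc
    )
  }
  list(image = img, boundary_row = b, anterior_fraction = anterior_fraction)
}
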