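#' Fit every eye in a multi-eye time-activity table
#'
#' Splits a long table by `(subject_id, eye)`, fits the two-compartment
#' model to each curve and returns one row per eye with the parameter
#' estimates, derived quantities and goodness-of-fit battery (the columns
#' of [glance()]), plus the fit objects in a list-column.
#'
#' @param data long tibble with columns `subject_id`, `eye`, `group`,
#'   `time_h`, `activity_pct` (the format of [read_time_activity_table()]
#'   and [simulate_cohort()]).
#' @inheritParams fit_two_compartment
#' @return A tibble, one row per eye, with a `fit` list-column of
#'   `ivt_fit` objects.
#' @export
#' @examples
#' sim <- simulate_cohort(control_config(n_eyes = 2, noise_cv = 0), seed = 3)
#' fits <- fit_cohort(sim$curves)
#' fits[, c("subject_id", "alpha", "beta", "r2")]
fit_cohort <- function(data, weighting = c("1/yhat2", "1/yhat", "none"), ...) {
  weighting <- resolve_weighting(weighting)
  need <- c("subject_id", "eye", "group", "time_h", "activity_pct")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(data) |>
    dplyr::group_by(.data$subject_id, .data$eye, .data$group) |>
    tidyr::nest(curve = c("time_h", "activity_pct")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      fit = purrr::map(.data$curve, fit_two_compartment,
                       weighting = weighting, ...),
      stats = purrr::map(.data$fit, glance)
    ) |>
    tidyr::unnest("stats") |>
    dplyr::select(-"curve")
}

# parameters summarised per group, in report row order
report_parameters <- function() {
  c("alpha", "beta", "t_half_alpha", "t_half_beta", "auc_inf", "mrt",
    "r2", "sy_x", "rmse", "aicc")
}

#' Summarise per-eye fits into group-level means and SDs
#'
#' Arithmetic mean and sample SD (denominator n-1) of each reported
#' parameter over the converged fits of one group. Derived quantities
#' (half-lives, AUC, MRT) are averaged per eye, never recomputed from the
#' mean rate constants: for heterogeneous eyes `mean(ln2/beta_i)` differs
#' from `ln2/mean(beta_i)` (Jensen's inequality), and the per-eye
#' convention is the one group tables of this kind follow.
#'
#' @param fits a per-eye tibble from [fit_cohort()] (or any tibble with the
#'   parameter columns plus `converged`).
#' @return A tibble with columns `parameter`, `mean`, `sd`, `n_eyes`,
#'   `n_excluded` (non-converged fits left out); `sd` is `NA` for a single
#'   eye. Rows follow the conventional order alpha, beta, half-lives, AUC,
#'   MRT, then the goodness-of-fit metrics. The group label is kept when
#'   present.
#' @export
summarize_group <- function(fits) {
  if (nrow(fits) == 0L) stop("no fits to summarise", call. = FALSE)
  conv <- if ("converged" %in% names(fits)) fits$converged else rep(TRUE, nrow(fits))
  kept <- fits[conv, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no converged fits to summarise", call. = FALSE)
  pars <- intersect(report_parameters(), names(kept))
  out <- kept |>
    dplyr::select(dplyr::any_of(c("group", pars))) |>
    tidyr::pivot_longer(dplyr::all_of(pars),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(dplyr::across(dplyr::any_of("group")), .data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      n_eyes = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      parameter = factor(.data$parameter, levels = report_parameters()),
      n_excluded = sum(!conv)
    ) |>
    dplyr::arrange(dplyr::across(dplyr::any_of("group")), .data$parameter)
  out
}

#' Compare one parameter between two groups
#'
#' Welch's two-sample t-test (the default: robust to unequal variances with
#' small unequal group sizes) and/or a seeded permutation test of the mean
#' difference (exact when the number of group assignments is small, else
#' `n_perm` random resamples).
#'
#' @param a,b numeric vectors of per-eye values, each of length `>= 2`.
#' @param method `"welch"`, `"permutation"` or `"both"`.
#' @param n_perm permutation resamples (default 1e5) when full enumeration
#'   exceeds `n_perm`.
#' @param seed integer seed for the permutation draw.
#' @return A tibble with columns `test`, `statistic`, `p_value`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(11, 12, 13))
compare_groups <- function(a, b, method = c("welch", "permutation", "both"),
                           n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)
  rows <- list()
  if (method %in% c("welch", "both")) {
    if (degenerate) {
      rows$welch <- tibble::tibble(test = "welch", statistic = 0, p_value = 1)
    } else {
      tt <- stats::t.test(a, b)
      rows$welch <- tibble::tibble(test = "welch",
                                   statistic = unname(tt$statistic),
                                   p_value = tt$p.value)
    }
  }
  if (method %in% c("permutation", "both")) {
    rows$perm <- permutation_test(a, b, n_perm = n_perm, seed = seed,
                                  degenerate = degenerate)
  }
  dplyr::bind_rows(rows)
}

permutation_test <- function(a, b, n_perm = 1e5, seed = 1L,
                             degenerate = FALSE) {
  obs <- mean(a) - mean(b)
  if (degenerate) {
    return(tibble::tibble(test = "permutation", statistic = 0, p_value = 1))
  }
  pool <- c(a, b)
  na <- length(a)
  n_total <- length(pool)
  n_comb <- choose(n_total, na)
  if (n_comb <= n_perm) {
    idx <- utils::combn(n_total, na)
    diffs <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
    p <- mean(abs(diffs) >= abs(obs) - 1e-12)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    diffs <- replicate(n_perm, {
      i <- sample.int(n_total, na)
      mean(pool[i]) - mean(pool[-i])
    })
    # add-one correction for the observed assignment
    p <- (sum(abs(diffs) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  }
  tibble::tibble(test = "permutation", statistic = obs, p_value = p)
}

#' Compare every reported parameter between two fitted groups
#'
#' @param fits a per-eye tibble from [fit_cohort()] containing exactly two
#'   groups.
#' @inheritParams compare_groups
#' @return A tibble with one row per parameter and test.
#' @export
compare_group_fits <- function(fits, method = c("welch", "permutation", "both"),
                               n_perm = 1e5, seed = 1L) {
  method <- match.arg(method)
  groups <- unique(fits$group)
  if (length(groups) != 2L) {
    stop("`fits` must contain exactly two groups", call. = FALSE)
  }
  conv <- if ("converged" %in% names(fits)) fits$converged else rep(TRUE, nrow(fits))
  kept <- fits[conv, , drop = FALSE]
  pars <- intersect(report_parameters(), names(kept))
  purrr::map(pars, function(p) {
    a <- kept[[p]][kept$group == groups[1]]
    b <- kept[[p]][kept$group == groups[2]]
    compare_groups(a, b, method = method, n_perm = n_perm, seed = seed) |>
      dplyr::mutate(parameter = p, group_a = groups[1], group_b = groups[2],
                    .before = 1)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = report_parameters())) |>
    dplyr::arrange(.data$parameter)
}

#' Build the group-level analysis report table
#'
#' Assembles group summaries (and optional comparisons) into a wide,
#' machine-readable table with one row per parameter in the conventional
#' order (alpha, beta, half-lives, AUC, MRT, R2, Sy.x, RMSE, AICc) and one
#' mean/SD column pair per group, with run metadata attached as attributes.
#'
#' @param summaries a [summarize_group()] tibble covering one or more
#'   groups (the `group` column must be present).
#' @param comparisons optional [compare_group_fits()] tibble, attached as
#'   the `"comparisons"` attribute and merged in as p-value columns.
#' @param config optional named list of run metadata (seed, weighting, ...)
#'   stored in the `"run_config"` attribute.
#' @return A tibble of class `ivt_report`.
#' @export
build_report <- function(summaries, comparisons = NULL, config = list()) {
  if (!"group" %in% names(summaries)) {
    stop("`summaries` must carry a `group` column", call. = FALSE)
  }
  wide <- summaries |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = report_parameters())) |>
    tidyr::pivot_wider(
      id_cols = "parameter",
      names_from = "group",
      values_from = c("mean", "sd"),
      names_glue = "{group}_{.value}"
    ) |>
    dplyr::arrange(.data$parameter)
  if (!is.null(comparisons)) {
    pcols <- comparisons |>
      dplyr::select("parameter", "test", "p_value") |>
      tidyr::pivot_wider(names_from = "test", values_from = "p_value",
                         names_glue = "p_{test}")
    wide <- dplyr::left_join(wide, pcols, by = "parameter")
  }
  attr(wide, "comparisons") <- comparisons
  attr(wide, "run_config") <- utils::modifyList(
    list(package_version = as.character(utils::packageVersion("ivtpk"))),
    config
  )
  class(wide) <- c("ivt_report", class(wide))
  wide
}

#' @export
print.ivt_report <- function(x, ...) {
  cat("<ivt_report> two-compartment cohort summary\n")
  cfg <- attr(x, "run_config")
  if (length(cfg)) {
    cat("  run:", paste(names(cfg), unlist(cfg), sep = "=", collapse = "  "), "\n")
  }
  NextMethod()
}

#' Write / read a report table as CSV
#'
#' The CSV round-trips the numeric content at full precision (values are
#' written with 17 significant digits); attributes are not persisted.
#'
#' @param report an `ivt_report` (or any data frame).
#' @param path file path.
#' @return `read_report()` returns a tibble; `write_report()` returns
#'   `path` invisibly.
#' @export
write_report <- function(report, path) {
  out <- as.data.frame(report)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
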