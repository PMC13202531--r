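#' Activity volume on a regular voxel grid
#'
#' Container for a 3-D grid of activity concentration (arbitrary units per
#' mL) with physical voxel spacing. Coordinates live in continuous
#' millimetre space; the centre of voxel `[1, 1, 1]` sits at
#' `origin + spacing/2` (half-voxel convention), so voxel `[i, j, k]` has
#' centre `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param voxels 3-D numeric array of non-negative activity concentrations.
#' @param spacing voxel size in mm along each axis (length 3 or scalar).
#' @param origin mm offset of the corner of the grid (length 3 or scalar).
#' @return An object of class `activity_volume`.
#' @export
activity_volume <- function(voxels, spacing = 0.5, origin = 0) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array", call. = FALSE)
  }
  if (any(voxels < 0)) stop("voxel values must be non-negative", call. = FALSE)
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin),
    class = "activity_volume"
  )
}

#' @export
print.activity_volume <- function(x, ...) {
  cat("<activity_volume> ", paste(dim(x$voxels), collapse = " x "),
      "voxels, spacing", paste(format(x$spacing), collapse = " x "),
      "mm, total", format(sum(x$voxels) * prod(x$spacing)), "\n")
  invisible(x)
}

#' Ellipsoidal region of interest
#'
#' Axis-aligned ellipsoid in mm space, specified by its centre and
#' semi-axes. The conventional ocular ROI is 12 x 12 x 12 mm in diameter
#' (semi-axes 6 mm, volume ~904 mm3, deliberately larger than a rat eye to
#' compensate for partial-volume effects); organ ROIs are 7 x 7 x 7 mm
#' (343 mm3).
#'
#' @param center mm coordinates of the centre (length 3 or scalar).
#' @param semi_axes mm semi-axes (length 3 or scalar), `> 0`. A 12 mm
#'   diameter ROI has `semi_axes = 6`.
#' @return An object of class `ellipsoid_roi`.
#' @export
ellipsoid_roi <- function(center, semi_axes) {
  center <- rep_len(as.numeric(center), 3L)
  semi_axes <- rep_len(as.numeric(semi_axes), 3L)
  if (any(!is.finite(center)) || any(!is.finite(semi_axes))) {
    stop("`center` and `semi_axes` must be finite", call. = FALSE)
  }
  if (any(semi_axes <= 0)) stop("`semi_axes` must be positive", call. = FALSE)
  structure(list(center = center, semi_axes = semi_axes),
            class = "ellipsoid_roi")
}

#' Correct measured activity for physical radioactive decay
#'
#' Rescales a measured activity back to injection time:
#' `corrected = measured * 2^(elapsed / half_life)`. The default half-life
#' is that of zirconium-89 taken as 3.3 days (79.2 h), the value used for
#' immuno-PET tracers of this kind.
#'
#' @param measured_activity measured activity (any consistent unit).
#' @param elapsed_hours time since injection, hours, `>= 0` (vectorised).
#' @param half_life_hours physical half-life in hours; default `79.2`.
#' @return Decay-corrected activity, same unit as the input.
#' @export
#' @examples
#' decay_correct(50, 79.2)   # one half-life: 100
decay_correct <- function(measured_activity, elapsed_hours,
                          half_life_hours = 79.2) {
  if (any(elapsed_hours < 0)) stop("negative elapsed time", call. = FALSE)
  if (half_life_hours <= 0) stop("`half_life_hours` must be > 0", call. = FALSE)
  measured_activity * 2^(elapsed_hours / half_life_hours)
}

#' Normalise a raw activity series to its first frame
#'
#' The concentration measured in the first post-injection frame is the
#' reference; all values are expressed as a percentage of it, so the series
#' starts at exactly 100.
#'
#' @param raw_series numeric vector of (decay-corrected) activities; first
#'   value `> 0`.
#' @return Numeric vector in percent of initial uptake, first element 100.
#' @export
#' @examples
#' normalize_to_first_frame(c(5, 4, 2.5))  # 100 80 50
normalize_to_first_frame <- function(raw_series) {
  if (length(raw_series) == 0L) stop("empty series", call. = FALSE)
  if (raw_series[1] <= 0) {
    stop("first-frame activity must be positive to serve as reference",
         call. = FALSE)
  }
  100 * raw_series / raw_series[1]
}

#' Extract an ellipsoidal ROI from an activity volume
#'
#' A voxel belongs to the ROI iff its centre satisfies
#' \eqn{\sum_i ((c_i - center_i)/a_i)^2 \le 1} (centre-inclusion, no
#' partial-volume weighting). The mean concentration is the mean over member
#' voxels; the total activity is `mean * member volume`, i.e. the sum of
#' member voxel values times the voxel volume.
#'
#' @param volume an [activity_volume()].
#' @param roi an [ellipsoid_roi()].
#' @return A one-row tibble with `mean_conc`, `total_activity`, `n_voxels`,
#'   `roi_volume_mm3` (volume of the member voxels).
#' @export
extract_ellipsoid_roi <- function(volume, roi) {
  stopifnot(inherits(volume, "activity_volume"), inherits(roi, "ellipsoid_roi"))
  dims <- dim(volume$voxels)
  cx <- volume$origin[1] + (seq_len(dims[1]) - 0.5) * volume$spacing[1]
  cy <- volume$origin[2] + (seq_len(dims[2]) - 0.5) * volume$spacing[2]
  cz <- volume$origin[3] + (seq_len(dims[3]) - 0.5) * volume$spacing[3]
  qx <- ((cx - roi$center[1]) / roi$semi_axes[1])^2
  qy <- ((cy - roi$center[2]) / roi$semi_axes[2])^2
  qz <- ((cz - roi$center[3]) / roi$semi_axes[3])^2
  # separable quadratic form: outer sums give the membership mask
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  inside <- q <= 1
  n <- sum(inside)
  if (n == 0L) {
    stop("empty ROI: no voxel centre falls inside the ellipsoid", call. = FALSE)
  }
  vox_vol <- prod(volume$spacing)
  vals <- volume$voxels[inside]
  tibble::tibble(
    mean_conc = mean(vals),
    total_activity = sum(vals) * vox_vol,
    n_voxels = n,
    roi_volume_mm3 = n * vox_vol
  )
}

#' Percentage of injected dose in an organ
#'
#' `%ID = 100 * mean_conc * organ_volume / injected_dose`: the mean ROI
#' concentration normalised to the injected dose and the organ volume.
#'
#' @param mean_conc mean activity concentration in the organ ROI (units/mL).
#' @param organ_volume_mL organ volume in mL, `> 0`.
#' @param injected_dose injected activity, same units as
#'   `mean_conc * organ_volume_mL`, `> 0`.
#' @return Percent of injected dose (vectorised over `mean_conc`).
#' @export
percent_id_per_organ <- function(mean_conc, organ_volume_mL, injected_dose) {
  if (any(organ_volume_mL <= 0)) stop("`organ_volume_mL` must be > 0", call. = FALSE)
  if (any(injected_dose <= 0)) stop("`injected_dose` must be > 0", call. = FALSE)
  100 * mean_conc * organ_volume_mL / injected_dose
}

#' Total blood activity from theoretical blood volume
#'
#' Blood sampling gives a concentration per mL; total blood activity is
#' estimated from the theoretical blood volume of the animal,
#' `BV (mL) = slope * body_weight (g) + intercept` (defaults are the
#' standard rat allometric coefficients, 0.06 mL/g and 0.77 mL), and
#' expressed as a percentage of the injected dose.
#'
#' @param sample_conc_per_mL blood sample concentration (units/mL).
#' @param body_weight_g body weight in grams, `> 0`.
#' @param injected_dose injected activity, `> 0`.
#' @param bv_slope,bv_intercept blood-volume formula coefficients.
#' @return Percent of injected dose in the total blood pool.
#' @export
#' @examples
#' total_blood_activity(0, 300, 1)          # 0 %
#' 0.06 * 300 + 0.77                        # the 18.77 mL blood volume used
total_blood_activity <- function(sample_conc_per_mL, body_weight_g,
                                 injected_dose,
                                 bv_slope = 0.06, bv_intercept = 0.77) {
  if (any(body_weight_g <= 0)) stop("`body_weight_g` must be > 0", call. = FALSE)
  if (any(injected_dose <= 0)) stop("`injected_dose` must be > 0", call. = FALSE)
  bv <- bv_slope * body_weight_g + bv_intercept
  100 * sample_conc_per_mL * bv / injected_dose
}

#' Theoretical blood volume of a rat
#'
#' @param body_weight_g body weight in grams.
#' @param bv_slope,bv_intercept formula coefficients (mL/g and mL).
#' @return Blood volume in mL.
#' @export
blood_volume_mL <- function(body_weight_g, bv_slope = 0.06, bv_intercept = 0.77) {
  if (any(body_weight_g <= 0)) stop("`body_weight_g` must be > 0", call. = FALSE)
  bv_slope * body_weight_g + bv_intercept
}

#' Anterior/posterior split of an ocular autoradiograph
#'
#' Semiquantitative analysis of a 2-D autoradiograph: total activity is
#' split at a single straight boundary orthogonal to the anterior-posterior
#' axis (image rows by convention; rows up to the boundary are anterior).
#' The two percentages sum to exactly 100.
#'
#' @param image non-negative 2-D matrix with positive total activity.
#' @param boundary either a row index (integer `>= 1`) or an axis fraction
#'   in `(0, 1)` converted to `round(fraction * nrow)`.
#' @return A one-row tibble with `pct_anterior`, `pct_posterior`,
#'   `boundary_row`.
#' @export
#' @examples
#' anterior_posterior_split(matrix(1, 10, 10), boundary = 0.5)  # 50 / 50
anterior_posterior_split <- function(image, boundary) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (any(image < 0)) stop("image values must be non-negative", call. = FALSE)
  total <- sum(image)
  if (total <= 0) stop("zero total activity in the image", call. = FALSE)
  nr <- nrow(image)
  if (length(boundary) != 1L || !is.finite(boundary)) {
    stop("`boundary` must be a single finite number", call. = FALSE)
  }
  b <- if (boundary > 0 && boundary < 1) round(boundary * nr) else as.integer(boundary)
  if (b < 1L || b >= nr) {
    stop("`boundary` must leave at least one row on each side", call. = FALSE)
  }
  ant <- sum(image[seq_len(b), , drop = FALSE])
  pct_ant <- 100 * ant / total
  tibble::tibble(
    pct_anterior = pct_ant,
    pct_posterior = 100 - pct_ant,
    boundary_row = b
  )
}

#' Read / write an activity volume as NIfTI
#'
#' Thin wrappers over the NIfTI format for voxel volumes; spacing is stored
#' in the pixel dimensions.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume an [activity_volume()].
#' @return `read_activity_volume()` returns an [activity_volume()];
#'   `write_activity_volume()` returns `path` invisibly.
#' @export
write_activity_volume <- function(volume, path) {
  stopifnot(inherits(volume, "activity_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_activity_volume
#' @param origin mm origin to attach on read (the plain NIfTI round-trip
#'   keeps spacing; the package convention anchors the grid corner here).
#' @export
read_activity_volume <- function(path, origin = 0) {
  img <- RNifti::readNifti(path)
  activity_volume(
    voxels = array(as.numeric(img), dim = dim(img)),
    spacing = RNifti::pixdim(img)[seq_len(3)],
    origin = origin
  )
}

#' Read / write a 2-D autoradiograph as a plain numeric-matrix text file
#'
#' Whitespace-separated numeric rows, one image row per line.
#'
#' @param image numeric matrix.
#' @param path file path.
#' @return `read_autoradiograph()` returns a numeric matrix;
#'   `write_autoradiograph()` returns `path` invisibly.
#' @export
write_autoradiograph <- function(image, path) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  utils::write.table(image, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_autoradiograph
#' @export
read_autoradiograph <- function(path) {
  unname(as.matrix(utils::read.table(path, header = FALSE)))
}
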