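#' Exposure from activity concentration and acquisition duration
#'
#' Exposure is defined as the integral of activity concentration over the
#' acquisition time. For a non-decaying source (decay constant 0) this is
#' simply `ac0 * t`; for a decaying source it is
#' `ac0 * (1 - exp(-lambda * t)) / lambda`.
#'
#' @param ac0 Activity concentration at the start of the acquisition, kBq/ml.
#' @param t Acquisition duration, seconds.
#' @param lambda Decay constant, 1/s. Use 0 for long-lived sources such as
#'   Ge-68 at the time scale of a phantom study.
#' @return Exposure in kBq/ml*s.
#' @examples
#' compute_exposure(9.54, 3)        # 28.62 kBq/ml*s
#' compute_exposure(10, 6586, log(2) / 6586)
#' @export
compute_exposure <- function(ac0, t, lambda = 0) {
  if (any(ac0 < 0)) stop("'ac0' must be non-negative")
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(lambda < 0)) stop("'lambda' must be non-negative")
  n <- max(length(ac0), length(t), length(lambda))
  ac0 <- rep_len(ac0, n)
  t <- rep_len(t, n)
  lambda <- rep_len(lambda, n)
  # -expm1 avoids catastrophic cancellation of 1 - exp(-x) for tiny x
  ifelse(lambda == 0, ac0 * t, ac0 * (-expm1(-lambda * t)) / lambda)
}

#' An exposure point: one (activity concentration, duration) measurement
#'
#' @param ac Activity concentration, kBq/ml.
#' @param t_acq Acquisition duration, s.
#' @param lambda Decay constant, 1/s.
#' @param replicate_id Integer replicate index.
#' @return A list of class `exposure_point` with fields `ac`, `t_acq`,
#'   `exposure` (kBq/ml*s) and `replicate_id`.
#' @export
exposure_point <- function(ac, t_acq, lambda = 0, replicate_id = 1L) {
  structure(
    list(ac = ac, t_acq = t_acq,
         exposure = compute_exposure(ac, t_acq, lambda),
         replicate_id = as.integer(replicate_id)),
    class = "exposure_point")
}

#' Cuboid VOI voxel counts for a target edge length
#'
#' Per axis, the edge length is adjusted to the even voxel count nearest to
#' `target_edge / spacing`, with ties rounded upward. This is the rule that
#' reproduces the published 50 mm VOI sizes for 4 mm, 2 mm and 1.5 mm voxel
#' grids (12/12/12, 24/24/26 and 32/32/34 voxels respectively).
#'
#' @param voxel_size Numeric length-3, voxel spacing in mm.
#' @param target_edge Target cuboid edge length in mm (default 50).
#' @return Integer length-3 vector of voxel counts, all even.
#' @examples
#' voi_dims(c(2.03, 2.03, 2.0))  # 24 24 26
#' @export
voi_dims <- function(voxel_size, target_edge = 50) {
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be three positive spacings in mm")
  if (target_edge <= 0) stop("'target_edge' must be positive")
  x <- target_edge / voxel_size
  # nearest even integer, ties upward: 2*floor(x/2 + 1/2)
  n <- 2L * as.integer(floor(x / 2 + 0.5))
  pmax(n, 2L)
}

#' Construct a cuboid VOI object
#'
#' @param values 3-D numeric array of activity concentrations, kBq/ml.
#' @param voxel_size Voxel spacing, mm (length 3).
#' @param exposure_point An [exposure_point()] or `NULL`.
#' @return A list of class `cuboid_voi`.
#' @export
cuboid_voi <- function(values, voxel_size, exposure_point = NULL) {
  if (length(dim(values)) != 3) stop("'values' must be a 3-D array")
  structure(
    list(values = values, dims = dim(values), voxel_size = voxel_size,
         exposure_point = exposure_point),
    class = "cuboid_voi")
}

#' @export
print.cuboid_voi <- function(x, ...) {
  cat("Cuboid VOI:", paste(x$dims, collapse = " x "), "voxels,",
      paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  cat("  mean AC:", signif(mean(x$values), 5), "kBq/ml, sd:",
      signif(stats::sd(x$values), 5), "\n")
  if (!is.null(x$exposure_point))
    cat("  exposure:", signif(x$exposure_point$exposure, 5), "kBq/ml*s (t =",
        signif(x$exposure_point$t_acq, 5), "s)\n")
  invisible(x)
}

#' Construct a volume object (a 3-D scalar field with spacing)
#'
#' @param values 3-D numeric array, kBq/ml.
#' @param voxel_size Voxel spacing, mm (length 3, all positive).
#' @param origin Physical coordinates of the first voxel centre, mm.
#' @return A list of class `pet_volume`.
#' @export
pet_volume <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3) stop("'values' must be a 3-D array")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive spacings in mm")
  structure(list(values = values, voxel_size = voxel_size, origin = origin),
            class = "pet_volume")
}

#' Locate the phantom centre in a volume
#'
#' Thresholds the volume at 50% of its 99th-percentile intensity and returns
#' the centre of mass of the supra-threshold voxels, in voxel coordinates.
#'
#' @param volume A [pet_volume()].
#' @return Numeric length-3 voxel-coordinate centre.
#' @export
detect_phantom_centre <- function(volume) {
  v <- volume$values
  thr <- 0.5 * stats::quantile(v, 0.99, names = FALSE)
  mask <- v > thr
  if (!any(mask)) stop("no voxels above the detection threshold")
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx)
}

#' Extract the central cuboid VOI from a volume
#'
#' Copies (never resamples) a cuboid of [voi_dims()] voxels centred either on
#' the detected phantom centre or on the image centre.
#'
#' @param volume A [pet_volume()].
#' @param target_edge Target cuboid edge, mm.
#' @param exposure_point Optional [exposure_point()] attached to the VOI.
#' @param centre `"detect"` (centre of mass of the thresholded phantom) or
#'   `"image"` (geometric centre of the array).
#' @return A [cuboid_voi()].
#' @export
extract_voi <- function(volume, target_edge = 50, exposure_point = NULL,
                        centre = c("detect", "image")) {
  centre <- match.arg(centre)
  n <- voi_dims(volume$voxel_size, target_edge)
  dm <- dim(volume$values)
  ctr <- if (centre == "detect") detect_phantom_centre(volume)
         else (dm + 1) / 2
  lo <- as.integer(round(ctr - n / 2 + 0.5))
  hi <- lo + n - 1L
  for (ax in 1:3) {
    if (lo[ax] < 1L || hi[ax] > dm[ax])
      stop(sprintf(
        "VOI exceeds volume bounds on axis %s: need voxels %d..%d of %d",
        c("x", "y", "z")[ax], lo[ax], hi[ax], dm[ax]))
  }
  vals <- volume$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cuboid_voi(vals, volume$voxel_size, exposure_point)
}
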