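#' Noise model for a homogeneous phantom VOI
#'
#' Parametric stand-in for the voxel-noise behaviour that PET reconstruction
#' algorithms imprint on a homogeneous object. Three archetypes are provided:
#' `gaussian_fbp` (filtered back-projection: Gaussian marginals at every
#' exposure, negative values possible), `gamma_iterative` and
#' `lognormal_iterative` (OSEM/PSF-like: right-skewed marginals that converge
#' to a Gaussian as exposure grows). In every archetype the voxel mean equals
#' the true activity concentration and the coefficient of variation follows
#' the count-statistics power law `CV(E) = alpha * E^(-1/2)` with exposure E
#' in kBq/ml*s.
#'
#' @param archetype One of `"gaussian_fbp"`, `"gamma_iterative"`,
#'   `"lognormal_iterative"`.
#' @param ac_true True activity concentration, kBq/ml (> 0).
#' @param alpha Noise coefficient, dimensionless (> 0, or 0 for the noiseless
#'   limit); `CV = alpha` at E = 1 kBq/ml*s. The default 5 gives CV = 0.5 at
#'   E = 100 kBq/ml*s.
#' @param smoothing_fwhm Full width at half maximum of an optional Gaussian
#'   spatial filter applied to the noise field, mm; 0 disables smoothing.
#' @param voxel_size Voxel spacing, mm (length 3).
#' @param seed Integer base seed for reproducible series generation.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(archetype = c("gaussian_fbp", "gamma_iterative",
                                      "lognormal_iterative"),
                        ac_true = 9.54, alpha = 5, smoothing_fwhm = 0,
                        voxel_size = c(2.03, 2.03, 2.0), seed = 1L) {
  archetype <- match.arg(archetype)
  if (ac_true <= 0) stop("'ac_true' must be positive")
  if (alpha < 0) stop("'alpha' must be non-negative")
  if (smoothing_fwhm < 0) stop("'smoothing_fwhm' must be non-negative")
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive spacings in mm")
  structure(
    list(archetype = archetype, ac_true = ac_true, alpha = alpha,
         smoothing_fwhm = smoothing_fwhm, voxel_size = voxel_size,
         seed = as.integer(seed)),
    class = "noise_model")
}

#' Acquisition schedule: frame durations and replicates
#'
#' The default reproduces the phantom study design: 25 frame durations placed
#' geometrically from 3 s to 10861 s (step ratio about 1.407), 20 replicate
#' acquisitions per duration, activity concentration 9.54 kBq/ml, and no
#' decay (Ge-68 is effectively constant over such a session).
#'
#' @param durations Strictly increasing positive frame durations, s.
#' @param replicates Replicate acquisitions per duration.
#' @param ac_at_start Activity concentration at acquisition start, kBq/ml.
#' @param decay_constant Decay constant lambda, 1/s.
#' @return A list of class `acquisition_schedule`.
#' @export
acquisition_schedule <- function(durations = default_durations(),
                                 replicates = 20L,
                                 ac_at_start = 9.54,
                                 decay_constant = 0) {
  if (any(durations <= 0)) stop("'durations' must all be positive")
  if (is.unsorted(durations, strictly = TRUE))
    stop("'durations' must be strictly increasing")
  if (replicates < 1) stop("'replicates' must be at least 1")
  if (ac_at_start <= 0) stop("'ac_at_start' must be positive")
  if (decay_constant < 0) stop("'decay_constant' must be non-negative")
  structure(
    list(durations = durations, replicates = as.integer(replicates),
         ac_at_start = ac_at_start, decay_constant = decay_constant),
    class = "acquisition_schedule")
}

#' Default geometric duration ladder, 3 s to 10861 s in 25 steps
#'
#' @param n Number of durations.
#' @param t_min,t_max First and last duration, s.
#' @return Numeric vector of durations.
#' @export
default_durations <- function(n = 25L, t_min = 3, t_max = 10861) {
  t_min * (t_max / t_min)^(seq(0, n - 1) / (n - 1))
}

# deterministic per-item seed below 2^31, reproducible in isolation
item_seed <- function(base_seed, duration_index, replicate_index) {
  as.integer((as.numeric(base_seed) + 100003 * duration_index +
                997 * replicate_index) %% 2147483629)
}

#' Simulate one homogeneous-phantom VOI at a given exposure
#'
#' Draws an i.i.d. voxel field from the archetype's marginal distribution,
#' matched to mean `ac_true` and `CV = alpha * E^(-1/2)`:
#' * `gaussian_fbp`: Normal(ac, ac*CV) — negatives permitted;
#' * `gamma_iterative`: Gamma with shape `k = E / alpha^2` and scale `ac/k`,
#'   so skewness `2/sqrt(k)` and excess kurtosis `6/k`;
#' * `lognormal_iterative`: log-normal matched to the same mean and CV.
#'
#' If `smoothing_fwhm > 0`, the zero-mean noise field is convolved with a
#' Gaussian kernel of that FWHM and rescaled so the marginal CV still equals
#' the target; this introduces neighbour correlation while keeping the
#' first-order moments analytic.
#'
#' @param spec A [noise_model()].
#' @param exposure Exposure E, kBq/ml*s (> 0).
#' @param dims Integer length-3 voxel counts, each >= 2.
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A [cuboid_voi()] whose `exposure_point` carries the implied
#'   acquisition duration `exposure / ac_true`.
#' @export
simulate_voi <- function(spec, exposure, dims, seed = spec$seed) {
  stopifnot(inherits(spec, "noise_model"))
  if (!is.numeric(exposure) || length(exposure) != 1 || exposure <= 0)
    stop("'exposure' must be a single positive value in kBq/ml*s")
  if (length(dims) != 3 || any(dims < 2))
    stop("'dims' must be three voxel counts, each at least 2")
  dims <- as.integer(dims)
  n <- prod(dims)
  ac <- spec$ac_true
  cv <- spec$alpha / sqrt(exposure)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (cv == 0) {
    v <- rep(ac, n)
  } else if (spec$archetype == "gaussian_fbp") {
    v <- stats::rnorm(n, mean = ac, sd = ac * cv)
  } else if (spec$archetype == "gamma_iterative") {
    k <- 1 / cv^2  # = exposure / alpha^2
    v <- stats::rgamma(n, shape = k, scale = ac / k)
  } else {
    sdlog <- sqrt(log1p(cv^2))
    v <- stats::rlnorm(n, meanlog = log(ac) - sdlog^2 / 2, sdlog = sdlog)
  }
  arr <- array(v, dim = dims)
  if (spec$smoothing_fwhm > 0 && cv > 0) {
    noise <- arr - mean(arr)
    sm <- gaussian_smooth3d(noise, spec$smoothing_fwhm, spec$voxel_size)
    s <- stats::sd(as.vector(sm))
    if (s > 0) sm <- sm * (stats::sd(as.vector(noise)) / s)
    arr <- mean(arr) + sm
  }
  ep <- exposure_point(ac, exposure / ac, 0, 1L)
  cuboid_voi(arr, spec$voxel_size, ep)
}

# separable Gaussian convolution with edge renormalization
gaussian_smooth3d <- function(arr, fwhm, voxel_size) {
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  out <- arr
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    out <- convolve_axis(out, k / sum(k), ax)
  }
  out
}

convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  r <- (length(kernel) - 1L) / 2L
  n <- nrow(m)
  res <- matrix(0, n, ncol(m))
  wt <- numeric(n)
  for (off in -r:r) {
    w <- kernel[off + r + 1L]
    src <- pmin(pmax(seq_len(n) + off, 1L), n)  # handled via valid range
    valid <- seq_len(n) + off >= 1L & seq_len(n) + off <= n
    res[valid, ] <- res[valid, ] + w * m[src[valid], ]
    wt[valid] <- wt[valid] + w
  }
  res <- res / wt
  a <- array(res, dim = d[perm])
  aperm(a, order(perm))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full exposure series of simulated VOIs
#'
#' One VOI per (duration, replicate), with exposures from
#' [compute_exposure()] and per-item seeds derived deterministically from the
#' model's base seed, so any single VOI is reproducible in isolation.
#'
#' @param spec A [noise_model()].
#' @param schedule An [acquisition_schedule()].
#' @param dims Integer length-3 voxel counts; default from [voi_dims()] on
#'   the model's voxel size.
#' @return A list of [cuboid_voi()] objects, ordered by duration then
#'   replicate; each `exposure_point` carries the replicate id.
#' @export
generate_exposure_series <- function(spec, schedule,
                                     dims = voi_dims(spec$voxel_size)) {
  stopifnot(inherits(spec, "noise_model"),
            inherits(schedule, "acquisition_schedule"))
  out <- vector("list", length(schedule$durations) * schedule$replicates)
  idx <- 1L
  for (di in seq_along(schedule$durations)) {
    t <- schedule$durations[di]
    e <- compute_exposure(schedule$ac_at_start, t, schedule$decay_constant)
    for (ri in seq_len(schedule$replicates)) {
      voi <- simulate_voi(spec, e, dims, seed = item_seed(spec$seed, di, ri))
      voi$exposure_point <- exposure_point(schedule$ac_at_start, t,
                                           schedule$decay_constant, ri)
      out[[idx]] <- voi
      idx <- idx + 1L
    }
  }
  out
}
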