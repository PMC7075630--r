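#' First-order statistics of a VOI value distribution
#'
#' Computes the eleven first-order descriptors used to characterise image
#' noise: mean, standard deviation, coefficient of variation, excess
#' kurtosis, skewness, the Lilliefors normality statistic D and its
#' Monte-Carlo p-value, the normalized RMS deviation of a Gaussian fitted to
#' the value histogram, the crest factor in dB, the normalized histogram
#' entropy (efficiency) and the mode/mean ratio.
#'
#' The standardized moments use the population (1/N) convention throughout,
#' including in `sd`; the Lilliefors test alone uses the conventional (n-1)
#' sample SD because it is a named test with a fixed definition.
#'
#' @param c A [cuboid_voi()] or a numeric vector/array of voxel values.
#' @param hist_levels Number of equal-width min-max levels used for the
#'   efficiency (normalized entropy) descriptor.
#' @param mc_reps Monte-Carlo replicates for the Lilliefors p-value.
#' @param seed Seed for the Monte-Carlo null.
#' @param null_D Optional precomputed null distribution of D for this sample
#'   size, from [lilliefors_null()]; when supplied `mc_reps`/`seed` are
#'   ignored. The null depends only on N, so it can be shared across VOIs.
#' @return A list of class `first_order_stats` with fields `mean`, `sd`,
#'   `cv`, `excess_kurtosis`, `skewness`, `lilliefors_D`, `lilliefors_p`,
#'   `gauss_fit_nrmsd`, `crest_factor`, `efficiency`, `mode_over_mean` and
#'   `n`. Degenerate inputs (zero variance) yield `NA` for the standardized
#'   moments with the `degenerate` flag set, never a silent zero.
#' @export
first_order_stats <- function(c, hist_levels = 256L, mc_reps = 2000L,
                              seed = 1L, null_D = NULL) {
  x <- voi_values(c)
  n <- length(x)
  if (n < 8) stop("need at least 8 voxels")
  mu <- mean(x)
  sg <- sqrt(mean((x - mu)^2))  # population convention
  degenerate <- sg == 0
  if (degenerate) {
    cv <- if (mu != 0) 0 else NA_real_
    skw <- kur <- NA_real_
    lD <- lp <- NA_real_
    nrmsd <- NA_real_
  } else {
    cv <- sg / mu
    z <- (x - mu) / sg
    skw <- mean(z^3)
    kur <- mean(z^4) - 3
    lt <- lilliefors_test(x, mc_reps = mc_reps, seed = seed, null_D = null_D)
    lD <- lt$D
    lp <- lt$p
    nrmsd <- gauss_fit_nrmsd(x)
  }
  rms <- sqrt(mean(x^2))
  crest <- if (rms > 0) 20 * log10(max(abs(x)) / rms) else NA_real_
  eff <- efficiency_entropy(x, hist_levels)
  mode_val <- if (degenerate) mu else histogram_mode(x)
  structure(
    list(mean = mu, sd = sg, cv = cv, excess_kurtosis = kur, skewness = skw,
         lilliefors_D = lD, lilliefors_p = lp, gauss_fit_nrmsd = nrmsd,
         crest_factor = crest, efficiency = eff,
         mode_over_mean = if (mu != 0) mode_val / mu else NA_real_,
         n = n, degenerate = degenerate),
    class = "first_order_stats")
}

#' @export
print.first_order_stats <- function(x, ...) {
  cat("First-order statistics (N =", x$n, "voxels)\n")
  v <- unlist(x[c("mean", "sd", "cv", "excess_kurtosis", "skewness",
                  "lilliefors_D", "lilliefors_p", "gauss_fit_nrmsd",
                  "crest_factor", "efficiency", "mode_over_mean")])
  print(signif(v, 5))
  if (isTRUE(x$degenerate)) cat("  (degenerate: zero variance)\n")
  invisible(x)
}

voi_values <- function(c) {
  if (inherits(c, "cuboid_voi")) as.vector(c$values) else as.vector(c)
}

# normalized histogram entropy, log base anchored to the voxel count N
efficiency_entropy <- function(x, hist_levels = 256L) {
  n <- length(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  g <- pmin(1L + floor(hist_levels * (x - rng[1]) / diff(rng)), hist_levels)
  p <- tabulate(g, nbins = hist_levels)
  p <- p[p > 0] / n
  -sum(p * log(p)) / log(n)
}

# mode as the centre of the tallest Freedman-Diaconis histogram bin
histogram_mode <- function(x) {
  b <- fd_breaks(x)
  h <- graphics::hist(x, breaks = b, plot = FALSE)
  h$mids[which.max(h$counts)]
}

fd_breaks <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0) return(range(x) + c(-0.5, 0.5))
  bw <- 2 * iqr / length(x)^(1 / 3)
  nb <- max(1L, ceiling(diff(range(x)) / bw))
  seq(min(x), max(x), length.out = nb + 1L)
}

#' Lilliefors normality test with a Monte-Carlo p-value
#'
#' D is the supremum distance between the empirical CDF and the Gaussian CDF
#' with the sample's mean and (n-1) SD, evaluated on both sides of every
#' step. The p-value is obtained from a seeded Monte-Carlo null of Gaussian
#' samples of the same size, so it remains meaningful far into the tail where
#' table approximations fail; it is floored at `1/(mc_reps + 1)` and never
#' reported as zero.
#'
#' @param c Numeric values (or a [cuboid_voi()]).
#' @param mc_reps Number of Monte-Carlo null replicates.
#' @param seed Seed for the null.
#' @param null_D Optional precomputed null D values from [lilliefors_null()].
#' @return A list with elements `D`, `p` and `n`.
#' @export
lilliefors_test <- function(c, mc_reps = 2000L, seed = 1L, null_D = NULL) {
  x <- voi_values(c)
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  D <- lilliefors_D(x)
  if (is.null(null_D)) null_D <- lilliefors_null(n, mc_reps, seed)
  r <- length(null_D)
  p <- (1 + sum(null_D >= D)) / (r + 1)
  list(D = D, p = min(max(p, 1 / (r + 1)), 1), n = n)
}

lilliefors_D <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  p <- stats::pnorm(sort(x), mean = mean(x), sd = s)
  i <- seq_len(n)
  max(i / n - p, p - (i - 1) / n)
}

#' Monte-Carlo null distribution of the Lilliefors D statistic
#'
#' @param n Sample size.
#' @param mc_reps Number of null replicates.
#' @param seed Seed.
#' @return Numeric vector of `mc_reps` null D values.
#' @export
lilliefors_null <- function(n, mc_reps = 2000L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- seq_len(n)
  vapply(seq_len(mc_reps), function(r) {
    z <- stats::rnorm(n)
    p <- stats::pnorm(sort(z), mean = mean(z), sd = stats::sd(z))
    max(i / n - p, p - (i - 1) / n)
  }, numeric(1))
}

#' Normalized RMS deviation of a Gaussian fitted to the value histogram
#'
#' Builds a Freedman-Diaconis histogram, fits a 3-parameter Gaussian
#' (amplitude, centre, width) to the bin counts by nonlinear least squares,
#' and returns the RMS deviation between fit and counts divided by the range
#' (max - min) of the counts.
#'
#' @param c Numeric values (or a [cuboid_voi()]).
#' @return NRMSD, dimensionless; `NA` with a warning if the fit fails to
#'   converge or fewer than 8 occupied bins exist.
#' @export
gauss_fit_nrmsd <- function(c) {
  x <- voi_values(c)
  b <- fd_breaks(x)
  h <- graphics::hist(x, breaks = b, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  if (sum(counts > 0) < 8) {
    warning("fewer than 8 occupied histogram bins; NRMSD undefined")
    return(NA_real_)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      counts ~ A * exp(-(mids - m)^2 / (2 * s^2)),
      start = list(A = max(counts), m = mean(x), s = stats::sd(x)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("Gaussian histogram fit did not converge; NRMSD undefined")
    return(NA_real_)
  }
  r <- counts - stats::fitted(fit)
  sqrt(mean(r^2)) / diff(range(counts))
}
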