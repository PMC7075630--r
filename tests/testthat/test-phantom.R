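test_that("simulated VOIs recover the target mean and CV", {
  for (arch in c("gaussian_fbp", "gamma_iterative", "lognormal_iterative")) {
    spec <- noise_model(arch, ac_true = 9.54, alpha = 5)
    for (E in c(30, 1000, 1e5)) {
      voi <- simulate_voi(spec, E, c(24, 24, 26), seed = 11)
      x <- as.vector(voi$values)
      cv_target <- 5 / sqrt(E)
      n <- length(x)
      expect_lt(abs(mean(x) - 9.54) / 9.54, 5 * cv_target / sqrt(n),
                label = paste(arch, "mean at E =", E))
      expect_lt(abs(stats::sd(x) / mean(x) - cv_target) / cv_target, 0.1,
                label = paste(arch, "CV at E =", E))
    }
  }
})

test_that("gamma archetype has the analytic skewness and kurtosis", {
  # k = E / alpha^2 = 10000: skewness 2/sqrt(k) = 0.02, excess kurt 6/k
  spec <- noise_model("gamma_iterative", alpha = 1)
  skews <- kurts <- numeric(5)
  for (s in 1:5) {
    voi <- simulate_voi(spec, 10000, c(24, 24, 26), seed = s)
    m <- pop_moments(as.vector(voi$values))
    skews[s] <- m$skew
    kurts[s] <- m$kurt
  }
  expect_lt(abs(mean(skews) - 0.02), 0.01)
  expect_lt(abs(mean(kurts) - 0.0006), 0.05)
})

test_that("Gaussian archetype stays Gaussian at every exposure", {
  spec <- noise_model("gaussian_fbp", alpha = 5)
  for (E in c(30, 300, 3e4)) {
    voi <- simulate_voi(spec, E, c(24, 24, 26), seed = 2)
    m <- pop_moments(as.vector(voi$values))
    n <- prod(c(24, 24, 26))
    expect_lt(abs(m$skew), 4 * sqrt(6 / n))
    expect_lt(abs(m$kurt), 4 * sqrt(24 / n))
  }
})

test_that("the noiseless limit returns a constant field", {
  for (arch in c("gaussian_fbp", "gamma_iterative", "lognormal_iterative")) {
    spec <- noise_model(arch, ac_true = 9.54, alpha = 0)
    voi <- simulate_voi(spec, 100, c(4, 4, 4), seed = 1)
    expect_true(all(voi$values == 9.54))
  }
})

test_that("degenerate inputs are rejected with a message", {
  spec <- noise_model("gaussian_fbp")
  expect_error(simulate_voi(spec, -5, c(4, 4, 4)), "positive")
  expect_error(simulate_voi(spec, 0, c(4, 4, 4)), "positive")
  expect_error(simulate_voi(spec, 100, c(1, 4, 4)), "at least 2")
})

test_that("sample CV follows the E^(-1/2) power law over the schedule", {
  sched <- acquisition_schedule(replicates = 2L)
  for (arch in c("gaussian_fbp", "gamma_iterative")) {
    spec <- noise_model(arch, alpha = 5, seed = 4)
    series <- generate_exposure_series(spec, sched, dims = c(12, 12, 12))
    E <- vapply(series, function(v) v$exposure_point$exposure, numeric(1))
    cv <- vapply(series, function(v) {
      x <- as.vector(v$values); stats::sd(x) / mean(x)
    }, numeric(1))
    slope <- stats::coef(stats::lm(log10(cv) ~ log10(E)))[2]
    expect_lt(abs(slope + 0.5), 0.02, label = paste(arch, "CV slope"))
  }
})

test_that("exposure series has the expected size, range and determinism", {
  sched <- acquisition_schedule()  # 25 durations x 20 replicates
  expect_length(sched$durations, 25)
  spec <- noise_model("gamma_iterative", seed = 9)
  small <- acquisition_schedule(durations = sched$durations[c(1, 13, 25)],
                                replicates = 2L)
  series <- generate_exposure_series(spec, small, dims = c(6, 6, 6))
  expect_length(series, 6)
  E <- vapply(series, function(v) v$exposure_point$exposure, numeric(1))
  expect_equal(min(E), 28.62)
  expect_equal(max(E), 10861 * 9.54)
  # full-schedule exposure range matches the published span
  expect_equal(range(compute_exposure(9.54, sched$durations, 0)),
               c(28.62, 103613.94), tolerance = 1e-6)
  # determinism: same spec and schedule give bit-identical arrays
  series2 <- generate_exposure_series(spec, small, dims = c(6, 6, 6))
  for (i in seq_along(series))
    expect_identical(series[[i]]$values, series2[[i]]$values)
  # single item: exposure = ac * t
  one <- generate_exposure_series(
    spec, acquisition_schedule(durations = 10, replicates = 1L),
    dims = c(6, 6, 6))
  expect_length(one, 1)
  expect_equal(one[[1]]$exposure_point$exposure, 95.4)
})

test_that("normality of the gamma archetype emerges with exposure", {
  # k = E/alpha^2; high k passes Lilliefors, low k fails, across seeds
  alpha <- 5
  null_D <- lilliefors_null(12^3, 400, seed = 99)
  hi <- lo <- logical(10)
  for (s in 1:10) {
    spec <- noise_model("gamma_iterative", alpha = alpha, seed = s)
    v_hi <- simulate_voi(spec, 1000 * alpha^2, c(12, 12, 12), seed = s)
    v_lo <- simulate_voi(spec, 25 * alpha^2, c(12, 12, 12), seed = s + 50)
    hi[s] <- lilliefors_test(v_hi, null_D = null_D)$p > 0.05
    lo[s] <- lilliefors_test(v_lo, null_D = null_D)$p < 0.05
  }
  expect_gte(mean(hi), 0.9)
  expect_gte(mean(lo), 0.9)
})

test_that("negative voxels appear in FBP at low exposure and vanish", {
  spec <- noise_model("gaussian_fbp", ac_true = 9.54, alpha = 5)
  E_low <- 20  # CV > 1: negatives common
  voi <- simulate_voi(spec, E_low, c(24, 24, 26), seed = 5)
  frac <- mean(voi$values < 0)
  cv <- 5 / sqrt(E_low)
  expect_lt(abs(frac - stats::pnorm(-1 / cv)), 0.02)
  voi_hi <- simulate_voi(spec, 1e5, c(24, 24, 26), seed = 5)
  expect_identical(sum(voi_hi$values < 0), 0L)
})

test_that("spatial smoothing preserves the marginal mean and CV", {
  spec <- noise_model("gaussian_fbp", alpha = 5, smoothing_fwhm = 4,
                      voxel_size = c(2, 2, 2))
  voi <- simulate_voi(spec, 100, c(24, 24, 26), seed = 3)
  x <- as.vector(voi$values)
  expect_lt(abs(stats::sd(x) / mean(x) - 0.5) / 0.5, 0.1)
  # smoothing induces positive neighbour correlation
  a <- voi$values
  r <- stats::cor(as.vector(a[-24, , ]), as.vector(a[-1, , ]))
  expect_gt(r, 0.2)
})
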