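test_that("mapped quantization follows the linear min-max rule", {
  g <- quantize(c(0, 5, 10), quantization_spec("mapped", 8))
  expect_identical(as.vector(g), c(1L, 5L, 8L))
  # min and max always occupy the end levels
  set.seed(1)
  for (G in c(8, 32, 256)) {
    x <- stats::rnorm(500)
    q <- quantize(x, quantization_spec("mapped", G))
    expect_identical(range(as.vector(q)), c(1L, as.integer(G)))
  }
})

test_that("degenerate mapped input is flagged, all voxels at level 1", {
  q <- quantize(rep(3.3, 27), quantization_spec("mapped", 16))
  expect_true(all(q == 1L))
  expect_true(attr(q, "degenerate"))
})

test_that("full-range quantization clamps out-of-range values, warning", {
  spec <- quantization_spec("full_range", 8, global_lo = 0, global_hi = 10)
  expect_warning(q <- quantize(c(-1, 5, 12), spec), "clamped")
  expect_identical(as.vector(q), c(1L, 5L, 8L))
  expect_identical(attr(q, "n_clamped"), 2L)
})

test_that("fixed-bin-from-zero quantization uses the published rule", {
  spec <- quantization_spec("fixed_bin_zero", 512, bin_upper = 25)
  expect_identical(as.vector(quantize(12.5, spec)), 257L)
  expect_identical(as.vector(quantize(-3, spec)), 1L)
  expect_identical(as.vector(quantize(30, spec)), 512L)
})

test_that("a 2x2 slice gives the hand-enumerated co-occurrence matrix", {
  g <- build_glcm(array(c(1L, 2L, 2L, 1L), c(2, 2, 1)), G = 2)
  expect_identical(g$R, 8)  # 4 horizontal + 4 vertical ordered pairs
  expect_equal(g$P[1, 2], 0.5)
  expect_equal(g$P[2, 1], 0.5)
  expect_equal(g$P[1, 1] + g$P[2, 2], 0)
})

test_that("GLCMs are normalized and symmetric under symmetric counting", {
  set.seed(5)
  for (i in 1:5) {
    arr <- array(sample.int(8, 6 * 7 * 5, replace = TRUE), c(6, 7, 5))
    g <- build_glcm(arr, G = 8)
    expect_equal(sum(g$P), 1, tolerance = 1e-12)
    expect_equal(g$P, t(g$P), tolerance = 1e-12)
    expect_true(all(g$P >= 0))
    g3 <- build_glcm(arr, G = 8, include_axial = TRUE)
    expect_equal(sum(g3$P), 1, tolerance = 1e-12)
    expect_gt(g3$R, g$R)
  }
  expect_error(build_glcm(array(1L, c(2, 2, 2)), G = 2,
                          directions = list()), "empty")
})

test_that("a constant grey volume concentrates all mass at one entry", {
  g <- build_glcm(array(3L, c(4, 4, 4)), G = 8)
  expect_equal(g$P[3, 3], 1)
  expect_equal(sum(g$P), 1)
})

test_that("marginals match the analytic diagonal-uniform values", {
  m <- glcm_marginals(diag(8) / 8)
  expect_equal(m$mu_x, 4.5)
  expect_equal(m$mu_y, 4.5)
  expect_equal(m$sigma_x^2, (8^2 - 1) / 12)  # discrete-uniform variance
  expect_equal(m$sigma_x, m$sigma_y)
  expect_equal(sum(m$p_sum), 1)
  expect_equal(sum(m$p_diff), 1)
})

test_that("single-entry GLCM marginals are degenerate as expected", {
  P <- matrix(0, 8, 8); P[1, 1] <- 1
  m <- glcm_marginals(P)
  expect_equal(m$mu_x, 1)
  expect_equal(m$sigma_x, 0)
  expect_identical(m$mode_x, 1L)
  expect_equal(unname(m$p_sum["2"]), 1)
})

test_that("marginals equal a brute-force double-loop oracle", {
  set.seed(11)
  for (i in 1:5) {
    P <- random_glcm(16)
    m <- glcm_marginals(P)
    o <- naive_marginals(P)
    expect_equal(m$mu_x, o$mu_x, tolerance = 1e-12)
    expect_equal(m$mu_y, o$mu_y, tolerance = 1e-12)
    expect_equal(m$sigma_x, o$sigma_x, tolerance = 1e-12)
    expect_equal(m$sigma_y, o$sigma_y, tolerance = 1e-12)
    expect_equal(m$p_sum, o$p_sum, tolerance = 1e-12)
    expect_equal(m$p_diff, o$p_diff, tolerance = 1e-12)
    expect_equal(sum(m$p_sum), 1, tolerance = 1e-12)
    expect_equal(sum(m$p_diff), 1, tolerance = 1e-12)
  }
})

test_that("mapped grey means drift with exposure only for skewed noise", {
  # gamma + mapped: mu_x in grey units rises with E (skew pulls the mean
  # towards the low levels at low exposure); gaussian + mapped: constant;
  # gamma + full_range (fixed AC bounds): exposure-invariant mean
  dims <- c(12, 12, 12)
  E_lo <- 100; E_hi <- 2e4
  spec_g <- noise_model("gamma_iterative", alpha = 5, seed = 31)
  q_map <- quantization_spec("mapped", 64)
  mu_map <- vapply(c(E_lo, E_hi), function(E) {
    v <- simulate_voi(spec_g, E, dims, seed = 13)
    glcm_marginals(build_glcm(quantize(v, q_map)))$mu_x
  }, numeric(1))
  expect_gt(mu_map[2], mu_map[1] * 1.2)
  q_fr <- quantization_spec("full_range", 64, global_lo = 0, global_hi = 40)
  mu_fr <- vapply(c(E_lo, E_hi), function(E) {
    v <- simulate_voi(spec_g, E, dims, seed = 13)
    glcm_marginals(build_glcm(suppressWarnings(quantize(v, q_fr))))$mu_x
  }, numeric(1))
  expect_lt(abs(mu_fr[2] - mu_fr[1]) / mu_fr[1], 0.06)
  spec_n <- noise_model("gaussian_fbp", alpha = 5, seed = 32)
  q_m <- quantization_spec("mapped", 64)
  mu_m <- vapply(c(E_lo, E_hi), function(E) {
    v <- simulate_voi(spec_n, E, dims, seed = 13)
    glcm_marginals(build_glcm(quantize(v, q_m)))$mu_x
  }, numeric(1))
  expect_lt(abs(mu_m[2] - mu_m[1]) / mu_m[1], 0.06)
})

test_that("GLCM export writes a readable matrix and sidecar", {
  arr <- array(sample.int(4, 4 * 4 * 4, replace = TRUE), c(4, 4, 4))
  q <- quantize(arr + 0.0, quantization_spec("mapped", 4))
  g <- build_glcm(q)
  tf <- tempfile(fileext = ".txt")
  paths <- write_glcm(g, tf)
  M <- as.matrix(utils::read.table(paths[1]))
  dimnames(M) <- NULL
  expect_equal(M, g$P, tolerance = 1e-12)
  meta <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(meta$G, 4)
  expect_equal(meta$R, g$R)
})
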