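#' Configuration for an exposure-stability study
#'
#' Validates and assembles everything `run_study()` needs. Defaults mirror
#' the phantom study design: activity concentration 9.54 kBq/ml, 25
#' geometric frame durations from 3 s to 10861 s with 20 replicates, a 50 mm
#' cuboid VOI on a 2.03 x 2.03 x 2.0 mm grid, 256 grey levels with per-VOI
#' min-max (mapped) quantization, a 13-station smoothing window and a 5%
#' relative-slope plateau threshold.
#'
#' @param archetypes Noise archetypes to simulate.
#' @param ac Activity concentration, kBq/ml.
#' @param alpha Noise coefficient (CV at E = 1 kBq/ml*s).
#' @param smoothing_fwhm Spatial smoothing FWHM, mm.
#' @param voxel_size Voxel spacing, mm.
#' @param target_edge VOI edge, mm.
#' @param durations Frame durations, s.
#' @param replicates Replicates per duration.
#' @param decay_constant Decay constant, 1/s.
#' @param levels Grey-level counts G to analyse.
#' @param schemes Quantization schemes (see [quantization_spec()]).
#' @param global_lo,global_hi,bin_upper Quantization bounds, kBq/ml.
#' @param include_axial Add the axial GLCM direction.
#' @param window Smoothing window in distinct exposure stations.
#' @param threshold Plateau relative-slope threshold.
#' @param ci_level Confidence level for island detection.
#' @param log_base Entropy log base for Haralick features.
#' @param variance_mu Variance-feature mean convention.
#' @param hist_levels Levels for the first-order efficiency descriptor.
#' @param lilliefors_reps Monte-Carlo replicates for the Lilliefors null.
#' @param seed Master seed; all randomness derives from it.
#' @return A list of class `study_config`.
#' @export
study_config <- function(archetypes = c("gaussian_fbp", "gamma_iterative"),
                         ac = 9.54, alpha = 5, smoothing_fwhm = 0,
                         voxel_size = c(2.03, 2.03, 2.0), target_edge = 50,
                         durations = default_durations(), replicates = 20L,
                         decay_constant = 0,
                         levels = 256L, schemes = "mapped",
                         global_lo = 0, global_hi = 25, bin_upper = 25,
                         include_axial = FALSE,
                         window = 13L, threshold = 0.05, ci_level = 0.99,
                         log_base = exp(1),
                         variance_mu = "as_printed", hist_levels = 256L,
                         lilliefors_reps = 1000L, seed = 1L) {
  ok_arch <- c("gaussian_fbp", "gamma_iterative", "lognormal_iterative")
  check <- function(cond, key, msg)
    if (!cond) stop(sprintf("invalid config key '%s': %s", key, msg))
  check(length(archetypes) >= 1 && all(archetypes %in% ok_arch),
        "archetypes", paste("must be among", paste(ok_arch, collapse = ", ")))
  check(is.numeric(ac) && ac > 0, "ac", "must be positive")
  check(is.numeric(alpha) && alpha >= 0, "alpha", "must be non-negative")
  check(length(voxel_size) == 3 && all(voxel_size > 0), "voxel_size",
        "must be three positive spacings")
  check(all(durations > 0) && !is.unsorted(durations, strictly = TRUE),
        "durations", "must be strictly increasing and positive")
  check(length(durations) >= window, "durations",
        sprintf("need at least 'window' (%d) durations", window))
  check(replicates >= 1, "replicates", "must be at least 1")
  check(all(levels >= 2), "levels", "each G must be at least 2")
  check(all(schemes %in% c("mapped", "full_range", "fixed_bin_zero")),
        "schemes", "must be mapped, full_range or fixed_bin_zero")
  check(threshold > 0, "threshold", "must be positive")
  check(ci_level > 0 && ci_level < 1, "ci_level", "must be in (0, 1)")
  check(lilliefors_reps >= 19, "lilliefors_reps", "must be at least 19")
  structure(
    list(archetypes = archetypes, ac = ac, alpha = alpha,
         smoothing_fwhm = smoothing_fwhm, voxel_size = voxel_size,
         target_edge = target_edge, durations = durations,
         replicates = as.integer(replicates),
         decay_constant = decay_constant,
         levels = as.integer(levels), schemes = schemes,
         global_lo = global_lo, global_hi = global_hi,
         bin_upper = bin_upper, include_axial = include_axial,
         window = as.integer(window), threshold = threshold,
         ci_level = ci_level, log_base = log_base,
         variance_mu = variance_mu, hist_levels = as.integer(hist_levels),
         lilliefors_reps = as.integer(lilliefors_reps),
         seed = as.integer(seed)),
    class = "study_config")
}

#' Run an exposure-stability study end to end
#'
#' Simulates (or accepts) exposure series for every archetype, computes
#' first-order and Haralick features for every (exposure, replicate, G,
#' scheme) combination, smooths each feature-exposure cloud, and derives
#' plateau onsets, islands of stability and variability ranges in Bel. Fully
#' deterministic given the config seed.
#'
#' @param config A [study_config()].
#' @param series Optional named list (by archetype) of precomputed VOI lists,
#'   e.g. from [generate_exposure_series()] or real data via
#'   [extract_voi()]; when omitted the synthetic generator is used.
#' @return An object of class `texstab_study` with components
#'   `config`, `first_order` (data frame of first-order stats per VOI),
#'   `features` (long data frame of Haralick values), `report` (one row per
#'   archetype/scheme/G/feature with `plateau_onset`, `onset_time`,
#'   `stable_over_range`, `n_islands`, `variability_bel`, `log_y`),
#'   `islands` (per-combination island intervals), `curves` (list of
#'   [loess_loglog()] fits), and `lilliefors` (per archetype, the exposure at
#'   which the median Lilliefors p first exceeds 0.5).
#' @export
run_study <- function(config = study_config(), series = NULL) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  dims <- voi_dims(cfg$voxel_size, cfg$target_edge)
  n_vox <- prod(dims)
  null_D <- lilliefors_null(n_vox, cfg$lilliefors_reps, cfg$seed)
  schedule <- acquisition_schedule(cfg$durations, cfg$replicates, cfg$ac,
                                   cfg$decay_constant)
  qspecs <- list()
  for (sc in cfg$schemes) for (G in cfg$levels)
    qspecs[[paste(sc, G, sep = "_")]] <-
      quantization_spec(sc, G, cfg$global_lo, cfg$global_hi, cfg$bin_upper)

  fo_rows <- list()
  feat_rows <- list()
  for (ai in seq_along(cfg$archetypes)) {
    arch <- cfg$archetypes[ai]
    if (!is.null(series)) {
      vois <- series[[arch]]
      if (is.null(vois)) stop(sprintf("series is missing archetype '%s'",
                                      arch))
    } else {
      spec <- noise_model(arch, cfg$ac, cfg$alpha, cfg$smoothing_fwhm,
                          cfg$voxel_size, seed = cfg$seed + 7919L * ai)
      vois <- generate_exposure_series(spec, schedule, dims)
    }
    for (voi in vois) {
      ep <- voi$exposure_point
      fo <- first_order_stats(voi, cfg$hist_levels, null_D = null_D)
      fo_rows[[length(fo_rows) + 1L]] <- data.frame(
        archetype = arch, exposure = ep$exposure, duration = ep$t_acq,
        replicate = ep$replicate_id,
        mean = fo$mean, sd = fo$sd, cv = fo$cv,
        excess_kurtosis = fo$excess_kurtosis, skewness = fo$skewness,
        lilliefors_D = fo$lilliefors_D, lilliefors_p = fo$lilliefors_p,
        gauss_fit_nrmsd = fo$gauss_fit_nrmsd,
        crest_factor = fo$crest_factor, efficiency = fo$efficiency,
        mode_over_mean = fo$mode_over_mean)
      for (qn in names(qspecs)) {
        qs <- qspecs[[qn]]
        grey <- suppressWarnings(quantize(voi, qs))
        gl <- build_glcm(grey, include_axial = cfg$include_axial)
        hv <- haralick_features(gl, log_base = cfg$log_base,
                                variance_mu = cfg$variance_mu)
        feat_rows[[length(feat_rows) + 1L]] <- data.frame(
          archetype = arch, scheme = qs$scheme, G = qs$levels,
          exposure = ep$exposure, duration = ep$t_acq,
          replicate = ep$replicate_id,
          feature = names(hv), value = as.numeric(hv))
      }
    }
  }
  first_order <- do.call(rbind, fo_rows)
  features <- do.call(rbind, feat_rows)
  rownames(features) <- NULL

  report_rows <- list()
  island_rows <- list()
  curves <- list()
  combos <- unique(features[c("archetype", "scheme", "G", "feature")])
  for (r in seq_len(nrow(combos))) {
    cb <- combos[r, ]
    sel <- features$archetype == cb$archetype &
      features$scheme == cb$scheme & features$G == cb$G &
      features$feature == cb$feature
    ff <- features[sel, ]
    finite <- is.finite(ff$value)
    curve <- loess_loglog(ff$exposure[finite], ff$value[finite],
                          window = cfg$window, ci_level = cfg$ci_level)
    onset <- plateau_onset(curve, cfg$threshold)
    isl <- islands_of_stability(curve)
    bel <- variability_bel(ff$value[finite])
    key <- paste(cb$archetype, cb$scheme, cb$G, cb$feature, sep = ".")
    curves[[key]] <- curve
    report_rows[[r]] <- data.frame(
      archetype = cb$archetype, scheme = cb$scheme, G = cb$G,
      feature = cb$feature, plateau_onset = onset,
      onset_time = onset / cfg$ac,
      stable_over_range = !is.na(onset) && onset <= min(curve$E),
      n_islands = nrow(isl),
      variability_bel = as.numeric(bel),
      n_excluded_bel = attr(bel, "n_excluded"),
      log_y = attr(curve, "log_y"))
    if (nrow(isl) > 0)
      island_rows[[length(island_rows) + 1L]] <-
        cbind(archetype = cb$archetype, scheme = cb$scheme, G = cb$G,
              feature = cb$feature, isl)
  }
  report <- do.call(rbind, report_rows)
  rownames(report) <- NULL
  islands <- if (length(island_rows)) do.call(rbind, island_rows)
    else data.frame()

  lill <- lapply(split(first_order, first_order$archetype), function(d) {
    med <- stats::aggregate(lilliefors_p ~ exposure, data = d, FUN =
                              stats::median)
    med <- med[order(med$exposure), ]
    cross <- med$exposure[med$lilliefors_p > 0.5][1]
    list(median_p = med, p_cross_exposure = cross)
  })

  structure(
    list(config = cfg, first_order = first_order, features = features,
         report = report, islands = islands, curves = curves,
         lilliefors = lill, dims = dims),
    class = "texstab_study")
}

#' @export
print.texstab_study <- function(x, ...) {
  cfg <- x$config
  cat("Exposure-stability study\n")
  cat("  archetypes:", paste(cfg$archetypes, collapse = ", "), "\n")
  cat("  VOI:", paste(x$dims, collapse = " x "), "voxels at",
      paste(signif(cfg$voxel_size, 4), collapse = " x "), "mm\n")
  cat("  schedule:", length(cfg$durations), "durations x",
      cfg$replicates, "replicates; exposure",
      signif(min(cfg$durations) * cfg$ac, 4), "-",
      signif(max(cfg$durations) * cfg$ac, 4), "kBq/ml*s\n")
  cat("  quantization:", paste(cfg$schemes, collapse = ", "), "at G =",
      paste(cfg$levels, collapse = ", "), "\n")
  cat("  report:", nrow(x$report), "feature curves\n")
  invisible(x)
}

#' @export
summary.texstab_study <- function(object, ...) {
  rep <- object$report
  out <- lapply(split(rep, list(rep$archetype, rep$scheme, rep$G),
                      drop = TRUE), function(d) {
    data.frame(
      archetype = d$archetype[1], scheme = d$scheme[1], G = d$G[1],
      n_features = nrow(d),
      n_stable_over_range = sum(d$stable_over_range),
      median_onset = stats::median(d$plateau_onset, na.rm = TRUE),
      median_onset_time = stats::median(d$onset_time, na.rm = TRUE),
      max_bel = max(d$variability_bel, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  for (a in names(object$lilliefors))
    out$lilliefors_cross[out$archetype == a] <-
      object$lilliefors[[a]]$p_cross_exposure
  class(out) <- c("summary.texstab_study", "data.frame")
  out
}

#' @export
print.summary.texstab_study <- function(x, ...) {
  cat("Stability summary (exposures in kBq/ml*s, times in s):\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' @export
plot.texstab_study <- function(x, features = c("asm", "entropy"),
                               archetype = x$config$archetypes[1],
                               scheme = x$config$schemes[1],
                               G = x$config$levels[1], ...) {
  keys <- paste(archetype, scheme, G, features, sep = ".")
  keys <- keys[keys %in% names(x$curves)]
  if (!length(keys)) stop("no matching curves in the study")
  old <- graphics::par(mfrow = c(1, length(keys)))
  on.exit(graphics::par(old))
  for (k in keys) plot(x$curves[[k]], main = k)
  invisible(x)
}
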