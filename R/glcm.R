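#' Grey-level quantization specification
#'
#' Three schemes map continuous activity concentrations to integer grey
#' levels `1..G`:
#' * `mapped`: the VOI minimum maps to level 1 and the VOI maximum to level
#'   G (per-VOI min-max resampling, the Tixier-style mapping);
#' * `full_range`: the same linear rule over fixed global bounds
#'   `[global_lo, global_hi]`, out-of-range values clamped to the end levels;
#' * `fixed_bin_zero`: fixed bin width from zero, `g = 1 + floor(c*G /
#'   bin_upper)`, clamped to `[1, G]` (negatives to level 1).
#'
#' @param scheme One of `"mapped"`, `"full_range"`, `"fixed_bin_zero"`.
#' @param levels Number of grey levels G (>= 2); the study used 8, 16, 32,
#'   64, 128 and 256.
#' @param global_lo,global_hi Global bounds in kBq/ml (`full_range` only).
#' @param bin_upper Upper intensity bound in kBq/ml (`fixed_bin_zero` only).
#' @return A list of class `quantization_spec`.
#' @export
quantization_spec <- function(scheme = c("mapped", "full_range",
                                         "fixed_bin_zero"),
                              levels = 256L, global_lo = 0, global_hi = 25,
                              bin_upper = 25) {
  scheme <- match.arg(scheme)
  levels <- as.integer(levels)
  if (levels < 2) stop("'levels' must be at least 2")
  if (scheme == "full_range" && global_lo >= global_hi)
    stop("'global_lo' must be below 'global_hi'")
  if (scheme == "fixed_bin_zero" && bin_upper <= 0)
    stop("'bin_upper' must be positive")
  structure(
    list(scheme = scheme, levels = levels, global_lo = global_lo,
         global_hi = global_hi, bin_upper = bin_upper),
    class = "quantization_spec")
}

#' Quantize VOI values to grey levels
#'
#' @param c A [cuboid_voi()] or numeric array.
#' @param spec A [quantization_spec()].
#' @return Integer array of grey levels in `1..G`, same shape as the input.
#'   Attribute `n_clamped` counts values clamped to the end levels
#'   (`full_range`, `fixed_bin_zero`); attribute `degenerate` flags a
#'   constant input under `mapped` (all voxels assigned level 1).
#' @export
quantize <- function(c, spec) {
  stopifnot(inherits(spec, "quantization_spec"))
  x <- if (inherits(c, "cuboid_voi")) c$values else c
  G <- spec$levels
  n_clamped <- 0L
  degenerate <- FALSE
  if (spec$scheme == "mapped") {
    rng <- range(x)
    if (rng[1] == rng[2]) {
      g <- array(1L, dim = dim(x) %||% length(x))
      degenerate <- TRUE
    } else {
      g <- 1L + floor(G * (x - rng[1]) / (rng[2] - rng[1]))
      g[g > G] <- G  # the maximum clamps to the last level
    }
  } else if (spec$scheme == "full_range") {
    lo <- spec$global_lo
    hi <- spec$global_hi
    g <- 1L + floor(G * (x - lo) / (hi - lo))
    n_clamped <- sum(g < 1L | g > G)
    if (n_clamped > 0)
      warning(sprintf("%d value(s) outside [%g, %g] clamped to end levels",
                      n_clamped, lo, hi))
    g[g < 1L] <- 1L
    g[g > G] <- G
  } else {
    g <- 1L + floor(x * G / spec$bin_upper)
    n_clamped <- sum(g < 1L | g > G)
    g[g < 1L] <- 1L
    g[g > G] <- G
  }
  g <- array(as.integer(g), dim = dim(x) %||% length(x))
  attr(g, "n_clamped") <- as.integer(n_clamped)
  attr(g, "degenerate") <- degenerate
  attr(g, "levels") <- G
  attr(g, "quantization") <- spec
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# direction offsets: unit displacements (d = 1)
glcm_directions <- function(include_axial = FALSE) {
  dirs <- list(c(1L, 0L, 0L), c(0L, 1L, 0L))
  if (include_axial) dirs <- c(dirs, list(c(0L, 0L, 1L)))
  dirs
}

#' Build a normalized grey-level co-occurrence matrix
#'
#' Counts orthogonally adjacent voxel pairs at displacement d = 1 along the
#' given direction offsets. With `symmetric = TRUE` (default) every pair is
#' counted in both orders, so P is symmetric; R is the total number of
#' ordered pairs and `P = counts / R`, hence `sum(P) == 1`.
#'
#' The default directions are the two in-plane orthogonal offsets (0 and 90
#' degrees) applied across all slices; `include_axial = TRUE` adds the axial
#' offset for a fully 3-D neighbourhood.
#'
#' @param grey Integer grey-level array from [quantize()], or any integer
#'   array with levels in `1..G`.
#' @param G Number of grey levels; defaults to the `levels` attribute.
#' @param directions List of integer length-3 offsets, or the result of
#'   `glcm_directions()`.
#' @param symmetric Count each pair in both orders.
#' @param include_axial Convenience switch adding the axial offset when
#'   `directions` is not given.
#' @return A list of class `glcm` with elements `P` (G x G matrix), `R`
#'   (ordered pair count), `d`, `directions`, `symmetric` and
#'   `quantization` (the spec used, if known).
#' @export
build_glcm <- function(grey, G = attr(grey, "levels"),
                       directions = glcm_directions(include_axial),
                       symmetric = TRUE, include_axial = FALSE) {
  if (is.null(G)) stop("'G' must be given when 'grey' carries no levels")
  if (length(directions) == 0) stop("'directions' must not be empty")
  g <- as.array(grey)
  if (length(dim(g)) == 2) dim(g) <- c(dim(g), 1L)
  if (min(g) < 1L || max(g) > G) stop("grey levels must lie in 1..G")
  dm <- dim(g)
  counts <- numeric(G * G)
  for (off in directions) {
    if (sum(abs(off)) != 1) stop("only unit displacements (d = 1) supported")
    ax <- which(off != 0L)
    if (dm[ax] < 2) next
    idx_a <- idx_b <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
    idx_a[[ax]] <- seq_len(dm[ax] - 1L)
    idx_b[[ax]] <- seq_len(dm[ax] - 1L) + 1L
    a <- g[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE]
    b <- g[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE]
    counts <- counts + tabulate(a + G * (b - 1L), nbins = G * G)
    if (symmetric)
      counts <- counts + tabulate(b + G * (a - 1L), nbins = G * G)
  }
  R <- sum(counts)
  if (R == 0) stop("no voxel pairs found along the given directions")
  structure(
    list(P = matrix(counts / R, G, G), R = R, d = 1L,
         directions = directions, symmetric = symmetric,
         quantization = attr(grey, "quantization")),
    class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  G <- nrow(x$P)
  cat("GLCM:", G, "grey levels,", x$R, "ordered voxel pairs, d = 1,",
      length(x$directions), "direction(s),",
      if (x$symmetric) "symmetric" else "asymmetric", "counting\n")
  invisible(x)
}

#' Marginal descriptors of a GLCM
#'
#' The x/y marginal means and probability-weighted marginal standard
#' deviations, the grey-scale sum vector `P_{x+y}(k)` for `k = 2..2G`, the
#' absolute-difference vector `P_{x-y}(k)` for `k = 0..G-1`, and the mode of
#' the x marginal (smallest index on ties).
#'
#' @param g A [build_glcm()] result, or a normalized G x G matrix.
#' @return A list of class `glcm_marginals` with fields `mu_x`, `mu_y`,
#'   `sigma_x`, `sigma_y`, `p_sum` (named, k = 2..2G), `p_diff` (named,
#'   k = 0..G-1), `mode_x`, `G`.
#' @export
glcm_marginals <- function(g) {
  P <- if (inherits(g, "glcm")) g$P else as.matrix(g)
  G <- nrow(P)
  i <- seq_len(G)
  Px <- rowSums(P)
  Py <- colSums(P)
  mu_x <- sum(i * Px)
  mu_y <- sum(i * Py)
  sigma_x <- sqrt(sum((i - mu_x)^2 * Px))
  sigma_y <- sqrt(sum((i - mu_y)^2 * Py))
  ii <- rep(i, times = G)
  jj <- rep(i, each = G)
  p <- as.vector(P)
  p_sum <- as.vector(rowsum(p, ii + jj))
  names(p_sum) <- sort(unique(ii + jj))
  full_sum <- stats::setNames(numeric(2 * G - 1), 2:(2 * G))
  full_sum[names(p_sum)] <- p_sum
  p_diff <- as.vector(rowsum(p, abs(ii - jj)))
  names(p_diff) <- sort(unique(abs(ii - jj)))
  full_diff <- stats::setNames(numeric(G), 0:(G - 1))
  full_diff[names(p_diff)] <- p_diff
  structure(
    list(mu_x = mu_x, mu_y = mu_y, sigma_x = sigma_x, sigma_y = sigma_y,
         p_sum = full_sum, p_diff = full_diff,
         mode_x = which.max(Px), G = G),
    class = "glcm_marginals")
}

#' Export a GLCM as a plain-text matrix with a JSON sidecar
#'
#' Writes the dense P matrix as whitespace-delimited text and a `.json`
#' sidecar carrying G, R, displacement, directions and the quantization
#' spec.
#'
#' @param g A [build_glcm()] result.
#' @param path Output path for the matrix; the sidecar gets `.json` added.
#' @return Invisibly, the two paths written.
#' @export
write_glcm <- function(g, path) {
  stopifnot(inherits(g, "glcm"))
  utils::write.table(g$P, path, row.names = FALSE, col.names = FALSE)
  meta <- list(G = nrow(g$P), R = g$R, d = g$d,
               directions = g$directions, symmetric = g$symmetric,
               quantization = if (!is.null(g$quantization))
                 unclass(g$quantization) else NULL)
  side <- paste0(path, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(path, side))
}
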