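#' Haralick texture features from a GLCM
#'
#' Evaluates the eleven second-order texture features: angular second moment
#' (ASM), contrast, inverse difference moment (IDM), entropy, correlation,
#' variance, sum average, sum entropy, difference entropy, cluster shade and
#' cluster prominence. The convention `0 * log(0) = 0` is applied
#' throughout, and entropies use the natural logarithm by default.
#'
#' The variance feature is defined here with an internal mean
#' `mu = (1/G^2) * sum(P)` which, for any normalized GLCM, reduces to the
#' constant `1/G^2`; this as-written form is the default. Setting
#' `variance_mu = "marginal_mean"` substitutes the conventional grey-level
#' mean `mu_x` instead.
#'
#' @param g A [build_glcm()] result, or a normalized G x G matrix.
#' @param m Marginals from [glcm_marginals()]; computed if missing.
#' @param log_base Base of the logarithm in the entropy features.
#' @param variance_mu `"as_printed"` (mu = 1/G^2) or `"marginal_mean"`
#'   (mu = mu_x).
#' @return Named numeric vector of the 11 features, class `haralick`.
#'   Correlation is `NA` for a degenerate GLCM with zero marginal SD.
#' @examples
#' P <- diag(8) / 8
#' haralick_features(P)  # asm 1/8, contrast 0, idm 1, entropy log(8), corr 1
#' @export
haralick_features <- function(g, m = glcm_marginals(g), log_base = exp(1),
                              variance_mu = c("as_printed",
                                              "marginal_mean")) {
  variance_mu <- match.arg(variance_mu)
  P <- if (inherits(g, "glcm")) g$P else as.matrix(g)
  G <- nrow(P)
  if (ncol(P) != G) stop("GLCM must be square")
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM is not normalized: sum(P) != 1")
  if (any(P < 0)) stop("GLCM has negative entries")
  i <- matrix(rep(seq_len(G), times = G), G, G)
  j <- matrix(rep(seq_len(G), each = G), G, G)
  lb <- log(log_base)
  xlogx <- function(p) {
    out <- numeric(length(p))
    pos <- p > 0
    out[pos] <- p[pos] * log(p[pos]) / lb
    out
  }
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  entropy <- -sum(xlogx(P))
  correlation <- if (m$sigma_x > 0 && m$sigma_y > 0)
    (sum(i * j * P) - m$mu_x * m$mu_y) / (m$sigma_x * m$sigma_y)
  else NA_real_
  mu_var <- if (variance_mu == "as_printed") sum(P) / G^2 else m$mu_x
  variance <- sum((i - mu_var)^2 * P)
  k_sum <- as.numeric(names(m$p_sum))
  sum_average <- sum(k_sum * m$p_sum)
  sum_entropy <- -sum(xlogx(m$p_sum))
  difference_entropy <- -sum(xlogx(m$p_diff))
  cs <- i + j - m$mu_x - m$mu_y
  cluster_shade <- sum(cs^3 * P)
  cluster_prominence <- sum(cs^4 * P)
  structure(
    c(asm = asm, contrast = contrast, idm = idm, entropy = entropy,
      correlation = correlation, variance = variance,
      sum_average = sum_average, sum_entropy = sum_entropy,
      difference_entropy = difference_entropy,
      cluster_shade = cluster_shade,
      cluster_prominence = cluster_prominence),
    class = c("haralick", "numeric"))
}

#' @export
print.haralick <- function(x, ...) {
  cat("Haralick features:\n")
  print(signif(unclass(x), 5))
  invisible(x)
}

#' Names of the eleven Haralick features, in canonical order
#' @return Character vector of length 11.
#' @export
haralick_feature_names <- function() {
  c("asm", "contrast", "idm", "entropy", "correlation", "variance",
    "sum_average", "sum_entropy", "difference_entropy", "cluster_shade",
    "cluster_prominence")
}
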