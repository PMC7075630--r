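#' Fixed-window local regression of a feature-exposure curve on log axes
#'
#' Smooths feature values F against exposure E with a degree-1 locally
#' weighted regression (tricube weights) evaluated at every distinct
#' exposure. The window contains the `window` nearest distinct exposure
#' stations in log10 E; every replicate measurement at those stations enters
#' the weighted fit. Smoothing is performed on log10 F when all values are
#' positive, otherwise on raw F (semi-log); the choice is recorded on the
#' returned object.
#'
#' Each local fit yields the smoothed value, the analytic derivative of the
#' local line (the log-log slope when both axes are logarithmic) and
#' t-based standard errors for both, from which confidence half-widths at
#' `ci_level` are formed.
#'
#' @param E Exposures, kBq/ml*s (> 0), one per measurement point.
#' @param F Feature values, same length.
#' @param window Number of distinct exposure stations per local fit
#'   (default 13).
#' @param ci_level Confidence level for the half-widths.
#' @param log_y Force log10 transformation of F (`TRUE`/`FALSE`); default
#'   `NULL` chooses log10 when all F > 0.
#' @return An object of class `feature_curve`: a data frame with one row per
#'   distinct exposure, columns `E`, `smooth` (on the F scale), `deriv`
#'   (slope on the fitted scale per log10 E), `rel_slope` (d ln F / d ln E),
#'   `se_smooth`, `se_deriv`, `ci_smooth`, `ci_deriv`, `df`, `n_window`;
#'   attributes `points` (the raw data), `window`, `ci_level`, `log_y`.
#' @export
loess_loglog <- function(E, F, window = 13L, ci_level = 0.95,
                         log_y = NULL) {
  if (length(E) != length(F)) stop("'E' and 'F' must have equal length")
  if (any(E <= 0)) stop("'E' must be positive")
  if (any(!is.finite(F))) stop("'F' must be finite")
  ord <- order(E)
  E <- E[ord]
  F <- F[ord]
  x <- log10(E)
  xs <- sort(unique(x))
  if (length(xs) < window)
    stop(sprintf("need at least %d distinct exposures, got %d",
                 window, length(xs)))
  if (is.null(log_y)) log_y <- all(F > 0)
  y <- if (log_y) log10(F) else F
  ns <- length(xs)
  res <- data.frame(E = 10^xs, smooth = NA_real_, deriv = NA_real_,
                    rel_slope = NA_real_, se_smooth = NA_real_,
                    se_deriv = NA_real_, ci_smooth = NA_real_,
                    ci_deriv = NA_real_, df = NA_real_,
                    n_window = NA_integer_)
  for (s in seq_len(ns)) {
    x0 <- xs[s]
    dstation <- abs(xs - x0)
    sel_stations <- xs[order(dstation)[seq_len(window)]]
    in_win <- x %in% sel_stations
    xi <- x[in_win]
    yi <- y[in_win]
    h <- max(abs(xi - x0))
    h <- if (h > 0) h * (1 + 1e-10) else 1
    w <- (1 - (abs(xi - x0) / h)^3)^3
    w[w < 0] <- 0
    fit <- wls_local(xi - x0, yi, w)
    res$smooth[s] <- if (log_y) 10^fit$b0 else fit$b0
    res$deriv[s] <- fit$b1
    res$se_smooth[s] <- fit$se0
    res$se_deriv[s] <- fit$se1
    res$df[s] <- fit$df
    res$n_window[s] <- length(xi)
    tq <- stats::qt(1 - (1 - ci_level) / 2, df = max(fit$df, 1))
    res$ci_smooth[s] <- tq * fit$se0
    res$ci_deriv[s] <- tq * fit$se1
    res$rel_slope[s] <- if (log_y) fit$b1
      else if (abs(res$smooth[s]) > 0) fit$b1 / (log(10) * abs(res$smooth[s]))
      else Inf
  }
  structure(res,
            points = data.frame(E = E, F = F),
            window = window, ci_level = ci_level, log_y = log_y,
            class = c("feature_curve", "data.frame"))
}

# weighted degree-1 least squares centred at x = 0, with sandwich SEs
wls_local <- function(x, y, w) {
  X <- cbind(1, x)
  W <- w
  XtWX <- crossprod(X, X * W)
  XtWy <- crossprod(X, y * W)
  beta <- tryCatch(solve(XtWX, XtWy), error = function(e) NULL)
  if (is.null(beta)) stop("singular local fit: no spread in exposures")
  r <- y - X %*% beta
  nw <- sum(w > 0)
  df <- max(nw - 2, 1)
  sigma2 <- sum(W * r^2) / df
  XtW2X <- crossprod(X, X * W^2)
  A <- solve(XtWX)
  V <- sigma2 * (A %*% XtW2X %*% A)
  list(b0 = beta[1], b1 = beta[2],
       se0 = sqrt(max(V[1, 1], 0)), se1 = sqrt(max(V[2, 2], 0)), df = df)
}

#' @export
print.feature_curve <- function(x, ...) {
  cat("Feature curve:", nrow(x), "exposure stations,",
      nrow(attr(x, "points")), "points, window", attr(x, "window"),
      if (attr(x, "log_y")) "(log-log)\n" else "(semi-log)\n")
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' @export
plot.feature_curve <- function(x, main = "Feature vs exposure", ...) {
  pts <- attr(x, "points")
  logy <- attr(x, "log_y")
  graphics::plot(pts$E, pts$F, log = if (logy) "xy" else "x",
                 xlab = "Exposure (kBq/ml*s)", ylab = "Feature value",
                 col = "grey60", pch = 16, cex = 0.5, main = main, ...)
  graphics::lines(x$E, x$smooth, col = "red3", lwd = 2)
  invisible(x)
}

#' Plateau onset: first exposure with a persistently flat relative slope
#'
#' A plateau starts at the smallest measured exposure where the absolute
#' relative slope `|d ln F / d ln E|` of the smoothed curve is at most
#' `threshold`, and remains so at every larger measured exposure. Returns
#' `NA` when no such exposure exists.
#'
#' @param curve A [loess_loglog()] result.
#' @param threshold Relative-slope threshold (default 0.05, i.e. 5% per
#'   relative change in E).
#' @return Onset exposure in kBq/ml*s, or `NA_real_`.
#' @export
plateau_onset <- function(curve, threshold = 0.05) {
  stopifnot(inherits(curve, "feature_curve"))
  ok <- abs(curve$rel_slope) <= threshold
  ok[is.na(ok)] <- FALSE
  # persistence: criterion must hold from the onset to the end of the range
  holds_to_end <- rev(cumprod(rev(ok))) > 0
  if (!any(holds_to_end)) return(NA_real_)
  curve$E[which(holds_to_end)[1]]
}

#' Islands of stability: intervals where the derivative CI contains zero
#'
#' For curves without a global plateau (typically full-range quantization),
#' stability shows up as maximal contiguous runs of exposure stations at
#' which the confidence interval of the local derivative contains zero.
#'
#' @param curve A [loess_loglog()] result (fit with the desired
#'   `ci_level`, conventionally 0.99).
#' @return Data frame with columns `E_start`, `E_end`, `E_mid` (geometric
#'   midpoint), `n_stations`; zero rows when no island exists.
#' @export
islands_of_stability <- function(curve) {
  stopifnot(inherits(curve, "feature_curve"))
  stable <- abs(curve$deriv) <= curve$ci_deriv + 1e-12
  stable[is.na(stable)] <- FALSE
  r <- rle(stable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    E_start = curve$E[starts[keep]],
    E_end = curve$E[ends[keep]],
    E_mid = sqrt(curve$E[starts[keep]] * curve$E[ends[keep]]),
    n_stations = r$lengths[keep])
}

#' Variability range of a feature in Bel
#'
#' The base-10 logarithmic range between the largest and smallest absolute
#' feature values: `log10(max|F|) - log10(min|F|)`, computed over values
#' with `|F| > eps`. A range of 2 Bel means a 100-fold spread.
#'
#' @param F Feature values.
#' @param eps Magnitude floor; values at or below it are excluded and
#'   counted in the `n_excluded` attribute.
#' @return Range in Bel (attribute `n_excluded`), or `NA` (flagged) when no
#'   value exceeds `eps`.
#' @export
variability_bel <- function(F, eps = 1e-12) {
  v <- abs(F)
  keep <- v > eps & is.finite(v)
  n_ex <- sum(!keep)
  if (!any(keep)) {
    out <- NA_real_
    attr(out, "n_excluded") <- n_ex
    attr(out, "all_below_eps") <- TRUE
    return(out)
  }
  out <- log10(max(v[keep])) - log10(min(v[keep]))
  attr(out, "n_excluded") <- n_ex
  out
}
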