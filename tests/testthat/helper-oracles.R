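# Independent reference implementations used as oracles. These are written
# naively (explicit double loops, brute-force searches) and must stay
# independent of the package code paths they check.

# All 11 Haralick features by explicit double loops over the matrix.
naive_haralick <- function(P) {
  G <- nrow(P)
  Px <- rowSums(P); Py <- colSums(P)
  mu_x <- sum((1:G) * Px); mu_y <- sum((1:G) * Py)
  sigma_x <- sqrt(sum(((1:G) - mu_x)^2 * Px))
  sigma_y <- sqrt(sum(((1:G) - mu_y)^2 * Py))
  asm <- 0; con <- 0; idm <- 0; ent <- 0; cor_num <- 0
  varr <- 0; shade <- 0; prom <- 0
  mu_print <- 0
  for (i in 1:G) for (j in 1:G) mu_print <- mu_print + P[i, j] / G^2
  for (i in 1:G) for (j in 1:G) {
    p <- P[i, j]
    asm <- asm + p^2
    con <- con + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log(p)
    cor_num <- cor_num + i * j * p
    varr <- varr + (i - mu_print)^2 * p
    shade <- shade + (i + j - mu_x - mu_y)^3 * p
    prom <- prom + (i + j - mu_x - mu_y)^4 * p
  }
  psum <- numeric(2 * G); pdiff <- numeric(G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  aver <- sum((2:(2 * G)) * psum[2:(2 * G)])
  sent <- 0; dent <- 0
  for (k in 2:(2 * G)) if (psum[k] > 0) sent <- sent - psum[k] * log(psum[k])
  for (k in 1:G) if (pdiff[k] > 0) dent <- dent - pdiff[k] * log(pdiff[k])
  c(asm = asm, contrast = con, idm = idm, entropy = ent,
    correlation = (cor_num - mu_x * mu_y) / (sigma_x * sigma_y),
    variance = varr, sum_average = aver, sum_entropy = sent,
    difference_entropy = dent, cluster_shade = shade,
    cluster_prominence = prom)
}

naive_marginals <- function(P) {
  G <- nrow(P)
  mu_x <- 0; mu_y <- 0
  for (i in 1:G) for (j in 1:G) {
    mu_x <- mu_x + i * P[i, j]
    mu_y <- mu_y + j * P[i, j]
  }
  sx <- 0; sy <- 0
  Px <- rowSums(P); Py <- colSums(P)
  for (i in 1:G) {
    sx <- sx + (i - mu_x)^2 * Px[i]
    sy <- sy + (i - mu_y)^2 * Py[i]
  }
  psum <- stats::setNames(numeric(2 * G - 1), 2:(2 * G))
  pdiff <- stats::setNames(numeric(G), 0:(G - 1))
  for (i in 1:G) for (j in 1:G) {
    psum[as.character(i + j)] <- psum[as.character(i + j)] + P[i, j]
    pdiff[as.character(abs(i - j))] <- pdiff[as.character(abs(i - j))] +
      P[i, j]
  }
  list(mu_x = mu_x, mu_y = mu_y, sigma_x = sqrt(sx), sigma_y = sqrt(sy),
       p_sum = psum, p_diff = pdiff)
}

# A random normalized symmetric GLCM.
random_glcm <- function(G) {
  M <- matrix(stats::runif(G * G), G, G)
  M <- M + t(M)
  M / sum(M)
}

# Brute-force grid-refinement fit of A*exp(-(x-m)^2/(2 s^2)) to histogram
# counts, minimizing the sum of squared deviations; returns the NRMSD.
grid_gauss_nrmsd <- function(x) {
  iqr <- stats::IQR(x)
  bw <- 2 * iqr / length(x)^(1 / 3)
  nb <- max(1L, ceiling(diff(range(x)) / bw))
  br <- seq(min(x), max(x), length.out = nb + 1L)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  ssr <- function(A, m, s) sum((counts - A * exp(-(mids - m)^2 /
                                                   (2 * s^2)))^2)
  ctr <- c(max(counts), mean(x), stats::sd(x))
  span <- c(max(counts), 2 * stats::sd(x), stats::sd(x))
  best <- ctr
  for (pass in 1:12) {
    grid_A <- seq(best[1] - span[1], best[1] + span[1], length.out = 11)
    grid_m <- seq(best[2] - span[2], best[2] + span[2], length.out = 11)
    grid_s <- seq(max(best[3] - span[3], 1e-8 * stats::sd(x)),
                  best[3] + span[3], length.out = 11)
    vals <- expand.grid(A = grid_A, m = grid_m, s = grid_s)
    sc <- mapply(ssr, vals$A, vals$m, vals$s)
    best <- unlist(vals[which.min(sc), ])
    span <- span / 4
  }
  r <- counts - best[1] * exp(-(mids - best[2])^2 / (2 * best[3]^2))
  sqrt(mean(r^2)) / diff(range(counts))
}

# Small helper: population-convention standardized moments.
pop_moments <- function(x) {
  mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
  z <- (x - mu) / sg
  list(mean = mu, sd = sg, skew = mean(z^3), kurt = mean(z^4) - 3)
}
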