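# Independent oracles used to validate the implementation paths.

# Raster oracle for polygon moments: rasterize the polygon interior on a
# fine pixel grid and compute pixel-based area/centroid/covariance. Slow
# but independent of the polygon-exact Green's-theorem formulas.
raster_moments <- function(vertices, resolution = 400) {
  xr <- range(vertices[, 1]); yr <- range(vertices[, 2])
  pad <- 0.02 * max(diff(xr), diff(yr))
  xs <- seq(xr[1] - pad, xr[2] + pad, length.out = resolution)
  ys <- seq(yr[1] - pad, yr[2] + pad, length.out = resolution)
  gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  gy <- matrix(ys, length(ys), length(xs))
  inside <- matrix(FALSE, length(ys), length(xs))
  n <- nrow(vertices); j <- n
  for (i in seq_len(n)) {
    cond <- (vertices[i, 2] > gy) != (vertices[j, 2] > gy)
    xint <- (vertices[j, 1] - vertices[i, 1]) * (gy - vertices[i, 2]) /
      (vertices[j, 2] - vertices[i, 2]) + vertices[i, 1]
    flip <- cond & (gx < xint)
    inside[flip] <- !inside[flip]
    j <- i
  }
  px <- gx[inside]; py <- gy[inside]
  dA <- (xs[2] - xs[1]) * (ys[2] - ys[1])
  list(area = length(px) * dA,
       centroid = c(mean(px), mean(py)),
       cov = stats::cov(cbind(px, py)) * (length(px) - 1) / length(px))
}

# Equivalent-ellipse axes from a covariance matrix + area (same convention
# as the implementation: moment ellipse rescaled to preserve area).
ellipse_axes_from_cov <- function(cov, area) {
  lam <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  a0 <- 2 * sqrt(lam[1]); b0 <- 2 * sqrt(lam[2])
  s <- sqrt(area / (pi * a0 * b0))
  c(major = 2 * a0 * s, minor = 2 * b0 * s)
}

# Dense grid-search oracle for the Kelvin-Voigt fit: best SSE over a
# (D, tau) grid. Used as a lower bound on fit quality.
kv_grid_sse <- function(t, dL, D_range = c(0.2, 8), tau_range = c(1, 120),
                        n_grid = 120) {
  Ds <- seq(D_range[1], D_range[2], length.out = n_grid)
  taus <- seq(tau_range[1], tau_range[2], length.out = n_grid)
  best <- Inf
  for (D in Ds) {
    pred0 <- outer(t, taus, function(tt, tau) 1 - exp(-tt / tau))
    sse <- colSums((dL - D * pred0)^2)
    m <- min(sse)
    if (m < best) best <- m
  }
  best
}

# Brute-force Fisher oracle: two-sided exact p by enumerating all tables
# with the observed margins and summing the hypergeometric probabilities
# of tables no more likely than the observed one.
fisher_enum_p <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_
  n <- r1 + r2
  as <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(as, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random simple polygon: points on a noisy star (angles sorted, radii
# jittered) are always simple.
random_star_polygon <- function(n = 12, r_mean = 5, r_jitter = 0.5) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- r_mean * (1 + stats::runif(n, -r_jitter, r_jitter))
  cbind(r * cos(th), r * sin(th))
}

# Simple threshold AUC of a score against a binary truth.
score_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
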