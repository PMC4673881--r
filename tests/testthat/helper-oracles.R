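# Shared fixtures and independent oracles used across test files.

# exact parabola contour y = h - (h/r^2) x^2 sampled at n stations
parabola_points <- function(h, r, n = 51) {
  x <- seq(-r, r, length.out = n)
  cbind(x = x, y = h - (h / r^2) * x^2)
}

# numeric-integration oracles for the paraboloid solid of revolution
oracle_volume <- function(h, r)
  stats::integrate(function(y) pi * r^2 * (1 - y / h), 0, h,
                   rel.tol = 1e-10)$value

oracle_surface <- function(h, r) {
  fp <- function(x) -2 * (h / r^2) * x
  stats::integrate(function(x) 2 * pi * x * sqrt(1 + fp(x)^2), 0, r,
                   rel.tol = 1e-10)$value
}

oracle_arc <- function(h, r) {
  fp <- function(x) -2 * (h / r^2) * x
  stats::integrate(function(x) sqrt(1 + fp(x)^2), -r, r,
                   rel.tol = 1e-10)$value
}

# dense mixed-model-equation solve for y ~ replicate (fixed) + genotype
# (random), given the variance-component ratio lambda = s2e / s2g
mme_blup_oracle <- function(tab, lambda) {
  g <- factor(tab$genotype)
  rp <- factor(tab$replicate)
  X <- stats::model.matrix(~rp, contrasts.arg = list(rp = stats::contr.sum))
  Z <- stats::model.matrix(~ 0 + g)
  y <- tab$volume
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * diag(ncol(Z))))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  list(beta = sol[seq_len(ncol(X))],
       u = stats::setNames(sol[-seq_len(ncol(X))], levels(g)))
}

# brute-force window scanner for phase-2 read trimming
brute_trim_phase2 <- function(q, thr = 15, window = 10) {
  n <- length(q)
  if (n < window) return(n)
  for (s in seq_len(n - window + 1)) {
    if (mean(q[s:(s + window - 1)]) < thr) return(s - 1)
  }
  n
}

# brute-force re-filter of a pileup for the homozygous-call rule
brute_call <- function(obs, ref, min_q = 20, min_reads = 5, edge = 3,
                       purity = 0.9) {
  ok <- obs$off_start >= edge & obs$off_end >= edge & obs$qual >= min_q
  obs <- obs[ok & !duplicated(obs$read), , drop = FALSE]
  if (nrow(obs) == 0) return(NA_integer_)
  n_ref <- sum(obs$base == ref)
  alt <- obs$base[obs$base != ref]
  n_alt <- if (length(alt)) max(table(alt)) else 0
  if (n_alt >= min_reads && n_alt / (n_alt + n_ref) >= purity) return(2L)
  if (n_ref >= min_reads && n_ref / (n_alt + n_ref) >= purity) return(0L)
  NA_integer_
}

# dense GLS oracle: direct V^-1-weighted solve, no eigen-rotation
dense_gls_oracle <- function(y, X, V) {
  Vi <- solve(V)
  A <- solve(t(X) %*% Vi %*% X)
  b <- A %*% t(X) %*% Vi %*% y
  n <- length(y); q <- ncol(X)
  rss <- as.numeric(t(y - X %*% b) %*% Vi %*% (y - X %*% b))
  s2 <- rss / (n - q)
  list(beta = as.vector(b), cov_unscaled = A, s2 = s2)
}

# continuous pixel coordinates of generator-truth centroids, via the
# generator's own pixel axes
truth_centroids_px <- function(im) {
  colf <- stats::approxfun(im$px_x, seq_along(im$px_x))
  rowf <- stats::approxfun(rev(im$px_y), rev(seq_along(im$px_y)))
  cbind(row = rowf(im$centroids_um[, 2]), col = colf(im$centroids_um[, 1]))
}

empty_causal <- data.frame(snp = integer(0), effect = numeric(0))
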