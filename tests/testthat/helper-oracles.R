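# Independent oracles used to validate analytic code paths.

# Riemann-sum quadrature of integral f_A f_B over a box covering both
# mixtures; independent of the closed-form pair formula.
quad_inner <- function(A, B, n = 64, pad_sigmas = 6) {
  sig <- function(g) {
    vapply(seq_along(g$weights), function(k) {
      sqrt(max(eigen(g$covariances[, , k], symmetric = TRUE,
                     only.values = TRUE)$values))
    }, numeric(1))
  }
  lo <- pmin(apply(A$means - pad_sigmas * sig(A), 2, min),
             apply(B$means - pad_sigmas * sig(B), 2, min))
  hi <- pmax(apply(A$means + pad_sigmas * sig(A), 2, max),
             apply(B$means + pad_sigmas * sig(B), 2, max))
  ax <- lapply(1:3, function(a) seq(lo[a], hi[a], length.out = n))
  h <- vapply(ax, function(v) v[2] - v[1], numeric(1))
  pts <- as.matrix(expand.grid(ax))
  sum(gmm_density(A, pts) * gmm_density(B, pts)) * prod(h)
}

# random valid mixture for property tests (uses current RNG state)
random_gmm <- function(K = 3, spread = 8, name = "rnd") {
  w <- stats::runif(K, 0.5, 2)
  mu <- matrix(stats::runif(3 * K, -spread, spread), K, 3)
  covs <- array(0, c(3, 3, K))
  for (k in seq_len(K)) {
    R <- shapesearch:::quat_to_mat(shapesearch:::random_quaternion())
    covs[, , k] <- R %*% diag(stats::runif(3, 3, 16)) %*% t(R)
  }
  gaussian_mixture(w, mu, covs, name = name)
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# density-weighted center of mass and covariance of a map (moment oracle)
map_moments <- function(map) {
  d <- dim(map$grid)
  ijk <- arrayInd(seq_along(map$grid), d)
  X <- sweep(ijk - 0.5, 2, map$spacing[1:3], `*`)
  w <- as.numeric(map$grid)
  w <- w / sum(w)
  mu <- colSums(w * X)
  Xc <- sweep(X, 2, mu)
  list(mean = mu, cov = crossprod(Xc * sqrt(w)))
}

# radius of the half-maximum isocontour of a roughly spherical map
halfmax_radius <- function(map) {
  d <- dim(map$grid)
  thr <- max(map$grid) / 2
  ijk <- arrayInd(which(map$grid >= thr), d)
  X <- sweep(ijk - 0.5, 2, map$spacing[1:3], `*`)
  ctr <- d * map$spacing / 2
  max(sqrt(rowSums(sweep(X, 2, ctr)^2)))
}
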