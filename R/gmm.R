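# Gaussian mixture representation of density maps.
#
# A map is summarized by K weighted 3D Gaussians fitted by
# expectation-maximization on density-weighted voxel centers. Two mixtures
# are compared by the normalized overlap of their density functions,
#
#   CC = <f_A, f_B> / sqrt(<f_A, f_A> <f_B, f_B>),
#
# where the inner product <f_A, f_B> = integral f_A(r) f_B(r) dr has the
# closed form sum_{k,l} w_k w_l N(mu_k - mu_l; 0, S_k + S_l). Superposition
# maximizes CC over proper rigid transforms of the second mixture.

COV_EIG_FLOOR <- 0.25  # A^2; prevents component collapse on sharp features

#' Construct a Gaussian mixture model
#'
#' @param weights Positive component weights; normalized to sum to 1.
#' @param means K x 3 matrix of component centers (angstrom).
#' @param covariances 3 x 3 x K array of symmetric positive-definite
#'   covariance matrices (square angstrom).
#' @param name Source model identifier.
#' @return A `GaussianMixture` object.
#' @export
gaussian_mixture <- function(weights, means, covariances, name = "gmm") {
  weights <- as.numeric(weights)
  means <- matrix(as.numeric(means), ncol = 3)
  K <- length(weights)
  stopifnot(nrow(means) == K)
  if (is.matrix(covariances)) covariances <- array(covariances, c(3, 3, 1))
  stopifnot(length(dim(covariances)) == 3, dim(covariances)[3] == K)
  if (any(weights <= 0)) {
    stop_shapesearch("component weights must be positive",
                     "shapesearch_domain_error")
  }
  for (k in seq_len(K)) {
    ev <- eigen(covariances[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop_shapesearch("covariance must be positive definite",
                       "shapesearch_degeneracy_error")
    }
  }
  structure(
    list(weights = weights / sum(weights), means = means,
         covariances = covariances, name = as.character(name)),
    class = "GaussianMixture"
  )
}

#' @export
print.GaussianMixture <- function(x, ...) {
  cat(sprintf("GaussianMixture '%s': %d components\n", x$name,
              length(x$weights)))
  invisible(x)
}

n_components <- function(gmm) length(gmm$weights)

# 6-column unpacking of a 3x3xK covariance array (upper triangle)
cov_to_six <- function(covs) {
  cbind(covs[1, 1, ], covs[2, 2, ], covs[3, 3, ],
        covs[1, 2, ], covs[1, 3, ], covs[2, 3, ])
}

six_to_cov <- function(m) {
  K <- nrow(m)
  covs <- array(0, c(3, 3, K))
  covs[1, 1, ] <- m[, 1]; covs[2, 2, ] <- m[, 2]; covs[3, 3, ] <- m[, 3]
  covs[1, 2, ] <- covs[2, 1, ] <- m[, 4]
  covs[1, 3, ] <- covs[3, 1, ] <- m[, 5]
  covs[2, 3, ] <- covs[3, 2, ] <- m[, 6]
  covs
}

#' Evaluate a mixture density at points
#' @param gmm A `GaussianMixture`.
#' @param pts N x 3 matrix of positions (angstrom).
#' @return Vector of densities.
#' @export
gmm_density <- function(gmm, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  out <- numeric(nrow(pts))
  for (k in seq_len(n_components(gmm))) {
    S <- gmm$covariances[, , k]
    dt <- det(S)
    if (dt <= 1e-12) {
      stop_shapesearch("singular component covariance",
                       "shapesearch_degeneracy_error")
    }
    Sinv <- solve(S)
    d <- sweep(pts, 2, gmm$means[k, ])
    q <- rowSums((d %*% Sinv) * d)
    out <- out + gmm$weights[k] * exp(-q / 2) / sqrt((2 * pi)^3 * dt)
  }
  out
}

#' Analytic overlap integral of two mixtures
#'
#' Computes `integral f_A(r) f_B(r) dr` in closed form using the Gaussian
#' product rule: each component pair contributes
#' `w_k w_l N(mu_k - mu_l; 0, S_k + S_l)`.
#'
#' @param A,B `GaussianMixture` objects.
#' @return Positive scalar overlap.
#' @export
gmm_inner_product <- function(A, B) {
  KA <- n_components(A); KB <- n_components(B)
  ia <- rep(seq_len(KA), times = KB)
  ib <- rep(seq_len(KB), each = KA)
  sa <- cov_to_six(A$covariances)
  sb <- cov_to_six(B$covariances)
  c11 <- sa[ia, 1] + sb[ib, 1]; c22 <- sa[ia, 2] + sb[ib, 2]
  c33 <- sa[ia, 3] + sb[ib, 3]; c12 <- sa[ia, 4] + sb[ib, 4]
  c13 <- sa[ia, 5] + sb[ib, 5]; c23 <- sa[ia, 6] + sb[ib, 6]
  dt <- c11 * (c22 * c33 - c23^2) - c12 * (c12 * c33 - c13 * c23) +
    c13 * (c12 * c23 - c22 * c13)
  if (any(dt <= 1e-12)) {
    stop_shapesearch("singular summed covariance in overlap integral",
                     "shapesearch_degeneracy_error")
  }
  d1 <- A$means[ia, 1] - B$means[ib, 1]
  d2 <- A$means[ia, 2] - B$means[ib, 2]
  d3 <- A$means[ia, 3] - B$means[ib, 3]
  a11 <- c22 * c33 - c23^2
  a22 <- c11 * c33 - c13^2
  a33 <- c11 * c22 - c12^2
  a12 <- -(c12 * c33 - c13 * c23)
  a13 <- c12 * c23 - c22 * c13
  a23 <- -(c11 * c23 - c12 * c13)
  q <- (d1^2 * a11 + d2^2 * a22 + d3^2 * a33 +
          2 * (d1 * d2 * a12 + d1 * d3 * a13 + d2 * d3 * a23)) / dt
  sum(A$weights[ia] * B$weights[ib] * exp(-q / 2) / sqrt((2 * pi)^3 * dt))
}

#' Overlap correlation coefficient between two mixtures
#'
#' `CC = <f_A, f_B> / sqrt(<f_A, f_A> <f_B, f_B>)`, in (0, 1] for
#' nonnegative mixtures; 1 only for identical densities.
#'
#' @param A,B `GaussianMixture` objects.
#' @return Scalar CC.
#' @export
gmm_overlap_cc <- function(A, B) {
  gmm_inner_product(A, B) /
    sqrt(gmm_inner_product(A, A) * gmm_inner_product(B, B))
}

#' Fit a Gaussian mixture to a density map
#'
#' Expectation-maximization on voxel-center positions weighted by density,
#' with k-means++ initialization from `seed`. Maps larger than
#' `max_voxels` per axis are first downsampled to that cap (the customary
#' speedup for mixture conversion of EM maps). Iterates until the relative
#' log-likelihood change is below `tol` or `max_iter` is reached.
#' Covariance eigenvalues are floored at 0.25 square angstrom.
#'
#' @param map A `DensityMap` with positive mass.
#' @param K Number of components (20 or 40 are typical for EM maps).
#' @param seed Integer seed for the initialization.
#' @param max_voxels Per-axis voxel cap before fitting (default 64).
#' @param tol Relative log-likelihood stopping tolerance.
#' @param max_iter Maximum EM iterations.
#' @param threshold Fraction of the maximum density below which voxels are
#'   excluded from the fit (default `1e-3`, which keeps essentially the
#'   whole soft edge). For maps with an additive noise floor, set this to
#'   about twice the noise SD so diffuse background does not claim mixture
#'   mass (it would otherwise inflate volume estimates badly).
#' @return A `GaussianMixture`.
#' @export
fit_gmm <- function(map, K = 20, seed = 1, max_voxels = 64, tol = 1e-6,
                    max_iter = 500, threshold = 1e-3) {
  stopifnot(K >= 1)
  d <- dim(map$grid)
  if (any(d > max_voxels)) {
    sp <- max(d * map$spacing) / max_voxels
    map <- resample_map(map, scale = 1, out_dim = max_voxels, out_spacing = sp)
  }
  g <- map$grid
  thr <- max(g) * threshold
  occ <- which(g > thr)
  if (length(occ) < K) {
    stop_shapesearch(sprintf(
      "infeasible fit: %d components but only %d occupied voxels",
      K, length(occ)), "shapesearch_domain_error")
  }
  d <- dim(g)
  ijk <- arrayInd(occ, d)
  X <- sweep(ijk - 0.5, 2, map$spacing[1:3], `*`)  # physical voxel centers
  w <- g[occ]
  w <- w / sum(w)
  N <- nrow(X)

  means <- with_seed(seed, kmeans_init(X, w, K))
  sigma0 <- max(4 * max(map$spacing)^2, COV_EIG_FLOOR)
  covs <- array(0, c(3, 3, K))
  for (k in seq_len(K)) covs[, , k] <- diag(sigma0, 3)
  wk <- rep(1 / K, K)

  const <- -1.5 * log(2 * pi)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logd <- matrix(0, N, K)
    for (k in seq_len(K)) {
      S <- covs[, , k]
      ch <- chol(S)
      logdet <- 2 * sum(log(diag(ch)))
      Xc <- sweep(X, 2, means[k, ])
      Y <- Xc %*% backsolve(ch, diag(3))
      q <- rowSums(Y * Y)
      logd[, k] <- log(wk[k]) + const - 0.5 * logdet - 0.5 * q
    }
    m <- logd[, 1]
    for (k in seq_len(K)[-1]) m <- pmax(m, logd[, k])
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(w * lse)
    resp <- exp(logd - lse) * w
    Nk <- colSums(resp)
    Nk[Nk < 1e-12] <- 1e-12
    wk <- Nk / sum(Nk)
    for (k in seq_len(K)) {
      mu <- colSums(resp[, k] * X) / Nk[k]
      Xc <- sweep(X, 2, mu)
      S <- crossprod(Xc * sqrt(resp[, k])) / Nk[k]
      # eigenvalue floor
      e <- eigen((S + t(S)) / 2, symmetric = TRUE)
      ev <- pmax(e$values, COV_EIG_FLOOR)
      covs[, , k] <- e$vectors %*% (ev * t(e$vectors))
      means[k, ] <- mu
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12)) break
    ll_old <- ll
  }
  gaussian_mixture(wk, means, covs, name = map$name)
}

# k-means++ seeding on weighted points, refined by a few Lloyd iterations
# (a well-placed start cuts the EM iteration count substantially)
kmeans_init <- function(X, w, K, lloyd_iter = 10) {
  N <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(N, 1, prob = w)
  means <- X[centers[1], , drop = FALSE]
  if (K > 1) {
    d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
    for (k in 2:K) {
      p <- w * d2
      if (sum(p) <= 0) p <- rep(1, N)
      centers[k] <- sample.int(N, 1, prob = p)
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[k], ])^2))
    }
    means <- X[centers, , drop = FALSE]
    for (it in seq_len(lloyd_iter)) {
      D2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(means)
      assign <- max.col(-D2, ties.method = "first")
      for (k in seq_len(K)) {
        sel <- assign == k
        if (any(sel)) {
          means[k, ] <- colSums(w[sel] * X[sel, , drop = FALSE]) / sum(w[sel])
        }
      }
    }
  }
  means
}

#' Estimate particle volume from a mixture
#'
#' Volume of the region enclosed by the isodensity surface containing
#' `mass_fraction` of the total mixture mass, evaluated on a 1 A grid:
#' densities are sorted in decreasing order and voxels counted until the
#' cumulative mass reaches the target.
#'
#' @param gmm A `GaussianMixture`.
#' @param mass_fraction Fraction of mass enclosed (default 0.95).
#' @param grid_spacing Evaluation grid spacing in angstrom (default 1).
#' @return Volume in cubic angstrom.
#' @export
estimate_volume <- function(gmm, mass_fraction = 0.95, grid_spacing = 1) {
  stopifnot(mass_fraction > 0, mass_fraction < 1)
  K <- n_components(gmm)
  rad <- numeric(K)
  for (k in seq_len(K)) {
    ev <- eigen(gmm$covariances[, , k], symmetric = TRUE,
                only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop_shapesearch("singular component covariance",
                       "shapesearch_degeneracy_error")
    }
    rad[k] <- 4.5 * sqrt(max(ev))
  }
  lo <- apply(gmm$means - rad, 2, min)
  hi <- apply(gmm$means + rad, 2, max)
  # guard against diffuse components blowing up the evaluation grid: coarsen
  # the spacing so the box never exceeds ~8e6 voxels (volume = count x h^3
  # stays consistent at any spacing)
  nvox <- prod((hi - lo) / grid_spacing + 1)
  if (nvox > 8e6) {
    grid_spacing <- grid_spacing * (nvox / 8e6)^(1 / 3)
  }
  ax <- lapply(1:3, function(a) seq(lo[a], hi[a], by = grid_spacing))
  pts <- as.matrix(expand.grid(ax))
  dens <- gmm_density(gmm, pts)
  vox <- grid_spacing^3
  dens <- sort(dens, decreasing = TRUE)
  cum <- cumsum(dens) * vox
  target <- mass_fraction * sum(gmm$weights)
  n_in <- which(cum >= target)[1]
  if (is.na(n_in)) n_in <- length(dens)
  n_in * vox
}

## ---- rigid transforms and superposition ----------------------------------

#' Apply a rigid transform to a mixture
#' @param gmm A `GaussianMixture`.
#' @param rotation 3x3 rotation matrix or unit quaternion (w, x, y, z).
#' @param translation Length-3 translation (angstrom).
#' @return Transformed `GaussianMixture`.
#' @export
transform_gmm <- function(gmm, rotation = diag(3), translation = c(0, 0, 0)) {
  R <- if (is.matrix(rotation)) rotation else quat_to_mat(rotation)
  out <- gmm
  out$means <- gmm$means %*% t(R) +
    matrix(translation, n_components(gmm), 3, byrow = TRUE)
  for (k in seq_len(n_components(gmm))) {
    out$covariances[, , k] <- R %*% gmm$covariances[, , k] %*% t(R)
  }
  out
}

# overall centroid and covariance of the mixture density
gmm_moments <- function(gmm) {
  mu <- colSums(gmm$weights * gmm$means)
  S <- matrix(0, 3, 3)
  for (k in seq_len(n_components(gmm))) {
    dm <- gmm$means[k, ] - mu
    S <- S + gmm$weights[k] * (gmm$covariances[, , k] + tcrossprod(dm))
  }
  list(mean = mu, cov = S)
}

#' Superpose one mixture onto another by maximizing overlap CC
#'
#' Multi-start local optimization over proper rigid transforms of `B`:
#' four principal-axis sign alignments plus `n_starts - 4` seeded random
#' rotations, each refined by Nelder-Mead on (rotation vector, translation).
#' Reflections are never searched.
#'
#' @param A,B `GaussianMixture` objects; the transform is applied to `B`.
#' @param n_starts Number of optimization starts (default 24).
#' @param seed Seed for the random starts.
#' @return A `Superposition3DResult`: list with `transform` (list of unit
#'   `quaternion` and `translation`) and `cc`.
#' @export
superpose_gmms <- function(A, B, n_starts = 24, seed = 1) {
  stopifnot(n_starts >= 1)
  denom <- sqrt(gmm_inner_product(A, A) * gmm_inner_product(B, B))
  momA <- gmm_moments(A); momB <- gmm_moments(B)
  eA <- eigen(momA$cov, symmetric = TRUE)
  eB <- eigen(momB$cov, symmetric = TRUE)
  VA <- eA$vectors; if (det(VA) < 0) VA[, 3] <- -VA[, 3]
  VB <- eB$vectors; if (det(VB) < 0) VB[, 3] <- -VB[, 3]
  starts <- list()
  for (s in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
    R0 <- VA %*% diag(s) %*% t(VB)
    starts[[length(starts) + 1]] <- R0
  }
  n_rand <- max(0, n_starts - length(starts))
  if (n_rand > 0) {
    qs <- with_seed(seed, replicate(n_rand, random_quaternion()))
    for (j in seq_len(n_rand)) {
      starts[[length(starts) + 1]] <- quat_to_mat(qs[, j])
    }
  }
  starts <- starts[seq_len(min(n_starts, length(starts)))]

  objective <- function(par, R0, t0) {
    R <- rotvec_to_mat(par[1:3]) %*% R0
    Bt <- transform_gmm(B, R, t0 + par[4:6])
    -gmm_inner_product(A, Bt) / denom
  }
  best <- list(cc = -Inf, R = diag(3), t = c(0, 0, 0))
  for (R0 in starts) {
    t0 <- momA$mean - as.vector(R0 %*% momB$mean)
    opt <- stats::optim(rep(0, 6), objective, R0 = R0, t0 = t0,
                        method = "Nelder-Mead",
                        control = list(maxit = 600, reltol = 1e-9))
    cc <- -opt$value
    if (cc > best$cc) {
      best <- list(cc = cc,
                   R = rotvec_to_mat(opt$par[1:3]) %*% R0,
                   t = t0 + opt$par[4:6])
    }
  }
  # never worse than the unaligned configuration
  cc0 <- gmm_inner_product(A, B) / denom
  if (cc0 > best$cc) best <- list(cc = cc0, R = diag(3), t = c(0, 0, 0))
  structure(
    list(transform = list(quaternion = mat_to_quat(best$R),
                          translation = best$t),
         cc = best$cc),
    class = "Superposition3DResult"
  )
}

#' Pairwise superposed overlap CC matrix
#'
#' Each unordered pair is superposed once (i < j) and the matrix is
#' symmetrized; the diagonal is exactly 1. CC values are floored at 0
#' (nonnegative mixtures cannot produce meaningful negative overlap).
#'
#' @param mixtures List of `GaussianMixture` objects.
#' @param seed Seed forwarded to [superpose_gmms()].
#' @param n_starts Starts per pair.
#' @return Symmetric CC matrix with model names as dimnames.
#' @export
pairwise_cc_matrix <- function(mixtures, seed = 1, n_starts = 24) {
  n <- length(mixtures)
  stopifnot(n >= 2)
  M <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      cc <- superpose_gmms(mixtures[[i]], mixtures[[j]],
                           n_starts = n_starts, seed = seed + 1000L * i + j)$cc
      M[i, j] <- M[j, i] <- max(0, cc)
    }
  }
  nm <- vapply(mixtures, function(g) g$name, character(1))
  dimnames(M) <- list(nm, nm)
  M
}

## ---- serialization --------------------------------------------------------

#' Write a mixture to a plain-text table or JSON
#'
#' One component per row: weight, mean x/y/z, and the six unique covariance
#' entries. A `.json` extension selects JSON; anything else writes TSV.
#' Round-trips are exact to 1e-12.
#'
#' @param gmm A `GaussianMixture`.
#' @param path Output path (`.tsv` or `.json`).
#' @export
write_gmm <- function(gmm, path) {
  tab <- data.frame(
    weight = gmm$weights,
    mx = gmm$means[, 1], my = gmm$means[, 2], mz = gmm$means[, 3],
    sxx = gmm$covariances[1, 1, ], syy = gmm$covariances[2, 2, ],
    szz = gmm$covariances[3, 3, ], sxy = gmm$covariances[1, 2, ],
    sxz = gmm$covariances[1, 3, ], syz = gmm$covariances[2, 3, ]
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(name = gmm$name, components = tab), path,
                         digits = NA, auto_unbox = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# gmm name=", gmm$name), con)
    out <- vapply(seq_len(nrow(tab)), function(i) {
      paste(format(as.numeric(tab[i, ]), digits = 17, scientific = TRUE,
                   trim = TRUE), collapse = "\t")
    }, character(1))
    writeLines(paste(colnames(tab), collapse = "\t"), con)
    writeLines(out, con)
  }
  invisible(path)
}

#' Read a mixture written by [write_gmm()]
#' @param path Path to a `.tsv` or `.json` mixture file.
#' @return A `GaussianMixture`.
#' @export
read_gmm <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tab <- as.data.frame(obj$components)
    name <- obj$name
  } else {
    first <- readLines(path, n = 1)
    name <- sub("^# gmm name=", "", first)
    tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1)
  }
  covs <- six_to_cov(as.matrix(tab[, c("sxx", "syy", "szz",
                                       "sxy", "sxz", "syz")]))
  gaussian_mixture(tab$weight, as.matrix(tab[, c("mx", "my", "mz")]),
                   covs, name = name)
}
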