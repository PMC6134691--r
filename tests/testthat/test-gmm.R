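# Gaussian mixture fitting, the analytic overlap integral, and rigid
# superposition.

test_that("K = 1 fit recovers the moments of an isotropic blob", {
  # Gaussian blob via a tiny sphere smoothed with a wide soft edge:
  # indicator(r<=2) * N(0, 6^2) approximately N(0, 6^2 + small)
  blob <- make_density(shape_spec("sphere", list(radius = 2), soft_edge = 6))
  g <- fit_gmm(blob, K = 1, seed = 1)
  mom <- map_moments(blob)
  # mean equals the density-weighted center of mass
  expect_lt(max(abs(g$means[1, ] - mom$mean)), 0.1)
  expect_equal(g$means[1, ], mom$mean, tolerance = 1e-6)
  # covariance approximately sigma^2 I within 5%
  expect_lt(max(abs(g$covariances[, , 1] - mom$cov)) /
              max(abs(mom$cov)), 0.05)
  dg <- diag(g$covariances[, , 1])
  expect_lt(max(abs(dg / dg[1] - 1)), 0.05)
})

test_that("two disjoint equal blobs split weight evenly under K = 2", {
  two <- make_density(shape_spec("dumbbell",
                                 list(lobe_radius = 9, separation = 44,
                                      bar_radius = 1)))
  g <- fit_gmm(two, K = 2, seed = 7)
  expect_lt(max(abs(sort(g$weights) - 0.5)), 0.02)
  zs <- sort(g$means[, 3])
  expect_lt(abs(zs[1] - (50 - 22)), 1.0)
  expect_lt(abs(zs[2] - (50 + 22)), 1.0)
  expect_error(fit_gmm(two, K = 1e6, seed = 1), "infeasible")
})

test_that("fits are deterministic for a fixed seed", {
  m <- fix_map("ellipsoid")
  g1 <- fit_gmm(m, K = 4, seed = 11)
  g2 <- fit_gmm(m, K = 4, seed = 11)
  expect_identical(g1, g2)
})

test_that("analytic inner product matches closed forms and quadrature", {
  iso <- function(s, at = c(0, 0, 0)) {
    gaussian_mixture(1, matrix(at, 1), array(diag(s^2, 3), c(3, 3, 1)))
  }
  # coincident unit-weight isotropic pair, sigma = 1: (4 pi)^(-3/2)
  expect_equal(gmm_inner_product(iso(1), iso(1)), (4 * pi)^(-3 / 2),
               tolerance = 1e-12)
  # separation s multiplies the overlap by exp(-s^2 / 4)
  s <- 3.2
  expect_equal(gmm_inner_product(iso(1), iso(1, c(s, 0, 0))),
               (4 * pi)^(-3 / 2) * exp(-s^2 / 4), tolerance = 1e-12)
  # symmetry is exact
  set.seed(42)
  A <- random_gmm(3); B <- random_gmm(4)
  expect_identical(gmm_inner_product(A, B), gmm_inner_product(B, A))

  # quadrature oracle spot check (the full 20-pair sweep runs in the
  # acceptance suite): <= 1e-6 relative error
  set.seed(2024)
  for (i in 1:8) {
    A <- random_gmm(sample(2:4, 1))
    B <- random_gmm(sample(2:4, 1))
    ana <- gmm_inner_product(A, B)
    num <- quad_inner(A, B)
    expect_lt(abs(ana - num) / num, 1e-6)
  }
})

test_that("overlap CC has the closed-form isotropic behavior", {
  iso <- function(s, at = c(0, 0, 0)) {
    gaussian_mixture(1, matrix(at, 1), array(diag(s^2, 3), c(3, 3, 1)))
  }
  set.seed(5)
  A <- random_gmm(3)
  expect_equal(gmm_overlap_cc(A, A), 1, tolerance = 1e-12)
  # isotropic pair, separation 2 sigma: CC = exp(-1)
  sg <- 2.5
  expect_equal(gmm_overlap_cc(iso(sg), iso(sg, c(2 * sg, 0, 0))),
               exp(-1), tolerance = 1e-12)
  # CC decays monotonically to 0 with separation
  seps <- seq(0, 40, by = 4)
  ccs <- vapply(seps, function(s) {
    gmm_overlap_cc(iso(sg), iso(sg, c(s, 0, 0)))
  }, numeric(1))
  expect_true(all(diff(ccs) < 0))
  expect_lt(ccs[length(ccs)], 1e-10)
})

test_that("CC is invariant under a common rigid transform", {
  set.seed(9)
  A <- random_gmm(3); B <- random_gmm(3)
  cc0 <- gmm_overlap_cc(A, B)
  q <- shapesearch:::random_quaternion()
  t <- runif(3, -5, 5)
  expect_equal(gmm_overlap_cc(transform_gmm(A, q, t), transform_gmm(B, q, t)),
               cc0, tolerance = 1e-9)
})

test_that("superposition recovers applied rigid transforms", {
  set.seed(31)
  for (i in 1:3) {
    A <- random_gmm(4)
    q <- shapesearch:::random_quaternion()
    tr <- runif(3, -8, 8)
    B <- transform_gmm(A, q, tr)
    res <- superpose_gmms(A, B, n_starts = 8, seed = i)
    expect_gte(res$cc, 0.999)
    # recovered transform composed with the applied one is the identity
    Rrec <- shapesearch:::quat_to_mat(res$transform$quaternion)
    Rapp <- shapesearch:::quat_to_mat(q)
    expect_lt(shapesearch:::rotation_angle_deg(Rrec %*% Rapp), 1)
    expect_lt(sqrt(sum((Rrec %*% tr + res$transform$translation)^2)), 0.5)
  }
  # self-superposition: cc = 1
  set.seed(33)
  A <- random_gmm(3)
  expect_gte(superpose_gmms(A, A, n_starts = 4, seed = 1)$cc, 1 - 1e-9)
})

test_that("superposition never scores below the unaligned CC and rejects mirrors", {
  set.seed(12)
  A <- random_gmm(4); B <- random_gmm(4)
  cc0 <- gmm_overlap_cc(A, B)
  expect_gte(superpose_gmms(A, B, n_starts = 6, seed = 2)$cc, cc0)
  # chiral shape vs its mirror image: proper rotations cannot reach cc = 1
  chiral <- gaussian_mixture(
    c(0.4, 0.3, 0.2, 0.1),
    rbind(c(0, 0, 0), c(6, 0, 0), c(0, 4, 0), c(0, 0, 2.5)),
    array(rep(diag(2, 3), 4), c(3, 3, 4)))
  mirrored <- chiral
  mirrored$means[, 1] <- -mirrored$means[, 1]
  expect_lt(superpose_gmms(chiral, mirrored, n_starts = 12, seed = 3)$cc,
            0.999)
})

test_that("pairwise CC matrix is symmetric, unit-diagonal, shape-monotone", {
  sphere <- fit_gmm(fix_map("sphere"), K = 4, seed = 2)
  near <- fit_gmm(make_density(shape_spec(
    "ellipsoid", list(a = 18 * 1.2, b = 18, c = 18))), K = 4, seed = 2)
  rod <- fit_gmm(fix_map("cylinder"), K = 4, seed = 2)
  M <- pairwise_cc_matrix(list(sphere, near, rod), seed = 1, n_starts = 6)
  expect_identical(unname(diag(M)), rep(1, 3))
  expect_identical(M, t(M))
  expect_true(all(M >= 0 & M <= 1 + 1e-12))
  # sphere is closer to a 1.2:1:1 ellipsoid than to a rod
  expect_gt(M[1, 2], M[1, 3])
  # identical mixtures give CC ~ 1
  M2 <- pairwise_cc_matrix(list(sphere, sphere, sphere), seed = 1,
                           n_starts = 4)
  expect_true(all(M2 >= 0.999))
})

test_that("mixture serialization round-trips through TSV and JSON", {
  set.seed(77)
  g <- random_gmm(3, name = "roundtrip")
  for (ext in c(".tsv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_gmm(g, path)
    g2 <- read_gmm(path)
    expect_equal(g2$weights, g$weights, tolerance = 1e-12)
    expect_equal(g2$means, g$means, tolerance = 1e-12)
    expect_equal(g2$covariances, g$covariances, tolerance = 1e-12)
    expect_identical(g2$name, "roundtrip")
  }
})

test_that("volume estimation matches the Gaussian closed form and scales", {
  iso <- function(s) {
    gaussian_mixture(1, matrix(0, 1, 3), array(diag(s^2, 3), c(3, 3, 1)))
  }
  # 95% of a 3D Gaussian's mass lies within radius sigma * sqrt(chi2_3(0.95))
  sg <- 5
  r95 <- sg * sqrt(qchisq(0.95, df = 3))
  expect_equal(estimate_volume(iso(sg)), 4 / 3 * pi * r95^3,
               tolerance = 0.05)
  # doubling sigma multiplies the volume by 8
  expect_equal(estimate_volume(iso(2 * sg)) / estimate_volume(iso(sg)), 8,
               tolerance = 0.05)
  # two far-separated identical components double the volume
  two <- gaussian_mixture(c(0.5, 0.5),
                          rbind(c(-40, 0, 0), c(40, 0, 0)),
                          array(rep(diag(sg^2, 3), 2), c(3, 3, 2)))
  expect_equal(estimate_volume(two) / estimate_volume(iso(sg)), 2,
               tolerance = 0.05)
})
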