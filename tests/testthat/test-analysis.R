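# MDS, per-model PCC profiles, grid binning, and model clustering.

test_that("classical MDS reproduces Euclidean configurations exactly", {
  set.seed(14)
  # 10 planar points: pairwise distances must be reproduced to 1e-8
  P <- cbind(runif(10, -3, 3), runif(10, -3, 3))
  D <- as.matrix(dist(P))
  emb <- classical_mds(D, k = 2)
  expect_lt(max(abs(as.matrix(dist(emb$points)) - D)), 1e-8)
  expect_lt(max(abs(colMeans(emb$points))), 1e-9)
  expect_true(all(diff(emb$eigenvalues) <= 1e-9))
  expect_equal(emb$gof, 1, tolerance = 1e-9)

  # 3 equidistant points embed as an equilateral triangle
  D3 <- matrix(0.8, 3, 3); diag(D3) <- 0
  emb3 <- classical_mds(D3, k = 2)
  d3 <- as.matrix(dist(emb3$points))
  expect_equal(d3[upper.tri(d3)], rep(0.8, 3), tolerance = 1e-8)

  expect_error(classical_mds(matrix(0, 3, 3)), "degenerate")
})

test_that("classical MDS agrees with the cmdscale oracle", {
  set.seed(15)
  for (i in 1:5) {
    n <- 8
    P <- matrix(runif(n * 3, -2, 2), n)
    D <- as.matrix(dist(P))
    emb <- classical_mds(D, k = 2)
    oracle <- cmdscale(D, k = 2, eig = TRUE)
    # embeddings agree up to an orthogonal transform: compare distances
    expect_lt(sqrt(mean((dist(emb$points) - dist(oracle$points))^2)), 1e-9)
    expect_equal(emb$eigenvalues[1:2], oracle$eig[1:2], tolerance = 1e-9)
  }
})

test_that("model PCC profiles separate and identify duplicated models", {
  st1 <- build_projection_set(fix_map("sphere"), n_images = 8)
  st2 <- build_projection_set(fix_map("cylinder"), n_images = 8)
  st2$info$model_id <- "cylinder_b"
  st3 <- build_projection_set(fix_map("cylinder"), n_images = 8)
  stack <- bind_stacks(st1, st2, st3)
  cc <- allpairs_cc_matrix(stack, psi_step = 10)
  idx <- stack$info$model_id
  P <- model_pcc_matrix(cc, idx)
  expect_identical(unname(diag(P)), rep(1, 3))
  expect_lt(max(abs(P - t(P))), 1e-12)
  # duplicated cylinder models have near-identical profiles
  expect_gte(P["cylinder_b", "cylinder"], 0.999)
  # and are more alike than sphere vs cylinder
  expect_gt(P["cylinder_b", "cylinder"], P["sphere", "cylinder"])
  expect_error(model_pcc_matrix(matrix(1, 4, 4), rep(c("a", "b"), 2)),
               "degenerate")
})

test_that("grid binning counts, means, and representatives are exact", {
  emb <- structure(list(points = rbind(
    c(0.05, 0.05), c(0.07, 0.02), c(0.08, 0.09),  # cell (0, 0)
    c(0.15, 0.05),                                # cell (1, 0)
    c(-0.02, 0.31)                                # cell (-1, 3)
  )), class = "MDSEmbedding")
  cc <- diag(5)
  cc[1, 2] <- cc[2, 1] <- 0.8
  cc[1, 3] <- cc[3, 1] <- 0.6
  cc[2, 3] <- cc[3, 2] <- 0.4
  idx <- c("A", "B", "B", "C", "A")
  cells <- grid_bin_embedding(emb, cc, idx, cell = 0.1)
  expect_identical(nrow(cells), 3L)
  expect_equal(sum(cells$count), 5)
  c00 <- cells[cells$row == 0 & cells$col == 0, ]
  expect_identical(c00$count, 3L)
  expect_equal(c00$mean_cc, mean(c(0.8, 0.6, 0.4)))
  expect_identical(c00$model_id, "B")       # most frequent model
  expect_identical(c00$representative, 2L)  # lowest image id of that model
  # singleton cells omit the mean CC
  expect_true(is.na(cells$mean_cc[cells$count == 1][1]))
})

test_that("cluster_models separates synthetic families from either input", {
  # two duplicated models merge at height ~0
  sim <- matrix(c(1, 0.999, 0.2,
                  0.999, 1, 0.2,
                  0.2, 0.2, 1), 3, 3)
  rownames(sim) <- colnames(sim) <- c("a1", "a2", "b")
  tree <- cluster_models(sim)
  expect_identical(tree$merge[1, ], c(-1L, -2L))
  expect_lt(tree$height[1], 0.05)
  # numerically equal inputs give identical trees (shared code path)
  expect_identical(cluster_models(sim), cluster_models(sim + 0))

  # spheres vs rods from the real 3D pipeline
  gm <- list(
    fit_gmm(make_density(shape_spec("sphere", list(radius = 14),
                                    name = "sph1")), K = 4, seed = 2),
    fit_gmm(make_density(shape_spec("sphere", list(radius = 17),
                                    name = "sph2")), K = 4, seed = 2),
    fit_gmm(make_density(shape_spec("cylinder", list(radius = 8, length = 40),
                                    name = "rod1")), K = 4, seed = 2),
    fit_gmm(make_density(shape_spec("cylinder", list(radius = 9, length = 46),
                                    name = "rod2")), K = 4, seed = 2))
  cc <- pairwise_cc_matrix(gm, seed = 6, n_starts = 6)
  tree2 <- cluster_models(cc)
  memb <- cutree(as.hclust(tree2), k = 2)
  expect_equal(adjusted_rand_index(memb, c(1, 1, 2, 2)), 1)

  # the two families occupy separated regions of the 2D embedding
  emb <- classical_mds(cc_to_distance(cc), k = 2)
  fam <- c(1, 1, 2, 2)
  centroids <- rbind(colMeans(emb$points[fam == 1, ]),
                     colMeans(emb$points[fam == 2, ]))
  within <- mean(sqrt(rowSums((emb$points - centroids[fam, ])^2)))
  between <- sqrt(sum((centroids[1, ] - centroids[2, ])^2))
  expect_gt(between, within)  # positive silhouette-like separation
})
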