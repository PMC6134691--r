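# Distance transform, Ward clustering, representative selection, and the
# end-to-end library build.

test_that("cc_to_distance implements d = sqrt(1 - CC^2)", {
  expect_identical(cc_to_distance(1), 0)
  expect_identical(cc_to_distance(0), 1)
  expect_equal(cc_to_distance(0.7), sqrt(0.51))
  expect_equal(cc_to_distance(-0.3), cc_to_distance(0.3))
  expect_error(cc_to_distance(1.2), "domain")
})

test_that("ward.D clustering matches the stats::hclust oracle", {
  set.seed(88)
  for (i in 1:5) {
    n <- 8
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 1)
    D <- D + t(D)
    tree <- ward_cluster(D)
    oracle <- stats::hclust(as.dist(D), method = "ward.D")
    expect_equal(tree$height, oracle$height, tolerance = 1e-9)
    # same partitions at every merge count
    for (k in 2:4) {
      ours <- cutree(as.hclust(tree), k = k)
      theirs <- cutree(oracle, k = k)
      expect_equal(adjusted_rand_index(ours, theirs), 1)
    }
  }
})

test_that("ward merges are deterministic with index-order tie-breaking", {
  # {A, A', B}: d(A, A') = 0 merges first, at height 0
  D <- matrix(c(0, 0, 1,
                0, 0, 1,
                1, 1, 0), 3, 3)
  rownames(D) <- colnames(D) <- c("A", "Ap", "B")
  tree <- ward_cluster(D)
  expect_identical(tree$merge[1, ], c(-1L, -2L))
  expect_identical(tree$height[1], 0)
  # exact ties: the lowest index pair merges first; after (1, 2) merge the
  # Ward update leaves all distances tied, so {1,2} absorbs 3 next
  D2 <- matrix(0.5, 4, 4); diag(D2) <- 0
  tree2 <- ward_cluster(D2)
  expect_identical(tree2$merge[1, ], c(-1L, -2L))
  expect_identical(tree2$merge[2, ], c(-3L, 1L))
  # no inversions: heights non-decreasing for ultrametric-like input
  expect_true(all(diff(tree$height) >= -1e-12))
})

test_that("two tight triads separate at the between-cluster gap", {
  # 6 points: two triads with intra-distance 0.1, inter-distance 1
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0.1; D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  tree <- ward_cluster(D)
  h <- sort(tree$height)
  # four within-triad merges below the final between-triad merge
  expect_lt(h[4], h[5])
  memb <- cutree(as.hclust(tree), h = mean(c(h[4], h[5])))
  expect_equal(adjusted_rand_index(memb, rep(1:2, each = 3)), 1)
})

test_that("representative selection cuts at the median and picks medoids", {
  set.seed(3)
  n <- 6
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- runif(15, 0.2, 1)
  D <- D + t(D)
  tree <- ward_cluster(D)
  # cutoff below all merge heights: everything retained
  expect_length(select_representatives(tree, cutoff = 0), n)
  # cutoff above all merge heights: single representative
  expect_length(select_representatives(tree, cutoff = max(tree$height) + 1), 1)
  expect_error(select_representatives(tree, cutoff = -1), "nonnegative")

  # duplicated shapes: d = 0 pairs collapse to one representative each at
  # the default median cut (the dedup-halving behavior)
  Ddup <- matrix(0, 8, 8)
  base <- matrix(0, 4, 4)
  base[upper.tri(base)] <- c(0.9, 0.8, 0.85, 0.7, 0.95, 0.75)
  base <- base + t(base)
  idx <- rep(1:4, each = 2)
  Ddup <- base[idx, idx]
  diag(Ddup) <- 0
  rownames(Ddup) <- colnames(Ddup) <- paste0("m", 1:8)
  treed <- ward_cluster(Ddup)
  reps <- select_representatives(treed)
  expect_length(reps, 4)
  cl <- attr(reps, "clusters")
  expect_equal(unname(cl[seq(1, 8, 2)]), unname(cl[seq(2, 8, 2)]))
})

test_that("build_library deduplicates duplicated shapes end to end", {
  kinds <- c("sphere", "cylinder", "L_block")
  maps <- list()
  for (k in kinds) {
    for (copy in 1:2) {
      m <- make_density(shape_spec(k, name = sprintf("%s_%d", k, copy)))
      maps[[length(maps) + 1]] <- m
    }
  }
  # L-block corners can overrun the box on upscale: crop warnings expected
  lib <- suppressWarnings(
    build_library(maps, K = 5, n_images = 8, cutoff_policy = "median",
                  seed = 9, n_starts = 6))
  expect_length(lib$models, 3)
  expect_identical(n_images(lib$stack), 24L)
  # one representative per duplicated pair
  fams <- sub("_[12]$", "", lib$models)
  expect_setequal(fams, kinds)

  # cutoff_policy = "none" keeps all six models
  lib_all <- suppressWarnings(
    build_library(maps, K = 5, n_images = 8, cutoff_policy = "none",
                  seed = 9, n_starts = 6))
  expect_length(lib_all$models, 6)
  expect_identical(n_images(lib_all$stack), 48L)

  # provenance and content survive a save/load round-trip
  dir <- withr::local_tempdir()
  save_library(lib, dir)
  lib2 <- load_library(dir)
  expect_identical(lib2$models, lib$models)
  expect_equal(lib2$provenance[c("K", "n_images", "cutoff_policy", "seed")],
               lib$provenance[c("K", "n_images", "cutoff_policy", "seed")])
  expect_equal(lib2$stack$pixels, lib$stack$pixels, tolerance = 1e-6)
  expect_equal(lib2$cc_matrix, lib$cc_matrix, tolerance = 1e-6)
  expect_equal(lib2$gmms[[1]]$means, lib$gmms[[1]]$means, tolerance = 1e-12)
})
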