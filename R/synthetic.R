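# Parametric phantom volumes emulating low-resolution single-particle EM
# envelopes: a solid indicator function smoothed by a Gaussian soft edge,
# optionally with additive clamped noise. Families cover the shape diversity
# seen in EM archives (globular, elongated, barrel-like, two-lobed, angular,
# capped-rod).

SHAPE_KINDS <- c("sphere", "ellipsoid", "cylinder", "dumbbell",
                 "L_block", "bullet")

default_shape_sizes <- function(kind) {
  switch(kind,
    sphere    = list(radius = 18),
    ellipsoid = list(a = 26, b = 16, c = 12),
    cylinder  = list(radius = 10, length = 46),
    dumbbell  = list(lobe_radius = 12, separation = 30, bar_radius = 5),
    L_block   = list(arm1 = 38, arm2 = 28, thickness = 14),
    bullet    = list(radius = 12, length = 34),
    stop_shapesearch(sprintf("unknown shape kind '%s'", kind),
                     "shapesearch_domain_error")
  )
}

#' Specify a synthetic shape
#'
#' @param kind One of `"sphere"`, `"ellipsoid"`, `"cylinder"`,
#'   `"dumbbell"`, `"L_block"`, `"bullet"`.
#' @param sizes Named list of size parameters in angstrom; missing entries
#'   take family defaults (see [make_density()]).
#' @param orientation Unit quaternion (w, x, y, z) applied to the solid;
#'   `NULL` for the canonical axis-aligned pose.
#' @param soft_edge Gaussian soft-edge width in angstrom (default 2),
#'   emulating the smooth falloff of low-resolution EM envelopes.
#' @param noise_sd Additive Gaussian noise SD as a fraction of the maximum
#'   density (default 0); negative values are clamped at zero.
#' @param seed Seed for the noise.
#' @param name Identifier.
#' @return A `ShapeSpec` list.
#' @export
shape_spec <- function(kind, sizes = list(), orientation = NULL,
                       soft_edge = 2, noise_sd = 0, seed = 1, name = NULL) {
  kind <- match.arg(kind, SHAPE_KINDS)
  def <- default_shape_sizes(kind)
  def[names(sizes)] <- sizes
  if (any(unlist(def) <= 0)) {
    stop_shapesearch("all size parameters must be positive",
                     "shapesearch_domain_error")
  }
  structure(
    list(kind = kind, sizes = def, orientation = orientation,
         soft_edge = soft_edge, noise_sd = noise_sd, seed = as.integer(seed),
         name = name %||% kind),
    class = "ShapeSpec"
  )
}

# signed membership of points (rows, centered coordinates) in the solid
shape_indicator <- function(kind, sz, P) {
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  switch(kind,
    sphere = x^2 + y^2 + z^2 <= sz$radius^2,
    ellipsoid = (x / sz$a)^2 + (y / sz$b)^2 + (z / sz$c)^2 <= 1,
    cylinder = x^2 + y^2 <= sz$radius^2 & abs(z) <= sz$length / 2,
    dumbbell = {
      h <- sz$separation / 2
      lobe1 <- x^2 + y^2 + (z - h)^2 <= sz$lobe_radius^2
      lobe2 <- x^2 + y^2 + (z + h)^2 <= sz$lobe_radius^2
      bar <- x^2 + y^2 <= sz$bar_radius^2 & abs(z) <= h
      lobe1 | lobe2 | bar
    },
    L_block = {
      t2 <- sz$thickness / 2
      armA <- abs(x) <= t2 & abs(y) <= t2 & z >= -t2 & z <= sz$arm1 - t2
      armB <- abs(z) <= t2 & abs(y) <= t2 & x >= -t2 & x <= sz$arm2 - t2
      armA | armB
    },
    bullet = {
      body <- x^2 + y^2 <= sz$radius^2 & z >= -sz$length / 2 & z <= sz$length / 2
      cap <- x^2 + y^2 + (z - sz$length / 2)^2 <= sz$radius^2 & z > sz$length / 2
      body | cap
    }
  )
}

shape_max_extent <- function(kind, sz) {
  switch(kind,
    sphere = 2 * sz$radius,
    ellipsoid = 2 * max(sz$a, sz$b, sz$c),
    cylinder = max(2 * sz$radius, sz$length),
    dumbbell = sz$separation + 2 * sz$lobe_radius,
    L_block = {
      t2 <- sz$thickness / 2
      2 * sqrt((max(sz$arm1, sz$arm2) - t2)^2 + 2 * t2^2)
    },
    bullet = sz$length + sz$radius
  )
}

#' Generate a density map from a shape specification
#'
#' The solid's indicator function is sampled on the standard 100 A cubic
#' grid (1 A spacing), smoothed by a Gaussian of the soft-edge width, and
#' optionally corrupted by seeded additive noise clamped at zero.
#' Deterministic for a fixed spec and seed.
#'
#' @param spec A [shape_spec()].
#' @return A `DensityMap` (100^3 voxels, 1 A spacing).
#' @export
make_density <- function(spec) {
  stopifnot(inherits(spec, "ShapeSpec"))
  ext <- shape_max_extent(spec$kind, spec$sizes) + 2 * spec$soft_edge
  if (ext > BOX_DIM) {
    stop_shapesearch(sprintf(
      "shape extent %.1f A exceeds the %d A box", ext, BOX_DIM),
      "shapesearch_domain_error")
  }
  n <- BOX_DIM
  ax <- (seq_len(n) - 0.5) - n / 2
  P <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  if (!is.null(spec$orientation)) {
    R <- quat_to_mat(spec$orientation)
    P <- P %*% R  # evaluate the solid at R^T p: rotates the shape by R
  }
  ind <- shape_indicator(spec$kind, spec$sizes, P)
  grid <- array(as.numeric(ind), dim = c(n, n, n))
  grid <- gaussian_smooth3(grid, spec$soft_edge)
  if (spec$noise_sd > 0) {
    noise <- with_seed(spec$seed,
                       stats::rnorm(length(grid),
                                    sd = spec$noise_sd * max(grid)))
    grid <- grid + noise
    grid[grid < 0] <- 0
  }
  density_map(grid, spacing = 1, origin = c(0, 0, 0), name = spec$name)
}

#' Generate a labelled fixture library of synthetic maps
#'
#' Draws shapes round-robin from `n_families` families, jittering size
#' parameters and orientation at random (or placing members on a
#' deterministic elongation ladder, see `aspect_spread`), with family
#' labels returned as clustering/retrieval ground truth.
#'
#' @param n_models Total number of maps.
#' @param n_families Number of distinct shape families (2-6).
#' @param seed Integer seed; the library is reproducible bit-for-bit.
#' @param noise_sd Per-map additive noise SD fraction (default 0).
#' @param soft_edge Soft-edge width in angstrom (default 2).
#' @param kinds Which shape kinds to use as families (default: the first
#'   `n_families` supported kinds).
#' @param aspect_spread `NULL` (default) for random, mild (about 12%)
#'   jitter only — family members stay mutually similar, as needed for
#'   family-recovery benchmarks. Or a length-2 range, e.g. `c(0.72, 1.5)`:
#'   family members
#'   are placed on a deterministic elongation ladder spanning that range
#'   (the dominant size parameter is scaled by `s`, the others by
#'   `1/sqrt(s)`), which emulates a redundancy-reduced library whose
#'   entries are pairwise distinct, as needed for retrieval benchmarks.
#' @return List with `maps` (list of `DensityMap`) and `families`
#'   (character vector of family labels, one per map).
#' @export
make_fixture_library <- function(n_models, n_families = 4, seed = 1,
                                 noise_sd = 0, soft_edge = 2,
                                 kinds = SHAPE_KINDS[seq_len(n_families)],
                                 aspect_spread = NULL) {
  stopifnot(n_models >= n_families, n_families >= 2,
            n_families <= length(SHAPE_KINDS))
  kinds <- match.arg(kinds, SHAPE_KINDS, several.ok = TRUE)
  stopifnot(length(kinds) == n_families)
  fam_of <- rep_len(seq_len(n_families), n_models)
  member <- stats::ave(fam_of, fam_of, FUN = seq_along)
  members_per <- tabulate(fam_of)
  specs <- with_seed(seed, {
    lapply(seq_len(n_models), function(i) {
      kind <- kinds[fam_of[i]]
      sz <- default_shape_sizes(kind)
      if (is.null(aspect_spread)) {
        sz <- lapply(sz, function(v) v * stats::runif(1, 0.88, 1.12))
      } else {
        ladder <- seq(aspect_spread[1], aspect_spread[2],
                      length.out = members_per[fam_of[i]])
        s <- ladder[member[i]]
        primary <- shape_primary_size(kind)
        sz[[primary]] <- sz[[primary]] * s
        for (nm in setdiff(names(sz), primary)) {
          sz[[nm]] <- sz[[nm]] / sqrt(s)
        }
        sz <- lapply(sz, function(v) v * stats::runif(1, 0.94, 1.06))
      }
      q <- random_quaternion()
      shape_spec(kind, sizes = sz, orientation = q, soft_edge = soft_edge,
                 noise_sd = noise_sd, seed = seed + i,
                 name = sprintf("%s_%02d", kind, i))
    })
  })
  maps <- lapply(specs, make_density)
  list(maps = maps,
       families = vapply(specs, function(s) s$kind, character(1)))
}

#' Curated set of mutually distinct synthetic shapes
#'
#' Twenty shape specifications spanning structurally different regimes
#' (sphere, prolate/oblate/triaxial ellipsoids, disk-to-rod cylinders,
#' dumbbell variants, L-blocks, a capped rod). Because volume
#' normalization removes overall scale, diversity comes from shape
#' structure and axis ratios, emulating the pairwise-distinct entries of a
#' redundancy-reduced shape library. Orientations are randomized from
#' `seed`; the set is reproducible bit-for-bit.
#'
#' @param seed Integer seed for the orientations.
#' @return List of 20 `ShapeSpec` objects (names carry the family kind).
#' @export
distinct_shape_specs <- function(seed = 1) {
  tab <- list(
    list("sphere",    list(radius = 18)),
    list("ellipsoid", list(a = 30, b = 12, c = 12)),
    list("ellipsoid", list(a = 36, b = 10, c = 10)),
    list("ellipsoid", list(a = 24, b = 24, c = 6)),
    list("ellipsoid", list(a = 26, b = 26, c = 13)),
    list("ellipsoid", list(a = 32, b = 20, c = 10)),
    list("dumbbell",  list(lobe_radius = 16, separation = 44, bar_radius = 6)),
    list("cylinder",  list(radius = 24, length = 12)),
    list("cylinder",  list(radius = 20, length = 20)),
    list("cylinder",  list(radius = 16, length = 30)),
    list("cylinder",  list(radius = 11, length = 44)),
    list("cylinder",  list(radius = 8,  length = 62)),
    list("bullet",    list(radius = 13, length = 34)),
    list("dumbbell",  list(lobe_radius = 12, separation = 30, bar_radius = 5)),
    list("dumbbell",  list(lobe_radius = 9,  separation = 46, bar_radius = 4)),
    list("dumbbell",  list(lobe_radius = 11, separation = 22, bar_radius = 10)),
    list("L_block",   list(arm1 = 34, arm2 = 22, thickness = 9)),
    list("L_block",   list(arm1 = 38, arm2 = 28, thickness = 14)),
    list("L_block",   list(arm1 = 30, arm2 = 30, thickness = 11)),
    list("L_block",   list(arm1 = 40, arm2 = 18, thickness = 17))
  )
  with_seed(seed, {
    lapply(seq_along(tab), function(i) {
      shape_spec(tab[[i]][[1]], sizes = tab[[i]][[2]],
                 orientation = random_quaternion(), seed = seed + i,
                 name = sprintf("%s_%02d", tab[[i]][[1]], i))
    })
  })
}

# the size parameter that controls a shape's elongation
shape_primary_size <- function(kind) {
  switch(kind,
    sphere = "radius", ellipsoid = "a", cylinder = "length",
    dumbbell = "separation", L_block = "arm1", bullet = "length")
}
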