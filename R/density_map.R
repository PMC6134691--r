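# Density maps and volume normalization.
#
# A DensityMap carries a nonnegative scalar field on a regular grid with
# physical voxel spacing. All shape comparison downstream assumes maps have
# been (1) normalized to a common 100 angstrom cubic grid at 1 angstrom per
# voxel and (2) rescaled so the particle occupies a common reference volume
# of 50^3 A^3, which makes retrieval insensitive to molecular size.

BOX_DIM <- 100L      # normalized cubic box, voxels (= angstrom at 1 A/voxel)
REF_DIM <- 50        # reference linear dimension, angstrom

#' Construct a density map
#'
#' @param grid 3D numeric array of densities (negatives are clamped to 0).
#' @param spacing Voxel spacing in angstrom, scalar or per-axis length-3.
#' @param origin Physical origin (angstrom), length-3. Voxel `i` (1-based) is
#'   centered at `origin + (i - 0.5) * spacing`.
#' @param name Identifier string.
#' @return A `DensityMap` object.
#' @export
density_map <- function(grid, spacing = 1, origin = c(0, 0, 0), name = "map") {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  grid[grid < 0] <- 0
  structure(
    list(grid = grid, spacing = rep_len(as.numeric(spacing), 3),
         origin = rep_len(as.numeric(origin), 3), name = as.character(name)),
    class = "DensityMap"
  )
}

#' @export
print.DensityMap <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("DensityMap '%s': %d x %d x %d voxels, spacing %s A, mass %.4g\n",
              x$name, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "/"), total_mass(x)))
  invisible(x)
}

#' Total integrated density of a map (sum of voxels times voxel volume)
#' @param map A `DensityMap`.
#' @return Scalar mass (density units times cubic angstrom).
#' @export
total_mass <- function(map) {
  sum(map$grid) * prod(map$spacing)
}

#' Load a density map from an MRC file
#'
#' Negative voxels (noise in experimental maps) are clamped to zero so the
#' map can be treated as a nonnegative mass distribution for Gaussian
#' mixture fitting.
#'
#' @param path Path to an MRC file (modes 0, 1, 2).
#' @param name Identifier; defaults to the file base name.
#' @return A `DensityMap`.
#' @export
load_density_map <- function(path, name = NULL) {
  m <- read_mrc(path)
  density_map(m$data, spacing = m$spacing, origin = m$origin,
              name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Save a density map as MRC2014 (mode 2)
#' @param map A `DensityMap`.
#' @param path Output path.
#' @export
save_density_map <- function(map, path) {
  write_mrc(path, map$grid, spacing = map$spacing, origin = map$origin)
  invisible(path)
}

#' Denoise a map for fitting and volume estimation
#'
#' Standard preparation for maps with an additive noise floor: low-pass
#' Gaussian filtering (default 2 angstrom), followed by subtraction of the
#' background pedestal (the median voxel value — the particle occupies a
#' small fraction of the box, so the median estimates the smoothed noise
#' background) and clamping at zero. A noise-free map passes through
#' unchanged apart from the filtering.
#'
#' @param map A `DensityMap`.
#' @param smooth Gaussian filter SD in angstrom (0 to skip).
#' @return A denoised `DensityMap`.
#' @export
denoise_map <- function(map, smooth = 2) {
  g <- map$grid
  if (smooth > 0) g <- gaussian_smooth3(g, smooth / mean(map$spacing))
  g <- g - stats::median(g)
  g[g < 0] <- 0
  out <- map
  out$grid <- g
  out
}

# Resample a map onto an out_dim^3 grid at out_spacing, scaling the content
# isotropically by `scale` about the box centers. Trilinear interpolation;
# out-of-box source positions contribute zero density.
resample_map <- function(map, scale, out_dim, out_spacing) {
  d <- dim(map$grid)
  ctr_old <- d * map$spacing / 2            # physical box centers
  ctr_new <- rep(out_dim * out_spacing / 2, 3)
  ax <- (seq_len(out_dim) - 0.5) * out_spacing
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  # physical position in the old frame
  old <- sweep(sweep(pts, 2, ctr_new), 2, rep(1 / scale, 3), `*`)
  old <- sweep(old, 2, ctr_old, `+`)
  # to fractional 1-based voxel index
  idx <- sweep(sweep(old, 2, map$spacing, `/`), 2, 0.5, `+`)
  vals <- trilinear_sample(map$grid, idx)
  grid <- array(vals, dim = rep(out_dim, 3))
  density_map(grid, spacing = out_spacing, origin = c(0, 0, 0),
              name = map$name)
}

#' Normalize a map to the standard 100-voxel cubic grid at 1 A spacing
#'
#' The map content is scaled isotropically so its largest physical extent
#' fills the 100 A box, centered, and resampled; total mass is preserved by
#' renormalization after interpolation. A map already on the standard grid is
#' returned unchanged.
#'
#' @param map A `DensityMap` (any grid size, possibly anisotropic spacing).
#' @return A `DensityMap` on a 100^3 grid at 1 A spacing.
#' @export
normalize_grid <- function(map) {
  mass0 <- total_mass(map)
  if (mass0 <= 0) {
    stop_shapesearch("degenerate map: zero total mass",
                     "shapesearch_degenerate_error")
  }
  d <- dim(map$grid)
  if (all(d == BOX_DIM) && all(abs(map$spacing - 1) < 1e-9)) {
    out <- map
    out$origin <- c(0, 0, 0)
    return(out)
  }
  extent <- d * map$spacing
  scale <- BOX_DIM / max(extent)
  out <- resample_map(map, scale = scale, out_dim = BOX_DIM, out_spacing = 1)
  m <- total_mass(out)
  if (m > 0) out$grid <- out$grid * (mass0 / m)
  out
}

#' New axis dimension for volume normalization
#'
#' Computes `D_new = D_old * D_ref / V_old^(1/3)`: the grid dimension to
#' which a normalized map must be resized so that its particle volume
#' becomes `D_ref^3`.
#'
#' @param V_old Estimated particle volume (cubic angstrom).
#' @param D_old Current cubic axis dimension (angstrom), default 100.
#' @param D_ref Reference linear dimension (angstrom), default 50.
#' @return `D_new` in angstrom.
#' @export
rescale_axis_dimension <- function(V_old, D_old = 100, D_ref = REF_DIM) {
  if (!is.finite(V_old) || V_old <= 0) {
    stop_shapesearch("V_old must be positive", "shapesearch_domain_error")
  }
  if (D_old <= 0 || D_ref <= 0) {
    stop_shapesearch("D_old and D_ref must be positive",
                     "shapesearch_domain_error")
  }
  D_old * D_ref / V_old^(1 / 3)
}

#' Resize a normalized map to the common particle volume
#'
#' Scales the map content so its estimated particle volume becomes
#' `D_ref^3` (50^3 A^3 by default), keeping the 100 A box and 1 A spacing.
#' Content that would leave the box on upscaling is cropped symmetrically
#' with a warning. Density is renormalized to preserve total mass (before
#' any crop loss).
#'
#' @param map A grid-normalized `DensityMap` (100^3 at 1 A).
#' @param V_old Estimated particle volume from [estimate_volume()].
#' @param D_ref Reference linear dimension, default 50 A.
#' @return A resized `DensityMap`.
#' @export
resize_to_common_volume <- function(map, V_old, D_ref = REF_DIM) {
  d <- dim(map$grid)
  if (!all(d == BOX_DIM)) {
    stop_shapesearch("map must be grid-normalized (100^3) before volume resize",
                     "shapesearch_domain_error")
  }
  D_new <- rescale_axis_dimension(V_old, D_old = BOX_DIM, D_ref = D_ref)
  if (D_new > 4 * BOX_DIM) {
    stop_shapesearch(
      sprintf("implausible volume: D_new = %.1f A exceeds 4 x box", D_new),
      "shapesearch_domain_error")
  }
  mass0 <- total_mass(map)
  # content scale factor: > 1 magnifies (small particles), < 1 shrinks
  s <- D_new / BOX_DIM
  out <- resample_map(map, scale = s, out_dim = BOX_DIM, out_spacing = 1)
  # analytic mass preservation under isotropic scaling
  out$grid <- out$grid / s^3
  m <- total_mass(out)
  if (s > 1 && m < 0.99 * mass0) {
    warning(sprintf(
      "resize_to_common_volume: %.1f%% of mass cropped at the box boundary",
      100 * (1 - m / mass0)))
  } else if (m > 0) {
    out$grid <- out$grid * (mass0 / m)
  }
  out
}
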