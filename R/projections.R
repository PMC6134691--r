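# Quasi-uniform projection directions and 2D projection images.
#
# View directions are vertices of a subdivided icosahedron (polar
# orientation, so +z is always a vertex), restricted to the upper
# hemisphere: the projection along -v is the mirror image of the projection
# along +v, so with mirror search enabled in 2D alignment the lower
# hemisphere is redundant. The vertex set is pruned to the requested count
# by farthest-point selection seeded at +z, which keeps the sampling
# quasi-uniform and deterministic.

IMG_SIZE <- 64L
PIXEL_SIZE <- 100 / 64  # angstrom per pixel: 100 A field of view, 64 px

# icosahedron vertices with two poles on the z axis
icosa_vertices_polar <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c(1,  phi, 0), c(-1,  phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0,  1), c(-phi, 0,  1), c(phi, 0, -1), c(-phi, 0, -1)
  )
  v <- v / sqrt(rowSums(v^2))
  # rotate vertex 1 to the +z pole
  a <- v[1, ]
  target <- c(0, 0, 1)
  axis <- cross3(a, target)
  s <- sqrt(sum(axis^2))
  if (s > 1e-12) {
    angle <- acos(max(-1, min(1, sum(a * target))))
    R <- rotvec_to_mat(axis / s * angle)
    v <- v %*% t(R)
  }
  v
}

icosa_faces <- function(v) {
  # faces = triples of mutually adjacent vertices (edge length = min distance)
  d <- as.matrix(stats::dist(v))
  edge <- min(d[d > 1e-9])
  adj <- d < edge * 1.1 & d > 1e-9
  faces <- list()
  n <- nrow(v)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (adj[i, j] && adj[j, k] && adj[i, k]) {
      faces[[length(faces) + 1]] <- c(i, j, k)
    }
  }
  do.call(rbind, faces)
}

# geodesic sphere vertices at subdivision frequency f (10 f^2 + 2 points)
geodesic_vertices <- function(f) {
  v <- icosa_vertices_polar()
  faces <- icosa_faces(v)
  pts <- v
  for (r in seq_len(nrow(faces))) {
    a <- v[faces[r, 1], ]; b <- v[faces[r, 2], ]; cc <- v[faces[r, 3], ]
    for (i in 0:f) {
      for (j in 0:(f - i)) {
        k <- f - i - j
        p <- (i * a + j * b + k * cc) / f
        pts <- rbind(pts, p / sqrt(sum(p^2)))
      }
    }
  }
  keep <- !duplicated(round(pts, 9))
  pts <- pts[keep, , drop = FALSE]
  pts / sqrt(rowSums(pts^2))
}

#' Sample quasi-uniform projection directions on the upper hemisphere
#'
#' Chooses the smallest icosahedral subdivision giving at least `n_target`
#' upper-hemisphere vertices, then prunes to exactly `n_target` by
#' farthest-point selection starting from (0, 0, 1). Equatorial antipode
#' pairs are collapsed to a single representative. Deterministic.
#'
#' @param n_target Number of directions (91 and 196 are the customary
#'   library settings).
#' @return Data frame with columns `id`, `x`, `y`, `z` (unit vectors,
#'   z >= 0).
#' @export
sample_directions <- function(n_target) {
  stopifnot(n_target >= 1)
  if (n_target == 1) {
    return(data.frame(id = 1L, x = 0, y = 0, z = 1))
  }
  f <- 1
  repeat {
    pts <- geodesic_vertices(f)
    up <- pts[pts[, 3] > 1e-9, , drop = FALSE]
    eq <- pts[abs(pts[, 3]) <= 1e-9, , drop = FALSE]
    if (nrow(eq) > 0) {
      # keep one of each antipodal equator pair, deterministically
      keep <- eq[, 1] > 1e-9 | (abs(eq[, 1]) <= 1e-9 & eq[, 2] > 0)
      up <- rbind(up, eq[keep, , drop = FALSE])
    }
    if (nrow(up) >= n_target) break
    f <- f + 1
    if (f > 40) stop_shapesearch("direction sampling failed to converge",
                                 "shapesearch_domain_error")
  }
  # deterministic ordering before selection
  ord <- order(-up[, 3], atan2(up[, 2], up[, 1]))
  up <- up[ord, , drop = FALSE]
  # farthest-point pruning, seeded at the direction closest to +z
  n <- nrow(up)
  sel <- integer(n_target)
  sel[1] <- which.max(up[, 3])
  mind <- acos(pmin(1, pmax(-1, up %*% up[sel[1], ])))
  for (m in seq_len(n_target - 1)) {
    cand <- which(mind == max(mind))
    sel[m + 1] <- cand[1]
    d_new <- acos(pmin(1, pmax(-1, up %*% up[sel[m + 1], ])))
    mind <- pmin(mind, d_new)
  }
  chosen <- up[sel, , drop = FALSE]
  data.frame(id = seq_len(n_target), x = chosen[, 1], y = chosen[, 2],
             z = chosen[, 3])
}

#' Project a density map along a view direction
#'
#' The map is sampled in a rotated frame whose z axis is the view
#' direction (trilinear interpolation) and integrated along z in 1 A steps;
#' the 100 x 100 A field of view is sampled on a 64 x 64 pixel raster
#' (1.5625 A per pixel). Pixel values are line integrals in density times
#' angstrom, so the pixel sum is proportional to total map mass for every
#' direction.
#'
#' @param map A grid-normalized `DensityMap` (100^3 at 1 A).
#' @param direction Length-3 view axis (normalized internally) or one row
#'   of [sample_directions()].
#' @return A 64 x 64 numeric matrix of class `ProjectionImage` with
#'   attribute `pixel_size`.
#' @export
project_map <- function(map, direction) {
  if (is.data.frame(direction)) {
    direction <- c(direction$x[1], direction$y[1], direction$z[1])
  }
  v <- as.numeric(direction)
  v <- v / sqrt(sum(v^2))
  if (sum(map$grid) <= 0) {
    stop_shapesearch("degenerate projection: empty map",
                     "shapesearch_degenerate_error")
  }
  d <- dim(map$grid)
  basis <- view_basis(v)  # columns e1, e2, v
  xs <- (seq_len(IMG_SIZE) - (IMG_SIZE + 1) / 2) * PIXEL_SIZE
  zs <- seq(-(d[3] * map$spacing[3]) / 2 + 0.5,
            (d[3] * map$spacing[3]) / 2 - 0.5, by = 1)
  img <- .project_cpp(map$grid, map$spacing, basis, xs, zs)  # dz = 1 A
  structure(img, class = c("ProjectionImage", class(img)),
            pixel_size = PIXEL_SIZE)
}

#' Build the projection image set for one model
#'
#' One 64 x 64 image per sampled direction, tagged with the model
#' identifier and direction.
#'
#' @param map A grid-normalized `DensityMap`.
#' @param n_images Number of projection directions (default 91).
#' @return An `ImageStack`.
#' @export
build_projection_set <- function(map, n_images = 91) {
  dirs <- sample_directions(n_images)
  imgs <- array(0, c(IMG_SIZE, IMG_SIZE, n_images))
  for (i in seq_len(n_images)) {
    imgs[, , i] <- project_map(map, c(dirs$x[i], dirs$y[i], dirs$z[i]))
  }
  image_stack(imgs, data.frame(
    image_index = seq_len(n_images), model_id = map$name,
    dir_id = dirs$id, dir_x = dirs$x, dir_y = dirs$y, dir_z = dirs$z,
    stringsAsFactors = FALSE))
}

#' Construct an image stack
#'
#' @param pixels 64 x 64 x M array of image pixels.
#' @param info Data frame with one row per image; must contain at least
#'   `image_index` and `model_id`.
#' @return An `ImageStack` object.
#' @export
image_stack <- function(pixels, info) {
  if (length(dim(pixels)) == 2) dim(pixels) <- c(dim(pixels), 1)
  stopifnot(dim(pixels)[1] == IMG_SIZE, dim(pixels)[2] == IMG_SIZE,
            nrow(info) == dim(pixels)[3], "model_id" %in% names(info))
  structure(list(pixels = pixels, info = info, pixel_size = PIXEL_SIZE),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  cat(sprintf("ImageStack: %d images (64 x 64), %d models\n",
              dim(x$pixels)[3], length(unique(x$info$model_id))))
  invisible(x)
}

#' Number of images in a stack
#' @param stack An `ImageStack`.
#' @return Integer count.
#' @export
n_images <- function(stack) dim(stack$pixels)[3]

#' Concatenate image stacks
#' @param ... `ImageStack` objects.
#' @return A combined `ImageStack` with re-numbered `image_index`.
#' @export
bind_stacks <- function(...) {
  stacks <- list(...)
  if (length(stacks) == 1 && is.list(stacks[[1]]) &&
      !inherits(stacks[[1]], "ImageStack")) {
    stacks <- stacks[[1]]
  }
  pix <- array(unlist(lapply(stacks, function(s) s$pixels)),
               c(IMG_SIZE, IMG_SIZE, sum(vapply(stacks, n_images, 1L))))
  info <- do.call(rbind, lapply(stacks, function(s) s$info))
  info$image_index <- seq_len(nrow(info))
  image_stack(pix, info)
}

#' Write an image stack as an MRC stack plus TSV metadata
#'
#' Writes `<path>.mrcs` (MRC mode 2, nz = number of images) and
#' `<path>.tsv` (columns `image_index`, `model_id`, `dir_x`, `dir_y`,
#' `dir_z`, plus any extra metadata columns).
#'
#' @param stack An `ImageStack`.
#' @param path Output path prefix (extensions are appended).
#' @export
write_image_stack <- function(stack, path) {
  write_mrc(paste0(path, ".mrcs"), stack$pixels,
            spacing = c(stack$pixel_size, stack$pixel_size, 1))
  utils::write.table(stack$info, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#' @param path Path prefix used at write time.
#' @return An `ImageStack`.
#' @export
read_image_stack <- function(path) {
  m <- read_mrc(paste0(path, ".mrcs"))
  info <- utils::read.table(paste0(path, ".tsv"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  image_stack(m$data, info)
}
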