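# 2D projection-image alignment.
#
# The similarity between two images is the maximum zero-mean, unit-norm
# cross-correlation inside a centered circular mask (radius 30 px of 64),
# searched exhaustively over in-plane rotation (default 2 degree step),
# mirror, and translations up to max_shift pixels (FFT scan). The mask
# removes corner artifacts introduced by rotation padding.
#
# Conventions (tested): psi rotates the query counterclockwise about the
# image center before correlation; mirroring flips the query's x axis
# before rotation; the returned shift is the translation applied to the
# rotated query to superpose it on the reference.

MASK_RADIUS <- 30

circular_mask <- function(n = IMG_SIZE, radius = MASK_RADIUS) {
  ctr <- (n + 1) / 2
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  matrix(as.numeric((ij$i - ctr)^2 + (ij$j - ctr)^2 <= radius^2), n, n)
}

# mask, zero-mean and unit-normalize inside the mask; NULL if constant
normalize_masked <- function(img, mask) {
  v <- img * mask
  np <- sum(mask)
  v <- v - (sum(v) / np) * mask
  nr <- sqrt(sum(v^2))
  if (nr < 1e-12) return(NULL)
  v / nr
}

# rotated/mirrored normalized variants of an image; returns list(pixels=cube,
# psi=vector, mirrored=vector)
make_variants <- function(img, psi_step, mask) {
  psis <- seq(0, 360 - psi_step, by = psi_step)
  nv <- length(psis)
  cube <- array(0, c(IMG_SIZE, IMG_SIZE, 2L * nv))
  cube[, , seq_len(nv)] <- .rotate_images_cpp(img, psis)
  cube[, , nv + seq_len(nv)] <- .rotate_images_cpp(img[IMG_SIZE:1, ], psis)
  np <- sum(mask)
  for (v in seq_len(2L * nv)) {
    nm <- normalize_masked(cube[, , v], mask)
    if (is.null(nm)) {
      stop_shapesearch("undefined correlation: constant image within mask",
                       "shapesearch_degenerate_error")
    }
    cube[, , v] <- nm
  }
  list(pixels = cube, psi = rep(psis, 2),
       mirrored = rep(c(FALSE, TRUE), each = nv))
}

signed_angle <- function(psi) ((psi + 180) %% 360) - 180

#' Align one image to a reference
#'
#' Exhaustive search over in-plane rotation, mirror, and translation for
#' the maximum masked normalized cross-correlation of `query` against
#' `ref`.
#'
#' @param query,ref 64 x 64 numeric matrices (projection images).
#' @param psi_step Rotational step in degrees (default 2).
#' @param max_shift Maximum translation in pixels (default 10, at most 16).
#' @return An `Alignment2DResult`: list with `cc_max`, `psi` (degrees, in
#'   (-180, 180], applied counterclockwise to the query), `shift`
#'   (pixels applied to the rotated query), and `mirrored`.
#' @export
align_pair <- function(query, ref, psi_step = 2, max_shift = 10) {
  stopifnot(psi_step > 0, max_shift <= 16, max_shift >= 0)
  query <- as_image(query); ref <- as_image(ref)
  mask <- circular_mask()
  var <- make_variants(query, psi_step, mask)
  refn <- normalize_masked(ref, mask)
  if (is.null(refn)) {
    stop_shapesearch("undefined correlation: constant image within mask",
                     "shapesearch_degenerate_error")
  }
  res <- .align_scan_cpp(var$pixels, array(ref, c(IMG_SIZE, IMG_SIZE, 1)),
                         mask, as.integer(max_shift))
  res[, 1] <- pmin(1, pmax(-1, res[, 1]))  # strip FP roundoff beyond +/-1
  v <- res[1, 2]
  structure(
    list(cc_max = res[1, 1], psi = signed_angle(var$psi[v]),
         shift = c(res[1, 3], res[1, 4]), mirrored = var$mirrored[v]),
    class = "Alignment2DResult"
  )
}

as_image <- function(x) {
  if (inherits(x, "ProjectionImage")) x <- unclass(x)
  x <- as.matrix(x)
  stopifnot(nrow(x) == IMG_SIZE, ncol(x) == IMG_SIZE)
  attributes(x) <- list(dim = dim(x))
  x
}

#' Maximum correlation of a reference image against every stack image
#'
#' The reference (query) image is rotated and mirrored once into its search
#' variants; every stack image is then scanned translationally against all
#' variants by FFT. This is equivalent (up to interpolation, since the mask
#' is isotropic) to rotating each stack image, and makes the per-image cost
#' independent of the rotational grid preparation.
#'
#' Images with zero variance inside the mask yield `NA` with a warning
#' rather than aborting the stack.
#'
#' @param ref The fixed query image (64 x 64).
#' @param stack An `ImageStack` (or 64 x 64 x M array).
#' @param psi_step Rotational step in degrees.
#' @param max_shift Maximum translation in pixels.
#' @param details If `TRUE`, return a data frame with `cc`, `psi`,
#'   `mirrored`, `dx`, `dy` per image; otherwise the vector of `cc_max`.
#' @return Numeric vector (or data frame) with one entry per stack image,
#'   order-preserving.
#' @export
align_stack_to_reference <- function(ref, stack, psi_step = 2, max_shift = 10,
                                     details = FALSE) {
  pix <- if (inherits(stack, "ImageStack")) stack$pixels else stack
  stopifnot(length(dim(pix)) == 3)
  ref <- as_image(ref)
  mask <- circular_mask()
  var <- make_variants(ref, psi_step, mask)
  res <- .align_scan_cpp(var$pixels, pix, mask, as.integer(max_shift))
  res[, 1] <- pmin(1, pmax(-1, res[, 1]))  # strip FP roundoff beyond +/-1
  if (anyNA(res[, 1])) {
    warning(sprintf("%d stack image(s) constant within mask: recorded as NA",
                    sum(is.na(res[, 1]))))
  }
  if (!details) return(res[, 1])
  v <- ifelse(is.na(res[, 1]), 1, res[, 2])
  data.frame(cc = res[, 1],
             psi = signed_angle(var$psi[v]),
             mirrored = var$mirrored[v],
             dx = res[, 3], dy = res[, 4])
}
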