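# Internal numeric and geometry helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (GMM
#' initialization, multi-start superposition, fixture generation) never
#' disturb the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_shapesearch <- function(msg, class) {
  stop(structure(
    class = c(class, "shapesearch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## ---- quaternions and rotations -------------------------------------------
## Convention: unit quaternion q = (w, x, y, z); rotations are proper
## (det(R) = +1) and act on column vectors, v' = R %*% v.

quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop_shapesearch("zero quaternion", "shapesearch_domain_error")
  q / n
}

quat_to_mat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

# axis-angle vector (radians) -> rotation matrix
rotvec_to_mat <- function(rv) {
  th <- sqrt(sum(rv^2))
  if (th < 1e-12) return(diag(3))
  a <- rv / th
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_angle_deg <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

# uniform random unit quaternion (Shoemake); uses current RNG state
random_quaternion <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic right-handed orthonormal basis (e1, e2, v) for a view axis v;
# for v = +z the image axes coincide with the map x and y axes
view_basis <- function(v) {
  v <- v / sqrt(sum(v^2))
  if (abs(v[3]) > 0.9999) {
    e1 <- c(1, 0, 0)
    e2 <- cross3(v, e1)
  } else {
    e1 <- c(-v[2], v[1], 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(v, e1)
  }
  cbind(e1, e2, v, deparse.level = 0)
}

## ---- interpolation --------------------------------------------------------

# Trilinear interpolation of a 3D array at fractional 1-based voxel indices.
# Points outside the grid contribute 0.
trilinear_sample <- function(grid, pts) {
  d <- dim(grid)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n <- length(x)
  out <- numeric(n)
  gather <- function(i, j, k) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    v <- numeric(n)
    if (any(ok)) {
      idx <- (k[ok] - 1) * (d[1] * d[2]) + (j[ok] - 1) * d[1] + i[ok]
      v[ok] <- grid[idx]
    }
    v
  }
  out <- gather(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    gather(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz) +
    gather(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz) +
    gather(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz) +
    gather(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz +
    gather(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz +
    gather(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz +
    gather(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out
}

# Bilinear interpolation of a matrix at fractional 1-based indices; outside -> 0
bilinear_sample <- function(img, pts) {
  d <- dim(img)
  x <- pts[, 1]; y <- pts[, 2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  n <- length(x)
  gather <- function(i, j) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
    v <- numeric(n)
    if (any(ok)) v[ok] <- img[(j[ok] - 1) * d[1] + i[ok]]
    v
  }
  gather(x0, y0) * (1 - fx) * (1 - fy) +
    gather(x0 + 1, y0) * fx * (1 - fy) +
    gather(x0, y0 + 1) * (1 - fx) * fy +
    gather(x0 + 1, y0 + 1) * fx * fy
}

# Rotate a square image counterclockwise by psi degrees about its center
# (bilinear resampling, zero padding). Axis 1 is x, axis 2 is y.
rotate_image <- function(img, psi_deg) {
  n <- nrow(img)
  ctr <- (n + 1) / 2
  th <- psi_deg * pi / 180
  cs <- cos(th); sn <- sin(th)
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  dx <- ij$i - ctr; dy <- ij$j - ctr
  # inverse rotation of output coordinates into the source image
  sx <- ctr + cs * dx + sn * dy
  sy <- ctr - sn * dx + cs * dy
  matrix(bilinear_sample(img, cbind(sx, sy)), n, n)
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels)
gaussian_smooth3 <- function(grid, sigma) {
  if (sigma <= 0) return(grid)
  d <- dim(grid)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    da <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- dim(ap)[1]
    # banded convolution matrix, zero boundary
    K <- matrix(0, m, m)
    for (o in seq(-r, r)) {
      idx <- seq_len(m)
      src <- idx + o
      ok <- src >= 1 & src <= m
      K[cbind(idx[ok], src[ok])] <- K[cbind(idx[ok], src[ok])] + k[o + r + 1]
    }
    res <- K %*% matrix(ap, nrow = m)
    dim(res) <- dim(ap)
    aperm(res, order(perm))
  }
  g <- smooth_axis(grid, 1)
  g <- smooth_axis(g, 2)
  smooth_axis(g, 3)
}
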