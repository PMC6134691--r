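# Minimal MRC2014 reader/writer (mode 2 float output; modes 0/1/2 on read).
# No MRC parser ships with the pre-installed R stack, so the format is handled
# here directly. Little-endian files only; the 'MAP ' magic is verified.
#
# Coordinate convention (used throughout the package): voxel i (1-based) is
# centered at origin + (i - 0.5) * spacing along each axis; the first array
# index is the fastest-varying (x) axis, as in the MRC column ordering.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 density file
#'
#' @param path Path to an MRC file.
#' @return A list with `data` (3D numeric array), `spacing` (length-3, in
#'   angstrom per voxel) and `origin` (length-3, angstrom).
#' @keywords internal
read_mrc <- function(path) {
  if (!file.exists(path)) {
    stop_shapesearch(sprintf("MRC file not found: %s", path),
                     "shapesearch_format_error")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = MRC_HEADER_BYTES)
  if (length(hdr_raw) < MRC_HEADER_BYTES) {
    stop_shapesearch("truncated MRC header (field: header)",
                     "shapesearch_format_error")
  }
  magic <- rawToChar(hdr_raw[209:212])
  if (magic != "MAP ") {
    stop_shapesearch("not an MRC2014 file: bad magic (field: map)",
                     "shapesearch_format_error")
  }
  ints <- readBin(hdr_raw, "integer", n = 56, size = 4, endian = "little")
  flts <- readBin(hdr_raw, "double", n = 56, size = 4, endian = "little")
  nx <- ints[1]; ny <- ints[2]; nz <- ints[3]
  mode <- ints[4]
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 4096 || ny > 4096 || nz > 4096) {
    stop_shapesearch(
      sprintf("implausible MRC dimensions %d x %d x %d (field: nx/ny/nz)",
              nx, ny, nz), "shapesearch_format_error")
  }
  if (!mode %in% c(0L, 1L, 2L)) {
    stop_shapesearch(sprintf("unsupported MRC mode %d (field: mode)", mode),
                     "shapesearch_format_error")
  }
  mx <- ints[8]; my <- ints[9]; mz <- ints[10]
  if (mx <= 0 || my <= 0 || mz <= 0) {
    stop_shapesearch("non-positive sampling counts (field: mx/my/mz)",
                     "shapesearch_format_error")
  }
  cella <- flts[11:13]
  spacing <- cella / c(mx, my, mz)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  mapc <- ints[17]; mapr <- ints[18]; maps <- ints[19]
  axis_order <- c(mapc, mapr, maps)
  if (!setequal(axis_order, 1:3)) {
    stop_shapesearch("invalid axis correspondence (field: mapc/mapr/maps)",
                     "shapesearch_format_error")
  }
  nsymbt <- ints[24]
  origin <- flts[50:52]
  if (nsymbt > 0) readBin(con, "raw", n = nsymbt)
  nvox <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = nvox, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = nvox, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "double", n = nvox, size = 4, endian = "little")
  )
  if (length(vals) < nvox) {
    stop_shapesearch(
      sprintf("truncated MRC data: expected %.0f voxels, got %d (field: data)",
              nvox, length(vals)), "shapesearch_format_error")
  }
  arr <- array(vals, dim = c(nx, ny, nz))
  if (!identical(axis_order, c(1L, 2L, 3L))) {
    # permute so that array index 1,2,3 correspond to crystal axes x,y,z
    perm <- order(axis_order)
    arr <- aperm(arr, perm)
    spacing <- spacing  # cella is per crystal axis already
  }
  list(data = arr, spacing = spacing, origin = origin)
}

#' Write an MRC2014 density file (mode 2, 32-bit float)
#'
#' @param path Output path.
#' @param data 3D numeric array.
#' @param spacing Voxel spacing, scalar or length-3 (angstrom).
#' @param origin Map origin, length-3 (angstrom).
#' @keywords internal
write_mrc <- function(path, data, spacing = 1, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  origin <- rep_len(as.numeric(origin), 3)
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                     # nx ny nz
  wi(2)                     # mode 2: float32
  wi(c(0, 0, 0))            # nxstart nystart nzstart
  wi(d)                     # mx my mz
  wf(d * spacing)           # cella
  wf(c(90, 90, 90))         # cellb
  wi(c(1, 2, 3))            # mapc mapr maps
  rng <- range(data)
  wf(c(rng[1], rng[2], mean(data)))  # dmin dmax dmean
  wi(1)                     # ispg
  wi(0)                     # nsymbt
  wi(rep(0, 25))            # extra
  wf(origin)                # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.numeric(data)))    # rms
  wi(1)                     # nlabl
  lab <- sprintf("%-80s", "shapesearch map")
  writeBin(charToRaw(lab), con)
  writeBin(raw(80 * 9), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}
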