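#' Single-channel 3D intensity image with physical voxel sizes
#'
#' A `vol_image` wraps a numeric 3D array stored in `(y, x, z)` order together
#' with its physical calibration. Defaults follow standard confocal smiFISH
#' acquisition: 70 nm lateral pixels, 300 nm z-spacing, 8-bit depth.
#'
#' Coordinate convention (used throughout the package): a voxel with 0-based
#' index `i` along an axis covers the half-open interval `[i, i+1)` in pixel
#' units, so its centre sits at `i + 0.5`; physical positions in nm are pixel
#' units multiplied by the voxel size for that axis. [nm_to_index()] and
#' [index_to_nm()] convert between the two.
#'
#' @param data numeric array, `dim = c(ny, nx, nz)` (a matrix is promoted to a
#'   single z-plane).
#' @param voxel_xy lateral voxel size in nm.
#' @param voxel_z axial voxel size (z-spacing) in nm.
#' @param bit_depth integer bit depth of the acquisition (intensities live in
#'   `[0, 2^bit_depth - 1]`).
#' @return An object of class `vol_image`.
#' @export
vol_image <- function(data, voxel_xy = 70, voxel_z = 300, bit_depth = 8L) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L,
            all(dim(data) >= 1L), voxel_xy > 0, voxel_z > 0, bit_depth >= 1)
  structure(
    list(data = data, voxel_xy = voxel_xy, voxel_z = voxel_z,
         bit_depth = as.integer(bit_depth)),
    class = "vol_image"
  )
}

#' @export
print.vol_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol_image> %d x %d x %d (y,x,z), %.0f nm xy / %.0f nm z, %d-bit\n",
              d[1], d[2], d[3], x$voxel_xy, x$voxel_z, x$bit_depth))
  invisible(x)
}

#' @export
dim.vol_image <- function(x) dim(x$data)

#' Convert physical nm positions to 0-based voxel indices
#'
#' The voxel containing continuous position `nm` is `floor(nm / voxel_size)`.
#'
#' @param nm numeric vector of positions in nm.
#' @param voxel_size voxel size along that axis in nm.
#' @return Integer 0-based indices.
#' @export
nm_to_index <- function(nm, voxel_size) as.integer(floor(nm / voxel_size))

#' Convert 0-based voxel indices to the physical nm position of voxel centres
#'
#' @param index integer 0-based indices.
#' @param voxel_size voxel size along that axis in nm.
#' @return Positions in nm of the voxel centres.
#' @export
index_to_nm <- function(index, voxel_size) (index + 0.5) * voxel_size

#' Read a multi-page TIFF stack as a `vol_image`
#'
#' Pages are interpreted as z-planes (ImageJ convention); pixel values are
#' rescaled back to the stated bit depth (the tiff package normalises to
#' `[0, 1]` on read).
#'
#' @param path TIFF file path.
#' @inheritParams vol_image
#' @return A [vol_image()].
#' @export
read_stack <- function(path, voxel_xy = 70, voxel_z = 300, bit_depth = 8L) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  maxval <- 2^bit_depth - 1
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * maxval
  vol_image(arr, voxel_xy = voxel_xy, voxel_z = voxel_z, bit_depth = bit_depth)
}

#' Write a `vol_image` (or 2D matrix) as a multi-page TIFF
#'
#' @param x a [vol_image()], 3D array or matrix.
#' @param path output file path.
#' @param bit_depth bits per sample to write (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, bit_depth = NULL) {
  if (inherits(x, "vol_image")) {
    if (is.null(bit_depth)) bit_depth <- x$bit_depth
    x <- x$data
  }
  if (is.null(bit_depth)) bit_depth <- 8L
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  maxval <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(x)[3]),
                  function(k) pmin(pmax(x[, , k], 0), maxval) / maxval)
  tiff::writeTIFF(pages, path, bits.per.sample = if (bit_depth > 8) 16L else 8L)
  invisible(path)
}

#' Write a 2D integer label mask as a 16-bit TIFF
#'
#' @param mask integer matrix of labels (0 = background).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0), max(mask) < 65536)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit label TIFF written by [write_label_mask()]
#'
#' @param path file path.
#' @return Integer label matrix.
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  storage.mode(m) <- "double"
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}

# evaluate `code` under a fixed seed, restoring the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}
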