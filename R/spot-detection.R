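#' A set of sub-voxel 3D spot coordinates
#'
#' Spots are stored in physical nm with their intensity and fit quality, plus
#' the channel name and the exact detection settings that produced them —
#' recorded verbatim so that analyses comparing experimental conditions can
#' assert that identical settings were used.
#'
#' @param spots data frame with at least columns `x_nm`, `y_nm`, `z_nm`,
#'   `intensity`; optional `quality`, `flags`, `cell_id`, `partner`.
#' @param channel channel name.
#' @param settings named list of the detection settings used.
#' @return An object of class `spot_set`.
#' @export
spot_set <- function(spots, channel = "fish", settings = list()) {
  stopifnot(is.data.frame(spots),
            all(c("x_nm", "y_nm", "z_nm", "intensity") %in% names(spots)))
  for (col in c("quality", "flags"))
    if (!col %in% names(spots))
      spots[[col]] <- if (col == "flags") rep("", nrow(spots)) else NA_real_
  structure(list(spots = spots, channel = channel, settings = settings),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> channel '%s': %d spot(s)\n",
              x$channel, nrow(x$spots)))
  invisible(x)
}

#' Number of spots in a `spot_set`
#' @param x a [spot_set()].
#' @param ... ignored.
#' @return Integer count.
#' @export
n_spots <- function(x, ...) nrow(x$spots)

#' Detect single-molecule FISH spots in 3D with sub-voxel localization
#'
#' Difference-of-Gaussians band-pass at the stated spot scales, 3D local
#' maxima above `threshold` (raw intensity at the candidate voxel), sub-voxel
#' refinement, and merging of duplicate maxima closer than one sigma (the
#' brighter one is kept). Coordinates are returned in nm. Two refiners are
#' available: `"gauss"` (default) fits a three-point parabola to the log of
#' the baseline-subtracted smoothed intensity along each axis — the
#' one-dimensional Gaussian maximum-likelihood fit, exact for an isolated
#' Gaussian peak — and falls back to the centroid where the fit is
#' ill-posed; `"centroid"` is the intensity-weighted centroid in a
#' `+-2 sigma` window after subtracting the window minimum. Candidates whose
#' refinement window is clipped by the stack border are kept and flagged
#' `"border"` rather than dropped. Deterministic.
#'
#' An all-zero (or blank) stack yields an empty spot set, not an error.
#'
#' @param stack a [vol_image()].
#' @param sigma_xy expected spot SD in pixels (lateral).
#' @param sigma_z expected spot SD in z-slices (axial).
#' @param threshold minimum raw intensity at a candidate maximum.
#' @param channel channel name recorded in the output.
#' @param refine sub-voxel refiner: `"gauss"` (log-parabola Gaussian fit,
#'   default) or `"centroid"`.
#' @param max_density sanity bound on spots per megavoxel; exceeding it
#'   triggers a warning that the threshold sits below the noise floor.
#' @return A [spot_set()] with columns `x_nm, y_nm, z_nm, intensity, quality,
#'   flags` (`quality` is the band-pass response at the peak).
#' @export
detect_spots <- function(stack, sigma_xy = 1.3, sigma_z = 1.0, threshold = 0,
                         channel = "fish", refine = c("gauss", "centroid"),
                         max_density = 2000) {
  stopifnot(inherits(stack, "vol_image"), sigma_xy > 0, sigma_z > 0,
            threshold >= 0)
  refine <- match.arg(refine)
  arr <- stack$data
  settings <- list(sigma_xy = sigma_xy, sigma_z = sigma_z,
                   threshold = threshold,
                   algorithm = paste0("dog+", refine),
                   voxel_xy = stack$voxel_xy, voxel_z = stack$voxel_z)
  empty <- spot_set(data.frame(x_nm = numeric(), y_nm = numeric(),
                               z_nm = numeric(), intensity = numeric(),
                               quality = numeric(), flags = character()),
                    channel = channel, settings = settings)
  if (all(arr == arr[1])) return(empty)

  g1 <- gaussian_blur3d(arr, sigma_xy, sigma_z)
  g2 <- gaussian_blur3d(arr, 1.6 * sigma_xy, 1.6 * sigma_z)
  dog <- g1 - g2

  cand <- local_maxima3d(dog)
  cand <- cand[dog[cand] > 0 & arr[cand] >= threshold]
  if (!length(cand)) return(empty)

  d <- dim(arr)
  ci <- arrayInd(cand, d)                       # 1-based (y, x, z)
  wxy <- max(1L, ceiling(2 * sigma_xy)); wz <- max(1L, ceiling(2 * sigma_z))
  res <- matrix(NA_real_, nrow(ci), 5)          # y, x, z (0-based), int, qual
  border <- logical(nrow(ci))
  for (i in seq_len(nrow(ci))) {
    ys <- (ci[i, 1] - wxy):(ci[i, 1] + wxy)
    xs <- (ci[i, 2] - wxy):(ci[i, 2] + wxy)
    zs <- (ci[i, 3] - wz):(ci[i, 3] + wz)
    border[i] <- any(ys < 1 | ys > d[1]) || any(xs < 1 | xs > d[2]) ||
                 any(zs < 1 | zs > d[3])
    ys <- ys[ys >= 1 & ys <= d[1]]
    xs <- xs[xs >= 1 & xs <= d[2]]
    zs <- zs[zs >= 1 & zs <= d[3]]
    w <- arr[ys, xs, zs, drop = FALSE]
    w <- w - min(w)
    tw <- sum(w)
    if (tw <= 0) {
      res[i, 1:3] <- ci[i, ] - 0.5              # flat window: keep the voxel
    } else {
      res[i, 1] <- sum(apply(w, 1, sum) * (ys - 0.5)) / tw
      res[i, 2] <- sum(apply(w, 2, sum) * (xs - 0.5)) / tw
      res[i, 3] <- sum(apply(w, 3, sum) * (zs - 0.5)) / tw
    }
    if (refine == "gauss") {
      base <- min(g1[ys, xs, zs])
      for (ax in 1:3) {
        dlt <- log_parabola_offset(g1, ci[i, ], ax, d, base)
        if (!is.na(dlt)) res[i, ax] <- ci[i, ax] - 0.5 + dlt
      }
    }
    res[i, 4] <- arr[ci[i, 1], ci[i, 2], ci[i, 3]]
    res[i, 5] <- dog[ci[i, 1], ci[i, 2], ci[i, 3]]
  }

  keep <- merge_duplicates(res, sigma_xy, sigma_z)
  res <- res[keep, , drop = FALSE]
  border <- border[keep]

  df <- data.frame(
    x_nm = res[, 2] * stack$voxel_xy,
    y_nm = res[, 1] * stack$voxel_xy,
    z_nm = res[, 3] * stack$voxel_z,
    intensity = res[, 4],
    quality = res[, 5],
    flags = ifelse(border, "border", "")
  )
  if (nrow(df) / prod(d) * 1e6 > max_density)
    warning("spot density exceeds ", max_density,
            " per megavoxel; threshold may be below the noise floor")
  spot_set(df, channel = channel, settings = settings)
}

# sub-voxel offset along one axis from a 3-point parabola fitted to the log
# of the baseline-subtracted smoothed intensity; exact for a Gaussian peak.
# NA when the fit is ill-posed (border, non-positive values, non-concave).
log_parabola_offset <- function(g, centre, axis, d, base) {
  if (centre[axis] <= 1L || centre[axis] >= d[axis]) return(NA_real_)
  idx <- function(off) {
    p <- centre; p[axis] <- p[axis] + off
    g[p[1], p[2], p[3]]
  }
  f <- c(idx(-1L), idx(0L), idx(1L)) - base + 1e-9
  if (any(f <= 0)) return(NA_real_)
  l <- log(f)
  den <- l[1] - 2 * l[2] + l[3]
  if (den >= -1e-12) return(NA_real_)
  delta <- 0.5 * (l[1] - l[3]) / den
  if (abs(delta) > 1) return(NA_real_)
  delta
}

# linear indices of voxels >= all 26 neighbours (plateaus included)
local_maxima3d <- function(arr) {
  d <- dim(arr)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
  ok <- array(TRUE, d)
  for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
    if (dy == 0 && dx == 0 && dz == 0) next
    nb <- pad[(2 + dy):(d[1] + 1 + dy),
              (2 + dx):(d[2] + 1 + dx),
              (2 + dz):(d[3] + 1 + dz)]
    ok <- ok & (arr >= nb)
  }
  which(ok)
}

# keep the brighter of any pair closer than 1 sigma (anisotropy-normalized);
# equal intensities resolve to the earlier (lower-index) spot
merge_duplicates <- function(res, sigma_xy, sigma_z) {
  n <- nrow(res)
  if (n <= 1) return(rep(TRUE, n))
  ord <- order(-res[, 4], seq_len(n))
  keep <- logical(n)
  for (i in ord) {
    sel <- which(keep)
    if (length(sel)) {
      dd <- ((res[sel, 1] - res[i, 1]) / sigma_xy)^2 +
            ((res[sel, 2] - res[i, 2]) / sigma_xy)^2 +
            ((res[sel, 3] - res[i, 3]) / sigma_z)^2
      if (any(dd < 1)) next
    }
    keep[i] <- TRUE
  }
  keep
}

#' Restrict a spot set to the cytoplasm of one cell
#'
#' Containment is evaluated in 2D: a spot belongs to a cell if its `(y, x)`
#' position falls on a cytoplasm pixel of that cell; z is unrestricted,
#' mirroring 2D outlines combined with 3D detection. Kept plus discarded
#' counts always equal the input count.
#'
#' @param spots a [spot_set()].
#' @param geometry a [cell_geometry()].
#' @param cell_id cell label (must exist in `geometry`).
#' @return A [spot_set()] of the kept spots; attribute `discarded` holds the
#'   number removed.
#' @export
filter_spots <- function(spots, geometry, cell_id) {
  stopifnot(inherits(spots, "spot_set"), inherits(geometry, "cell_geometry"))
  cyto <- cytoplasm_mask(geometry, cell_id)
  df <- spots$spots
  iy <- nm_to_index(df$y_nm, attr_voxel_xy(spots, geometry)) + 1L
  ix <- nm_to_index(df$x_nm, attr_voxel_xy(spots, geometry)) + 1L
  inside <- iy >= 1 & iy <= nrow(cyto) & ix >= 1 & ix <= ncol(cyto)
  inside[inside] <- cyto[cbind(iy[inside], ix[inside])]
  out <- spot_set(df[inside, , drop = FALSE], channel = spots$channel,
                  settings = spots$settings)
  attr(out, "discarded") <- sum(!inside)
  out
}

# lateral voxel size for mask containment; spot sets produced by this package
# record it in their settings, otherwise the acquisition default is used
attr_voxel_xy <- function(spots, geometry) {
  vs <- spots$settings$voxel_xy
  if (!is.null(vs)) vs else 70
}

#' Write / read the spot CSV interchange format
#'
#' Columns: `channel, x_nm, y_nm, z_nm, intensity, quality, flags` (plus any
#' extra columns present, e.g. `cell_id` or ground-truth `partner`).
#'
#' @param spots a [spot_set()].
#' @param path CSV path.
#' @return `write_spots`: `path` invisibly. `read_spots`: a [spot_set()].
#' @export
write_spots <- function(spots, path) {
  stopifnot(inherits(spots, "spot_set"))
  df <- spots$spots
  df <- cbind(channel = spots$channel, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spots
#' @param channel if the file holds several channels, which one to load
#'   (default: all rows).
#' @export
read_spots <- function(path, channel = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ch <- if (!is.null(channel)) channel else
    if ("channel" %in% names(df)) df$channel[1] else "fish"
  if (!is.null(channel) && "channel" %in% names(df))
    df <- df[df$channel == channel, , drop = FALSE]
  df$channel <- NULL
  if (!"intensity" %in% names(df)) df$intensity <- NA_real_
  if (!"flags" %in% names(df)) df$flags <- ""
  df$flags[is.na(df$flags)] <- ""
  spot_set(df, channel = ch, settings = list(source = path))
}
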