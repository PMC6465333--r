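#' Parameters of a synthetic IF-smiFISH scene
#'
#' Bundles and validates every knob of the scene simulator. Geometry defaults
#' follow standard confocal smiFISH acquisition (70 nm lateral pixels, 300 nm
#' z-spacing, 8-bit); cells are simulated as 2D ellipses extruded over z with
#' concentric elliptical nuclei, matching the common analysis design of 2D
#' outlines combined with 3D spot detection.
#'
#' The scene carries one or two diffraction-limited FISH spot channels
#' (`fish_a`, `fish_b`). For two-colour scenes a fraction `rho` of `fish_b`
#' spots is placed at a `fish_a` partner position plus isotropic Gaussian
#' jitter of `jitter_sd_nm` per axis. The IF channel is flat cytoplasmic
#' background `if_background` elevated to `if_background * r` in a small
#' neighbourhood of each `fish_a` spot, so the true per-cell enrichment ratio
#' equals `r` by construction.
#'
#' @param shape stack shape in voxels, named `c(z=, y=, x=)`.
#' @param voxel_xy,voxel_z voxel sizes in nm.
#' @param n_cells number of cells; the generator fails if they cannot be
#'   placed without overlap.
#' @param cell_radius,nucleus_radius nominal radii in pixels
#'   (`nucleus_radius <= 0.8 * cell_radius`).
#' @param spots_per_cell spots per cell and channel.
#' @param n_channels 1 (single-colour) or 2 (dual-colour FISH).
#' @param rho co-localized fraction of `fish_b` spots, in `[0, 1]`; per cell,
#'   exactly `round(rho * spots_per_cell)` spots are partnered.
#' @param jitter_sd_nm per-axis SD (nm) of the partner displacement.
#' @param r IF enrichment factor at RNA positions (`r >= 0`).
#' @param if_background,if_noise_sd IF cytoplasmic background level and
#'   Gaussian noise SD (intensity units).
#' @param fish_background uniform in-cell background of the FISH channels
#'   (diffuse cellular signal; lets cells be segmented in the FISH channel).
#' @param dapi_level nucleus intensity in the DAPI channel.
#' @param spot_amplitude peak amplitude of a rendered spot above background.
#' @param sigma_xy,sigma_z spot Gaussian SD in pixels (xy) and slices (z).
#' @param camera_noise_sd Gaussian camera noise SD for FISH/DAPI channels.
#' @param bit_depth rendered bit depth; values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param spot_min_dist_nm minimum pairwise 3D distance between same-channel
#'   spots within a cell (0 = unconstrained).
#' @param z_margin margin in slices kept free of spots at the axial borders.
#' @param seed RNG seed; each operation derives its own stream from it.
#' @return A validated list of class `scene_params`.
#' @export
scene_params <- function(shape = c(z = 8L, y = 256L, x = 256L),
                         voxel_xy = 70, voxel_z = 300,
                         n_cells = 4L, cell_radius = 24, nucleus_radius = 10,
                         spots_per_cell = 80L, n_channels = 2L,
                         rho = 0.5, jitter_sd_nm = 50,
                         r = 2, if_background = 60, if_noise_sd = 6,
                         fish_background = 8, dapi_level = 180,
                         spot_amplitude = 150, sigma_xy = 1.3, sigma_z = 1.0,
                         camera_noise_sd = 15, bit_depth = 8L,
                         spot_min_dist_nm = 0, z_margin = 2, seed = 1L) {
  shape <- shape[c("z", "y", "x")]
  stopifnot(!anyNA(shape), all(shape >= 1),
            voxel_xy > 0, voxel_z > 0,
            n_cells >= 1, cell_radius > 0, nucleus_radius > 0,
            spots_per_cell >= 0, n_channels %in% 1:2,
            rho >= 0, rho <= 1, jitter_sd_nm >= 0, r >= 0,
            if_background > 0, if_noise_sd >= 0, fish_background >= 0,
            spot_amplitude > 0, sigma_xy > 0, sigma_z > 0,
            camera_noise_sd >= 0, bit_depth >= 1,
            spot_min_dist_nm >= 0, z_margin >= 0)
  if (nucleus_radius > 0.8 * cell_radius)
    stop("nucleus_radius must be <= 0.8 * cell_radius so the nucleus lies ",
         "strictly inside the cell")
  if (shape[["z"]] <= 2 * z_margin && spots_per_cell > 0)
    stop("shape z = ", shape[["z"]], " leaves no room for spots with ",
         "z_margin = ", z_margin)
  p <- as.list(environment())
  structure(p, class = "scene_params")
}

#' Simulate a ground-truth IF-smiFISH scene
#'
#' Places non-overlapping elliptical cells with concentric nuclei, draws
#' cytoplasmic spot positions per channel, and records the co-localization
#' partner structure. Deterministic for a given `params$seed`. Every spot
#' lies inside the cytoplasm of exactly one cell.
#'
#' @param params a [scene_params()] object.
#' @return A `synthetic_scene`: list with `geometry` ([cell_geometry()]),
#'   `spots` (named list of [spot_set()]s; `fish_b` spots carry a `partner`
#'   column indexing their `fish_a` partner, `NA` if none), `r`, `rho` and
#'   `params`.
#' @export
simulate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, {
    ny <- params$shape[["y"]]; nx <- params$shape[["x"]]
    nz <- params$shape[["z"]]

    cells <- place_cells(params, ny, nx)
    cell_m <- matrix(0L, ny, nx)
    nuc_m <- matrix(0L, ny, nx)
    yy <- row(cell_m) - 0.5   # pixel centres, 0-based continuous coords
    xx <- col(cell_m) - 0.5
    scale <- params$nucleus_radius / params$cell_radius
    for (i in seq_len(nrow(cells))) {
      e <- ((yy - cells$cy[i]) / cells$ay[i])^2 +
           ((xx - cells$cx[i]) / cells$ax[i])^2
      cell_m[e <= 1] <- i
      nuc_m[e <= scale^2] <- i
    }
    geometry <- cell_geometry(cell_m, nuc_m)

    spots_a <- draw_channel_spots(params, geometry, nz)
    spots <- list(fish_a = make_true_spot_set(spots_a, "fish_a", params))
    if (params$n_channels == 2L) {
      spots_b <- draw_partnered_spots(params, geometry, nz, spots_a)
      spots$fish_b <- make_true_spot_set(spots_b, "fish_b", params)
    }
    structure(list(geometry = geometry, spots = spots,
                   r = params$r, rho = params$rho,
                   cells = cells, params = params),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d cell(s), channels: %s, r = %g, rho = %g\n",
              length(x$geometry$labels),
              paste(names(x$spots), collapse = ", "), x$r, x$rho))
  invisible(x)
}

place_cells <- function(params, ny, nx) {
  rmax <- params$cell_radius
  if (2 * rmax + 2 > min(ny, nx))
    stop("cell_radius ", rmax, " does not fit the image shape")
  out <- data.frame(cy = numeric(), cx = numeric(),
                    ay = numeric(), ax = numeric())
  for (i in seq_len(params$n_cells)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      ay <- params$cell_radius * runif(1, 0.85, 1.0)
      ax <- params$cell_radius * runif(1, 0.85, 1.0)
      cy <- runif(1, rmax + 1, ny - rmax - 1)
      cx <- runif(1, rmax + 1, nx - rmax - 1)
      if (nrow(out) == 0 ||
          all(sqrt((out$cy - cy)^2 + (out$cx - cx)^2) >
              pmax(out$ay, out$ax) + max(ay, ax) + 2)) {
        out[i, ] <- c(cy, cx, ay, ax)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", params$n_cells, " non-overlapping cells of ",
           "radius ", params$cell_radius, " in a ", ny, " x ", nx,
           " image; reduce n_cells or cell_radius, or enlarge shape")
  }
  out
}

# uniform spot draw in the cytoplasm of each cell; pixel-unit coords
draw_channel_spots <- function(params, geometry, nz) {
  res <- lapply(geometry$labels, function(l) {
    cyto <- which(cytoplasm_mask(geometry, l), arr.ind = TRUE)
    n <- params$spots_per_cell
    if (n == 0) return(NULL)
    acc <- matrix(NA_real_, n, 3)
    for (k in seq_len(n)) {
      for (try in seq_len(200L)) {
        j <- sample.int(nrow(cyto), 1L)
        cand <- c(cyto[j, 1] - 1 + runif(1),      # y, 0-based pixel units
                  cyto[j, 2] - 1 + runif(1),      # x
                  runif(1, params$z_margin, nz - params$z_margin))
        if (params$spot_min_dist_nm <= 0 || k == 1L ||
            min_dist_nm(cand, acc[seq_len(k - 1L), , drop = FALSE], params) >=
              params$spot_min_dist_nm) {
          acc[k, ] <- cand
          break
        }
      }
      if (anyNA(acc[k, ]))
        stop("could not satisfy spot_min_dist_nm = ", params$spot_min_dist_nm,
             " for ", n, " spots in cell ", l)
    }
    data.frame(cell_id = l, y = acc[, 1], x = acc[, 2], z = acc[, 3],
               partner = NA_integer_)
  })
  do.call(rbind, res)
}

min_dist_nm <- function(cand, prev, params) {
  d <- sqrt(((prev[, 1] - cand[1]) * params$voxel_xy)^2 +
            ((prev[, 2] - cand[2]) * params$voxel_xy)^2 +
            ((prev[, 3] - cand[3]) * params$voxel_z)^2)
  if (length(d)) min(d) else Inf
}

# channel-b spots: per cell, round(rho * n) partnered with jitter, rest uniform
draw_partnered_spots <- function(params, geometry, nz, spots_a) {
  uniform <- draw_channel_spots(params, geometry, nz)
  if (is.null(uniform) || params$spots_per_cell == 0) return(uniform)
  for (l in geometry$labels) {
    rows_b <- which(uniform$cell_id == l)
    rows_a <- which(spots_a$cell_id == l)
    n_p <- round(params$rho * length(rows_b))
    if (n_p == 0) next
    partners <- rows_a[sample.int(length(rows_a), n_p)]
    cyto <- cytoplasm_mask(geometry, l)
    for (k in seq_len(n_p)) {
      pa <- as.numeric(spots_a[partners[k], c("y", "x", "z")])
      pos <- jittered_position(pa, params, cyto, nz)
      uniform[rows_b[k], c("y", "x", "z")] <- as.list(pos)
      uniform$partner[rows_b[k]] <- partners[k]
    }
  }
  uniform
}

# partner displacement: per-axis Gaussian truncated at 3 SD (so the stated
# jitter genuinely bounds every partner distance), re-drawn until the spot
# stays inside the cytoplasm and the axial margins
jittered_position <- function(pa, params, cyto, nz) {
  sds <- params$jitter_sd_nm /
    c(params$voxel_xy, params$voxel_xy, params$voxel_z)
  for (try in seq_len(200L)) {
    jit <- rnorm(3, 0, sds)
    if (any(abs(jit) > 3 * sds)) next
    pos <- pa + jit
    iy <- floor(pos[1]) + 1; ix <- floor(pos[2]) + 1
    if (iy >= 1 && iy <= nrow(cyto) && ix >= 1 && ix <= ncol(cyto) &&
        cyto[iy, ix] && pos[3] >= params$z_margin &&
        pos[3] <= nz - params$z_margin)
      return(pos)
  }
  pa   # jitter could not stay inside the cytoplasm: collapse onto the partner
}

make_true_spot_set <- function(df, channel, params) {
  if (is.null(df))
    df <- data.frame(cell_id = integer(), y = numeric(), x = numeric(),
                     z = numeric(), partner = integer())
  spot_set(
    data.frame(cell_id = df$cell_id,
               x_nm = df$x * params$voxel_xy,
               y_nm = df$y * params$voxel_xy,
               z_nm = df$z * params$voxel_z,
               intensity = rep(params$spot_amplitude, nrow(df)),
               quality = rep(NA_real_, nrow(df)),
               flags = rep("", nrow(df)),
               partner = df$partner),
    channel = channel,
    settings = list(source = "simulated", seed = params$seed,
                    voxel_xy = params$voxel_xy, voxel_z = params$voxel_z)
  )
}

#' Render the multi-channel 3D stacks of a synthetic scene
#'
#' FISH channels are sums of anisotropic 3D Gaussians at the true spot
#' positions over a flat in-cell background, plus Gaussian camera noise,
#' clipped to the bit depth. The IF channel is `if_background` inside cells,
#' raised to `if_background * r` within a radius `sigma_xy` (and `sigma_z`
#' axially) of each `fish_a` spot. DAPI is the nucleus mask at `dapi_level`.
#' Deterministic for a given scene seed and channel selection.
#'
#' @param scene a [simulate_scene()] result.
#' @param channels channels to render, subset of
#'   `c("dapi", "if", "fish_a", "fish_b")`.
#' @return Named list of [vol_image()]s with attribute `report` (per-channel
#'   count of voxels clipped at the top of the intensity range).
#' @export
render_stacks <- function(scene,
                          channels = c("dapi", "if", names(scene$spots))) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  channels <- intersect(channels, c("dapi", "if", names(scene$spots)))
  with_seed(p$seed + 1L, {
    ny <- p$shape[["y"]]; nx <- p$shape[["x"]]; nz <- p$shape[["z"]]
    maxval <- 2^p$bit_depth - 1
    cell3d <- array(rep(scene$geometry$cells > 0L, nz), dim = c(ny, nx, nz))
    out <- list()
    clipped <- integer(0)
    if (p$spot_amplitude + p$fish_background > maxval)
      warning("spot_amplitude + fish_background exceeds the ", p$bit_depth,
              "-bit range; peaks will be clipped")
    for (ch in channels) {
      arr <- switch(
        ch,
        dapi = p$dapi_level * array(rep(scene$geometry$nuclei > 0L, nz),
                                    dim = c(ny, nx, nz)),
        `if` = render_if(scene, cell3d),
        render_fish(scene$spots[[ch]], p, cell3d)
      )
      sd <- if (ch == "if") p$if_noise_sd else p$camera_noise_sd
      if (sd > 0) arr <- arr + rnorm(length(arr), 0, sd)
      clipped[ch] <- sum(arr > maxval)
      arr <- pmin(pmax(arr, 0), maxval)
      dim(arr) <- c(ny, nx, nz)
      out[[ch]] <- vol_image(arr, voxel_xy = p$voxel_xy, voxel_z = p$voxel_z,
                             bit_depth = p$bit_depth)
    }
    attr(out, "report") <- list(clipped = clipped)
    out
  })
}

render_fish <- function(spots, p, cell3d) {
  arr <- p$fish_background * cell3d
  d <- dim(cell3d)
  wxy <- ceiling(4 * p$sigma_xy); wz <- ceiling(4 * p$sigma_z)
  df <- spots$spots
  for (i in seq_len(nrow(df))) {
    py <- df$y_nm[i] / p$voxel_xy
    px <- df$x_nm[i] / p$voxel_xy
    pz <- df$z_nm[i] / p$voxel_z
    ys <- max(0, floor(py) - wxy):min(d[1] - 1, floor(py) + wxy)
    xs <- max(0, floor(px) - wxy):min(d[2] - 1, floor(px) + wxy)
    zs <- max(0, floor(pz) - wz):min(d[3] - 1, floor(pz) + wz)
    gy <- exp(-(ys + 0.5 - py)^2 / (2 * p$sigma_xy^2))
    gx <- exp(-(xs + 0.5 - px)^2 / (2 * p$sigma_xy^2))
    gz <- exp(-(zs + 0.5 - pz)^2 / (2 * p$sigma_z^2))
    arr[ys + 1, xs + 1, zs + 1] <- arr[ys + 1, xs + 1, zs + 1] +
      df$intensity[i] * (gy %o% gx %o% gz)
  }
  arr
}

render_if <- function(scene, cell3d) {
  p <- scene$params
  arr <- p$if_background * cell3d
  d <- dim(cell3d)
  wxy <- ceiling(p$sigma_xy)
  df <- scene$spots$fish_a$spots
  for (i in seq_len(nrow(df))) {
    py <- df$y_nm[i] / p$voxel_xy
    px <- df$x_nm[i] / p$voxel_xy
    pz <- df$z_nm[i] / p$voxel_z
    ys <- max(0, floor(py) - wxy):min(d[1] - 1, floor(py) + wxy)
    xs <- max(0, floor(px) - wxy):min(d[2] - 1, floor(px) + wxy)
    zs <- max(0, floor(pz - p$sigma_z)):min(d[3] - 1, floor(pz + p$sigma_z))
    near <- outer((ys + 0.5 - py)^2, (xs + 0.5 - px)^2, `+`) <= p$sigma_xy^2
    zin <- abs(zs + 0.5 - pz) <= p$sigma_z
    for (k in which(zin)) {
      sl <- arr[ys + 1, xs + 1, zs[k] + 1]
      sl[near & sl > 0] <- p$if_background * p$r
      arr[ys + 1, xs + 1, zs[k] + 1] <- sl
    }
  }
  arr
}

#' Write a scene's ground truth to disk
#'
#' Writes the label masks (16-bit TIFF), the true spot table (CSV with
#' columns `cell_id, channel, x_nm, y_nm, z_nm, partner_id`) and the scene
#' parameters (JSON) to `dir`.
#'
#' @param scene a [simulate_scene()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    cells = file.path(dir, "cells_mask.tif"),
    nuclei = file.path(dir, "nuclei_mask.tif"),
    spots = file.path(dir, "true_spots.csv"),
    params = file.path(dir, "scene_params.json")
  )
  write_label_mask(scene$geometry$cells, paths["cells"])
  write_label_mask(scene$geometry$nuclei, paths["nuclei"])
  truth <- do.call(rbind, lapply(names(scene$spots), function(ch) {
    df <- scene$spots[[ch]]$spots
    data.frame(cell_id = df$cell_id, channel = ch,
               x_nm = df$x_nm, y_nm = df$y_nm, z_nm = df$z_nm,
               partner_id = df$partner)
  }))
  utils::write.csv(truth, paths["spots"], row.names = FALSE)
  pj <- scene$params
  pj$shape <- as.list(pj$shape)
  jsonlite::write_json(pj[setdiff(names(pj), "")], paths["params"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
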