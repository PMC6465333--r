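#' Per-cell enrichment of IF signal at RNA positions
#'
#' The central image statistic: for one cell, the median immunofluorescence
#' pixel intensity sampled at the detected RNA positions, divided by a
#' normalization factor summarising the cytoplasmic IF level of that cell. A
#' ratio above 1 indicates protein enrichment at the mRNA. The computation,
#' per cell:
#'
#' 1. restrict the spots to the cytoplasm of `cell_id` (2D containment);
#' 2. sample the IF stack at each spot's nearest voxel and take the median;
#' 3. take the z-range (inclusive) spanned by the spots' z slices;
#' 4. normalization factor = median (default; or mean, see `norm`) IF
#'    intensity over the cytoplasm pixels across that z-range;
#' 5. ratio = (2) / (4).
#'
#' The statistic is invariant to rescaling the IF channel by any positive
#' constant. Cells with fewer than `min_spots` cytoplasmic spots are not
#' analysable: the result carries `ratio = NA` and the reason, so that
#' excluded cells remain reportable.
#'
#' @param if_stack the IF channel as a [vol_image()].
#' @param spots a [spot_set()] of detected RNA positions (nm).
#' @param geometry a [cell_geometry()].
#' @param cell_id cell label to analyse.
#' @param min_spots minimum number of cytoplasmic spots required (median
#'   stability threshold; reported alongside results).
#' @param norm `"median"` (default) or `"mean"` cytoplasmic normalization.
#' @return An `enrichment_result`: list with `cell_id`, `n_spots`,
#'   `median_at_spots`, `norm_factor`, `ratio`, `z_range` (0-based slice
#'   indices), `norm`, and `reason` (`NA` unless the cell was excluded).
#' @export
enrichment_ratio <- function(if_stack, spots, geometry, cell_id,
                             min_spots = 5L, norm = c("median", "mean")) {
  stopifnot(inherits(if_stack, "vol_image"))
  norm <- match.arg(norm)
  cyto <- cytoplasm_mask(geometry, cell_id)
  kept <- filter_spots(spots, geometry, cell_id)
  n <- n_spots(kept)
  res <- list(cell_id = cell_id, n_spots = n, median_at_spots = NA_real_,
              norm_factor = NA_real_, ratio = NA_real_,
              z_range = c(NA_integer_, NA_integer_), norm = norm,
              reason = NA_character_)
  class(res) <- "enrichment_result"
  if (n < min_spots) {
    res$reason <- sprintf("only %d cytoplasmic spots (min_spots = %d)",
                          n, min_spots)
    return(res)
  }
  d <- dim(if_stack$data)
  df <- kept$spots
  iy <- pmin(pmax(nm_to_index(df$y_nm, if_stack$voxel_xy), 0L), d[1] - 1L)
  ix <- pmin(pmax(nm_to_index(df$x_nm, if_stack$voxel_xy), 0L), d[2] - 1L)
  iz <- pmin(pmax(nm_to_index(df$z_nm, if_stack$voxel_z), 0L), d[3] - 1L)
  res$median_at_spots <- stats::median(
    if_stack$data[cbind(iy + 1L, ix + 1L, iz + 1L)])
  zr <- range(iz)
  res$z_range <- zr
  vals <- as.vector(if_stack$data[, , (zr[1] + 1L):(zr[2] + 1L)][
    rep(cyto, zr[2] - zr[1] + 1L)])
  res$norm_factor <- if (norm == "median") stats::median(vals) else mean(vals)
  if (res$norm_factor == 0)
    stop("flat/empty IF cytoplasm: normalization factor is zero for cell ",
         cell_id)
  res$ratio <- res$median_at_spots / res$norm_factor
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  if (is.na(x$ratio))
    cat(sprintf("<enrichment_result> cell %s: excluded (%s)\n",
                x$cell_id, x$reason))
  else
    cat(sprintf(
      "<enrichment_result> cell %s: ratio %.3f (%d spots, z %d..%d, %s norm)\n",
      x$cell_id, x$ratio, x$n_spots, x$z_range[1], x$z_range[2], x$norm))
  invisible(x)
}

#' Enrichment ratios for all analysable cells of a geometry
#'
#' Convenience wrapper around [enrichment_ratio()]; one row per cell,
#' excluded cells included with their reason.
#'
#' @inheritParams enrichment_ratio
#' @return Data frame with columns `cell_id, n_spots, median_at_spots,
#'   norm_factor, ratio, z_min, z_max, reason`.
#' @export
enrichment_table <- function(if_stack, spots, geometry, min_spots = 5L,
                             norm = c("median", "mean")) {
  norm <- match.arg(norm)
  rows <- lapply(geometry$labels, function(l) {
    r <- enrichment_ratio(if_stack, spots, geometry, l,
                          min_spots = min_spots, norm = norm)
    data.frame(cell_id = r$cell_id, n_spots = r$n_spots,
               median_at_spots = r$median_at_spots,
               norm_factor = r$norm_factor, ratio = r$ratio,
               z_min = r$z_range[1], z_max = r$z_range[2],
               reason = r$reason)
  })
  do.call(rbind, rows)
}

#' Summarise per-cell enrichment ratios of one condition
#'
#' Mean, standard deviation (n-1 denominator) and the t-based 95% confidence
#' interval of the mean, matching the mean line, SD band and 95% CI band of
#' the usual per-cell dot plot (each dot is one cell).
#'
#' @param ratios numeric vector of per-cell ratios (length >= 2).
#' @param label condition label.
#' @param conf confidence level for the CI of the mean.
#' @return A `condition_summary`: list with `label`, `ratios`, `n`, `mean`,
#'   `sd`, `ci` (length-2 vector).
#' @export
summarize_condition <- function(ratios, label = "condition", conf = 0.95) {
  ratios <- ratios[!is.na(ratios)]
  n <- length(ratios)
  if (n < 2) stop("need at least 2 cells to summarise a condition")
  m <- mean(ratios)
  s <- stats::sd(ratios)
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
  structure(list(label = label, ratios = ratios, n = n, mean = m, sd = s,
                 ci = c(m - half, m + half), conf = conf),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> '%s': n = %d, mean = %.3f, sd = %.3f, %g%% CI [%.3f, %.3f]\n",
              x$label, x$n, x$mean, x$sd, 100 * x$conf, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of per-cell ratios
#'
#' The D statistic is the supremum of the absolute difference between the two
#' empirical distribution functions, evaluated at the pooled sample points.
#' The p value uses the asymptotic Kolmogorov distribution with effective
#' sample size `n_a * n_b / (n_a + n_b)` and the Stephens small-sample
#' correction `lambda = (sqrt(n) + 0.12 + 0.11/sqrt(n)) * D`, the convention
#' of the widely used two-sample implementations this mirrors.
#'
#' @param a,b numeric samples (non-empty).
#' @return List with `statistic` (D) and `p.value`.
#' @export
compare_ks <- function(a, b) {
  a <- sort(a[!is.na(a)]); b <- sort(b[!is.na(b)])
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  pooled <- sort(unique(c(a, b)))
  fa <- vapply(pooled, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pooled, function(t) mean(b <= t), numeric(1))
  D <- max(abs(fa - fb))
  n_eff <- length(a) * length(b) / (length(a) + length(b))
  lambda <- (sqrt(n_eff) + 0.12 + 0.11 / sqrt(n_eff)) * D
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(statistic = D, p.value = min(max(p, 0), 1))
}

#' Per-cell dot plot of condition summaries
#'
#' One jittered dot per cell, a horizontal mean line, a band for the 95%
#' confidence interval of the mean (red) and a band for +-1 SD (blue).
#'
#' @param summaries list of [summarize_condition()] results.
#' @param ylab y-axis label.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `summaries`.
#' @export
plot_condition_summary <- function(summaries, ylab = "enrichment ratio", ...) {
  if (inherits(summaries, "condition_summary")) summaries <- list(summaries)
  k <- length(summaries)
  all_r <- unlist(lapply(summaries, `[[`, "ratios"))
  graphics::plot(NULL, xlim = c(0.5, k + 0.5), ylim = range(all_r),
                 xaxt = "n", xlab = "", ylab = ylab, ...)
  graphics::axis(1, at = seq_len(k),
                 labels = vapply(summaries, `[[`, "", "label"))
  for (i in seq_len(k)) {
    s <- summaries[[i]]
    graphics::rect(i - 0.3, s$mean - s$sd, i + 0.3, s$mean + s$sd,
                   col = grDevices::adjustcolor("blue", 0.15), border = NA)
    graphics::rect(i - 0.3, s$ci[1], i + 0.3, s$ci[2],
                   col = grDevices::adjustcolor("red", 0.25), border = NA)
    graphics::points(i + stats::runif(s$n, -0.2, 0.2), s$ratios, pch = 16,
                     cex = 0.6)
    graphics::segments(i - 0.35, s$mean, i + 0.35, s$mean, lwd = 2)
  }
  invisible(summaries)
}
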