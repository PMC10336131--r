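# Quantitative evaluation: PSF size by the 10%-of-max calibration protocol,
# FWHM, PSNR/SSIM, Michelson contrast, chromatic-similarity curves, and the
# size-reduction arithmetic.

#' PSF size by thresholded connected component
#'
#' Calibration protocol for measured pinhole PSFs: binarize at
#' `threshold_frac` of the maximum intensity (default 10%), keep the largest
#' 8-connected component, and report its bounding extents along x (columns)
#' and y (rows).
#'
#' @param psf Non-negative, nonzero matrix.
#' @param threshold_frac Threshold as a fraction of the maximum, in (0, 1).
#' @param pixel_pitch_um Optional pitch to also report extents in um.
#' @return Object of class `psf_size_result`: list with `extent_x`,
#'   `extent_y` (pixels), `extent_x_um`, `extent_y_um` (or NA),
#'   `component_pixels`, `threshold_frac`.
#' @export
psf_size <- function(psf, threshold_frac = 0.1, pixel_pitch_um = NULL) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  m <- unclass(psf)
  if (all(m == 0)) stop("all-zero PSF")
  if (any(m < 0)) stop("PSF must be non-negative")
  bw <- m >= threshold_frac * max(m)
  lab <- label_components(bw)
  sizes <- tabulate(lab[lab > 0])
  comp <- which(lab == which.max(sizes), arr.ind = TRUE)
  ey <- diff(range(comp[, 1])) + 1
  ex <- diff(range(comp[, 2])) + 1
  structure(list(extent_x = ex, extent_y = ey,
                 extent_x_um = if (is.null(pixel_pitch_um)) NA_real_
                               else ex * pixel_pitch_um,
                 extent_y_um = if (is.null(pixel_pitch_um)) NA_real_
                               else ey * pixel_pitch_um,
                 component_pixels = max(sizes),
                 threshold_frac = threshold_frac),
            class = "psf_size_result")
}

#' @export
print.psf_size_result <- function(x, ...) {
  cat(sprintf("PSF size (>= %.0f%% of max, largest 8-connected component):\n",
              100 * x$threshold_frac))
  cat("  extent x:", x$extent_x, "px, extent y:", x$extent_y, "px,",
      x$component_pixels, "px in component\n")
  if (!is.na(x$extent_x_um)) {
    cat("  in um:", signif(x$extent_x_um, 4), "x", signif(x$extent_y_um, 4), "\n")
  }
  invisible(x)
}

# 8-connected component labeling (iterative flood fill).
label_components <- function(bw) {
  n <- nrow(bw); m <- ncol(bw)
  lab <- matrix(0L, n, m)
  cur <- 0L
  off <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), ]
  for (start in which(bw)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      si <- (s - 1L) %% n + 1L; sj <- (s - 1L) %/% n + 1L
      ni <- si + off[, 1]; nj <- sj + off[, 2]
      ok <- ni >= 1 & ni <= n & nj >= 1 & nj <= m
      idx <- (nj[ok] - 1L) * n + ni[ok]
      idx <- idx[bw[idx] & lab[idx] == 0L]
      lab[idx] <- cur
      stack <- c(stack, idx)
    }
  }
  lab
}

#' Full width at half maximum of a 1-D profile
#'
#' Linear-interpolated half-maximum crossings; for multimodal profiles the
#' widest crossing pair is used.
#'
#' @param profile Numeric intensity profile.
#' @param x Abscissa values (default sample index 1..n).
#' @return Width in abscissa units.
#' @export
fwhm <- function(profile, x = seq_along(profile)) {
  stopifnot(length(profile) == length(x), length(profile) >= 2)
  half <- max(profile) / 2
  above <- profile >= half
  if (!any(above)) stop("profile never reaches half maximum")
  i1 <- which(above)[1]
  i2 <- rev(which(above))[1]
  left <- if (i1 == 1) x[1] else {
    x[i1 - 1] + (half - profile[i1 - 1]) / (profile[i1] - profile[i1 - 1]) *
      (x[i1] - x[i1 - 1])
  }
  right <- if (i2 == length(profile)) x[length(x)] else {
    x[i2] + (profile[i2] - half) / (profile[i2] - profile[i2 + 1]) *
      (x[i2 + 1] - x[i2])
  }
  right - left
}

#' Peak signal-to-noise ratio
#'
#' PSNR = 10 log10(peak^2 / MSE) in dB; identical inputs give `Inf`.
#'
#' @param a,b Arrays of identical shape.
#' @param peak Dynamic range peak (default `max(b)`; the reference image).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, peak = max(b)) {
  if (!all(dim(a) %||% length(a) == dim(b) %||% length(b))) {
    stop("shape mismatch")
  }
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Standard SSIM with an 11 x 11 Gaussian weighting window (sigma = 1.5) and
#' constants K1 = 0.01, K2 = 0.03 on the given dynamic range. Local
#' statistics are computed by valid-region convolution (no padding), so the
#' SSIM map excludes a (window-1)/2 border; the score is the mean of the
#' map, optionally restricted by a mask.
#'
#' @param a,b Matrices (or h x w x C arrays, averaged over channels) of
#'   identical shape, larger than the window.
#' @param window Odd window size (default 11).
#' @param sigma Gaussian window sigma (default 1.5).
#' @param K1,K2 Stability constants.
#' @param data_range Dynamic range L (default `max(a, b) - min(a, b)`).
#' @param mask Optional logical matrix (full image size); the score averages
#'   the SSIM map over the mask's valid-region interior.
#' @param map Return the full SSIM map instead of the scalar mean.
#' @return Mean SSIM in \[-1, 1\] (or the map).
#' @export
ssim <- function(a, b, window = 11, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 data_range = NULL, mask = NULL, map = FALSE) {
  da <- dim(a) %||% length(a); db <- dim(b) %||% length(b)
  if (!all(da == db)) stop("shape mismatch")
  if (length(dim(a)) == 3) {
    vals <- vapply(seq_len(dim(a)[3]), function(c) {
      ssim(a[, , c], b[, , c], window, sigma, K1, K2, data_range, mask)
    }, numeric(1))
    return(mean(vals))
  }
  if (is.null(data_range)) data_range <- max(a, b) - min(a, b)
  if (data_range == 0) data_range <- 1
  half <- (window - 1) %/% 2
  g <- gaussian_kernel(sigma, half)
  fv <- function(x) conv2_valid(x, g)
  mu_a <- fv(a); mu_b <- fv(b)
  va <- fv(a^2) - mu_a^2
  vb <- fv(b^2) - mu_b^2
  cab <- fv(a * b) - mu_a * mu_b
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  s <- ((2 * mu_a * mu_b + C1) * (2 * cab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  if (map) return(s)
  if (!is.null(mask)) {
    mi <- mask[(half + 1):(nrow(mask) - half), (half + 1):(ncol(mask) - half)]
    if (!any(mi)) stop("mask empty in the valid region")
    mean(s[mi])
  } else mean(s)
}

# Valid-region (no padding) convolution with a small kernel.
conv2_valid <- function(x, k) {
  nx <- dim(x); nk <- dim(k)
  full <- conv2_same(x, k)
  half <- floor(nk / 2)
  full[(half[1] + 1):(nx[1] - half[1]), (half[2] + 1):(nx[2] - half[2]),
       drop = FALSE]
}

#' Michelson contrast of an image region
#'
#' (Imax - Imin) / (Imax + Imin) over the region.
#'
#' @param image Matrix.
#' @param region Optional logical mask or index set; default whole image.
#' @return Contrast in \[0, 1\].
#' @export
michelson_contrast <- function(image, region = NULL) {
  v <- if (is.null(region)) as.vector(image) else image[region]
  if (length(v) == 0) stop("empty region")
  mx <- max(v); mn <- min(v)
  if (mx + mn <= 0) stop("degenerate region: Imax + Imin must be positive")
  (mx - mn) / (mx + mn)
}

#' Chromatic similarity curves across the field
#'
#' For every calibration field point, the SSIM between the PSFs of two color
#' channels; plotted against field position this quantifies lateral
#' chromatic aberration of the coded system.
#'
#' @param grid A `psf_grid` with >= 2 channels.
#' @param z_um Depth plane.
#' @param channel_pairs List of 2-vectors of channel indices; default all
#'   unordered pairs.
#' @return Data frame with columns `field_index`, `u`, `v`, `radius`,
#'   `channel_a`, `channel_b`, `ssim`.
#' @export
chromatic_similarity <- function(grid, z_um = 0, channel_pairs = NULL) {
  stopifnot(inherits(grid, "psf_grid"))
  nc <- length(grid$wavelengths_nm)
  if (nc < 2) stop("need at least 2 channels")
  if (is.null(channel_pairs)) {
    channel_pairs <- utils::combn(nc, 2, simplify = FALSE)
  }
  zi <- match_depth(grid$z_um, z_um)
  M <- dim(grid$psf)[1]
  rows <- list()
  for (cp in channel_pairs) {
    for (m in seq_len(M)) {
      pa <- grid$psf[m, zi, cp[1], , ]
      pb <- grid$psf[m, zi, cp[2], , ]
      rows[[length(rows) + 1]] <- data.frame(
        field_index = m, u = grid$field_uv$u[m], v = grid$field_uv$v[m],
        radius = sqrt(grid$field_uv$u[m]^2 + grid$field_uv$v[m]^2),
        channel_a = cp[1], channel_b = cp[2],
        ssim = ssim(pa / max(pa), pb / max(pb), data_range = 1))
    }
  }
  do.call(rbind, rows)
}

#' Device size-reduction arithmetic
#'
#' Volume of a benchtop instrument from its W x D x H dimensions and the
#' ratio to a miniaturized device volume.
#'
#' @param dims_mm Length-3 numeric, instrument dimensions in mm.
#' @param device_mm3 Device volume in mm^3.
#' @return List with `volume_mm3`, `ratio`, `orders_of_magnitude`.
#' @export
size_reduction <- function(dims_mm = c(323, 475, 656), device_mm3 = 150) {
  stopifnot(length(dims_mm) == 3, all(dims_mm > 0), device_mm3 > 0)
  v <- prod(dims_mm)
  list(volume_mm3 = v, ratio = v / device_mm3,
       orders_of_magnitude = floor(log10(v / device_mm3)))
}
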