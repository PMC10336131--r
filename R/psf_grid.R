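# Field/depth/channel-sampled PSF grids: simulation, persistence, lookup.

#' Regular calibration field grid
#'
#' A side x side grid of normalized field positions spanning
#' \[-extent, extent\] in both u (rows) and v (columns), matching the
#' pixel-to-field mapping of [field_coords()]. side = 7 gives the full
#' M = 49 calibration layout; side = 3 gives M = 9.
#'
#' @param side Points per side (>= 1).
#' @param extent Half-width of the field square (default 0.7, keeping the
#'   corners inside the unit disk).
#' @return Data frame with columns `u`, `v` (row-major order) and attribute
#'   `side`, `extent`.
#' @export
field_grid <- function(side = 3, extent = 0.7) {
  stopifnot(side >= 1, extent > 0, extent * sqrt(2) <= 1 + 1e-12)
  g <- if (side == 1) 0 else seq(-extent, extent, length.out = side)
  df <- expand.grid(v = g, u = g)[, c("u", "v")]
  structure(df, side = side, extent = extent)
}

#' Normalized field coordinates of image pixels
#'
#' Maps pixel (i, j) of an h x w image to a normalized field position:
#' u = extent * (2 (i - 1) / (h - 1) - 1), likewise v over columns, so that
#' image corners sit at field radius extent * sqrt(2). The same mapping is
#' used by the forward model and the coefficient-map interpolation.
#'
#' @param h,w Image size in pixels.
#' @param extent Field half-width (see [field_grid()]).
#' @return List with vectors `u` (length h) and `v` (length w).
#' @export
field_coords <- function(h, w, extent = 0.7) {
  u <- if (h == 1) 0 else extent * (2 * (seq_len(h) - 1) / (h - 1) - 1)
  v <- if (w == 1) 0 else extent * (2 * (seq_len(w) - 1) / (w - 1) - 1)
  list(u = u, v = v)
}

#' Simulate a field/depth/channel PSF grid
#'
#' Simulates the coded (or uncoded) PSF at every calibration field point,
#' depth and wavelength channel, integrates each onto the sensor pixel grid
#' and crops to a common support. This is the simulated stand-in for a
#' pinhole-array calibration of the assembled system.
#'
#' @param model An [optical_model()].
#' @param mask A [cubic_phase_mask()] or `NULL`.
#' @param fields A [field_grid()] (M rows).
#' @param zs Depths (um), default the model depth grid.
#' @param wavelengths_nm Channel wavelengths, default from the model.
#' @param crop Odd sensor-pixel crop size for each PSF.
#' @return Object of class `psf_grid`: list with `psf` (5-D array
#'   \[field, z, channel, y, x\]), `field_uv`, `z_um`, `wavelengths_nm`,
#'   `pitch_um`, `meta`.
#' @export
simulate_psf_grid <- function(model, mask = NULL, fields = field_grid(3),
                              zs = depth_grid(model),
                              wavelengths_nm = model$wavelengths_nm,
                              crop = 41) {
  M <- nrow(fields)
  A <- array(NA_real_, c(M, length(zs), length(wavelengths_nm), crop, crop))
  for (ci in seq_along(wavelengths_nm)) {
    for (zi in seq_along(zs)) {
      for (m in seq_len(M)) {
        p <- simulate_psf(model, mask, zs[zi],
                          c(fields$u[m], fields$v[m]), wavelengths_nm[ci])
        A[m, zi, ci, , ] <- psf_to_sensor(p, model$pixel_pitch_um, size = crop)
      }
    }
  }
  structure(list(psf = A, field_uv = as.data.frame(fields), z_um = zs,
                 wavelengths_nm = wavelengths_nm,
                 pitch_um = model$pixel_pitch_um,
                 meta = list(na = model$na,
                             alpha = if (is.null(mask)) 0 else mask$alpha,
                             field_extent = attr(fields, "extent"),
                             field_side = attr(fields, "side"),
                             crop = crop)),
            class = "psf_grid")
}

#' @export
print.psf_grid <- function(x, ...) {
  d <- dim(x$psf)
  cat("PSF grid:", d[1], "field points x", d[2], "depths x", d[3],
      "channels, PSFs", d[4], "x", d[5], "px @", x$pitch_um, "um\n")
  cat("  alpha =", x$meta$alpha, "; z", min(x$z_um), "..", max(x$z_um), "um\n")
  invisible(x)
}

#' Extract one PSF from a grid
#' @param grid A `psf_grid`.
#' @param m Field point index.
#' @param z_um Depth (must match a grid depth).
#' @param channel Channel index.
#' @return A `psf` matrix at the sensor pitch.
#' @export
grid_psf <- function(grid, m, z_um = 0, channel = 1) {
  zi <- match_depth(grid$z_um, z_um)
  structure(grid$psf[m, zi, channel, , ], class = "psf",
            dx_um = grid$pitch_um,
            wavelength_nm = grid$wavelengths_nm[channel], z_um = z_um,
            field = c(grid$field_uv$u[m], grid$field_uv$v[m]))
}

match_depth <- function(zs, z) {
  zi <- which(abs(zs - z) < 1e-6)
  if (length(zi) != 1) stop("depth ", z, " um is not on the grid")
  zi
}

#' Write / read a PSF grid
#'
#' Grids persist as RDS containers holding the documented fields
#' (`psf`, `z_um`, `field_uv`, `meta`).
#'
#' @param grid A `psf_grid`.
#' @param path File path.
#' @return `read_psf_grid` returns the grid; `write_psf_grid` the path,
#'   invisibly.
#' @export
write_psf_grid <- function(grid, path) {
  stopifnot(inherits(grid, "psf_grid"))
  saveRDS(grid, path)
  invisible(path)
}

#' @rdname write_psf_grid
#' @export
read_psf_grid <- function(path) {
  g <- readRDS(path)
  if (!inherits(g, "psf_grid")) stop("not a psf_grid container")
  g
}
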