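# Fourier-optics simulation of coded / uncoded PSFs and MTFs, the
# Fisher-information depth-invariance merit, and modulation-strength selection.

#' Aspheric surface description
#'
#' Standard even-asphere description used for molded plastic lens surfaces:
#' a conic base plus even polynomial terms up to r^16.
#'
#' @param curvature Surface curvature `c` (1/mm); 0 gives a plane base.
#' @param conic Conic constant `k` (dimensionless); -1 is parabolic.
#' @param coefficients Numeric vector of up to 8 polynomial coefficients
#'   `a1..a8` multiplying `r^2, r^4, ..., r^16` (mm^(1-2i) each).
#' @param semi_diameter Clear semi-diameter of the surface (mm).
#' @return An object of class `aspheric_surface`.
#' @seealso [aspheric_sag()]
#' @export
aspheric_surface <- function(curvature = 0, conic = 0, coefficients = numeric(8),
                             semi_diameter = 1) {
  stopifnot(is.numeric(curvature), length(curvature) == 1,
            is.numeric(conic), length(conic) == 1,
            is.numeric(coefficients), length(coefficients) <= 8,
            semi_diameter > 0)
  coef <- numeric(8)
  coef[seq_along(coefficients)] <- coefficients
  structure(list(curvature = curvature, conic = conic, coefficients = coef,
                 semi_diameter = semi_diameter),
            class = "aspheric_surface")
}

#' Sag of an even-asphere surface
#'
#' Surface height z(r) = c r^2 / (1 + sqrt(1 - (1+k) c^2 r^2)) +
#' a1 r^2 + a2 r^4 + ... + a8 r^16.
#'
#' @param surface An [aspheric_surface()].
#' @param r Radial coordinate(s), mm; must satisfy `0 <= r <= semi_diameter`
#'   and keep the square-root argument non-negative.
#' @return Sag in mm, vectorized over `r`.
#' @export
aspheric_sag <- function(surface, r) {
  stopifnot(inherits(surface, "aspheric_surface"))
  if (any(r < 0) || any(r > surface$semi_diameter)) {
    stop("r must lie in [0, semi_diameter]")
  }
  cc <- surface$curvature
  k <- surface$conic
  arg <- 1 - (1 + k) * cc^2 * r^2
  if (any(arg < 0)) stop("square-root argument negative: surface undefined at this r")
  base <- cc * r^2 / (1 + sqrt(arg))
  poly <- 0
  r2 <- r^2
  for (i in 1:8) poly <- poly + surface$coefficients[i] * r2^i
  base + poly
}

#' Cubic phase mask (wavefront-coding element)
#'
#' A pupil-plane diffractive element with antisymmetric surface height
#' h(x, y) = alpha (x^3 + y^3) in physical mask coordinates. The single
#' modulation strength `alpha` controls how strongly the PSF is spread
#' (and hence made defocus-invariant).
#'
#' @param alpha Modulation strength (mm^-2) applied to physical coordinates.
#' @param n_ref Refractive index of the mask material (default 1.5).
#' @param semi_diameter Aperture semi-diameter of the mask (mm).
#' @return An object of class `cubic_phase_mask`.
#' @export
cubic_phase_mask <- function(alpha, n_ref = 1.5, semi_diameter = 0.5) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, n_ref > 1, semi_diameter > 0)
  structure(list(alpha = alpha, n_ref = n_ref, semi_diameter = semi_diameter),
            class = "cubic_phase_mask")
}

#' Phase delay of a cubic phase mask
#'
#' phase = 2 pi (n - 1) alpha (x^3 + y^3) / lambda, with lambda converted
#' to mm. Antisymmetric: phase(-x, -y) = -phase(x, y).
#'
#' @param mask A [cubic_phase_mask()].
#' @param x,y Physical mask coordinates (mm), vectorized.
#' @param wavelength_nm Wavelength in nm.
#' @return Phase in radians.
#' @export
cubic_phase <- function(mask, x, y, wavelength_nm) {
  stopifnot(inherits(mask, "cubic_phase_mask"))
  if (any(abs(x) > mask$semi_diameter) || any(abs(y) > mask$semi_diameter)) {
    stop("coordinates outside the mask aperture")
  }
  lam_mm <- wavelength_nm * 1e-6
  2 * pi * (mask$n_ref - 1) * mask$alpha * (x^3 + y^3) / lam_mm
}

#' Optical model of the miniaturized microscope
#'
#' System constants of the pupil-function imaging model: numerical aperture,
#' focal length, conjugate distance, per-channel wavelengths, object-space
#' pixel pitch, pupil sampling, and parametric field-aberration terms (tilt
#' and coma in waves at the field edge) that make the PSF shift-variant.
#'
#' Defaults describe an NA 0.16, f = 1 mm system working at a 6 mm conjugate
#' distance with blue/green/amber channels, a 2 um object pixel pitch and a
#' +/-150 um design depth range sampled every 10 um.
#'
#' @param na Numerical aperture, in (0, 1).
#' @param focal_length_mm Focal length (mm).
#' @param conjugate_mm Conjugate distance (mm).
#' @param wavelengths_nm Channel wavelengths (nm); default 470/530/590.
#' @param pixel_pitch_um Object-space pixel pitch (um).
#' @param pupil_grid Pupil grid size (samples across the diameter); even, >= 64.
#' @param pad_factor Zero-padding factor of the pupil FFT (>= 2 avoids
#'   aliasing of the intensity PSF).
#' @param field_tilt_waves Wavefront tilt, waves at unit field radius.
#' @param field_coma_waves Wavefront coma, waves at unit field radius.
#' @param depth_range_um Half-width of the design defocus range (um).
#' @param depth_step_um Depth grid step (um); must divide the range.
#' @param mag_per_um Optional linear magnification change per um defocus
#'   (default 0 = off).
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(na = 0.16, focal_length_mm = 1, conjugate_mm = 6,
                          wavelengths_nm = c(470, 530, 590), pixel_pitch_um = 2,
                          pupil_grid = 256, pad_factor = 2,
                          field_tilt_waves = 1.5, field_coma_waves = 0.4,
                          depth_range_um = 150, depth_step_um = 10,
                          mag_per_um = 0) {
  stopifnot(na > 0, na < 1, focal_length_mm > 0, conjugate_mm > 0,
            length(wavelengths_nm) >= 1, all(wavelengths_nm > 0),
            pixel_pitch_um > 0, pad_factor >= 2)
  if (pupil_grid %% 2 != 0 || pupil_grid < 64) {
    stop("pupil_grid must be even and >= 64")
  }
  if (abs(depth_range_um / depth_step_um - round(depth_range_um / depth_step_um)) > 1e-9) {
    stop("depth_step_um must divide depth_range_um")
  }
  structure(list(na = na, focal_length_mm = focal_length_mm,
                 conjugate_mm = conjugate_mm, wavelengths_nm = wavelengths_nm,
                 pixel_pitch_um = pixel_pitch_um, pupil_grid = pupil_grid,
                 pad_factor = pad_factor, field_tilt_waves = field_tilt_waves,
                 field_coma_waves = field_coma_waves,
                 depth_range_um = depth_range_um, depth_step_um = depth_step_um,
                 mag_per_um = mag_per_um),
            class = "optical_model")
}

#' @export
print.optical_model <- function(x, ...) {
  cat("Optical model: NA", x$na, ", f =", x$focal_length_mm,
      "mm, conjugate", x$conjugate_mm, "mm\n")
  cat("  wavelengths:", paste(x$wavelengths_nm, collapse = "/"), "nm;",
      "pixel pitch", x$pixel_pitch_um, "um\n")
  cat("  pupil grid", x$pupil_grid, "(pad", x$pad_factor, "); depth +/-",
      x$depth_range_um, "um step", x$depth_step_um, "um\n")
  cat("  field aberrations: tilt", x$field_tilt_waves, "waves, coma",
      x$field_coma_waves, "waves at unit field\n")
  invisible(x)
}

#' Depth grid of an optical model
#' @param model An [optical_model()].
#' @return Depths in um from -range to +range in steps of `depth_step_um`.
#' @export
depth_grid <- function(model) {
  seq(-model$depth_range_um, model$depth_range_um, by = model$depth_step_um)
}

#' Sensor Nyquist frequency
#' @param model An [optical_model()].
#' @return Nyquist frequency in cycles/um (1 / (2 * pixel pitch)).
#' @export
nyquist_frequency <- function(model) 1 / (2 * model$pixel_pitch_um)

# Pixel size (um) of the oversampled PSF grid produced by simulate_psf.
psf_pixel_um <- function(model, wavelength_nm) {
  (wavelength_nm * 1e-3) / (2 * model$na) / model$pad_factor
}

# Pupil coordinates and aperture mask; rho in [-1, 1], no sample exactly at 0
# so the grid is symmetric under (x, y) -> (-x, -y).
pupil_coords <- function(G) {
  rho <- seq(-1 + 1 / G, 1 - 1 / G, length.out = G)
  X <- matrix(rho, G, G)       # row coordinate
  Y <- matrix(rho, G, G, byrow = TRUE)
  list(X = X, Y = Y, R2 = X^2 + Y^2)
}

# Total pupil phase (radians) at defocus z_um and normalized field (u, v);
# lambda_um in micrometers.
pupil_phase <- function(model, mask, z_um, field, lambda_um, pc) {
  ph <- 2 * pi / lambda_um * z_um * model$na^2 / 2 * pc$R2
  if (!is.null(mask) && mask$alpha != 0) {
    lam_mm <- lambda_um * 1e-3
    a <- mask$semi_diameter
    ph <- ph + 2 * pi * (mask$n_ref - 1) * mask$alpha *
      ((pc$X * a)^3 + (pc$Y * a)^3) / lam_mm
  }
  u <- field[1]; v <- field[2]
  if (u != 0 || v != 0) {
    lin <- u * pc$X + v * pc$Y
    ph <- ph + 2 * pi * model$field_tilt_waves * lin +
      2 * pi * model$field_coma_waves * (3 * pc$R2 - 2) * lin
  }
  ph
}

#' Simulate a point spread function
#'
#' Pupil-function (Fraunhofer) model of the incoherent PSF:
#' PSF = |FT\{ A(rho) exp(i \[phi_cubic + phi_defocus(z) + phi_field\]) \}|^2
#' with defocus phase (2 pi / lambda) z (NA^2 / 2) rho^2 on the normalized
#' pupil radius. The result is sampled at
#' `lambda / (2 NA) / pad_factor` um per pixel (see [psf_to_sensor()] to
#' integrate onto the sensor grid) and normalized to unit sum.
#'
#' A sampling guard rejects pupil grids too coarse for the total phase
#' gradient (adjacent-sample phase step above pi would alias).
#'
#' @param model An [optical_model()].
#' @param mask A [cubic_phase_mask()] or `NULL` for the uncoded system.
#' @param z_um Defocus (um), within the model depth range.
#' @param field Normalized field position `c(u, v)` inside the unit disk;
#'   u indexes rows, v columns.
#' @param wavelength_nm Wavelength; default is the model's middle channel.
#' @param allow_extended Permit defocus up to twice the design depth range
#'   (relative defocus between a pixel and a focal plane during focal-stack
#'   rendering can reach 2x the range).
#' @return Matrix of class `psf` (unit sum) with attributes `dx_um`,
#'   `wavelength_nm`, `z_um`, `field`.
#' @export
simulate_psf <- function(model, mask = NULL, z_um = 0, field = c(0, 0),
                         wavelength_nm = NULL, allow_extended = FALSE) {
  stopifnot(inherits(model, "optical_model"))
  if (is.null(wavelength_nm)) {
    wavelength_nm <- model$wavelengths_nm[ceiling(length(model$wavelengths_nm) / 2)]
  }
  lambda_um <- wavelength_nm * 1e-3
  z_lim <- model$depth_range_um * if (allow_extended) 2 else 1
  if (abs(z_um) > z_lim + 1e-9) {
    stop("z_um outside the model depth range")
  }
  if (sum(field^2) > 1 + 1e-12) stop("field position outside the unit disk")
  G <- model$pupil_grid
  pc <- pupil_coords(G)
  ap <- pc$R2 <= 1
  ph <- pupil_phase(model, mask, z_um, field, lambda_um, pc)

  # anti-aliasing guard: largest phase step between adjacent aperture samples
  phm <- ph; phm[!ap] <- NA
  step_max <- max(abs(diff(phm)), abs(t(diff(t(phm)))), na.rm = TRUE)
  if (step_max > pi) {
    stop(sprintf(paste0("pupil grid too coarse: max phase step %.2f rad > pi; ",
                        "increase pupil_grid or reduce alpha/defocus"), step_max))
  }

  K <- G * model$pad_factor
  P <- matrix(0 + 0i, K, K)
  P[1:G, 1:G] <- ifelse(ap, exp(1i * ph), 0 + 0i)
  psf <- Mod(stats::fft(P))^2
  half <- K / 2
  idx <- c((half + 1):K, 1:half)
  psf <- psf[idx, idx]
  psf <- psf / sum(psf)
  structure(psf, class = "psf",
            dx_um = psf_pixel_um(model, wavelength_nm) /
              (1 + model$mag_per_um * z_um),
            wavelength_nm = wavelength_nm, z_um = z_um, field = field)
}

#' @export
print.psf <- function(x, ...) {
  cat("PSF", nrow(x), "x", ncol(x), "@", signif(attr(x, "dx_um"), 4),
      "um/px, z =", attr(x, "z_um"), "um, field =",
      paste(signif(attr(x, "field"), 3), collapse = ","), "\n")
  invisible(x)
}

#' @export
plot.psf <- function(x, log = FALSE, ...) {
  z <- unclass(x)
  if (log) z <- log10(z + max(z) * 1e-6)
  graphics::image(z, asp = 1, useRaster = TRUE, axes = FALSE, ...)
  invisible(x)
}

# 1-D overlap matrix for exact area-weighted rebinning from a fine grid
# (n_fine samples of width dx) to a coarse grid (width pitch), both centered.
overlap_matrix <- function(n_fine, dx, pitch, n_coarse) {
  fine_lo <- (seq_len(n_fine) - 1 - n_fine / 2) * dx
  coarse_lo <- (seq_len(n_coarse) - 1 - n_coarse / 2) * pitch
  B <- matrix(0, n_coarse, n_fine)
  for (i in seq_len(n_coarse)) {
    lo <- coarse_lo[i]; hi <- lo + pitch
    ov <- pmin(hi, fine_lo + dx) - pmax(lo, fine_lo)
    B[i, ] <- pmax(ov, 0) / dx
  }
  B
}

#' Integrate an oversampled PSF onto the sensor pixel grid
#'
#' Exact area-overlap binning (separable in x and y) from the fine simulation
#' grid to pixels of the given pitch, mimicking the integration performed by
#' the sensor. The result is optionally cropped to `size` x `size` pixels
#' about the center and renormalized to unit sum.
#'
#' @param psf A `psf` from [simulate_psf()] (attribute `dx_um` required).
#' @param pitch_um Sensor/object pixel pitch (um).
#' @param size Odd crop size in pixels, or `NULL` for no crop.
#' @param renormalize Renormalize to unit sum after binning/cropping.
#' @return Matrix of class `psf` at the sensor pitch.
#' @export
psf_to_sensor <- function(psf, pitch_um, size = NULL, renormalize = TRUE) {
  dx <- attr(psf, "dx_um")
  stopifnot(!is.null(dx), pitch_um > 0)
  n <- nrow(psf)
  n_c <- floor(n * dx / pitch_um / 2) * 2 + 1  # odd, covers the fine field
  B <- overlap_matrix(n, dx, pitch_um, n_c)
  out <- B %*% unclass(psf) %*% t(B)
  if (!is.null(size)) {
    if (size %% 2 == 0) stop("crop size must be odd")
    if (size > n_c) stop("crop size exceeds binned PSF extent")
    c0 <- (n_c + 1) / 2
    h <- (size - 1) / 2
    out <- out[(c0 - h):(c0 + h), (c0 - h):(c0 + h)]
  }
  if (renormalize) out <- out / sum(out)
  structure(out, class = "psf", dx_um = pitch_um,
            wavelength_nm = attr(psf, "wavelength_nm"),
            z_um = attr(psf, "z_um"), field = attr(psf, "field"))
}

#' Modulation transfer function of a PSF
#'
#' Modulus of the Fourier transform of the PSF, normalized so MTF(0) = 1.
#'
#' @param psf A `psf` matrix (any normalization) with attribute `dx_um`.
#' @return An object of class `mtf`: the 2-D MTF (DC at element \[1, 1\],
#'   unshifted) with attribute `df_cpum` (frequency bin spacing, cycles/um).
#' @export
mtf_from_psf <- function(psf) {
  dx <- attr(psf, "dx_um")
  if (is.null(dx)) dx <- 1
  O <- Mod(stats::fft(unclass(psf)))
  O <- O / O[1, 1]
  structure(O, class = "mtf", df_cpum = 1 / (nrow(psf) * dx))
}

#' Axis profile of a 2-D MTF
#'
#' @param mtf An `mtf` object.
#' @param axis `"x"`, `"y"`, or `"min"` (pointwise minimum of both axis
#'   profiles; conservative for non-isotropic coded MTFs).
#' @return Data frame with columns `freq` (cycles/um) and `mtf`, for bins
#'   0 .. K/2.
#' @export
mtf_profile <- function(mtf, axis = c("min", "x", "y")) {
  axis <- match.arg(axis)
  K <- nrow(mtf)
  n <- floor(K / 2) + 1
  px <- unclass(mtf)[1:n, 1]
  py <- unclass(mtf)[1, 1:n]
  p <- switch(axis, x = px, y = py, min = pmin(px, py))
  data.frame(freq = (0:(n - 1)) * attr(mtf, "df_cpum"), mtf = p)
}

#' MTF value at a frequency (linear interpolation on an axis profile)
#' @param mtf An `mtf` object.
#' @param freq_cpum Frequency in cycles/um.
#' @param axis Passed to [mtf_profile()].
#' @return Scalar MTF value.
#' @export
mtf_at <- function(mtf, freq_cpum, axis = "min") {
  pr <- mtf_profile(mtf, axis)
  stats::approx(pr$freq, pr$mtf, xout = freq_cpum, rule = 2)$y
}

#' MTF stack over the design depth range
#'
#' Simulates the PSF at every depth and collects 1-D MTF axis profiles into
#' a (frequency x defocus) stack, the input to [fisher_information()].
#'
#' @param model An [optical_model()].
#' @param mask A [cubic_phase_mask()] or `NULL`.
#' @param zs Defocus values (um); default the model depth grid.
#' @param field,wavelength_nm Passed to [simulate_psf()].
#' @param axis Profile direction, see [mtf_profile()].
#' @return Object of class `mtf_stack`: list with `mtf` (matrix freq x z),
#'   `freq` (cycles/um), `z_um`, `nyquist_cpum`.
#' @export
mtf_stack <- function(model, mask = NULL, zs = depth_grid(model),
                      field = c(0, 0), wavelength_nm = NULL, axis = "min") {
  profs <- lapply(zs, function(z) {
    mtf_profile(mtf_from_psf(simulate_psf(model, mask, z, field, wavelength_nm)),
                axis)
  })
  M <- vapply(profs, function(p) p$mtf, numeric(nrow(profs[[1]])))
  structure(list(mtf = M, freq = profs[[1]]$freq, z_um = zs,
                 nyquist_cpum = nyquist_frequency(model)),
            class = "mtf_stack")
}

#' Fisher-information merit of MTF depth-invariance
#'
#' Discrete squared defocus-derivative of the MTF, summed over all frequency
#' bins up to the Nyquist frequency and over adjacent depth planes:
#' FI = sum_f sum_z (MTF(f, z + dz) - MTF(f, z))^2 / dz^2. Zero iff all
#' planes are identical; small values mean defocus-invariant imaging.
#'
#' @param stack An `mtf_stack` (>= 2 depth planes).
#' @param max_freq_cpum Upper frequency bound; defaults to the stack Nyquist.
#' @return Non-negative scalar.
#' @export
fisher_information <- function(stack, max_freq_cpum = NULL) {
  stopifnot(inherits(stack, "mtf_stack"), length(stack$z_um) >= 2)
  if (is.null(max_freq_cpum)) max_freq_cpum <- stack$nyquist_cpum
  keep <- stack$freq <= max_freq_cpum + 1e-12
  M <- stack$mtf[keep, , drop = FALSE]
  dz <- diff(stack$z_um)
  if (any(dz <= 0)) stop("depth planes must be strictly increasing")
  D <- sweep(M[, -1, drop = FALSE] - M[, -ncol(M), drop = FALSE], 2, dz, "/")
  sum(D^2)
}

#' Minimum Nyquist-frequency MTF over a depth range
#'
#' Design constraint of the coded system: the MTF at the sensor Nyquist
#' frequency must stay above a floor (0.1) at every design depth, otherwise
#' information is irrecoverably lost.
#'
#' @param stack An `mtf_stack`.
#' @return Minimum over depth of the MTF at the Nyquist frequency.
#' @export
min_nyquist_mtf <- function(stack) {
  stopifnot(inherits(stack, "mtf_stack"))
  vals <- apply(stack$mtf, 2, function(m) {
    stats::approx(stack$freq, m, xout = stack$nyquist_cpum, rule = 2)$y
  })
  min(vals)
}

#' Sweep the cubic-phase modulation strength
#'
#' Enumerates candidate modulation strengths `alpha` from `alpha_min` to
#' `alpha_max` inclusively in steps of `alpha_step` (the design protocol uses
#' 0.005 to 0.075 in 0.005 steps, 15 candidates). Each candidate is scored by
#' the Fisher-information merit over the design depth range and by its minimum
#' Nyquist-frequency MTF; candidates with min Nyquist MTF >= `mtf_floor` are
#' feasible, and the selected design is the feasible candidate with minimum
#' Fisher information.
#'
#' @param model An [optical_model()].
#' @param alpha_min,alpha_max,alpha_step Sweep range (mm^-2), step > 0.
#' @param mtf_floor Nyquist MTF feasibility floor (default 0.1).
#' @param mask_semi_diameter,n_ref Mask geometry passed to [cubic_phase_mask()].
#' @param zs,wavelength_nm,field Passed to [mtf_stack()].
#' @return Object of class `alpha_sweep`: data frame with columns `alpha`,
#'   `fi`, `min_nyquist_mtf`, `feasible`, `rank` (rank 1 = selected among
#'   feasible; NA if infeasible), and attributes `selected` (alpha or NA) and
#'   `mtf_floor`. An empty feasible set is reported, not an error.
#' @export
sweep_alpha <- function(model, alpha_min = 0.005, alpha_max = 0.075,
                        alpha_step = 0.005, mtf_floor = 0.1,
                        mask_semi_diameter = 0.5, n_ref = 1.5,
                        zs = depth_grid(model), wavelength_nm = NULL,
                        field = c(0, 0)) {
  stopifnot(alpha_step > 0, alpha_min <= alpha_max)
  alphas <- seq(alpha_min, alpha_max + alpha_step * 1e-9, by = alpha_step)
  res <- lapply(alphas, function(a) {
    st <- mtf_stack(model, cubic_phase_mask(a, n_ref, mask_semi_diameter),
                    zs = zs, field = field, wavelength_nm = wavelength_nm)
    c(fi = fisher_information(st), mnm = min_nyquist_mtf(st))
  })
  fi <- vapply(res, `[[`, numeric(1), "fi")
  mnm <- vapply(res, `[[`, numeric(1), "mnm")
  feasible <- mnm >= mtf_floor
  rk <- rep(NA_integer_, length(alphas))
  if (any(feasible)) rk[feasible] <- rank(fi[feasible], ties.method = "first")
  out <- data.frame(alpha = alphas, fi = fi, min_nyquist_mtf = mnm,
                    feasible = feasible, rank = rk)
  structure(out, class = c("alpha_sweep", "data.frame"),
            selected = if (any(feasible)) alphas[which(rk == 1)] else NA_real_,
            mtf_floor = mtf_floor)
}

#' @export
print.alpha_sweep <- function(x, ...) {
  cat("Modulation-strength sweep:", nrow(x), "candidates, floor",
      attr(x, "mtf_floor"), "\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  sel <- attr(x, "selected")
  if (is.na(sel)) cat("No feasible candidate (empty feasible set).\n")
  else cat("Selected alpha:", sel, "\n")
  invisible(x)
}

#' Strehl ratio of a PSF
#'
#' Peak intensity relative to the diffraction-limited (uncoded, in-focus,
#' on-axis) PSF of the same model, grid and wavelength.
#'
#' @param psf A `psf` from [simulate_psf()] (unbinned).
#' @param model The [optical_model()] that produced it.
#' @return Scalar in (0, 1 + eps\].
#' @export
strehl_ratio <- function(psf, model) {
  ref <- simulate_psf(model, mask = NULL, z_um = 0, field = c(0, 0),
                      wavelength_nm = attr(psf, "wavelength_nm"))
  if (!isTRUE(all.equal(attr(psf, "dx_um"), attr(ref, "dx_um")))) {
    stop("PSF sampling differs from the reference grid; use an unbinned PSF")
  }
  max(psf) / max(ref)
}
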