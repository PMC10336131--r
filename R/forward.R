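# Shift-variant, depth-resolved image formation: brute-force superposition
# oracle, FFT-accelerated low-rank forward model, multi-depth propagation,
# and sensor noise.
#
# Coordinate convention (used everywhere): pixel indices are 0-based in the
# documentation, row-major, origin top-left; the PSF center sits at the
# floor-midpoint pixel (for an odd k x k PSF, offset (k-1)/2). Convolution is
# full linear convolution with zero padding, cropped back to the scene frame
# ("same" semantics).

#' 2-D linear convolution with "same" cropping
#'
#' FFT-based full linear convolution of an image with a kernel, zero-padded,
#' cropped so that a delta kernel centered at its floor-midpoint pixel acts
#' as the identity.
#'
#' @param x Image matrix.
#' @param k Kernel matrix (any size not larger than is representable; PSFs
#'   here are odd-sized).
#' @param adjoint If `TRUE`, apply the exact adjoint of the forward operator
#'   instead (correlation with the kernel, complementary crop offset).
#' @return Matrix of the same size as `x`.
#' @export
conv2_same <- function(x, k, adjoint = FALSE) {
  nx <- dim(x); nk <- dim(k)
  c0 <- floor(nk / 2)                       # 0-based kernel center
  if (adjoint) {
    k <- k[nk[1]:1, nk[2]:1, drop = FALSE]
    c0 <- nk - 1 - c0
  }
  np <- nx + nk - 1
  X <- matrix(0, np[1], np[2]); X[1:nx[1], 1:nx[2]] <- x
  K <- matrix(0, np[1], np[2]); K[1:nk[1], 1:nk[2]] <- k
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) /
    prod(np)
  full[(c0[1] + 1):(c0[1] + nx[1]), (c0[2] + 1):(c0[2] + nx[2]), drop = FALSE]
}

#' Synthetic imaging scene
#'
#' A non-negative sample intensity with an optional per-pixel depth map.
#'
#' @param intensity Matrix (h x w) or array (h x w x channels), >= 0.
#' @param depth_um Per-pixel depth map (h x w, um) or `NULL` (flat at 0).
#' @param pitch_um Pixel pitch (um).
#' @param field_extent Normalized field half-width spanned by the image
#'   (see [field_coords()]).
#' @return Object of class `scene`.
#' @export
scene <- function(intensity, depth_um = NULL, pitch_um = 2, field_extent = 0.7) {
  if (is.matrix(intensity)) intensity <- array(intensity, c(dim(intensity), 1))
  stopifnot(length(dim(intensity)) == 3)
  if (min(intensity) < -1e-9 * max(abs(intensity))) {
    stop("intensity must be non-negative")
  }
  intensity <- pmax(intensity, 0)   # clamp FFT round-off
  if (!is.null(depth_um)) {
    stopifnot(all(dim(depth_um) == dim(intensity)[1:2]))
  }
  structure(list(intensity = intensity, depth_um = depth_um,
                 pitch_um = pitch_um, field_extent = field_extent),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$intensity)
  cat("Scene", d[1], "x", d[2], "px,", d[3], "channel(s),",
      if (is.null(x$depth_um)) "flat depth" else
        paste0("depth ", signif(min(x$depth_um), 3), "..",
               signif(max(x$depth_um), 3), " um"), "\n")
  invisible(x)
}

#' Snap a continuous depth map to a depth grid
#'
#' Nearest-grid-depth assignment (one-hot per pixel); ties resolve to the
#' first (shallower) grid depth.
#'
#' @param depth_um Depth map matrix (um).
#' @param zs Grid depths (um).
#' @return Matrix of snapped depths, same shape as `depth_um`.
#' @export
snap_depths <- function(depth_um, zs) {
  idx <- vapply(as.vector(depth_um), function(d) which.min(abs(zs - d)),
                integer(1))
  matrix(zs[idx], nrow(depth_um), ncol(depth_um))
}

#' Brute-force shift-variant superposition (oracle forward model)
#'
#' Direct evaluation of the superposition imaging equation
#' i(x, y) = sum_\{u, v\} s(u, v) p(u, v, x - u, y - v): every scene pixel
#' deposits its own field-dependent PSF, zero-padded outside the frame.
#' O(pixels x PSF size) work; intended as the exactness oracle for
#' [forward_lowrank()] on small scenes.
#'
#' @param sc A [scene()] (single depth; the depth map is ignored here).
#' @param psf_lookup Function `(u, v) -> PSF matrix` giving the local PSF at
#'   normalized field position (u, v) at the scene's sensor pitch (odd size).
#' @param channel Channel of the scene to image.
#' @return Matrix: the coded capture, same size as the scene.
#' @export
forward_superposition <- function(sc, psf_lookup, channel = 1) {
  stopifnot(inherits(sc, "scene"))
  s <- sc$intensity[, , channel]
  h <- nrow(s); w <- ncol(s)
  fc <- field_coords(h, w, sc$field_extent)
  p0 <- psf_lookup(fc$u[1], fc$v[1])
  nk <- dim(p0); c0 <- floor(nk / 2)
  acc <- matrix(0, h + nk[1] - 1, w + nk[2] - 1)
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      si <- s[i, j]
      if (si == 0) next
      p <- psf_lookup(fc$u[i], fc$v[j])
      acc[i:(i + nk[1] - 1), j:(j + nk[2] - 1)] <-
        acc[i:(i + nk[1] - 1), j:(j + nk[2] - 1)] + si * p
    }
  }
  acc[(c0[1] + 1):(c0[1] + h), (c0[2] + 1):(c0[2] + w), drop = FALSE]
}

#' FFT-accelerated low-rank shift-variant forward model
#'
#' Images a single-depth scene through the factorized shift-variant system:
#' i = sum_\{i=1..N\} (s * w_i) conv h_i, each convolution computed in the
#' frequency domain with zero padding to full linear convolution and a
#' center crop back to the scene frame.
#'
#' @param sc A [scene()].
#' @param basis A `basis_model` for the scene's depth plane.
#' @param weight_maps Optional precomputed maps from
#'   [interpolate_coefficients()] (h x w x N); computed on the fly otherwise.
#' @return Object of class `capture`: array h x w x channels, >= 0.
#' @export
forward_lowrank <- function(sc, basis, weight_maps = NULL) {
  stopifnot(inherits(sc, "scene"), inherits(basis, "basis_model"))
  d <- dim(sc$intensity)
  C <- d[3]
  if (is.null(weight_maps)) {
    weight_maps <- interpolate_coefficients(basis, d[1:2], sc$field_extent)
  }
  if (!all(dim(weight_maps)[1:2] == d[1:2])) {
    stop("weight maps do not match the scene shape")
  }
  N <- dim(weight_maps)[3]
  out <- array(0, d)
  for (c in seq_len(C)) {
    cc <- min(c, dim(basis$H)[3])
    acc <- matrix(0, d[1], d[2])
    for (i in seq_len(N)) {
      hi <- matrix(basis$H[, i, cc], basis$dim_yx[1], basis$dim_yx[2])
      acc <- acc + conv2_same(sc$intensity[, , c] * weight_maps[, , i], hi)
    }
    out[, , c] <- acc
  }
  out <- pmax(out, 0)   # clamp FFT round-off
  structure(out, class = "capture", pitch_um = sc$pitch_um)
}

#' Propagate a depth-mapped scene / focal stack through the coded system
#'
#' Decomposes the scene by depth (each pixel snapped to the nearest grid
#' depth, one-hot assignment), images every depth slice with its own basis
#' model, and sums the contributions (slices combine additively).
#'
#' @param sc A [scene()] with a depth map (or flat, treated as z = 0).
#' @param basis_set Named list of `basis_model`s keyed by depth in um
#'   (names as produced by [make_basis_set()]); every scene depth must be
#'   covered.
#' @return A `capture` array (h x w x channels).
#' @export
propagate_focal_stack <- function(sc, basis_set) {
  stopifnot(inherits(sc, "scene"))
  zs <- suppressWarnings(as.numeric(names(basis_set)))
  if (length(zs) == 0 || any(is.na(zs))) {
    stop("basis_set must be named by depth (um)")
  }
  d <- dim(sc$intensity)
  depth <- if (is.null(sc$depth_um)) matrix(0, d[1], d[2]) else sc$depth_um
  snapped <- snap_depths(depth, zs)
  out <- array(0, d)
  for (z in sort(unique(as.vector(snapped)))) {
    bi <- which(abs(zs - z) < 1e-6)
    if (length(bi) != 1) stop("missing basis for depth ", z, " um")
    mask <- snapped == z
    slice <- sc$intensity * as.vector(mask)   # recycles over channels
    cap <- forward_lowrank(scene(slice, NULL, sc$pitch_um, sc$field_extent),
                           basis_set[[bi]])
    out <- out + unclass(cap)
  }
  structure(out, class = "capture", pitch_um = sc$pitch_um)
}

#' Factorize a PSF grid at several depths
#'
#' Convenience builder: assembles the PSF matrix and runs [hals_nmf()] at
#' each requested depth, returning the named list consumed by
#' [propagate_focal_stack()].
#'
#' @param grid A `psf_grid`.
#' @param zs Depths (um), default all grid depths.
#' @param rank,iterations,seed,channel_uniform Passed to [hals_nmf()].
#' @return Named list of `basis_model`s (names = depth in um).
#' @export
make_basis_set <- function(grid, zs = grid$z_um, rank = 9, iterations = 100,
                           seed = 0, channel_uniform = TRUE) {
  out <- lapply(zs, function(z) {
    hals_nmf(assemble_psf_matrix(grid, z), rank = rank,
             iterations = iterations, seed = seed,
             channel_uniform = channel_uniform)
  })
  names(out) <- as.character(zs)
  out
}

#' Add sensor noise to a capture
#'
#' Signal-dependent shot noise (Poisson statistics at `gain` photoelectrons
#' per intensity unit) plus additive Gaussian read noise, clipped at zero.
#' Reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param capture A `capture` or non-negative array/matrix.
#' @param gain Photoelectrons per intensity unit (> 0; `Inf` disables shot
#'   noise).
#' @param read_sigma Read-noise standard deviation (intensity units, >= 0).
#' @param seed Integer seed.
#' @return Noisy capture, same shape and class.
#' @export
add_sensor_noise <- function(capture, gain = 100, read_sigma = 0.01, seed = 0) {
  stopifnot(gain > 0, read_sigma >= 0)
  x <- unclass(capture)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  if (is.finite(gain)) {
    lam <- x * gain
    big <- lam > 1e7          # gaussian limit; rpois is unstable there
    y <- numeric(length(lam))
    y[!big] <- stats::rpois(sum(!big), lam[!big])
    y[big] <- lam[big] + sqrt(lam[big]) * stats::rnorm(sum(big))
    x <- array(y / gain, dim(x) %||% length(x))
  }
  if (read_sigma > 0) x <- x + array(stats::rnorm(length(x), 0, read_sigma),
                                     dim(x) %||% length(x))
  out <- pmax(x, 0)
  if (!is.null(dim(capture))) dim(out) <- dim(capture)
  attributes(out) <- attributes(capture)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
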