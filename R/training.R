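# Simulation-supervision pipeline: synthetic scenes and focal stacks, depth
# fusion to all-in-focus labels, coded-capture/label pairing, and patch
# extraction.

#' Generate a synthetic scene with a depth map
#'
#' Reproducible synthetic samples emulating thick microscopy specimens:
#' `beads` (Gaussian spots), `bars` (resolution-target-like bar groups),
#' `texture` (band-passed positive noise), or `mixed` (all three). The depth
#' map is a tilted plane spanning the full +/- `depth_range_um` along the
#' column axis (`depth = "tilted"`), a flat plane at 0, or piecewise-planar
#' steps.
#'
#' @param kind One of `"mixed"`, `"beads"`, `"bars"`, `"texture"`.
#' @param size Image side in pixels (>= 64).
#' @param density Feature density in (0, 1\]; scales the number of beads/bars.
#' @param seed Integer seed; scenes are bitwise reproducible.
#' @param depth `"tilted"`, `"flat"` or `"steps"`.
#' @param depth_range_um Depth half-range of the tilted/step map (um).
#' @param n_channels Number of color channels (features shared, per-channel
#'   brightness jitter).
#' @param band_limit_sigma Gaussian blur sigma (pixels) applied to the
#'   pattern so the scene respects the optical band limit (a 3 um resolution
#'   system sampled at 2 um cannot form pixel-level detail); 0 disables.
#' @param pitch_um,field_extent Passed to [scene()].
#' @return A [scene()].
#' @export
synth_scene <- function(kind = c("mixed", "beads", "bars", "texture"),
                        size = 256, density = 0.02, seed = 0,
                        depth = c("tilted", "flat", "steps"),
                        depth_range_um = 150, n_channels = 1,
                        band_limit_sigma = 0.75,
                        pitch_um = 2, field_extent = 0.7) {
  kind <- match.arg(kind)
  depth <- match.arg(depth)
  stopifnot(size >= 64, density > 0, density <= 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  img <- matrix(0, size, size)
  if (kind %in% c("beads", "mixed")) {
    n_beads <- max(round(density * size^2 / 40), if (kind == "beads") 0 else 1)
    if (n_beads > 0) {
      ci <- stats::runif(n_beads, 4, size - 3)
      cj <- stats::runif(n_beads, 4, size - 3)
      amp <- stats::runif(n_beads, 0.5, 1)
      sg <- stats::runif(n_beads, 0.8, 1.6)
      ix <- seq_len(size)
      for (b in seq_len(n_beads)) {
        gi <- exp(-(ix - ci[b])^2 / (2 * sg[b]^2))
        gj <- exp(-(ix - cj[b])^2 / (2 * sg[b]^2))
        img <- img + amp[b] * outer(gi, gj)
      }
    }
  }
  if (kind %in% c("bars", "mixed")) {
    n_groups <- max(1, round(density * size / 4))
    for (g in seq_len(n_groups)) {
      per <- sample(4:10, 1)
      bw <- max(1, per %/% 2)
      i0 <- sample.int(size - 4 * per, 1)
      j0 <- sample.int(size - 4 * per, 1)
      len <- sample(seq(2 * per, 4 * per), 1)
      amp <- stats::runif(1, 0.6, 1)
      horiz <- stats::runif(1) < 0.5
      for (b in 0:2) {
        o <- b * per
        if (horiz) img[i0 + o + seq_len(bw) - 1, j0:(j0 + len - 1)] <-
            img[i0 + o + seq_len(bw) - 1, j0:(j0 + len - 1)] + amp
        else img[i0:(i0 + len - 1), j0 + o + seq_len(bw) - 1] <-
            img[i0:(i0 + len - 1), j0 + o + seq_len(bw) - 1] + amp
      }
    }
  }
  if (kind %in% c("texture", "mixed")) {
    z <- matrix(stats::rnorm(size^2), size, size)
    g5 <- gaussian_kernel(2)
    lo <- conv2_same(z, g5)
    tex <- z - lo                       # band-passed
    tex <- tex / max(abs(tex))
    img <- img + pmax(tex, 0) * if (kind == "mixed") 0.5 else 1
  }
  if (band_limit_sigma > 0) {
    img <- pmax(conv2_same(img, gaussian_kernel(band_limit_sigma)), 0)
  }
  img <- img / max(img, 1e-12)

  dmap <- switch(depth,
    flat = matrix(0, size, size),
    tilted = matrix(seq(-depth_range_um, depth_range_um, length.out = size),
                    size, size, byrow = TRUE),
    steps = {
      nstep <- 5
      lv <- seq(-depth_range_um, depth_range_um, length.out = nstep)
      matrix(lv[pmin(nstep, 1 + (col(img) - 1) %/% ceiling(size / nstep))],
             size, size)
    })

  arr <- array(NA_real_, c(size, size, n_channels))
  for (c in seq_len(n_channels)) {
    arr[, , c] <- img * stats::runif(1, 0.8, 1)
  }
  scene(arr, dmap, pitch_um, field_extent)
}

#' Normalized 2-D Gaussian kernel
#'
#' Separable Gaussian, truncated at 3 sigma by default (odd support),
#' normalized to unit sum.
#'
#' @param sigma Standard deviation in pixels.
#' @param half Half-width of the support (default `ceiling(3 * sigma)`).
#' @return (2 half + 1) square matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, half = NULL) {
  if (is.null(half)) half <- max(1, ceiling(3 * sigma))
  x <- (-half):half
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Render a focal stack of a depth-mapped scene
#'
#' Emulates a conventional-microscope focal scan: for each focal plane z,
#' every scene pixel at depth d is blurred by the uncoded (alpha = 0)
#' on-axis PSF at defocus (d - z). Pixels are sharpest in the slice focused
#' at their own depth.
#'
#' @param sc A [scene()] with a depth map.
#' @param model An [optical_model()].
#' @param zs Focal plane positions (um), default the model depth grid.
#' @param psf_size Odd crop (sensor pixels) of the defocus PSFs.
#' @return Object of class `focal_stack`: list with `slices`
#'   (h x w x channels x Z array), `z_um`, `pitch_um`, `field_extent`.
#' @export
render_focal_stack <- function(sc, model, zs = depth_grid(model),
                               psf_size = 41) {
  stopifnot(inherits(sc, "scene"), inherits(model, "optical_model"))
  d <- dim(sc$intensity)
  depth <- if (is.null(sc$depth_um)) matrix(0, d[1], d[2]) else sc$depth_um
  snapped <- snap_depths(depth, zs)
  ds <- sort(unique(as.vector(snapped)))
  # cache sensor-pitch uncoded PSFs by defocus offset
  offsets <- sort(unique(round(as.vector(outer(ds, zs, "-")), 6)))
  cache <- new.env(parent = emptyenv())
  get_psf <- function(off) {
    key <- sprintf("%.6f", off)
    if (is.null(cache[[key]])) {
      p <- simulate_psf(model, NULL, z_um = off, allow_extended = TRUE)
      cache[[key]] <- unclass(psf_to_sensor(p, sc$pitch_um, size = psf_size))
    }
    cache[[key]]
  }
  slices <- array(0, c(d[1], d[2], d[3], length(zs)))
  for (zi in seq_along(zs)) {
    for (dd in ds) {
      mask <- snapped == dd
      if (!any(mask)) next
      p <- get_psf(round(dd - zs[zi], 6))
      for (c in seq_len(d[3])) {
        slices[, , c, zi] <- slices[, , c, zi] +
          conv2_same(sc$intensity[, , c] * mask, p)
      }
    }
  }
  structure(list(slices = slices, z_um = zs, pitch_um = sc$pitch_um,
                 field_extent = sc$field_extent),
            class = "focal_stack")
}

#' @export
print.focal_stack <- function(x, ...) {
  d <- dim(x$slices)
  cat("Focal stack:", d[4], "slices of", d[1], "x", d[2], "px,", d[3],
      "channel(s), z", min(x$z_um), "..", max(x$z_um), "um\n")
  invisible(x)
}

# Box filter via cumulative sums (same-size, zero padding outside).
box_filter <- function(x, half) {
  n1 <- nrow(x); n2 <- ncol(x)
  cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed integral image
  cs <- t(cs)
  pad <- matrix(0, n1 + 1, n2 + 1)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- cs
  i1 <- pmax(seq_len(n1) - half, 1); i2 <- pmin(seq_len(n1) + half, n1)
  j1 <- pmax(seq_len(n2) - half, 1); j2 <- pmin(seq_len(n2) + half, n2)
  pad[i2 + 1, j2 + 1] - pad[i1, j2 + 1] - pad[i2 + 1, j1] + pad[i1, j1]
}

#' Per-pixel focus measure (local Laplacian energy)
#'
#' Squared discrete Laplacian, box-summed over a window. High values mean
#' locally sharp structure.
#'
#' @param img Matrix.
#' @param window Odd window size (default 11).
#' @return Matrix of focus-measure values.
#' @export
focus_measure <- function(img, window = 11) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  L <- conv2_same(img, lap)
  box_filter(L^2, (window - 1) %/% 2)
}

#' Depth fusion of a focal stack (all-in-focus composite)
#'
#' Per-pixel focus measure (local Laplacian energy, summed over channels),
#' winner-take-all slice index (pixels without focus evidence inherit the
#' modal index of the evidenced pixels), majority smoothing of the index
#' map, then per-pixel assembly of the fused image from the winning slices.
#'
#' @param stack A `focal_stack` with >= 2 slices.
#' @param window Focus-measure window (odd, default 11).
#' @param smooth Majority-filter window for the index map (odd; 1 disables).
#' @param min_evidence Focus-evidence floor as a fraction of the maximum
#'   focus measure (default 0.01, i.e. local contrast below 10% of the
#'   strongest feature); pixels below it are featureless background, prone
#'   to defocus-halo winners, and inherit the modal index of the evidenced
#'   pixels.
#' @return List with `fused` (h x w x channels), `index_map` (winning slice
#'   index per pixel), `focus` (h x w x Z focus measures).
#' @export
depth_fusion <- function(stack, window = 11, smooth = 5,
                         min_evidence = 0.01) {
  stopifnot(inherits(stack, "focal_stack"))
  d <- dim(stack$slices)
  if (d[4] < 2) stop("need at least 2 slices")
  fm <- array(0, c(d[1], d[2], d[4]))
  for (zi in seq_len(d[4])) {
    for (c in seq_len(d[3])) {
      fm[, , zi] <- fm[, , zi] + focus_measure(stack$slices[, , c, zi], window)
    }
  }
  idx <- apply(fm, c(1, 2), which.max)
  # pixels with essentially no focus evidence (flat background) carry no
  # depth information; give them the modal index of the evidenced pixels
  conf <- apply(fm, c(1, 2), max)
  low <- conf < min_evidence * max(conf)
  if (any(low) && !all(low)) {
    idx[low] <- as.integer(names(which.max(table(idx[!low]))))
  }
  if (smooth > 1) {
    half <- (smooth - 1) %/% 2
    votes <- array(0, c(d[1], d[2], d[4]))
    for (zi in seq_len(d[4])) {
      votes[, , zi] <- box_filter((idx == zi) * 1, half)
    }
    idx <- apply(votes, c(1, 2), which.max)
  }
  fused <- array(0, d[1:3])
  flat <- cbind(rep(seq_len(d[1]), d[2]), rep(seq_len(d[2]), each = d[1]),
                as.vector(idx))
  for (c in seq_len(d[3])) {
    fused[, , c] <- matrix(stack$slices[cbind(flat[, 1], flat[, 2],
                                              rep(c, nrow(flat)), flat[, 3])],
                           d[1], d[2])
  }
  list(fused = fused, index_map = idx, focus = fm)
}

#' Build a simulation-supervised training pair
#'
#' The label is the all-in-focus depth fusion of the stack; its fusion index
#' map assigns every pixel a depth, and the resulting depth-decomposed scene
#' is propagated through the coded system (optionally with sensor noise) to
#' form the network input.
#'
#' @param stack A `focal_stack`.
#' @param basis_set Named list of `basis_model`s covering the stack depths
#'   (see [make_basis_set()]).
#' @param noise `NULL` for a clean input, else `list(gain =, read_sigma =)`.
#' @param seed Seed for the noise stage.
#' @param window,smooth Passed to [depth_fusion()].
#' @return Object of class `training_pair`: list with `input`, `label`
#'   (h x w x channels), `index_map`, `z_um`, `patches` (filled by
#'   [patchify()]).
#' @export
make_training_pair <- function(stack, basis_set, noise = NULL, seed = 0,
                               window = 11, smooth = 5) {
  stopifnot(inherits(stack, "focal_stack"))
  zs <- stack$z_um
  if (!all(as.character(zs) %in% names(basis_set))) {
    stop("basis_set does not cover all stack depths")
  }
  fu <- depth_fusion(stack, window, smooth)
  depth <- matrix(zs[fu$index_map], nrow(fu$index_map), ncol(fu$index_map))
  sc <- scene(fu$fused, depth, stack$pitch_um, stack$field_extent)
  input <- propagate_focal_stack(sc, basis_set)
  if (!is.null(noise)) {
    input <- add_sensor_noise(input, gain = noise$gain,
                              read_sigma = noise$read_sigma, seed = seed)
  }
  structure(list(input = unclass(input), label = fu$fused,
                 index_map = fu$index_map, z_um = zs, patches = NULL,
                 pitch_um = stack$pitch_um),
            class = "training_pair")
}

#' Extract aligned random patches from a training pair
#'
#' Draws `n_patches` uniform random patch corners (reproducible per seed)
#' and crops identical windows from input and label. The full-scale protocol
#' uses 20 patches of 512 x 512 per image.
#'
#' @param pair A `training_pair`.
#' @param n_patches Number of patches.
#' @param size Patch side (pixels); the pair must be at least this large.
#' @param seed Integer seed.
#' @return List of `n_patches` elements, each `list(input, label, corner)`
#'   where `corner` is the 1-based top-left (row, col).
#' @export
patchify <- function(pair, n_patches = 20, size = 512, seed = 0) {
  stopifnot(inherits(pair, "training_pair"))
  d <- dim(pair$input)
  if (d[1] < size || d[2] < size) stop("image smaller than the patch size")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  ci <- sample.int(d[1] - size + 1, n_patches, replace = TRUE)
  cj <- sample.int(d[2] - size + 1, n_patches, replace = TRUE)
  lapply(seq_len(n_patches), function(k) {
    ri <- ci[k]:(ci[k] + size - 1); rj <- cj[k]:(cj[k] + size - 1)
    list(input = pair$input[ri, rj, , drop = FALSE],
         label = pair$label[ri, rj, , drop = FALSE],
         corner = c(ci[k], cj[k]))
  })
}
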