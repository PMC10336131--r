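# Shared fixtures and independent oracles for the test suite.

# Small optical models: fast pupil grids, coarse depth steps.
tiny_model <- function(...) {
  optical_model(pupil_grid = 64, depth_step_um = 75, ...)
}
small_model <- function(...) {
  optical_model(pupil_grid = 128, depth_step_um = 75, ...)
}

# A coded PSF grid + basis set on the small model, memoized across tests.
.fixture_env <- new.env(parent = emptyenv())
coded_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    m <- small_model()
    mask <- cubic_phase_mask(0.03)
    grid <- simulate_psf_grid(m, mask, field_grid(3), wavelengths_nm = 530,
                              crop = 31)
    basis_set <- make_basis_set(grid, rank = 6, iterations = 120, seed = 0)
    .fixture_env$fx <- list(model = m, mask = mask, grid = grid,
                            basis_set = basis_set)
  }
  .fixture_env$fx
}

# Hand-built exact low-rank basis model (no fitting): two known PSFs on a
# 2 x 2 field grid with random non-negative coefficients.
manual_basis <- function(seed = 1, n_px = 9) {
  set.seed(seed)
  fg <- field_grid(2)
  h1 <- matrix(0, n_px, n_px); h1[(n_px + 1) / 2, (n_px + 1) / 2] <- 1
  h2 <- gaussian_kernel(1.2, (n_px - 1) / 2)
  H <- array(c(as.vector(h1), as.vector(h2)), c(n_px^2, 2, 1))
  W <- matrix(stats::runif(8), 2, 4)
  structure(list(H = H, W = W, residual_trace = 0,
                 field_uv = as.data.frame(fg), dim_yx = c(n_px, n_px),
                 z_um = 0, channel_uniform = TRUE, rank = 2,
                 interpolation = "bilinear", pitch_um = 2, meta = list()),
            class = "basis_model")
}

# PSF lookup matching manual_basis: bilinear coefficient interpolation done
# independently of interpolate_coefficients (direct arithmetic on the 2 x 2
# grid with constant extrapolation).
manual_lookup <- function(basis) {
  fu <- basis$field_uv
  us <- sort(unique(fu$u)); vs <- sort(unique(fu$v))
  hs <- lapply(seq_len(basis$rank), function(i) {
    matrix(basis$H[, i, 1], basis$dim_yx[1], basis$dim_yx[2])
  })
  function(u, v) {
    cu <- min(max(u, us[1]), us[2]); cv <- min(max(v, vs[1]), vs[2])
    tu <- (cu - us[1]) / (us[2] - us[1])
    tv <- (cv - vs[1]) / (vs[2] - vs[1])
    out <- 0
    for (i in seq_len(basis$rank)) {
      Wg <- matrix(NA, 2, 2)
      Wg[cbind(match(fu$u, us), match(fu$v, vs))] <- basis$W[i, ]
      wi <- (1 - tu) * (1 - tv) * Wg[1, 1] + tu * (1 - tv) * Wg[2, 1] +
        (1 - tu) * tv * Wg[1, 2] + tu * tv * Wg[2, 2]
      out <- out + wi * hs[[i]]
    }
    out
  }
}

# Direct spatial-domain "same" convolution (zero padding), independent of
# the package's FFT path: explicit shift-and-add over kernel taps.
direct_conv_same <- function(x, k) {
  h <- nrow(x); w <- ncol(x); nk <- dim(k); c0 <- floor(nk / 2)
  out <- matrix(0, h, w)
  for (a in seq_len(nk[1])) {
    for (b in seq_len(nk[2])) {
      di <- a - 1 - c0[1]; dj <- b - 1 - c0[2]
      si <- max(1, 1 - di):min(h, h - di)
      sj <- max(1, 1 - dj):min(w, w - dj)
      xs <- matrix(0, h, w)
      xs[si + di, sj + dj] <- x[si, sj]
      out <- out + k[a, b] * xs
    }
  }
  out
}

# Textbook Richardson-Lucy with flux normalization, built on the direct
# spatial convolution above (fully independent of the package solver).
rl_textbook <- function(I, k, n_iter) {
  S <- matrix(mean(I), nrow(I), ncol(I))
  kf <- k[nrow(k):1, ncol(k):1]
  eps <- 1e-8 * max(I)
  sens <- direct_conv_same(matrix(1, nrow(I), ncol(I)), kf)
  sens <- pmax(sens, 1e-8 * max(sens))
  for (i in seq_len(n_iter)) {
    blur <- direct_conv_same(S, k)
    R <- I / pmax(blur, eps)
    S <- S * direct_conv_same(R, kf) / sens
  }
  S
}
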