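# Classical restoration: TV-regularized ADMM deconvolution (shift-invariant)
# and the shift-variant Richardson-Lucy iteration with a total-variation
# regularization factor.

#' Deconvolution parameters
#'
#' @param lambda_tv TV regularization weight (dimensionless, >= 0); the
#'   design value is 0.00015.
#' @param iterations Iteration budget (>= 1); both solvers are
#'   iteration-capped, convergence is not an error.
#' @param epsilon Relative guard for gradient magnitudes and ratio
#'   denominators (scaled by the data maximum).
#' @param rho ADMM penalty parameter.
#' @param boundary `"zero"` (pad with zeros to linear convolution) for the
#'   RL solver; the ADMM solver works on a replicate-padded periodic domain.
#' @param adjoint `"exact"` back-projects with the true adjoint of the
#'   forward operator (correlation with each basis PSF, weight maps applied
#'   outside); `"literal"` back-projects with the unflipped PSF and the
#'   weights inside the convolution, as the iteration is usually written.
#'   Both coincide for centro-symmetric PSFs.
#' @return Object of class `deconv_params`.
#' @export
deconv_params <- function(lambda_tv = 0.00015, iterations = 50,
                          epsilon = 1e-8, rho = 1,
                          boundary = c("zero", "periodic"),
                          adjoint = c("exact", "literal")) {
  stopifnot(lambda_tv >= 0, iterations >= 1, epsilon > 0, rho > 0)
  structure(list(lambda_tv = lambda_tv, iterations = iterations,
                 epsilon = epsilon, rho = rho,
                 boundary = match.arg(boundary),
                 adjoint = match.arg(adjoint)),
            class = "deconv_params")
}

# Forward differences with symmetric (replicated last row/col) boundary,
# and the divergence defined as their negative adjoint.
grad_fwd <- function(x) {
  gx <- rbind(x[-1, , drop = FALSE], x[nrow(x), , drop = FALSE]) - x
  gy <- cbind(x[, -1, drop = FALSE], x[, ncol(x), drop = FALSE]) - x
  list(gx = gx, gy = gy)
}

div_bwd <- function(gx, gy) {
  n <- nrow(gx); m <- ncol(gx)
  dx <- gx - rbind(matrix(0, 1, m), gx[-n, , drop = FALSE])
  dx[n, ] <- -gx[n - 1, ]
  dy <- gy - cbind(matrix(0, n, 1), gy[, -m, drop = FALSE])
  dy[, m] <- -gy[, m - 1]
  dx + dy
}

# Centered PSF -> OTF on an n1 x n2 periodic domain.
psf_to_otf <- function(k, n1, n2) {
  nk <- dim(k)
  K <- matrix(0, n1, n2)
  K[1:nk[1], 1:nk[2]] <- k
  c0 <- floor(nk / 2)
  K <- K[c((c0[1] + 1):n1, 1:c0[1]), c((c0[2] + 1):n2, 1:c0[2])]
  stats::fft(K)
}

#' TV-regularized deconvolution by ADMM (shift-invariant PSF)
#'
#' Approximates argmin_S ||A S - I||^2 + lambda_TV ||D S||_1 with A a
#' shift-invariant blur and D the forward-difference gradient, by the
#' alternating direction method of multipliers with variable splitting on
#' the gradient (soft-thresholding for the l1 term, closed-form Fourier
#' solve for the quadratic subproblem). The image is replicate-padded by the
#' PSF half-width so the periodic solve approximates zero-gradient
#' boundaries, then cropped back.
#'
#' @param capture Observed image (matrix or h x w x C array), >= 0.
#' @param psf Shift-invariant PSF (odd-sized matrix, unit sum recommended).
#' @param params A [deconv_params()].
#' @return List with `estimate` (same shape as capture) and `objective`
#'   (per-iteration data term + TV term, one column per channel).
#' @export
admm_tv_deconv <- function(capture, psf, params = deconv_params()) {
  x3 <- if (is.matrix(capture)) array(capture, c(dim(capture), 1)) else capture
  C <- dim(x3)[3]
  est <- array(NA_real_, dim(x3))
  obj <- matrix(NA_real_, params$iterations, C)
  for (c in seq_len(C)) {
    r <- admm_tv_channel(x3[, , c], psf, params)
    est[, , c] <- r$estimate
    obj[, c] <- r$objective
  }
  if (is.matrix(capture)) est <- est[, , 1]
  list(estimate = est, objective = obj)
}

admm_tv_channel <- function(I0, psf, params) {
  nk <- dim(psf)
  pad <- floor(max(nk) / 2)
  n10 <- nrow(I0); n20 <- ncol(I0)
  ii <- pmin(pmax(seq_len(n10 + 2 * pad) - pad, 1), n10)
  jj <- pmin(pmax(seq_len(n20 + 2 * pad) - pad, 1), n20)
  I <- I0[ii, jj]
  n1 <- nrow(I); n2 <- ncol(I)
  Kf <- psf_to_otf(psf, n1, n2)
  # spectra of the forward-difference operators (periodic):
  # d/dx kernel = delta(+1 row) - delta(0)
  Dx <- matrix(0, n1, n2); Dx[1, 1] <- -1; Dx[2, 1] <- 1
  Dy <- matrix(0, n1, n2); Dy[1, 1] <- -1; Dy[1, 2] <- 1
  Dxf <- stats::fft(Dx); Dyf <- stats::fft(Dy)
  lam <- params$lambda_tv; rho <- params$rho
  denom <- Mod(Kf)^2 + rho * (Mod(Dxf)^2 + Mod(Dyf)^2)
  denom[denom < 1e-12] <- 1e-12
  KtI <- Conj(Kf) * stats::fft(I)
  x <- I
  gx <- Re(stats::fft(Dxf * stats::fft(x), inverse = TRUE)) / (n1 * n2)
  gy <- Re(stats::fft(Dyf * stats::fft(x), inverse = TRUE)) / (n1 * n2)
  zx <- gx; zy <- gy
  ux <- matrix(0, n1, n2); uy <- matrix(0, n1, n2)
  objective <- numeric(params$iterations)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  for (it in seq_len(params$iterations)) {
    rhs <- KtI + rho * (Conj(Dxf) * stats::fft(zx - ux) +
                        Conj(Dyf) * stats::fft(zy - uy))
    x <- Re(stats::fft(rhs / denom, inverse = TRUE)) / (n1 * n2)
    gx <- Re(stats::fft(Dxf * stats::fft(x), inverse = TRUE)) / (n1 * n2)
    gy <- Re(stats::fft(Dyf * stats::fft(x), inverse = TRUE)) / (n1 * n2)
    zx <- soft(gx + ux, lam / (2 * rho))
    zy <- soft(gy + uy, lam / (2 * rho))
    ux <- ux + gx - zx
    uy <- uy + gy - zy
    Ax <- Re(stats::fft(Kf * stats::fft(x), inverse = TRUE)) / (n1 * n2)
    objective[it] <- sum((Ax - I)^2) + lam * sum(abs(gx) + abs(gy))
  }
  list(estimate = x[pad + seq_len(n10), pad + seq_len(n20)],
       objective = objective)
}

#' Shift-variant Richardson-Lucy deconvolution with TV regularization
#'
#' Multiplicative RL iteration against the low-rank shift-variant forward
#' operator. Per iteration k:
#' \enumerate{
#'   \item TV factor: TV_k = 1 / (1 - lambda_TV div(grad S_k / |grad S_k|)),
#'     with |grad S_k| guarded below by epsilon * max(capture);
#'   \item forward blur: I*_k = sum_i (a_i S_k) conv p_i;
#'   \item ratio: R_k = I / I*_k with a guarded denominator;
#'   \item back-projection E*_k: exact adjoint sum_i a_i (R_k corr p_i), or
#'     the literal sum_i (a_i R_k) conv p_i, normalized by the
#'     operator sensitivity (the same back-projection applied to a unit
#'     image), the standard Richardson-Lucy flux normalization;
#'   \item update: S_\{k+1\} = TV_k E*_k S_k, clipped at zero.
#' }
#' Iterates stay non-negative throughout; a NaN/Inf guard stops hard.
#'
#' @param capture Observed image (matrix or h x w x C array), >= 0.
#' @param basis A `basis_model`, or `NULL` when `psfs`/`weight_maps` are
#'   given directly.
#' @param params A [deconv_params()].
#' @param psfs Optional list of N basis PSF matrices (overrides `basis`).
#' @param weight_maps Optional h x w x N array of coefficient maps a_i;
#'   defaults to the interpolated maps of `basis` (or uniform 1 for N = 1).
#' @param field_extent Field half-width of the capture (for map
#'   interpolation from `basis`).
#' @return List with `estimate` (same shape as the capture) and `kl_trace`
#'   (per-iteration, per-channel Kullback-Leibler divergence between the
#'   capture and its reblurred estimate).
#' @export
rl_tv_shift_variant <- function(capture, basis = NULL,
                                params = deconv_params(), psfs = NULL,
                                weight_maps = NULL, field_extent = 0.7) {
  x3 <- if (is.matrix(capture)) array(capture, c(dim(capture), 1)) else capture
  if (min(x3) < -1e-9 * max(abs(x3))) stop("capture must be non-negative")
  x3 <- pmax(x3, 0)   # clamp FFT round-off
  d <- dim(x3)
  if (is.null(psfs)) {
    if (is.null(basis)) stop("provide a basis model or explicit psfs")
    N <- basis$rank
    psfs_c <- lapply(seq_len(dim(basis$H)[3]), function(c) {
      lapply(seq_len(N), function(i) {
        matrix(basis$H[, i, c], basis$dim_yx[1], basis$dim_yx[2])
      })
    })
    if (is.null(weight_maps)) {
      weight_maps <- interpolate_coefficients(basis, d[1:2], field_extent)
    }
  } else {
    N <- length(psfs)
    psfs_c <- list(psfs)
    if (is.null(weight_maps)) {
      weight_maps <- array(1, c(d[1], d[2], N))
    }
  }
  if (!all(dim(weight_maps)[1:2] == d[1:2])) {
    stop("weight maps do not match the capture shape")
  }
  est <- array(NA_real_, d)
  kl <- matrix(NA_real_, params$iterations, d[3])
  for (c in seq_len(d[3])) {
    pl <- psfs_c[[min(c, length(psfs_c))]]
    r <- rl_tv_channel(x3[, , c], pl, weight_maps, params)
    est[, , c] <- r$estimate
    kl[, c] <- r$kl_trace
  }
  if (is.matrix(capture)) est <- est[, , 1]
  list(estimate = est, kl_trace = kl)
}

rl_tv_channel <- function(I, psfs, wmap, params) {
  N <- length(psfs)
  eps_d <- params$epsilon * max(I, 1e-300)
  lam <- params$lambda_tv
  S <- matrix(mean(I), nrow(I), ncol(I))
  literal <- params$adjoint == "literal"
  # sensitivity map: back-projection of a unit image (iteration-independent)
  ones <- matrix(1, nrow(I), ncol(I))
  sens <- matrix(0, nrow(I), ncol(I))
  for (i in seq_len(N)) {
    if (literal) sens <- sens + conv2_same(wmap[, , i] * ones, psfs[[i]])
    else sens <- sens + wmap[, , i] * conv2_same(ones, psfs[[i]], adjoint = TRUE)
  }
  sens <- pmax(sens, params$epsilon * max(sens))
  kl_trace <- numeric(params$iterations)
  for (it in seq_len(params$iterations)) {
    blur <- matrix(0, nrow(I), ncol(I))
    for (i in seq_len(N)) {
      blur <- blur + conv2_same(wmap[, , i] * S, psfs[[i]])
    }
    R <- I / pmax(blur, eps_d)
    E <- matrix(0, nrow(I), ncol(I))
    for (i in seq_len(N)) {
      if (literal) E <- E + conv2_same(wmap[, , i] * R, psfs[[i]])
      else E <- E + wmap[, , i] * conv2_same(R, psfs[[i]], adjoint = TRUE)
    }
    E <- E / sens
    if (lam > 0) {
      g <- grad_fwd(S)
      mag <- sqrt(g$gx^2 + g$gy^2)
      mag <- pmax(mag, eps_d)
      tv <- 1 / (1 - lam * div_bwd(g$gx / mag, g$gy / mag))
    } else tv <- 1
    S <- pmax(tv * E * S, 0)
    if (any(!is.finite(S))) stop("RL-TV iterate diverged (NaN/Inf)")
    pos <- blur > eps_d & I > 0
    kl_trace[it] <- sum(I[pos] * log(I[pos] / blur[pos])) - sum(I) + sum(blur)
  }
  list(estimate = S, kl_trace = kl_trace)
}

#' Depth-resolved components for shift-variant deconvolution
#'
#' Expands a per-depth basis set and a known (or estimated) depth map into a
#' single flat list of (PSF, weight map) components: each depth contributes
#' its basis PSFs with coefficient maps masked to the pixels assigned to
#' that depth. Feeding these to [rl_tv_shift_variant()] deconvolves against
#' exactly the depth-resolved forward operator of
#' [propagate_focal_stack()].
#'
#' @param basis_set Named list of `basis_model`s keyed by depth (um).
#' @param depth_um Depth map (h x w, um; snapped to the basis depths).
#' @param field_extent Field half-width of the image.
#' @param channel Channel for the basis PSFs.
#' @return List with `psfs` (list of matrices) and `weight_maps`
#'   (h x w x (N * Z) array).
#' @export
depth_aware_components <- function(basis_set, depth_um, field_extent = 0.7,
                                   channel = 1) {
  zs <- as.numeric(names(basis_set))
  snapped <- snap_depths(depth_um, zs)
  d <- dim(depth_um)
  psfs <- list()
  maps <- list()
  for (z in sort(unique(as.vector(snapped)))) {
    b <- basis_set[[which(abs(zs - z) < 1e-6)]]
    wm <- interpolate_coefficients(b, d, field_extent, channel)
    mz <- (snapped == z) * 1
    for (i in seq_len(b$rank)) {
      psfs[[length(psfs) + 1]] <- matrix(b$H[, i, channel],
                                         b$dim_yx[1], b$dim_yx[2])
      maps[[length(maps) + 1]] <- wm[, , i] * mz
    }
  }
  wm_arr <- array(unlist(maps), c(d[1], d[2], length(maps)))
  list(psfs = psfs, weight_maps = wm_arr)
}
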