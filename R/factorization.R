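# Low-rank representation of the shift-variant PSF: vectorized PSF matrix,
# HALS non-negative matrix factorization with channel-uniform coefficients,
# coefficient-map interpolation, and per-field reconstruction.

#' Assemble a vectorized PSF matrix
#'
#' Downsamples, crops and vectorizes the PSFs of one depth plane into the
#' matrix P (ab x M): column m is the flattened (column-major) PSF of field
#' point m. Channels are stacked in a third array dimension.
#'
#' @param grid A `psf_grid` from [simulate_psf_grid()].
#' @param z_um Depth plane to extract.
#' @param downsample Integer pixel-decimation factor (>= 1; samples every
#'   `downsample`-th pixel starting at the first).
#' @param crop Odd crop size (pixels, before downsampling) or `NULL`.
#' @param channels Channel indices to include (default all).
#' @return Object of class `psf_matrix`: list with `P` (array ab x M x C),
#'   `field_uv`, `dim_yx` (PSF shape after crop/downsample), `z_um`,
#'   `downsample`, `pitch_um`, `meta`.
#' @export
assemble_psf_matrix <- function(grid, z_um = 0, downsample = 1, crop = NULL,
                                channels = NULL) {
  stopifnot(inherits(grid, "psf_grid"), downsample >= 1,
            downsample == round(downsample))
  zi <- match_depth(grid$z_um, z_um)
  if (is.null(channels)) channels <- seq_along(grid$wavelengths_nm)
  d <- dim(grid$psf)
  M <- d[1]; n <- d[4]
  if (d[4] != d[5]) stop("PSFs must be square")
  sel <- seq_len(n)
  if (!is.null(crop)) {
    if (crop %% 2 == 0 || crop > n) stop("crop must be odd and <= PSF size")
    c0 <- (n + 1) / 2; h <- (crop - 1) / 2
    sel <- (c0 - h):(c0 + h)
  }
  sel <- sel[seq(1, length(sel), by = downsample)]
  k <- length(sel)
  P <- array(NA_real_, c(k * k, M, length(channels)))
  for (ci in seq_along(channels)) {
    for (m in seq_len(M)) {
      P[, m, ci] <- as.vector(grid$psf[m, zi, channels[ci], sel, sel])
    }
  }
  structure(list(P = P, field_uv = grid$field_uv, dim_yx = c(k, k),
                 z_um = z_um, downsample = downsample,
                 pitch_um = grid$pitch_um * downsample,
                 meta = grid$meta),
            class = "psf_matrix")
}

#' HALS non-negative matrix factorization of a PSF matrix
#'
#' Factorizes P ~ H W with H >= 0 (ab x N bases) and W >= 0 (N x M
#' coefficients at the calibration field points) by hierarchical alternating
#' least squares: cyclic exact coordinate updates clipped at zero, with
#' zero-column re-initialization from the largest residual column. With
#' `channel_uniform = TRUE` (the default) a single W is fit jointly against
#' the channel-stacked matrix \[P_r; P_g; P_b\] with channel-stacked bases,
#' so coefficient maps are shared across color channels (reducing color
#' fringing); otherwise each channel is factorized independently.
#'
#' @param pm A `psf_matrix` (or a plain non-negative matrix for testing).
#' @param rank Number of bases N, 1 <= N <= M.
#' @param iterations Number of HALS sweeps (iteration-capped; convergence is
#'   not required).
#' @param seed Seed for the uniform random initialization.
#' @param channel_uniform Share W across channels (see above).
#' @return Object of class `basis_model`: list with `H` (array ab x N x C),
#'   `W` (N x M matrix, or N x M x C array when not channel-uniform),
#'   `residual_trace` (Frobenius residual after each sweep), `field_uv`,
#'   `dim_yx`, `z_um`, `channel_uniform`, `interpolation` ("bilinear"),
#'   `meta`.
#' @export
hals_nmf <- function(pm, rank, iterations = 200, seed = 0,
                     channel_uniform = TRUE) {
  if (is.matrix(pm)) {
    pm <- list(P = array(pm, c(dim(pm), 1)), field_uv = NULL,
               dim_yx = c(nrow(pm), 1), z_um = NA_real_, meta = list())
  } else stopifnot(inherits(pm, "psf_matrix"))
  P <- pm$P
  ab <- dim(P)[1]; M <- dim(P)[2]; C <- dim(P)[3]
  if (rank > M) stop("rank must be <= number of field points M")
  stopifnot(rank >= 1, iterations >= 1, all(P >= 0))

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  if (channel_uniform) {
    Ps <- do.call(rbind, lapply(seq_len(C), function(c) P[, , c]))
    fit <- hals_core(Ps, rank, iterations)
    H <- array(NA_real_, c(ab, rank, C))
    for (c in seq_len(C)) H[, , c] <- fit$H[((c - 1) * ab + 1):(c * ab), , drop = FALSE]
    W <- fit$W
    trace <- fit$trace
  } else {
    H <- array(NA_real_, c(ab, rank, C))
    W <- array(NA_real_, c(rank, M, C))
    traces <- matrix(NA_real_, iterations, C)
    for (c in seq_len(C)) {
      fit <- hals_core(P[, , c], rank, iterations)
      H[, , c] <- fit$H; W[, , c] <- fit$W; traces[, c] <- fit$trace
    }
    trace <- sqrt(rowSums(traces^2))
  }
  structure(list(H = H, W = W, residual_trace = trace,
                 field_uv = pm$field_uv, dim_yx = pm$dim_yx, z_um = pm$z_um,
                 channel_uniform = channel_uniform, rank = rank,
                 interpolation = "bilinear", pitch_um = pm$pitch_um,
                 meta = pm$meta),
            class = "basis_model")
}

# One HALS run on a stacked matrix: exact per-component coordinate updates,
# clipped at zero; monotone non-increasing Frobenius objective.
hals_core <- function(P, N, iterations, eps = 1e-12) {
  ab <- nrow(P); M <- ncol(P)
  H <- matrix(stats::runif(ab * N), ab, N)
  W <- matrix(stats::runif(N * M), N, M)
  trace <- numeric(iterations)
  for (it in seq_len(iterations)) {
    HtP <- crossprod(H, P)          # N x M
    HtH <- crossprod(H)             # N x N
    for (j in seq_len(N)) {
      num <- HtP[j, ] - HtH[j, ] %*% W + HtH[j, j] * W[j, ]
      W[j, ] <- pmax(as.vector(num) / max(HtH[j, j], eps), 0)
    }
    PWt <- P %*% t(W)               # ab x N
    WWt <- tcrossprod(W)            # N x N
    for (j in seq_len(N)) {
      num <- PWt[, j] - H %*% WWt[, j] + WWt[j, j] * H[, j]
      h <- pmax(as.vector(num) / max(WWt[j, j], eps), 0)
      if (all(h == 0)) {
        # re-seed a dead component from the worst-approximated column;
        # leaving its coefficients at zero keeps the objective monotone
        R <- P - H %*% W
        h <- pmax(R[, which.max(colSums(R^2))], 0)
        W[j, ] <- 0
        WWt <- tcrossprod(W)
      }
      H[, j] <- h
    }
    trace[it] <- norm(P - H %*% W, "F")
  }
  list(H = H, W = W, trace = trace)
}

#' @export
print.basis_model <- function(x, ...) {
  cat("Basis model: rank", x$rank, ",", dim(x$H)[1], "pixels,",
      if (x$channel_uniform) "channel-uniform W," else "per-channel W,",
      dim(x$H)[3], "channel(s)\n")
  tr <- x$residual_trace
  cat("  residual (Frobenius):", signif(tr[length(tr)], 4), "after",
      length(tr), "sweeps\n")
  invisible(x)
}

#' Relative residual of a basis model fit
#' @param basis A `basis_model`.
#' @param pm The `psf_matrix` (or matrix) it was fit to.
#' @return ||H W - P||_F / ||P||_F over all channels.
#' @export
nmf_relative_residual <- function(basis, pm) {
  P <- if (is.matrix(pm)) array(pm, c(dim(pm), 1)) else pm$P
  num <- 0; den <- 0
  for (c in seq_len(dim(P)[3])) {
    W <- if (is.matrix(basis$W)) basis$W else basis$W[, , c]
    num <- num + norm(P[, , c] - basis$H[, , c] %*% W, "F")^2
    den <- den + norm(P[, , c], "F")^2
  }
  sqrt(num / den)
}

#' Interpolate coefficient maps to full resolution
#'
#' Bilinearly interpolates the fitted coefficients W (defined at the
#' calibration field grid) to a full-resolution map w_i(u, v) for every
#' basis, with constant (nearest-edge) extrapolation outside the calibration
#' hull and clipping at zero. At the calibration points the maps reproduce W
#' exactly.
#'
#' @param basis A `basis_model` whose `field_uv` came from a regular
#'   [field_grid()].
#' @param dim_out Output size `c(h, w)` in pixels.
#' @param extent Field half-width of the output image (default the grid's
#'   calibration extent, i.e. the maps span the calibrated field exactly).
#' @param channel Channel (only relevant for per-channel W).
#' @return Array h x w x N of non-negative weight maps.
#' @export
interpolate_coefficients <- function(basis, dim_out, extent = NULL,
                                     channel = 1) {
  stopifnot(inherits(basis, "basis_model"))
  fu <- basis$field_uv
  if (is.null(fu)) stop("basis model has no field coordinates")
  us <- sort(unique(fu$u)); vs <- sort(unique(fu$v))
  if (nrow(fu) != length(us) * length(vs)) {
    stop("field points do not form a regular grid")
  }
  if (is.null(extent)) extent <- max(abs(c(fu$u, fu$v)))
  W <- if (is.matrix(basis$W)) basis$W else basis$W[, , channel]
  N <- nrow(W)
  fc <- field_coords(dim_out[1], dim_out[2], extent)
  out <- array(NA_real_, c(dim_out[1], dim_out[2], N))
  # index of each field point into the (u, v) grid
  iu <- match(round(fu$u, 9), round(us, 9))
  iv <- match(round(fu$v, 9), round(vs, 9))
  for (i in seq_len(N)) {
    Wg <- matrix(NA_real_, length(us), length(vs))
    Wg[cbind(iu, iv)] <- W[i, ]
    out[, , i] <- pmax(bilinear_grid(us, vs, Wg, fc$u, fc$v), 0)
  }
  out
}

# Bilinear interpolation of a function tabulated on the rectangular grid
# (us x vs) at all combinations of query coordinates uq (rows) and vq
# (columns); constant extrapolation beyond the grid edge.
bilinear_grid <- function(us, vs, Wg, uq, vq) {
  cu <- pmin(pmax(uq, us[1]), us[length(us)])
  cv <- pmin(pmax(vq, vs[1]), vs[length(vs)])
  iu <- pmin(pmax(findInterval(cu, us), 1), max(length(us) - 1, 1))
  iv <- pmin(pmax(findInterval(cv, vs), 1), max(length(vs) - 1, 1))
  if (length(us) == 1) { tu <- rep(0, length(cu)); iu2 <- iu } else {
    tu <- (cu - us[iu]) / (us[iu + 1] - us[iu]); iu2 <- iu + 1
  }
  if (length(vs) == 1) { tv <- rep(0, length(cv)); iv2 <- iv } else {
    tv <- (cv - vs[iv]) / (vs[iv + 1] - vs[iv]); iv2 <- iv + 1
  }
  TU <- matrix(tu, length(uq), length(vq))
  TV <- matrix(tv, length(uq), length(vq), byrow = TRUE)
  (1 - TU) * (1 - TV) * Wg[cbind(rep(iu, length(vq)), rep(iv, each = length(uq)))] +
    TU * (1 - TV) * Wg[cbind(rep(iu2, length(vq)), rep(iv, each = length(uq)))] +
    (1 - TU) * TV * Wg[cbind(rep(iu, length(vq)), rep(iv2, each = length(uq)))] +
    TU * TV * Wg[cbind(rep(iu2, length(vq)), rep(iv2, each = length(uq)))]
}

#' Reconstruct the PSF at a calibration field point
#'
#' Returns sum_i W\[i, m\] H\[, i\] reshaped to the PSF support: the low-rank
#' estimate of the calibrated PSF.
#'
#' @param basis A `basis_model`.
#' @param m Field point index (1 .. M).
#' @param channel Channel index.
#' @return Non-negative PSF estimate matrix.
#' @export
reconstruct_psf <- function(basis, m, channel = 1) {
  stopifnot(inherits(basis, "basis_model"))
  W <- if (is.matrix(basis$W)) basis$W else
    matrix(basis$W[, , channel], dim(basis$W)[1], dim(basis$W)[2])
  if (m < 1 || m > ncol(W)) stop("field index out of range")
  H <- matrix(basis$H[, , channel], dim(basis$H)[1], dim(basis$H)[2])
  v <- H %*% W[, m, drop = FALSE]
  matrix(v, basis$dim_yx[1], basis$dim_yx[2])
}

#' Write / read a basis model
#' @param basis A `basis_model`.
#' @param path File path.
#' @return `read_basis_model` returns the model; the writer returns `path`
#'   invisibly.
#' @export
write_basis_model <- function(basis, path) {
  stopifnot(inherits(basis, "basis_model"))
  saveRDS(basis, path)
  invisible(path)
}

#' @rdname write_basis_model
#' @export
read_basis_model <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "basis_model")) stop("not a basis_model container")
  b
}
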