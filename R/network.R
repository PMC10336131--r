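# Restoration network family: U-Net generator with residual bottleneck,
# PatchGAN discriminator, composite loss, channel pruning with exact
# parameter accounting, and a toy pure-R trainer.
#
# Parameter counting convention (printed in reports): generator only,
# convolution weights + biases (k^2 * c_in * c_out + c_out per layer), no
# normalization layers; bilinear upsampling and activations carry no
# parameters.

#' Generator architecture specification
#'
#' Four stride-2 4x4 encoder convolutions (LeakyReLU), a residual bottleneck
#' (two 3x3 convolutions + shortcut per block) at the last encoder width,
#' four decoder blocks (bilinear 2x upsample then 3x3 convolution, ReLU)
#' mirroring the encoder, skip connections by channel concatenation, and a
#' final 3x3 convolution to the output channels. The full-scale design uses
#' encoder widths 128/256/512/512 with 9 residual blocks; the pruned
#' deployment variant uses 32/64/128/256.
#'
#' @param encoder Four positive encoder output widths.
#' @param residual_blocks Number of residual blocks (>= 0).
#' @param in_channels,out_channels Image channels (default 3).
#' @param skips Use skip connections (channel concatenation).
#' @param output_activation `"tanh"` (training parity) or `"sigmoid"`
#'   (deployment).
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(encoder = c(128, 256, 512, 512),
                           residual_blocks = 9, in_channels = 3,
                           out_channels = 3, skips = TRUE,
                           output_activation = c("tanh", "sigmoid")) {
  if (length(encoder) != 4 || any(encoder <= 0) ||
      any(encoder != round(encoder))) {
    stop("encoder must be 4 positive integer widths")
  }
  stopifnot(residual_blocks >= 0, in_channels >= 1, out_channels >= 1)
  structure(list(encoder = as.integer(encoder),
                 residual_blocks = as.integer(residual_blocks),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 skips = isTRUE(skips),
                 output_activation = match.arg(output_activation)),
            class = "generator_spec")
}

conv_params <- function(k, c_in, c_out) k * k * c_in * c_out + c_out

#' Build the generator layer graph
#'
#' Expands a [generator_spec()] into an explicit layer list with kernel
#' sizes, strides, channel counts and exact parameter counts; no weights are
#' instantiated. Input spatial size must be divisible by 16 (four stride-2
#' stages).
#'
#' @param spec A [generator_spec()].
#' @return Object of class `network_graph`: data frame of layers (columns
#'   `name`, `type`, `kernel`, `stride`, `in_ch`, `out_ch`, `params`) with
#'   attributes `total_params` and `spec`.
#' @export
build_generator <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  w <- spec$encoder
  rows <- list()
  add <- function(name, type, k, s, ci, co) {
    p <- if (type == "conv") conv_params(k, ci, co) else 0L
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, type = type, kernel = k, stride = s,
      in_ch = ci, out_ch = co, params = p, stringsAsFactors = FALSE)
  }
  prev <- spec$in_channels
  for (i in 1:4) {
    add(paste0("enc", i), "conv", 4, 2, prev, w[i])
    add(paste0("enc", i, "_lrelu"), "leaky_relu", 0, 1, w[i], w[i])
    prev <- w[i]
  }
  for (r in seq_len(spec$residual_blocks)) {
    add(paste0("res", r, "_conv1"), "conv", 3, 1, prev, prev)
    add(paste0("res", r, "_conv2"), "conv", 3, 1, prev, prev)
  }
  # decoder mirrors the encoder; skip j fuses encoder block (4 - j) output
  dec_out <- c(w[3], w[2], w[1], w[1])
  for (j in 1:4) {
    add(paste0("dec", j, "_up"), "bilinear_upsample", 0, 1, prev, prev)
    ci <- prev + if (spec$skips && j <= 3) w[4 - j] else 0
    add(paste0("dec", j), "conv", 3, 1, ci, dec_out[j])
    add(paste0("dec", j, "_relu"), "relu", 0, 1, dec_out[j], dec_out[j])
    prev <- dec_out[j]
  }
  add("out", "conv", 3, 1, prev, spec$out_channels)
  add(paste0("out_", spec$output_activation), spec$output_activation,
      0, 1, spec$out_channels, spec$out_channels)
  g <- do.call(rbind, rows)
  structure(g, class = c("network_graph", "data.frame"),
            total_params = sum(g$params), spec = spec)
}

#' @export
print.network_graph <- function(x, ...) {
  cat("Network graph:", nrow(x), "layers,",
      format(attr(x, "total_params"), big.mark = ","), "parameters",
      "(conv weights + biases)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Total parameter count of a network graph or generator spec
#' @param x A `network_graph` or `generator_spec`.
#' @return Integer parameter count (pure function of the spec).
#' @export
parameter_count <- function(x) {
  if (inherits(x, "generator_spec")) x <- build_generator(x)
  attr(x, "total_params")
}

#' Build the PatchGAN discriminator layer graph
#'
#' Standard 70x70-receptive-field patch discriminator: 4x4 convolutions with
#' strides 2, 2, 2, 1 (widths 64/128/256/512) and a final stride-1 4x4
#' convolution to a 1-channel patch map. The receptive field of each output
#' unit is computed by layer arithmetic and stored in the result.
#'
#' @param in_channels Input channels (default 6: input and output
#'   concatenated, conditional-GAN style).
#' @param widths Four convolution widths.
#' @return A `network_graph` with attributes `total_params` and
#'   `receptive_field`.
#' @export
build_discriminator <- function(in_channels = 6,
                                widths = c(64, 128, 256, 512)) {
  stopifnot(length(widths) == 4, all(widths > 0))
  strides <- c(2, 2, 2, 1, 1)
  chans <- c(widths, 1)
  rows <- list()
  prev <- in_channels
  for (i in seq_along(chans)) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("d", i), type = "conv", kernel = 4, stride = strides[i],
      in_ch = prev, out_ch = chans[i],
      params = conv_params(4, prev, chans[i]), stringsAsFactors = FALSE)
    prev <- chans[i]
  }
  g <- do.call(rbind, rows)
  # receptive field: walk layers output-to-input, r <- r * s + (k - s)
  r <- 1
  for (i in rev(seq_along(chans))) r <- r * strides[i] + (4 - strides[i])
  structure(g, class = c("network_graph", "data.frame"),
            total_params = sum(g$params), receptive_field = r)
}

#' Channel-pruning report
#'
#' Compares the exact parameter counts of a full and a pruned generator of
#' identical topology and reports the reduction fraction. The full-scale
#' design (128/256/512/512, 9 residual blocks) pruned to 32/64/128/256
#' reduces the generator parameters by about 78%.
#'
#' @param full,pruned [generator_spec()]s with equal residual-block counts
#'   and channel layouts differing only in width.
#' @return Object of class `prune_report`: list with `full_params`,
#'   `pruned_params`, `reduction` (1 - pruned/full), `identical` flag, and
#'   the counting `convention` string.
#' @export
prune_report <- function(full, pruned) {
  stopifnot(inherits(full, "generator_spec"), inherits(pruned, "generator_spec"))
  if (full$residual_blocks != pruned$residual_blocks ||
      full$in_channels != pruned$in_channels ||
      full$out_channels != pruned$out_channels ||
      full$skips != pruned$skips) {
    stop("topology mismatch between full and pruned specs")
  }
  fp <- parameter_count(full)
  pp <- parameter_count(pruned)
  structure(list(full_params = fp, pruned_params = pp,
                 reduction = 1 - pp / fp, identical = fp == pp,
                 convention = paste("generator only; convolution weights +",
                                    "biases; no normalization layers")),
            class = "prune_report")
}

#' @export
print.prune_report <- function(x, ...) {
  cat("Pruning report (", x$convention, ")\n", sep = "")
  cat(sprintf("  full:   %s parameters\n  pruned: %s parameters\n",
              format(x$full_params, big.mark = ","),
              format(x$pruned_params, big.mark = ",")))
  cat(sprintf("  reduction: %.1f%%%s\n", 100 * x$reduction,
              if (x$identical) "  [identical specs]" else ""))
  invisible(x)
}

#' Composite restoration loss
#'
#' Weighted sum of a GAN term (binary cross-entropy of discriminator scores
#' on the restored image), an L2-norm term, and a perceptual term (L2 in a
#' feature space). Every term is non-negative; a zero weight disables its
#' term and its inputs.
#'
#' @param output,label Arrays of identical shape.
#' @param weights Named numeric: `gan`, `l2`, `perceptual`.
#' @param disc_scores Discriminator scores on `output`, in (0, 1\]; required
#'   when `weights["gan"] > 0`.
#' @param extractor Feature-extractor function `image -> features`; required
#'   when `weights["perceptual"] > 0` (a pretrained network or a configured
#'   stub).
#' @return List with `total` and `terms` (named, already weighted);
#'   `sum(terms) == total`.
#' @export
composite_loss <- function(output, label,
                           weights = c(gan = 0, l2 = 1, perceptual = 0),
                           disc_scores = NULL, extractor = NULL) {
  if (!all(dim(output) == dim(label))) stop("output/label shape mismatch")
  w <- c(gan = 0, l2 = 0, perceptual = 0)
  w[names(weights)] <- weights
  terms <- c(gan = 0, l2 = 0, perceptual = 0)
  if (w["l2"] > 0) terms["l2"] <- w["l2"] * mean((output - label)^2)
  if (w["gan"] > 0) {
    if (is.null(disc_scores)) stop("gan weight > 0 requires disc_scores")
    s <- pmin(pmax(disc_scores, 1e-12), 1)
    terms["gan"] <- w["gan"] * mean(-log(s))
  }
  if (w["perceptual"] > 0) {
    if (is.null(extractor)) stop("perceptual weight > 0 requires an extractor")
    terms["perceptual"] <- w["perceptual"] *
      mean((extractor(output) - extractor(label))^2)
  }
  list(total = sum(terms), terms = terms)
}

# ---- toy pure-R convolutional trainer -------------------------------------
# 3x3 "same" cross-correlation by shift-and-add; analytic backprop; Adam.

shift2 <- function(x, di, dj) {
  # returns y with y[i, j] = x[i + di, j + dj], zero outside
  n <- nrow(x); m <- ncol(x)
  y <- matrix(0, n, m)
  si <- max(1, 1 + di):min(n, n + di)
  sj <- max(1, 1 + dj):min(m, m + dj)
  y[si - di, sj - dj] <- x[si, sj]
  y
}

conv3_fwd <- function(x, K, b) {
  # x: h x w x cin; K: 3 x 3 x cin x cout; b: cout
  d <- dim(x); cout <- dim(K)[4]
  y <- array(rep(b, each = d[1] * d[2]), c(d[1], d[2], cout))
  for (o in seq_len(cout)) for (ci in seq_len(d[3])) {
    xc <- x[, , ci]
    for (a in 1:3) for (bb in 1:3) {
      k <- K[a, bb, ci, o]
      if (k != 0) y[, , o] <- y[, , o] + k * shift2(xc, a - 2, bb - 2)
    }
  }
  y
}

conv3_bwd <- function(x, K, g) {
  d <- dim(x); cout <- dim(K)[4]
  dK <- array(0, dim(K)); db <- numeric(cout)
  dx <- array(0, d)
  for (o in seq_len(cout)) {
    go <- g[, , o]
    db[o] <- sum(go)
    for (ci in seq_len(d[3])) {
      xc <- x[, , ci]
      for (a in 1:3) for (bb in 1:3) {
        dK[a, bb, ci, o] <- sum(shift2(xc, a - 2, bb - 2) * go)
        dx[, , ci] <- dx[, , ci] + K[a, bb, ci, o] * shift2(go, 2 - a, 2 - bb)
      }
    }
  }
  list(dK = dK, db = db, dx = dx)
}

toy_init <- function(c_img, width, residual_blocks, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  he <- function(ci, co) array(stats::rnorm(9 * ci * co, 0,
                                            sqrt(2 / (9 * ci))),
                               c(3, 3, ci, co))
  w <- list(K_in = he(c_img, width), b_in = numeric(width),
            res = lapply(seq_len(residual_blocks), function(r) {
              list(K1 = he(width, width), b1 = numeric(width),
                   K2 = he(width, width), b2 = numeric(width))
            }),
            K_out = he(width, c_img), b_out = numeric(c_img))
  w
}

lrelu <- function(x, a = 0.2) ifelse(x > 0, x, a * x)
lrelu_g <- function(x, a = 0.2) ifelse(x > 0, 1, a)

toy_forward <- function(x, w, keep = FALSE) {
  acts <- list(x = x)
  z0 <- conv3_fwd(x, w$K_in, w$b_in)
  h <- lrelu(z0)
  if (keep) { acts$z0 <- z0; acts$h0 <- h }
  for (r in seq_along(w$res)) {
    z1 <- conv3_fwd(h, w$res[[r]]$K1, w$res[[r]]$b1)
    a1 <- lrelu(z1)
    z2 <- conv3_fwd(a1, w$res[[r]]$K2, w$res[[r]]$b2)
    hn <- h + z2
    if (keep) acts[[paste0("r", r)]] <- list(h_in = h, z1 = z1, a1 = a1)
    h <- hn
  }
  y <- x + conv3_fwd(h, w$K_out, w$b_out)   # global residual
  if (keep) { acts$h_last <- h; acts$y <- y }
  if (keep) acts else y
}

#' Train the toy restoration network
#'
#' A deliberately small, self-contained convolutional trainer used to
#' exercise the training loop end-to-end on synthetic pairs: a 3x3 input
#' convolution (LeakyReLU), `residual_blocks` residual blocks, a 3x3 output
#' convolution with a global residual connection, trained with Adam on the
#' mean-squared (L2) loss. All arithmetic is plain R; gradients are analytic.
#' It is a scale model of the training procedure, not the full-resolution
#' GAN.
#'
#' @param pairs List of training pairs, each `list(input, label)` of equal
#'   h x w x C arrays (at least 4 pairs of >= 32 x 32 recommended).
#' @param width Hidden channel width.
#' @param residual_blocks Residual blocks (>= 0).
#' @param epochs Training epochs (0 returns the initialization unchanged).
#' @param lr Adam learning rate (design value 2e-4).
#' @param betas Adam exponential decay rates (design values 0.9, 0.999).
#' @param seed Initialization/ordering seed; runs are reproducible.
#' @return Object of class `toy_restoration_net`: list with `weights`,
#'   `loss_trace` (mean L2 per epoch; element 1 is the pre-training loss),
#'   `config`.
#' @export
train_toy <- function(pairs, width = 8, residual_blocks = 1, epochs = 30,
                      lr = 2e-4, betas = c(0.9, 0.999), seed = 0) {
  stopifnot(length(pairs) >= 1, epochs >= 0)
  d <- dim(pairs[[1]]$input)
  if (length(d) == 2) {
    pairs <- lapply(pairs, function(p) list(input = array(p$input, c(d, 1)),
                                            label = array(p$label, c(d, 1))))
    d <- c(d, 1)
  }
  w <- toy_init(d[3], width, residual_blocks, seed)
  flat <- function(w) unlist(w, use.names = FALSE)
  mse_all <- function(w) {
    mean(vapply(pairs, function(p) mean((toy_forward(p$input, w) - p$label)^2),
                numeric(1)))
  }
  loss_trace <- mse_all(w)
  if (epochs > 0) {
    # Adam state mirrors the flattened weight layout
    relist_template <- w
    theta <- flat(w)
    m <- numeric(length(theta)); v <- numeric(length(theta))
    t_step <- 0
    for (ep in seq_len(epochs)) {
      for (p in pairs) {
        acts <- toy_forward(p$input, w, keep = TRUE)
        n_el <- length(p$label)
        gy <- 2 * (acts$y - p$label) / n_el
        grads <- list()
        bo <- conv3_bwd(acts$h_last, w$K_out, gy)
        grads$K_out <- bo$dK; grads$b_out <- bo$db
        gh <- bo$dx
        grads$res <- vector("list", length(w$res))
        for (r in rev(seq_along(w$res))) {
          a <- acts[[paste0("r", r)]]
          b2 <- conv3_bwd(a$a1, w$res[[r]]$K2, gh)
          ga1 <- b2$dx * lrelu_g(a$z1)
          b1 <- conv3_bwd(a$h_in, w$res[[r]]$K1, ga1)
          grads$res[[r]] <- list(K1 = b1$dK, b1 = b1$db,
                                 K2 = b2$dK, b2 = b2$db)
          gh <- gh + b1$dx   # residual shortcut
        }
        g0 <- gh * lrelu_g(acts$z0)
        bi <- conv3_bwd(acts$x, w$K_in, g0)
        grads$K_in <- bi$dK; grads$b_in <- bi$db
        # order grads to match w's layout
        grads <- grads[names(w)]
        gvec <- flat(grads)
        t_step <- t_step + 1
        m <- betas[1] * m + (1 - betas[1]) * gvec
        v <- betas[2] * v + (1 - betas[2]) * gvec^2
        mh <- m / (1 - betas[1]^t_step)
        vh <- v / (1 - betas[2]^t_step)
        theta <- flat(w) - lr * mh / (sqrt(vh) + 1e-8)
        w <- utils::relist(theta, relist_template)
        # relist drops array dims; restore them
        w <- restore_dims(w, relist_template)
      }
      loss_trace <- c(loss_trace, mse_all(w))
    }
  }
  structure(list(weights = w, loss_trace = loss_trace,
                 config = list(width = width,
                               residual_blocks = residual_blocks,
                               epochs = epochs, lr = lr, betas = betas,
                               seed = seed)),
            class = "toy_restoration_net")
}

restore_dims <- function(w, tmpl) {
  if (is.list(w)) {
    for (nm in seq_along(w)) w[[nm]] <- restore_dims(w[[nm]], tmpl[[nm]])
    w
  } else {
    if (!is.null(dim(tmpl))) dim(w) <- dim(tmpl)
    w
  }
}

#' @export
print.toy_restoration_net <- function(x, ...) {
  lt <- x$loss_trace
  cat("Toy restoration net: width", x$config$width, ",",
      x$config$residual_blocks, "residual block(s),", x$config$epochs,
      "epochs\n")
  cat("  L2 loss:", signif(lt[1], 4), "->", signif(lt[length(lt)], 4), "\n")
  invisible(x)
}

#' @export
predict.toy_restoration_net <- function(object, newdata, ...) {
  x <- newdata
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  toy_forward(x, object$weights)
}
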