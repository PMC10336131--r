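test_that("ADMM-TV deconvolution honors its fixed points and recovers beads", {
  set.seed(20)
  k <- gaussian_kernel(1.5, 5)
  # identity operator at lambda = 0: estimate equals the capture
  d <- matrix(0, 5, 5); d[3, 3] <- 1
  cap <- matrix(stats::runif(40 * 40), 40, 40)
  r <- admm_tv_deconv(cap, d, deconv_params(lambda_tv = 0, iterations = 10))
  expect_lt(max(abs(r$estimate - cap)), 1e-6)
  # constant capture with a unit-sum PSF: constant estimate of the same level
  cst <- matrix(0.4, 30, 30)
  r2 <- admm_tv_deconv(cst, k, deconv_params(lambda_tv = 0, iterations = 10))
  expect_lt(max(abs(r2$estimate - 0.4)), 1e-6)
  # noiseless sparse beads: peaks recovered at the right positions, narrower
  truth <- matrix(0, 48, 48)
  pos <- cbind(c(12, 25, 37, 18), c(14, 30, 22, 40))
  truth[pos] <- c(1, 0.8, 0.9, 0.7)
  blur <- direct_conv_same(truth, k)
  r3 <- admm_tv_deconv(blur, k,
                       deconv_params(lambda_tv = 1e-4, iterations = 80))
  for (i in seq_len(nrow(pos))) {
    win <- r3$estimate[pos[i, 1] + (-3:3), pos[i, 2] + (-3:3)]
    pk <- which(win == max(win), arr.ind = TRUE)
    expect_equal(unname(pk[1, ]), c(4, 4))   # peak at the true pixel
    # peak sharper than the blurred observation
    expect_gt(max(win), max(blur[pos[i, 1] + (-3:3), pos[i, 2] + (-3:3)]))
  }
  # objective trace non-increasing after burn-in (last 80% of iterations)
  obj <- r3$objective[, 1]
  tail80 <- obj[ceiling(0.2 * length(obj)):length(obj)]
  expect_true(all(diff(tail80) <= 1e-8 * obj[1]))
})

test_that("shift-variant RL-TV reduces to textbook RL for N = 1, a == 1", {
  set.seed(21)
  k <- gaussian_kernel(1.5, 5)
  truth <- matrix(0, 40, 40)
  truth[cbind(sample(8:32, 8), sample(8:32, 8))] <- stats::runif(8, 0.5, 1)
  cap <- direct_conv_same(truth, k)
  for (n_iter in c(1, 3, 6)) {
    ours <- rl_tv_shift_variant(cap, psfs = list(k),
                                params = deconv_params(lambda_tv = 0,
                                                       iterations = n_iter))
    oracle <- rl_textbook(cap, k, n_iter)
    expect_lt(max(abs(ours$estimate - oracle)), 1e-6)
  }
})

test_that("RL-TV fixed points, non-negativity and KL monotonicity hold", {
  # uniform capture + delta PSF is a fixed point
  d <- matrix(0, 5, 5); d[3, 3] <- 1
  u <- matrix(0.7, 24, 24)
  r <- rl_tv_shift_variant(u, psfs = list(d),
                           params = deconv_params(lambda_tv = 0,
                                                  iterations = 6))
  expect_lt(max(abs(r$estimate - 0.7)), 1e-9)
  # non-negativity for all iterates (final estimate is representative; the
  # update is multiplicative with guarded denominators)
  set.seed(22)
  k <- gaussian_kernel(2, 5)
  cap <- direct_conv_same(matrix(stats::runif(30 * 30), 30, 30), k)
  wm <- array(stats::runif(30 * 30 * 2), c(30, 30, 2))
  r2 <- rl_tv_shift_variant(cap, psfs = list(k, gaussian_kernel(1, 5)),
                            weight_maps = wm,
                            params = deconv_params(lambda_tv = 0.00015,
                                                   iterations = 15))
  expect_true(all(r2$estimate >= 0))
  # KL divergence between capture and reblurred estimate is non-increasing
  expect_true(all(diff(r2$kl_trace[, 1]) <= 1e-9))
  # NaN guard trips on a pathological operator (all-zero PSF)
  expect_error(rl_tv_shift_variant(cap, psfs = list(k * 0),
                                   params = deconv_params(iterations = 2)),
               "NaN|diverged")
})

test_that("exact and literal adjoints agree on centro-symmetric PSFs", {
  set.seed(23)
  k1 <- gaussian_kernel(1.2, 5); k2 <- gaussian_kernel(2, 5)
  cap <- matrix(stats::runif(32 * 32), 32, 32)
  # uniform maps: back-projections coincide exactly for symmetric PSFs
  e1 <- rl_tv_shift_variant(cap, psfs = list(k1, k2),
                            params = deconv_params(lambda_tv = 0,
                                                   iterations = 5,
                                                   adjoint = "exact"))
  e2 <- rl_tv_shift_variant(cap, psfs = list(k1, k2),
                            params = deconv_params(lambda_tv = 0,
                                                   iterations = 5,
                                                   adjoint = "literal"))
  expect_lt(max(abs(e1$estimate - e2$estimate)), 1e-9)
})

test_that("deconvolving shift-variant blur improves PSNR monotonically", {
  fx <- coded_fixture()
  bs <- fx$basis_set
  sb <- synth_scene("beads", size = 96, seed = 5, depth = "flat",
                    density = 0.08)
  truth <- sb$intensity[, , 1]
  cap <- unclass(forward_lowrank(sb, bs[["0"]]))[, , 1]
  # improvement at the design regularization
  est <- rl_tv_shift_variant(cap, bs[["0"]],
                             deconv_params(lambda_tv = 0.00015,
                                           iterations = 30))
  expect_gt(psnr(est$estimate, truth, max(truth)),
            psnr(cap, truth, max(truth)))
  # monotone PSNR gain over the first 10 iterations on noiseless beads
  ps <- vapply(1:10, function(n) {
    psnr(rl_tv_shift_variant(cap, bs[["0"]],
                             deconv_params(lambda_tv = 0,
                                           iterations = n))$estimate,
         truth, max(truth))
  }, numeric(1))
  expect_true(all(diff(ps) > 0))
})

test_that("depth-aware components reproduce the multi-depth forward operator", {
  fx <- coded_fixture()
  bs <- fx$basis_set
  sc <- synth_scene("texture", size = 64, seed = 6, depth = "tilted")
  cap <- unclass(propagate_focal_stack(sc, bs))[, , 1]
  dc <- depth_aware_components(bs, snap_depths(sc$depth_um,
                                               as.numeric(names(bs))))
  blur <- matrix(0, 64, 64)
  for (i in seq_along(dc$psfs)) {
    blur <- blur + conv2_same(dc$weight_maps[, , i] * sc$intensity[, , 1],
                              dc$psfs[[i]])
  }
  expect_lt(max(abs(blur - cap)), 1e-9)
})
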