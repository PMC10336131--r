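test_that("generator layer graph matches the architecture description", {
  g <- build_generator(generator_spec())
  df <- as.data.frame(g)
  conv <- df[df$type == "conv", ]
  expect_equal(sum(grepl("^enc", conv$name)), 4)
  expect_equal(sum(grepl("^res", conv$name)), 18)  # 2 convs per block
  expect_equal(sum(grepl("^dec", conv$name)), 4)
  expect_true(all(conv$kernel[grepl("^enc", conv$name)] == 4))
  expect_true(all(conv$stride[grepl("^enc", conv$name)] == 2))
  expect_true(all(conv$kernel[grepl("^dec|^res|^out", conv$name)] == 3))
  # skip connections widen decoder inputs by the mirrored encoder width
  expect_equal(conv$in_ch[conv$name == "dec1"], 512 + 512)
  expect_equal(conv$in_ch[conv$name == "dec2"], 512 + 256)
  expect_equal(conv$in_ch[conv$name == "dec3"], 256 + 128)
  expect_equal(conv$in_ch[conv$name == "dec4"], 128)
  # zero residual blocks feed the encoder straight into the decoder
  g0 <- build_generator(generator_spec(residual_blocks = 0))
  expect_false(any(grepl("^res", as.data.frame(g0)$name)))
  expect_error(generator_spec(encoder = c(64, 128)), "4 positive")
})

test_that("parameter counts equal an independent layer-by-layer recount", {
  spec <- generator_spec(encoder = c(8, 16, 32, 32), residual_blocks = 2,
                         in_channels = 3, out_channels = 3)
  # hand recount: k^2 c_in c_out + c_out per convolution
  hand <- (16 * 3 * 8 + 8) + (16 * 8 * 16 + 16) + (16 * 16 * 32 + 32) +
    (16 * 32 * 32 + 32) +                       # encoder
    2 * 2 * (9 * 32 * 32 + 32) +                # residual blocks
    (9 * (32 + 32) * 32 + 32) + (9 * (32 + 16) * 16 + 16) +
    (9 * (16 + 8) * 8 + 8) + (9 * 8 * 8 + 8) +  # decoder with skips
    (9 * 8 * 3 + 3)                             # output conv
  expect_equal(parameter_count(spec), hand)
  # counting is a pure function of the spec
  expect_equal(parameter_count(spec),
               parameter_count(generator_spec(c(8, 16, 32, 32), 2)))
})

test_that("pruning report reproduces the deployment parameter reduction", {
  rep <- prune_report(generator_spec(c(128, 256, 512, 512)),
                      generator_spec(c(32, 64, 128, 256)))
  expect_lt(abs(rep$reduction - 0.78), 0.02)
  expect_lt(rep$pruned_params, rep$full_params)
  expect_equal(rep$reduction, 1 - rep$pruned_params / rep$full_params)
  # identical specs: zero reduction, flagged
  rep0 <- prune_report(generator_spec(), generator_spec())
  expect_equal(rep0$reduction, 0)
  expect_true(rep0$identical)
  # halving all widths in a conv graph reduces parameters roughly 4-fold
  full <- generator_spec(c(64, 128, 256, 256), residual_blocks = 4)
  half <- generator_spec(c(32, 64, 128, 128), residual_blocks = 4)
  reph <- prune_report(full, half)
  # independent recount from the layer tables
  recount <- function(sp) {
    df <- as.data.frame(build_generator(sp))
    cv <- df[df$type == "conv", ]
    sum(cv$kernel^2 * cv$in_ch * cv$out_ch + cv$out_ch)
  }
  expect_equal(reph$reduction, 1 - recount(half) / recount(full))
  expect_lt(abs(reph$reduction - 0.75), 0.03)
  expect_error(prune_report(generator_spec(residual_blocks = 9),
                            generator_spec(residual_blocks = 3)),
               "topology")
})

test_that("the PatchGAN discriminator has a 70 x 70 receptive field", {
  d <- build_discriminator()
  expect_equal(attr(d, "receptive_field"), 70)
  df <- as.data.frame(d)
  # output patch map is smaller than the input (stride arithmetic, pad 1)
  sz <- 256
  for (i in seq_len(nrow(df))) {
    sz <- floor((sz - df$kernel[i] + 2) / df$stride[i]) + 1
  }
  expect_lt(sz, 256)
  expect_gt(sz, 1)   # a patch map, not a scalar
  # parameter recount
  expect_equal(attr(d, "total_params"),
               sum(df$kernel^2 * df$in_ch * df$out_ch + df$out_ch))
})

test_that("composite loss terms are exact, non-negative and additive", {
  a <- array(stats::runif(16 * 16 * 1), c(16, 16, 1))
  # perfect output: every enabled term vanishes
  l0 <- composite_loss(a, a, weights = c(l2 = 1))
  expect_equal(l0$total, 0)
  # constant offset d: L2 term is d^2 under mean normalization
  b <- a + 0.25
  l1 <- composite_loss(b, a, weights = c(l2 = 1))
  expect_equal(l1$terms[["l2"]], 0.0625, tolerance = 1e-12)
  # weighted sum with a GAN term and a stub extractor
  ext <- function(x) x[seq(1, length(x), by = 7)]
  sc <- matrix(0.8, 4, 4)
  l2 <- composite_loss(b, a, weights = c(gan = 0.5, l2 = 1, perceptual = 2),
                       disc_scores = sc, extractor = ext)
  expect_equal(sum(l2$terms), l2$total, tolerance = 1e-9)
  expect_true(all(l2$terms >= 0))
  expect_equal(l2$terms[["gan"]], 0.5 * -log(0.8), tolerance = 1e-12)
  # missing inputs are hard errors
  expect_error(composite_loss(b, a, weights = c(gan = 1)), "disc_scores")
  expect_error(composite_loss(b, a, weights = c(perceptual = 1)),
               "extractor")
  expect_error(composite_loss(b, array(0, c(2, 2, 1))), "mismatch")
})

test_that("the toy trainer reduces the L2 loss reproducibly", {
  set.seed(30)
  k <- gaussian_kernel(1, 3)
  mk <- function() {
    x <- matrix(stats::runif(32 * 32), 32, 32)
    list(input = array(direct_conv_same(x, k), c(32, 32, 1)),
         label = array(x, c(32, 32, 1)))
  }
  pairs <- replicate(4, mk(), simplify = FALSE)
  net <- train_toy(pairs, width = 4, residual_blocks = 1, epochs = 12,
                   seed = 0)
  lt <- net$loss_trace
  expect_lt(lt[length(lt)], lt[1])
  # reproducible: identical trace for the same seed
  net2 <- train_toy(pairs, width = 4, residual_blocks = 1, epochs = 12,
                    seed = 0)
  expect_identical(net$loss_trace, net2$loss_trace)
  # zero epochs return the initialization unchanged
  net0a <- train_toy(pairs, width = 4, residual_blocks = 1, epochs = 0,
                     seed = 1)
  net0b <- train_toy(pairs, width = 4, residual_blocks = 1, epochs = 0,
                     seed = 1)
  expect_identical(net0a$weights, net0b$weights)
  expect_length(net0a$loss_trace, 1)
  # prediction runs and matches shapes
  pred <- predict(net, pairs[[1]]$input)
  expect_equal(dim(pred), c(32, 32, 1))
})
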