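test_that("synthetic scenes are reproducible and depth-mapped as designed", {
  s1 <- synth_scene("mixed", size = 64, seed = 11)
  s2 <- synth_scene("mixed", size = 64, seed = 11)
  expect_identical(s1$intensity, s2$intensity)
  expect_identical(s1$depth_um, s2$depth_um)
  expect_false(identical(s1$intensity,
                         synth_scene("mixed", size = 64, seed = 12)$intensity))
  # tilted plane: monotone along the tilt axis, full +/-150 um span
  expect_equal(range(s1$depth_um), c(-150, 150))
  expect_true(all(diff(s1$depth_um[1, ]) >= 0))
  expect_equal(s1$depth_um[1, ], s1$depth_um[64, ])  # planar
  # vanishing density leaves a bead scene empty
  sb <- synth_scene("beads", size = 64, density = 1e-6, seed = 1)
  expect_equal(max(sb$intensity), 0)
  # every kind produces a non-negative scene of the right shape
  for (kind in c("beads", "bars", "texture")) {
    sk <- synth_scene(kind, size = 64, seed = 2, n_channels = 2)
    expect_equal(dim(sk$intensity), c(64, 64, 2))
    expect_true(all(sk$intensity >= 0))
  }
  expect_error(synth_scene("mixed", size = 32), "size")
})

test_that("focal-stack rendering focuses each pixel at its own depth", {
  m <- tiny_model()
  # flat z = 0 sample: in-focus slice is sharpest, +/-150 slices blurrier
  sc <- synth_scene("bars", size = 64, seed = 13, depth = "flat")
  st <- render_focal_stack(sc, m, psf_size = 31)
  sharp <- function(zi) sum(focus_measure(st$slices[, , 1, zi]))
  zi0 <- which(st$z_um == 0)
  expect_gt(sharp(zi0), sharp(1))
  expect_gt(sharp(zi0), sharp(length(st$z_um)))
  # a bead peaks in the slice focused at its own depth
  sb <- synth_scene("beads", size = 64, seed = 4, depth = "flat",
                    density = 0.05)
  sb$depth_um <- matrix(75, 64, 64)
  stb <- render_focal_stack(sb, m, psf_size = 31)
  pk <- which(sb$intensity[, , 1] == max(sb$intensity), arr.ind = TRUE)[1, ]
  peaks <- vapply(seq_along(stb$z_um),
                  function(z) stb$slices[pk[1], pk[2], 1, z], numeric(1))
  expect_equal(stb$z_um[which.max(peaks)], 75)
  # zero scene -> all-zero stack
  s0 <- scene(matrix(0, 64, 64), matrix(0, 64, 64))
  expect_equal(max(abs(render_focal_stack(s0, m, psf_size = 21)$slices)), 0)
})

test_that("depth fusion assembles the sharpest slice per pixel", {
  m <- tiny_model()
  sc <- synth_scene("bars", size = 64, seed = 13, depth = "flat")
  st <- render_focal_stack(sc, m, psf_size = 31)
  # all slices identical -> fused equals any slice exactly (idempotence)
  st_id <- st
  for (zi in seq_along(st$z_um)) st_id$slices[, , , zi] <- st$slices[, , , 3]
  fu_id <- depth_fusion(st_id)
  expect_equal(fu_id$fused[, , 1], st$slices[, , 1, 3])
  # flat z = 0 stack: index map equals the focus-measure argmax wherever
  # there is focus evidence (no smoothing, no background fallback)
  fu <- depth_fusion(st, smooth = 1)
  fm_argmax <- apply(fu$focus, c(1, 2), which.max)
  conf <- apply(fu$focus, c(1, 2), max)
  ev <- conf >= 0.01 * max(conf)
  expect_equal(fu$index_map[ev], fm_argmax[ev])
  tex <- focus_measure(sc$intensity[, , 1]) >
    stats::quantile(focus_measure(sc$intensity[, , 1]), 0.9)
  zi0 <- which(st$z_um == 0)
  expect_true(mean(fu$index_map[tex] == zi0) > 0.9)
  expect_error(depth_fusion(structure(list(slices = st$slices[, , , 1,
                                                              drop = FALSE]),
                                      class = "focal_stack")), "2 slices")
})

test_that("tilted-sample fusion recovers the sharp scene on textured regions", {
  m <- optical_model(pupil_grid = 64, depth_step_um = 10)
  sc <- synth_scene("mixed", size = 96, seed = 3, depth = "tilted")
  st <- render_focal_stack(sc, m, psf_size = 31)
  fu <- depth_fusion(st)
  truth <- sc$intensity[, , 1]
  fm <- focus_measure(truth)
  tex <- fm > stats::quantile(fm, 0.8)
  expect_gte(ssim(fu$fused[, , 1], truth, data_range = max(truth),
                  mask = tex), 0.90)
  # fusion index tracks the tilted plane where there is texture
  z_win <- matrix(st$z_um[fu$index_map], 96, 96)
  expect_lt(stats::median(abs(z_win - sc$depth_um)[tex]), 15)
})

test_that("training pairs pair coded captures with all-in-focus labels", {
  fx <- coded_fixture()
  m <- fx$model
  # zero stack -> zero input and label
  s0 <- scene(matrix(0, 48, 48), matrix(0, 48, 48))
  st0 <- render_focal_stack(s0, m, psf_size = 21)
  p0 <- make_training_pair(st0, fx$basis_set)
  expect_equal(max(abs(p0$input)), 0)
  expect_equal(max(abs(p0$label)), 0)
  # flat z = 0 stack, no noise: input equals the single-depth forward model
  # applied to the label
  sc <- synth_scene("beads", size = 64, seed = 6, depth = "flat",
                    density = 0.05)
  st <- render_focal_stack(sc, m, psf_size = 21)
  pair <- make_training_pair(st, fx$basis_set)
  expect_equal(dim(pair$input), dim(pair$label))
  ref <- forward_lowrank(scene(pair$label, NULL, 2, 0.7),
                         fx$basis_set[["0"]])
  expect_lt(max(abs(pair$input - unclass(ref))), 1e-9)
  # bitwise reproducibility with noise
  pn1 <- make_training_pair(st, fx$basis_set,
                            noise = list(gain = 100, read_sigma = 0.01),
                            seed = 3)
  pn2 <- make_training_pair(st, fx$basis_set,
                            noise = list(gain = 100, read_sigma = 0.01),
                            seed = 3)
  expect_identical(pn1$input, pn2$input)
  # end-to-end: coded capture is less sharp than the all-in-focus label
  scm <- synth_scene("mixed", size = 64, seed = 7, depth = "tilted")
  stm <- render_focal_stack(scm, m, psf_size = 21)
  pm <- make_training_pair(stm, fx$basis_set)
  expect_lt(sum(focus_measure(pm$input[, , 1])),
            sum(focus_measure(pm$label[, , 1])))
})

test_that("patch extraction is aligned, sized and seeded", {
  pair <- structure(list(input = array(stats::runif(96 * 80), c(96, 80, 1)),
                         label = array(stats::runif(96 * 80), c(96, 80, 1)),
                         index_map = NULL, z_um = 0, patches = NULL,
                         pitch_um = 2),
                    class = "training_pair")
  ps <- patchify(pair, n_patches = 20, size = 48, seed = 2)
  expect_length(ps, 20)
  for (p in ps) {
    expect_equal(dim(p$input), c(48, 48, 1))
    expect_equal(dim(p$label), c(48, 48, 1))
    ci <- p$corner
    expect_equal(p$input[1, 1, 1], pair$input[ci[1], ci[2], 1])
    expect_equal(p$label[1, 1, 1], pair$label[ci[1], ci[2], 1])
  }
  # identical corners for identical seeds
  ps2 <- patchify(pair, n_patches = 20, size = 48, seed = 2)
  expect_identical(lapply(ps, `[[`, "corner"), lapply(ps2, `[[`, "corner"))
  # exact-size dimension pins that corner coordinate at the origin
  psx <- patchify(pair, n_patches = 3, size = 80, seed = 1)
  expect_true(all(vapply(psx, function(p) p$corner[2] == 1, logical(1))))
  expect_error(patchify(pair, size = 200), "smaller")
})
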