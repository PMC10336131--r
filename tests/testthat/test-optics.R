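test_that("aspheric sag matches closed forms and symbolic evaluation", {
  # flat surface
  expect_equal(aspheric_sag(aspheric_surface(), c(0, 0.3, 0.9)), c(0, 0, 0))
  # pure sphere: sag = R - sqrt(R^2 - r^2)
  r <- seq(0, 1, by = 0.1)
  s <- aspheric_surface(curvature = 0.5)
  expect_equal(aspheric_sag(s, r), 2 - sqrt(4 - r^2), tolerance = 1e-12)
  expect_equal(aspheric_sag(s, 1), 2 - sqrt(3), tolerance = 1e-12)
  # conic + polynomial term: k = -1 kills the square root, so the value is
  # c r^2 / (1 + 1) + a1 r^2 = 0.25 + 0.1 (term-by-term arithmetic)
  s2 <- aspheric_surface(curvature = 0.5, conic = -1, coefficients = 0.1)
  expect_equal(aspheric_sag(s2, 1), 0.35, tolerance = 1e-14)
  # sag(0) = 0 always
  expect_identical(aspheric_sag(s2, 0), 0)
  # domain error when the square-root argument goes negative
  s3 <- aspheric_surface(curvature = 2, conic = 3, semi_diameter = 1)
  expect_error(aspheric_sag(s3, 0.9), "square-root")
  expect_error(aspheric_sag(s, 1.5), "semi_diameter")
})

test_that("cubic phase follows the profile formula and is antisymmetric", {
  expect_equal(cubic_phase(cubic_phase_mask(0), 0.2, -0.1, 530), 0)
  # hand arithmetic: 2 pi (n-1) alpha (x^3+y^3) / lambda_mm
  # = 2 pi * 0.5 * 0.03 * 0.054 / 5.3e-4
  expect_equal(cubic_phase(cubic_phase_mask(0.03), 0.3, 0.3, 530),
               9.6026039, tolerance = 1e-6)
  mask <- cubic_phase_mask(0.02, semi_diameter = 0.5)
  set.seed(1)
  x <- stats::runif(20, -0.5, 0.5); y <- stats::runif(20, -0.5, 0.5)
  expect_equal(cubic_phase(mask, -x, -y, 470),
               -cubic_phase(mask, x, y, 470), tolerance = 1e-12)
  expect_error(cubic_phase(mask, 0.6, 0, 530), "aperture")
})

test_that("optical model validates its invariants", {
  expect_error(optical_model(na = 1.2), "na")
  expect_error(optical_model(pupil_grid = 63), "even")
  expect_error(optical_model(pupil_grid = 32), "64")
  expect_error(optical_model(depth_range_um = 150, depth_step_um = 40),
               "divide")
  expect_equal(depth_grid(tiny_model()), seq(-150, 150, 75))
  expect_equal(nyquist_frequency(optical_model(pixel_pitch_um = 2)), 0.25)
})

test_that("simulated PSFs are normalized, non-negative and well sampled", {
  m <- tiny_model()
  # property sweep over modulation, defocus and field
  for (alpha in c(0, 0.01)) {
    for (z in c(-150, 0, 75)) {
      for (field in list(c(0, 0), c(0.5, -0.3))) {
        mask <- if (alpha > 0) cubic_phase_mask(alpha) else NULL
        p <- simulate_psf(m, mask, z, field)
        expect_true(all(p >= 0))
        expect_equal(sum(p), 1, tolerance = 1e-9)
      }
    }
  }
  # on-axis in-focus: centered and centro-symmetric
  p0 <- simulate_psf(m)
  K <- nrow(p0)
  pk <- which(p0 == max(p0), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(K / 2 + 1, K / 2 + 1))
  flipped <- p0[c(1, K:2), c(1, K:2)]  # i -> K + 2 - i about the center
  expect_lt(max(abs(unclass(p0)[2:K, 2:K] - flipped[2:K, 2:K])), 1e-9)
  # the sampling guard rejects phase gradients above Nyquist
  expect_error(simulate_psf(m, cubic_phase_mask(0.075), 150),
               "too coarse")
  expect_error(simulate_psf(m, NULL, 400), "depth range")
  expect_error(simulate_psf(m, NULL, 0, c(0.9, 0.9)), "unit disk")
})

test_that("sensor binning conserves flux and respects the crop contract", {
  m <- tiny_model()
  p <- simulate_psf(m)
  pb <- psf_to_sensor(p, 2, size = 21)
  expect_equal(dim(pb), c(21, 21))
  expect_equal(sum(pb), 1, tolerance = 1e-12)
  expect_equal(attr(pb, "dx_um"), 2)
  # unbinned total flux is preserved before renormalization
  pb2 <- psf_to_sensor(p, 2, renormalize = FALSE)
  expect_equal(sum(pb2), sum(p), tolerance = 1e-9)
  expect_error(psf_to_sensor(p, 2, size = 20), "odd")
})

test_that("MTF obeys its defining identities", {
  # delta PSF -> MTF identically 1
  d <- matrix(0, 32, 32); d[17, 17] <- 1
  attr(d, "dx_um") <- 1
  md <- mtf_from_psf(d)
  expect_equal(max(abs(unclass(md) - 1)), 0, tolerance = 1e-12)
  # MTF(0) = 1 and MTF <= 1 for a real PSF
  p <- simulate_psf(tiny_model(), cubic_phase_mask(0.01), 50)
  mp <- mtf_from_psf(p)
  expect_equal(unclass(mp)[1, 1], 1)
  expect_true(all(unclass(mp) <= 1 + 1e-12))
  # isotropic Gaussian: MTF(f) = exp(-2 pi^2 sigma^2 f^2)
  n <- 128; sigma <- 3
  x <- (1:n) - n / 2 - 1
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  g <- g / sum(g)
  attr(g, "dx_um") <- 1
  pr <- mtf_profile(mtf_from_psf(g), axis = "x")
  expect_lt(max(abs(pr$mtf - exp(-2 * pi^2 * sigma^2 * pr$freq^2))), 1e-6)
})

test_that("Fisher information measures MTF variation across defocus", {
  m <- tiny_model()
  # identical planes at distinct depths -> exactly zero
  ident <- structure(list(mtf = cbind(c(1, 0.4), c(1, 0.4), c(1, 0.4)),
                          freq = c(0, 0.1), z_um = c(-1, 0, 1),
                          nyquist_cpum = 0.25),
                     class = "mtf_stack")
  expect_identical(fisher_information(ident), 0)
  # two-plane stack, one differing bin of size d, dz = 1 -> d^2
  fake <- structure(list(mtf = cbind(c(1, 0.5, 0.2), c(1, 0.5 + 0.07, 0.2)),
                         freq = c(0, 0.1, 0.2), z_um = c(0, 1),
                         nyquist_cpum = 0.25),
                    class = "mtf_stack")
  expect_equal(fisher_information(fake), 0.07^2, tolerance = 1e-12)
  # coded system varies less with defocus than the uncoded one
  zs <- c(-150, 0, 150)
  fi_coded <- fisher_information(mtf_stack(m, cubic_phase_mask(0.02), zs = zs))
  fi_uncoded <- fisher_information(mtf_stack(m, NULL, zs = zs))
  expect_gt(fi_uncoded, fi_coded)
  expect_gte(fi_coded, 0)
})

test_that("alpha sweep enumerates, scores and filters candidates", {
  m <- small_model()
  zs <- c(-150, 0, 150)
  sw <- sweep_alpha(m, 0.01, 0.03, 0.01, zs = zs)
  expect_equal(nrow(sw), 3)
  expect_equal(sw$alpha, c(0.01, 0.02, 0.03))
  # feasibility equals an independent filter of the same candidate list
  brute <- vapply(sw$alpha, function(a) {
    min_nyquist_mtf(mtf_stack(m, cubic_phase_mask(a), zs = zs)) >= 0.1
  }, logical(1))
  expect_equal(sw$feasible, brute)
  # a single candidate is ranked first (when feasible) or reported infeasible
  sw1 <- sweep_alpha(m, 0.03, 0.03, 0.01, zs = zs)
  expect_equal(nrow(sw1), 1)
  if (sw1$feasible[1]) expect_equal(sw1$rank[1], 1L)
  # empty feasible set is reported, not raised
  sw0 <- sweep_alpha(m, 0.001, 0.001, 0.001, zs = zs)
  expect_true(is.na(attr(sw0, "selected")) || sw0$feasible[1])
})

test_that("Strehl ratio is bounded and penalizes defocus more without coding", {
  m <- tiny_model()
  p0 <- simulate_psf(m)
  expect_equal(strehl_ratio(p0, m), 1)
  for (z in c(50, 150)) {
    expect_lt(strehl_ratio(simulate_psf(m, NULL, z), m), 1 + 1e-6)
  }
  # heavily defocused uncoded PSF falls below the coded PSF at the same z
  su <- strehl_ratio(simulate_psf(m, NULL, 150), m)
  sc <- strehl_ratio(simulate_psf(m, cubic_phase_mask(0.02), 150), m)
  expect_lt(su, sc)
})

test_that("coded PSFs stay similar across the depth range, uncoded do not", {
  m <- small_model()
  mask <- cubic_phase_mask(0.03)
  bin <- function(mk, z) {
    p <- psf_to_sensor(simulate_psf(m, mk, z), 2, size = 31)
    unclass(p) / max(p)
  }
  s_coded <- ssim(bin(mask, 0), bin(mask, 150), data_range = 1)
  s_uncoded <- ssim(bin(NULL, 0), bin(NULL, 150), data_range = 1)
  expect_gt(s_coded, s_uncoded)
  # and the coded Nyquist MTF at the depth edge beats the uncoded one
  fN <- nyquist_frequency(m)
  mc <- mtf_at(mtf_from_psf(simulate_psf(m, mask, 150)), fN)
  mu <- mtf_at(mtf_from_psf(simulate_psf(m, NULL, 150)), fN)
  expect_gt(mc, mu)
})

test_that("PSF grids store, retrieve and persist field-indexed PSFs", {
  m <- tiny_model()
  g <- simulate_psf_grid(m, cubic_phase_mask(0.01), field_grid(2),
                         zs = c(-75, 0), wavelengths_nm = c(470, 530),
                         crop = 21)
  expect_equal(dim(g$psf), c(4, 2, 2, 21, 21))
  p <- grid_psf(g, 3, z_um = 0, channel = 2)
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(attr(p, "wavelength_nm"), 530)
  expect_error(grid_psf(g, 1, z_um = 33), "not on the grid")
  f <- tempfile(fileext = ".rds")
  write_psf_grid(g, f)
  expect_equal(read_psf_grid(f)$psf, g$psf)
})
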