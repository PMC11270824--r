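# Orientational averaging, response assembly, 2D FFT, kinetics, anisotropy.

test_that("orientational weight tensors have 21 nonzero components and match
           the rotational-quadrature oracle", {
  Apar <- orientational_weights("parallel")
  Aper <- orientational_weights("perpendicular")
  expect_equal(sum(Apar != 0), 21L)
  expect_equal(sum(Aper != 0), 21L)
  set.seed(27)
  mus <- lapply(1:4, function(i) rnorm(3))
  for (scheme in c("parallel", "perpendicular")) {
    A <- orientational_weights(scheme)
    expect_equal(weights_contract(A, mus[[1]], mus[[2]], mus[[3]], mus[[4]]),
                 iso_average_oracle(mus[[1]], mus[[2]], mus[[3]], mus[[4]],
                                    scheme),
                 tolerance = 1e-10)
  }
  # all four dipoles parallel: <cos^4> = 1/5 and <cos^2 sin^2 cos^2 phi> = 1/15
  u <- c(1, 0, 0)
  expect_equal(weights_contract(Apar, u, u, u, u), 1 / 5)
  expect_equal(weights_contract(Aper, u, u, u, u), 1 / 15)
  # rotational invariance of the contraction under a global rotation
  R <- rot_zyz(0.4, 1.1, -0.7)
  rot <- lapply(mus, function(m) drop(R %*% m))
  expect_equal(weights_contract(Apar, rot[[1]], rot[[2]], rot[[3]], rot[[4]]),
               weights_contract(Apar, mus[[1]], mus[[2]], mus[[3]], mus[[4]]),
               tolerance = 1e-12)
  expect_error(orientational_weights("magic"), "arg")
})

make_tiny_cg <- function(sys, K, t2s, nt = 48, R = 20, seed = 31) {
  cg_2des(sys, K, t2s, nt1 = nt, nt3 = nt, realizations = R, seed = seed)
}

test_that("single-segment response is exactly waiting-time independent and
           T = identity reduces to per-segment products", {
  sys <- make_dimer_fixture("single_segment")
  res <- make_tiny_cg(sys, matrix(0, 1, 1), c(0, 7.5, 42))
  expect_identical(res$responses[[1]]$nonrephasing$values,
                   res$responses[[2]]$nonrephasing$values)
  expect_identical(res$spectra[[1]]$absorptive, res$spectra[[3]]$absorptive)
  # two-segment system with identity transfer: sum of segment products
  sys2 <- make_dimer_fixture("double_segment")
  tabs <- cg_segment_tables(sys2, 32, 32, realizations = 10, seed = 7)
  A <- orientational_weights("parallel")
  Tm <- transfer_map(matrix(0, 2, 2), 5)        # K = 0 -> T = I at any t2
  expect_equal(unclass(Tm), diag(2), ignore_attr = TRUE)
  full <- assemble_response(tabs$doorways, tabs$windows, Tm, A, "nonrephasing")
  manual <- matrix(0i, 32, 32)
  A2 <- cg2des:::weights_as_matrix(A)
  for (j in 1:2) for (d in c("GB", "SE", "EA")) {
    Dm <- cg2des:::flatten_dw(tabs$doorways[[j]]) %*% A2
    manual <- manual + Dm %*% t(cg2des:::flatten_dw(tabs$windows[[j]][[d]]))
  }
  expect_equal(full$values, manual, tolerance = 1e-12)
})

test_that("two-segment weights approach the stationary distribution at long t2", {
  sys <- make_dimer_fixture("double_segment")
  K <- build_dimer_rate_fixture("RT")
  p <- stationary_distribution(K)
  Tm <- transfer_map(K, 500)
  expect_equal(Tm[, 1], p, tolerance = 1e-8)
  expect_equal(Tm[, 2], p, tolerance = 1e-8)
})

test_that("a static isolated site yields an absorptive peak at its energy,
           zero response transforms to zero", {
  b0 <- bath_params(0, 100)
  sys <- system_model(12000, b0, matrix(0, 1, 1), matrix(c(1, 0, 0), 1, 3),
                      segmentation(1L), Inf)
  res <- cg_2des(sys, matrix(0, 1, 1), 0, nt1 = 64, nt3 = 64,
                 realizations = 2, seed = 1)
  sp <- res$spectra[[1]]
  idx <- which(sp$absorptive == max(sp$absorptive), arr.ind = TRUE)
  dw <- diff(sp$omega1[1:2])
  expect_lt(abs(sp$omega1[idx[1]] - 12000), dw + 1e-9)
  expect_lt(abs(sp$omega3[idx[2]] - 12000), dw + 1e-9)
  # doubling the padding must not move the peak beyond original resolution
  nr <- res$responses[[1]]$nonrephasing; rp <- res$responses[[1]]$rephasing
  sp8 <- spectrum_2d(nr, rp, res$ref_freq, zero_pad = 8)
  idx8 <- which(sp8$absorptive == max(sp8$absorptive), arr.ind = TRUE)
  expect_lt(abs(sp8$omega1[idx8[1]] - sp$omega1[idx[1]]), dw)
  zresp <- nr; zresp$values[] <- 0i
  spz <- spectrum_2d(zresp, zresp, 12000)
  expect_true(all(spz$absorptive == 0))
})

test_that("saturating-exponential fits recover known rates and flag constants", {
  t2 <- c(0, 1, 2, 4, 7, 11, 16, 25)
  I <- 3.2 * (1 - exp(-0.23 * t2)) + 0.7
  fit <- fit_saturating_exponential(t2, I)
  expect_equal(fit$k, 0.23, tolerance = 1e-2)
  expect_equal(fit$A, 3.2, tolerance = 1e-2)
  fitc <- fit_saturating_exponential(t2, rep(1.5, length(t2)))
  expect_true(fitc$degenerate)
  expect_equal(fitc$k, 0)
})

test_that("cross-peak growth in the two-segment dimer follows the rate-matrix
           eigenvalue", {
  sys <- make_dimer_fixture("double_segment")
  K <- build_dimer_rate_fixture("RT")
  lam <- max(relaxation_eigenvalues(K)$rates)
  t2s <- c(0, 3, 7, 14, 25, 45)
  res <- cg_2des(sys, K, t2s, nt1 = 64, nt3 = 64, realizations = 30, seed = 5)
  fit <- cross_peak_kinetics(res$spectra, t2s, c(11850, 12150), c(11350, 11650))
  expect_equal(fit$k, lam, tolerance = 0.01)
  expect_error(cross_peak_kinetics(res$spectra[1:2], t2s[1:2],
                                   c(11850, 12150), c(11350, 11650)), ">= 3")
})

test_that("anisotropy: r = 0.4 for a fixed isolated dipole, 0 for equal
           intensities, NA on zero denominator", {
  b <- bath_params(90, 150)
  dip <- matrix(c(0.3, -0.8, 0.52), 1, 3)
  sys <- system_model(12000, b, matrix(0, 1, 1), dip, segmentation(1L), Inf)
  tabs <- cg_segment_tables(sys, 48, 48, realizations = 25, seed = 9)
  K0 <- matrix(0, 1, 1)
  Ipar <- box_intensity(cg_2des(sys, K0, 0, scheme = "parallel",
                                tables = tabs)$spectra[[1]],
                        c(11600, 12400), c(11600, 12400))
  Iper <- box_intensity(cg_2des(sys, K0, 0, scheme = "perpendicular",
                                tables = tabs)$spectra[[1]],
                        c(11600, 12400), c(11600, 12400))
  expect_equal(anisotropy(Ipar, Iper), 0.4, tolerance = 1e-6)
  expect_equal(Ipar / Iper, 3, tolerance = 1e-6)
  expect_equal(anisotropy(2.2, 2.2), 0)
  expect_true(is.na(anisotropy(1, -0.5)))
})
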