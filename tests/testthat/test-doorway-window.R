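# Doorway and window functions, equilibrium densities, segment energies.

test_that("equilibrium density: HT identity/D, single site, Boltzmann dimer", {
  m <- make_two_ring_fixture()
  tr <- static_traj(m$means, n_frames = 3)
  rho_ht <- equilibrium_density(tr, m$J, m$seg, 1, Inf)
  expect_equal(rho_ht, diag(18) / 18)
  rho_1 <- equilibrium_density(tr, m$J, m$seg, 2, 300)
  expect_equal(rho_1, matrix(1, 1, 1))
  # static uncoupled two-site segment at 300 K: closed-form site weights
  means <- c(11500, 12000)
  tr2 <- static_traj(means, n_frames = 3)
  seg2 <- segmentation(c(1, 1))
  rho <- equilibrium_density(tr2, matrix(0, 2, 2), seg2, 1, 300)
  w <- exp(-means / (cg_constants$kB * 300)); w <- w / sum(w)
  expect_equal(diag(rho), w, tolerance = 1e-12)
  expect_equal(rho[1, 2], 0)
  expect_equal(sum(diag(rho)), 1, tolerance = 1e-10)
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_error(equilibrium_density(tr2, matrix(0, 2, 2), seg2, 1, -5), "temperature")
})

test_that("segment energies: HT average, Boltzmann weighting, ground-state limit", {
  tr1 <- static_traj(12465, n_frames = 4)
  seg1 <- segmentation(1L)
  expect_equal(segment_energy(tr1, matrix(0, 1, 1), seg1, 1, Inf), 12465)
  sys <- make_dimer_fixture("single_segment")
  tr <- static_traj(sys$means, n_frames = 4)
  lam <- eigen(matrix(c(11500, 100, 100, 12000), 2, 2), symmetric = TRUE)$values
  for (temp in c(300, 77)) {
    w <- exp(-(lam - min(lam)) / (cg_constants$kB * temp))
    expect_equal(segment_energy(tr, sys$J, sys$seg, 1, temp),
                 sum(lam * w) / sum(w), tolerance = 1e-10)
  }
  expect_equal(segment_energy(tr, sys$J, sys$seg, 1, 0.5), min(lam),
               tolerance = 1e-6)
  expect_equal(segment_energy(tr, sys$J, sys$seg, 1, Inf), mean(lam))
})

test_that("doorway t1 = 0 contraction, rephasing conjugation, zero-noise phase", {
  sys <- make_dimer_fixture("single_segment")
  D <- doorway(sys, 1, nt = 16, realizations = 4, seed = 2)
  expect_equal(Re(D$values[1, 1, 1]), 2, tolerance = 1e-10)  # sum mu_x^2
  expect_equal(Im(D$values[1, 1, 1]), 0, tolerance = 1e-10)
  expect_equal(D$values[1, 2, 2], 0 + 0i)                    # no y dipoles
  Dr <- doorway(sys, 1, nt = 16, realizations = 4, seed = 2,
                pathway = "rephasing")
  expect_identical(Dr$values, Conj(D$values))
  # sigma = 0 single site: pure oscillation at the mean frequency
  b0 <- bath_params(0, 100)
  s1 <- system_model(12000, b0, matrix(0, 1, 1), matrix(c(1, 0, 0), 1, 3),
                     segmentation(1L), Inf)
  D0 <- doorway(s1, 1, nt = 32, realizations = 2, seed = 1)
  expect_equal(D0$values[, 1, 1],
               exp(-1i * cg_constants$twopic * 12000 * D0$times),
               tolerance = 1e-9)
})

test_that("GB window equals the doorway contraction; SE and EA t3 = 0 values
           match explicit operator contractions", {
  sys <- make_dimer_fixture("single_segment")
  D <- doorway(sys, 1, nt = 12, realizations = 5, seed = 3)
  G <- window_gb(sys, 1, nt = 12, realizations = 5, seed = 3)
  expect_identical(G$values, D$values)
  rho <- diag(2) / 2
  S <- window_se(sys, 1, rho, nt = 12, realizations = 5, seed = 3)
  expect_equal(Re(S$values[1, 1, 1]), 1, tolerance = 1e-10)  # (1/2) sum mu^2
  E <- window_ea(sys, 1, rho, nt = 12, realizations = 5, seed = 3)
  b2 <- build_two_exciton_basis(2, "strict")
  m2x <- matrix(transition_dipole_ef(sys$dipoles, b2)[, , 1], nrow = 1)
  expect_equal(Re(E$values[1, 1, 1]), -Re(sum(diag(t(m2x) %*% m2x %*% rho))),
               tolerance = 1e-10)
  expect_lt(Re(E$values[1, 1, 1]) * Re(G$values[1, 1, 1]), 0)  # opposite signs
  expect_error(window_se(sys, 1, diag(2), 12, 5), "trace")
})

test_that("finite-temperature SE window at t3 = 0 matches a brute-force trace", {
  sys <- make_dimer_fixture("single_segment", temperature = 300)
  tr <- static_traj(sys$means, n_frames = 40)
  rho <- equilibrium_density(tr, sys$J, sys$seg, 1, 300)
  S <- window_se(sys, 1, rho, nt = 8, realizations = 3, seed = 4, traj = tr)
  mu_x <- sys$dipoles[, 1]
  expect_equal(S$values[1, 1, 1], (t(mu_x) %*% rho %*% mu_x)[1, 1] + 0i,
               tolerance = 1e-10)
})

test_that("single-site segments: SE equals GB and EA vanishes identically", {
  sys <- make_dimer_fixture("double_segment")
  G <- window_gb(sys, 2, nt = 10, realizations = 4, seed = 5)
  S <- window_se(sys, 2, matrix(1, 1, 1), nt = 10, realizations = 4, seed = 5)
  expect_equal(S$values, G$values, tolerance = 1e-12)
  E <- window_ea(sys, 2, matrix(1, 1, 1), nt = 10, realizations = 4, seed = 5)
  expect_true(all(E$values == 0))
})

test_that("doorway magnitude follows the closed-form OU (Kubo) lineshape", {
  b <- bath_params(198, 220)
  s1 <- system_model(12000, b, matrix(0, 1, 1), matrix(c(1, 0, 0), 1, 3),
                     segmentation(1L), Inf)
  D <- doorway(s1, 1, nt = 128, realizations = 600, seed = 21, spacing = 64)
  L <- 1 / 220
  sw <- cg_constants$twopic * 198
  g <- (sw / L)^2 * (exp(-L * D$times) - 1 + L * D$times)
  expect_lt(max(abs(abs(D$values[, 1, 1]) - exp(-g))), 0.08)  # ~1/sqrt(R)
})
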