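# One- and two-exciton propagation against dense and operator oracles.

test_that("decoupled sites accumulate pure diagonal phases", {
  b <- bath_params(c(150, 150), c(220, 220))
  tr <- generate_ou_trajectory(b, c(11500, 12000), 64, 2, seed = 6)
  seg <- segmentation(c(1, 1))
  U <- propagate_one(tr, matrix(0, 2, 2), seg, 1, 1, 64)$U
  phases <- exp(-1i * cg_constants$twopic * colSums(tr$energies[1:63, ]) * 2)
  expect_lt(max(abs(U - diag(phases))), 1e-10)
})

test_that("dense path reproduces the matrix exponential for a static dimer
           and the Trotter split is second order", {
  sys <- make_dimer_fixture("single_segment")
  tr <- static_traj(sys$means, n_frames = 200, dt = 2)
  H <- sys$J; diag(H) <- sys$means
  e <- eigen(H, symmetric = TRUE)
  Uexact <- e$vectors %*% (exp(-1i * cg_constants$twopic * e$values * 256) *
                           t(e$vectors))
  Ud <- propagate_one(tr, sys$J, sys$seg, 1, 1, 129, method = "dense")$U
  expect_lt(max(abs(Ud - Uexact)), 1e-10)
  # Trotter error drops ~4x when dt halves (same total time)
  err_at <- function(dt) {
    trd <- static_traj(sys$means, n_frames = round(256 / dt) + 1, dt = dt)
    Ut <- propagate_one(trd, sys$J, sys$seg, 1, 1, round(256 / dt) + 1)$U
    max(abs(Ut - Uexact))
  }
  r <- err_at(2) / err_at(1)
  expect_gt(r, 3.4); expect_lt(r, 4.6)
})

test_that("propagators are unitary and compose exactly", {
  sys <- make_dimer_fixture("single_segment")
  tr <- generate_ou_trajectory(sys$bath, sys$means, 200, 2, seed = 8)
  U <- propagate_one(tr, sys$J, sys$seg, 1, 1, 129)
  expect_lt(unitarity_error(U$U), 1e-8)
  Ua <- propagate_one(tr, sys$J, sys$seg, 1, 1, 70)$U
  Ub <- propagate_one(tr, sys$J, sys$seg, 1, 70, 129)$U
  expect_lt(max(abs(U$U - Ub %*% Ua)), 1e-12)
  expect_error(propagate_one(tr, sys$J, sys$seg, 1, 1, 500), "range")
})

test_that("two-exciton basis dimensions follow the mode formula", {
  expect_equal(nrow(build_two_exciton_basis(2, "strict")$pairs), 1L)
  expect_equal(nrow(build_two_exciton_basis(2, "paper")$pairs), 3L)
  expect_equal(nrow(build_two_exciton_basis(27, "strict")$pairs), 351L)
  expect_equal(nrow(build_two_exciton_basis(27, "paper")$pairs), 27 * 28 / 2)
  expect_error(build_two_exciton_basis(1, "strict"), "N >= 2")
})

test_that("two-exciton Hamiltonian matches the many-body operator oracle", {
  set.seed(11)
  N <- 3
  J <- matrix(rnorm(9, sd = 60), N, N); J <- (J + t(J)) / 2; diag(J) <- 0
  eps <- c(11900, 12100, 12300)
  basis <- build_two_exciton_basis(N, "strict")
  H2 <- two_exciton_hamiltonian(eps, J, basis)
  expect_equal(H2, brute_two_exciton(eps, J), tolerance = 1e-12)
  expect_equal(H2, t(H2))
  # dimer / zero-coupling degenerate cases
  b2 <- build_two_exciton_basis(2, "strict")
  expect_equal(two_exciton_hamiltonian(c(11500, 12000),
                                       matrix(c(0, 100, 100, 0), 2, 2), b2),
               matrix(23500, 1, 1))
  H0 <- two_exciton_hamiltonian(eps, matrix(0, N, N), basis)
  expect_equal(H0, diag(eps[basis$pairs[, 1]] + eps[basis$pairs[, 2]]))
  expect_error(two_exciton_hamiltonian(eps[1:2], J, basis), "mismatch")
})

test_that("two-exciton propagation: dimer closed form, unitarity, and
           trotter/dense agreement", {
  sys <- make_dimer_fixture("single_segment")
  tr <- generate_ou_trajectory(sys$bath, sys$means, 80, 2, seed = 12)
  b2 <- build_two_exciton_basis(2, "strict")
  U2 <- propagate_two(tr, sys$J, sys$seg, 1, b2, 1, 65)$U
  phase <- exp(-1i * cg_constants$twopic * sum(rowSums(tr$energies[1:64, ])) * 2)
  expect_lt(abs(U2[1, 1] - phase), 1e-10)
  expect_lt(unitarity_error(U2), 1e-8)
  # N = 3: sparse (trotter) path converges to the dense exponential path
  # (second-order split: fine steps for the tight elementwise bound)
  set.seed(13)
  N <- 3
  J <- matrix(rnorm(9, sd = 40), N, N); J <- (J + t(J)) / 2; diag(J) <- 0
  b <- bath_params(rep(120, N), rep(150, N))
  tr3 <- generate_ou_trajectory(b, rep(12000, N), 40, 0.25, seed = 14)
  seg3 <- segmentation(rep(1L, N))
  b3 <- build_two_exciton_basis(N, "strict")
  Ud <- propagate_two(tr3, J, seg3, 1, b3, 1, 33, method = "dense")$U
  Ut <- propagate_two(tr3, J, seg3, 1, b3, 1, 33, method = "trotter")$U
  expect_lt(max(abs(Ud - Ut)), 1e-6)
  expect_lt(unitarity_error(Ud), 1e-8)
})

test_that("e->f transition dipoles match the operator-algebra oracle", {
  # dimer: pair state couples to e=1 via mu_2 and to e=2 via mu_1
  dip2 <- rbind(c(1, 0, 0), c(0, 2, 0))
  b2 <- build_two_exciton_basis(2, "strict")
  m2 <- transition_dipole_ef(dip2, b2)
  expect_equal(m2[1, 1, ], c(0, 2, 0))
  expect_equal(m2[1, 2, ], c(1, 0, 0))
  set.seed(15)
  dip3 <- matrix(rnorm(9), 3, 3)
  b3 <- build_two_exciton_basis(3, "strict")
  expect_equal(transition_dipole_ef(dip3, b3), brute_mu_ef(dip3),
               tolerance = 1e-12)
  expect_equal(transition_dipole_ef(matrix(0, 3, 3), b3),
               array(0, dim = c(3, 3, 3)))
  expect_error(transition_dipole_ef(dip2, b3), "matching")
})

test_that("paper-convention basis carries sqrt(2) same-site factors", {
  bp <- build_two_exciton_basis(2, "paper", anharmonicity = 100)
  eps <- c(11500, 12000)
  J <- matrix(c(0, 50, 50, 0), 2, 2)
  H <- two_exciton_hamiltonian(eps, J, bp)
  # lexicographic pairs: (1,1), (1,2), (2,2)
  expect_equal(diag(H), c(2 * 11500 + 100, 23500, 2 * 12000 + 100))
  expect_equal(H[1, 2], sqrt(2) * 50)
  expect_equal(H[2, 3], sqrt(2) * 50)
  expect_equal(H[1, 3], 0)
  dip <- rbind(c(1, 0, 0), c(1, 0, 0))
  m2 <- transition_dipole_ef(dip, bp)
  expect_equal(m2[1, 1, 1], sqrt(2))
  expect_equal(m2[1, 2, 1], 0)
})
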