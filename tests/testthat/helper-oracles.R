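# Independent oracles used across the test files.

# Gauss-Legendre nodes/weights on [-1, 1] (Golub-Welsch)
gl_nodes <- function(n) {
  k <- seq_len(n - 1L)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1L)] <- b
  J[cbind(k + 1L, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1L, ]^2)
}

rot_zyz <- function(phi, theta, psi) {
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(phi) %*% ry(theta) %*% rz(psi)
}

# Numerical isotropic average of (e1.Ra)(e1.Rb)(e2.Rc)(e2.Rd) over all
# molecular orientations R, by quadrature over ZYZ Euler angles (exact for
# the degree-4 trigonometric integrand at these orders).  e1 is the pump
# polarization (lab Z); e2 is Z for the parallel scheme and X for the
# perpendicular one.
iso_average_oracle <- function(mu_a, mu_b, mu_c, mu_d, scheme) {
  e1 <- c(0, 0, 1)
  e2 <- if (scheme == "parallel") c(0, 0, 1) else c(1, 0, 0)
  m <- 9L                                 # azimuthal points (exact for deg 4)
  ang <- 2 * pi * (seq_len(m) - 1L) / m
  gl <- gl_nodes(8L)
  acc <- 0
  for (ip in seq_len(m)) for (it in seq_len(8L)) for (is in seq_len(m)) {
    R <- rot_zyz(ang[ip], acos(gl$x[it]), ang[is])
    f <- sum(e1 * (R %*% mu_a)) * sum(e1 * (R %*% mu_b)) *
         sum(e2 * (R %*% mu_c)) * sum(e2 * (R %*% mu_d))
    acc <- acc + f * gl$w[it] / (m * m * 2)
  }
  acc
}

# contraction of the packaged weight tensor with four dipoles
weights_contract <- function(A, mu_a, mu_b, mu_c, mu_d) {
  acc <- 0
  for (a in 1:3) for (b in 1:3) for (g in 1:3) for (d in 1:3)
    acc <- acc + A[a, b, g, d] * mu_a[a] * mu_b[b] * mu_c[g] * mu_d[d]
  acc
}

# Many-body construction of the two-exciton Hamiltonian: build the full
# 2^N Hamiltonian from Pauli raising/lowering operators and project onto
# the doubly excited occupation subspace, matched to the strict pair order.
brute_two_exciton <- function(eps, J) {
  N <- length(eps)
  low <- matrix(c(0, 0, 1, 0), 2, 2)      # |0><1|
  occ <- matrix(c(0, 0, 0, 1), 2, 2)
  op_site <- function(op, n) {
    M <- 1
    for (k in seq_len(N)) M <- kronecker(M, if (k == n) op else diag(2))
    M
  }
  H <- matrix(0, 2^N, 2^N)
  for (n in seq_len(N)) H <- H + eps[n] * op_site(occ, n)
  for (n in seq_len(N)) for (mm in seq_len(N)) if (n != mm)
    H <- H + J[n, mm] * op_site(t(low), n) %*% op_site(low, mm)
  nbits <- function(i) sum(as.integer(intToBits(i))[seq_len(N)])
  states <- which(vapply(0:(2^N - 1), nbits, integer(1)) == 2L) - 1L
  # occupation integer for pair (m, n): bit order matches kronecker order
  pair_state <- function(m, n) sum(2^(N - c(m, n)))
  basis <- build_two_exciton_basis(N, "strict")
  idx <- vapply(seq_len(nrow(basis$pairs)), function(p)
    which(states == pair_state(basis$pairs[p, 1], basis$pairs[p, 2])),
    integer(1))
  H[states[idx] + 1L, states[idx] + 1L, drop = FALSE]
}

# Operator-algebra oracle for the e->f transition dipoles: apply
# sum_n mu_n (B_n^+ + B_n) between the explicit one- and two-exciton
# occupation subspaces.
brute_mu_ef <- function(dip) {
  N <- nrow(dip)
  low <- matrix(c(0, 0, 1, 0), 2, 2)
  op_site <- function(op, n) {
    M <- 1
    for (k in seq_len(N)) M <- kronecker(M, if (k == n) op else diag(2))
    M
  }
  nbits <- function(i) sum(as.integer(intToBits(i))[seq_len(N)])
  occn <- vapply(0:(2^N - 1), nbits, integer(1))
  ones <- which(occn == 1L) - 1L
  twos <- which(occn == 2L) - 1L
  one_state <- function(k) 2^(N - k)
  pair_state <- function(m, n) sum(2^(N - c(m, n)))
  basis <- build_two_exciton_basis(N, "strict")
  e_idx <- vapply(seq_len(N), function(k) which(ones == one_state(k)), integer(1))
  f_idx <- vapply(seq_len(nrow(basis$pairs)), function(p)
    which(twos == pair_state(basis$pairs[p, 1], basis$pairs[p, 2])),
    integer(1))
  out <- array(0, dim = c(nrow(basis$pairs), N, 3))
  for (a in 1:3) {
    M <- matrix(0, 2^N, 2^N)
    for (n in seq_len(N)) M <- M + dip[n, a] * (op_site(t(low), n) + op_site(low, n))
    out[, , a] <- M[twos[f_idx] + 1L, ones[e_idx] + 1L, drop = FALSE]
  }
  out
}

# static (sigma = 0) trajectory at given site energies
static_traj <- function(means, n_frames = 16L, dt = 2) {
  generate_ou_trajectory(bath_params(rep(0, length(means)),
                                     rep(100, length(means))),
                         means, n_frames, dt, seed = 1L)
}
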