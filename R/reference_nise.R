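# Brute-force full third-order response for small systems (N <= 4).
#
# All six double-sided diagrams (GB/SE/EA, rephasing and nonrephasing) are
# evaluated by explicit one- and two-exciton wavefunction propagation over
# all three time intervals on the unsegmented system, with no equilibration
# assumption.  Serves as the validation oracle for the coarse-grained
# path; the formalism is a high-temperature-limit method.
#
# Internally, cumulative propagators P(tau) = U(tau1, tau) from the first
# interaction time give any interval propagator as U(a, b) = P(b) P(a)^H,
# and contraction vectors w_x(tau) = P(tau)^H mu_x reduce every diagram to
# inner products: e.g. mu_d^T U(a, b) mu_c = w_d(b)^H w_c(a).

#' Full 2DES response of a small unsegmented system
#'
#' Direct evaluation of the six response diagrams at one waiting time,
#' ensemble-averaged over trajectory starting points and contracted with
#' the isotropic orientational weights of the requested polarization
#' scheme.  Refuses systems with more than `max_sites` sites: use the
#' coarse-grained path for larger systems.
#'
#' @param system a [system_model()] (segmentation is ignored; the full
#'   coupling matrix is used)
#' @param nt1,nt3 coherence-time grid lengths (spacing `dt`)
#' @param t2_fs waiting time in fs (rounded to a whole number of frames)
#' @param realizations number of trajectory starting points
#' @param seed master seed for the internally generated trajectory
#' @param dt time step (fs) when `traj` is NULL
#' @param spacing frames between starting points (default `nt1`)
#' @param offset frame offset of the first starting point
#' @param traj optional precomputed trajectory (for shared-noise
#'   comparisons with the coarse-grained path)
#' @param scheme polarization scheme for the orientational contraction
#' @param max_sites guard for the dense propagation path
#' @return list with `response_grid`s `nonrephasing` and `rephasing`
#'   (summed over diagrams) and `diagrams` (per-pathway GB/SE/EA matrices)
#' @export
full_2des_small <- function(system, nt1, nt3, t2_fs, realizations = 50L,
                            seed = 1L, dt = 2, spacing = NULL, offset = 0L,
                            traj = NULL, scheme = "parallel",
                            max_sites = 4L) {
  N <- system$seg$N
  if (N > max_sites)
    stop_invalid("full response oracle is restricted to <= ", max_sites,
                 " sites (got ", N, "); use the coarse-grained path")
  if (is.null(spacing)) spacing <- nt1
  n2 <- as.integer(round(t2_fs / dt))
  ntot <- nt1 + n2 + nt3 - 1L           # rel frames 0 .. ntot-1
  if (is.null(traj)) {
    nf <- frames_needed(realizations, spacing, ntot, offset)
    traj <- default_trajectory(system, nf, dt, seed)
  } else {
    dt <- traj$dt
    n2 <- as.integer(round(t2_fs / dt))
    ntot <- nt1 + n2 + nt3 - 1L
  }
  starts <- ensemble_starts(realizations, spacing, offset)
  if (max(starts) + ntot - 1L > nrow(traj$energies))
    stop_invalid("trajectory too short for requested realizations/grids")

  dip <- system$dipoles
  act <- which(colSums(abs(dip)) > 0)   # active Cartesian components
  if (length(act) == 0L) act <- 1L
  A <- orientational_weights(scheme)
  combos <- NULL
  for (a in act) for (b in act) for (g in act) for (d in act)
    if (A[a, b, g, d] != 0) combos <- rbind(combos, c(a, b, g, d, A[a, b, g, d]))

  EJ <- unitary_exp(system$J, dt)
  if (N >= 2L) {
    basis <- build_two_exciton_basis(N, "strict")
    K <- nrow(basis$pairs)
    mu2a <- transition_dipole_ef(dip, basis)
    mu2 <- lapply(1:3, function(a) matrix(mu2a[, , a], nrow = K))
    EJ2 <- unitary_exp(two_exciton_coupling_block(system$J, basis), dt)
  } else {
    basis <- NULL; K <- 0L
  }

  zero <- matrix(0i, nt1, nt3)
  acc <- list(
    nonrephasing = list(GB = zero, SE = zero, EA = zero),
    rephasing    = list(GB = zero, SE = zero, EA = zero))

  i1g <- seq_len(nt1)                    # rel tau2 index = i1 (1-based at 0 fs)
  for (s in starts) {
    eps <- traj$energies[s:(s + ntot - 1L), , drop = FALSE]
    # cumulative one-exciton propagator P[, , t] = U(rel 0 -> rel t-1)
    P <- array(0i, dim = c(N, N, ntot))
    P[, , 1L] <- diag(N)
    for (f in seq_len(ntot - 1L)) {
      ph <- half_phases(eps[f, ], dt)
      P[, , f + 1L] <- (ph * EJ * rep(ph, each = N)) %*% P[, , f]
    }
    Pflat <- matrix(P, N * N, ntot)
    # cumulative two-exciton propagator on rel frames (n2 .. ntot-1),
    # reference at rel frame n2 (any common reference cancels in U2(a,b))
    off2 <- n2                           # rel index -> slice idx - off2
    n2len <- ntot - n2
    if (K > 0L) {
      P2 <- array(0i, dim = c(K, K, n2len))
      P2[, , 1L] <- diag(K)
      pr <- basis$pairs
      for (f in seq_len(n2len - 1L)) {
        fa <- n2 + f                     # eps row for rel slice n2 + f
        pe <- eps[fa, pr[, 1L]] + eps[fa, pr[, 2L]]
        ph2 <- half_phases(pe, dt)
        P2[, , f + 1L] <- (ph2 * EJ2 * rep(ph2, each = K)) %*% P2[, , f]
      }
      P2flat <- matrix(P2, K * K, n2len)
    }
    # w_x[k, t] = (P(t)^H mu_x)[k]
    W <- array(0i, dim = c(N, ntot, 3L))
    for (a in act) for (k in seq_len(N)) {
      wk <- rep(0i, ntot)
      for (j in seq_len(N))
        wk <- wk + Conj(Pflat[j + N * (k - 1L), ]) * dip[j, a]
      W[k, , a] <- wk
    }
    inner_w <- function(xidx, x, yidx, y)   # w_x(tau_a)^H w_y(tau_b), batched
      colSums(matrix(Conj(W[, xidx, x]), N) * matrix(W[, yidx, y], N))
    applyPH <- function(tidx, Smat) {       # P(t)^H applied columnwise
      out <- matrix(0i, N, length(tidx))
      for (k in seq_len(N)) for (j in seq_len(N))
        out[k, ] <- out[k, ] + Conj(Pflat[j + N * (k - 1L), tidx]) * Smat[j, ]
      out
    }
    applyP2 <- function(tidx, r) {          # P2(t) r, batched over tidx
      out <- matrix(0i, K, length(tidx))
      for (k in seq_len(K)) for (j in seq_len(K))
        out[k, ] <- out[k, ] + P2flat[k + K * (j - 1L), tidx - off2] * r[j]
      out
    }
    for (i1 in i1g) {
      tau1 <- 1L; tau2 <- i1; tau3 <- i1 + n2
      tau4 <- tau3 + seq_len(nt3) - 1L
      for (ci in seq_len(nrow(combos))) {
        a <- combos[ci, 1L]; b <- combos[ci, 2L]
        g <- combos[ci, 3L]; d <- combos[ci, 4L]
        wt <- combos[ci, 5L]
        # --- GB ---
        g3 <- inner_w(tau4, d, rep(tau3, nt3), g)
        g1nr <- sum(Conj(W[, tau2, b]) * W[, tau1, a])
        g1r  <- sum(Conj(W[, tau1, a]) * W[, tau2, b])
        acc$nonrephasing$GB[i1, ] <- acc$nonrephasing$GB[i1, ] + wt * g3 * g1nr
        acc$rephasing$GB[i1, ]    <- acc$rephasing$GB[i1, ]    + wt * g3 * g1r
        # --- SE ---
        se_nr <- inner_w(tau4, d, rep(tau1, nt3), a) *
                 sum(Conj(W[, tau2, b]) * W[, tau3, g])
        se_r  <- inner_w(tau4, d, rep(tau2, nt3), b) *
                 sum(Conj(W[, tau1, a]) * W[, tau3, g])
        acc$nonrephasing$SE[i1, ] <- acc$nonrephasing$SE[i1, ] + wt * se_nr
        acc$rephasing$SE[i1, ]    <- acc$rephasing$SE[i1, ]    + wt * se_r
        # --- EA ---
        if (K > 0L) {
          P3w_nr <- P[, , tau3] %*% W[, tau1, a]     # U(tau1,tau3) mu_a
          P3w_r  <- P[, , tau3] %*% W[, tau2, b]     # U(tau2,tau3) mu_b
          r_nr <- Conj(t(P2[, , tau3 - off2])) %*% (mu2[[g]] %*% P3w_nr)
          r_r  <- Conj(t(P2[, , tau3 - off2])) %*% (mu2[[g]] %*% P3w_r)
          q_nr <- applyP2(tau4, r_nr)
          q_r  <- applyP2(tau4, r_r)
          s_nr <- t(mu2[[d]]) %*% q_nr               # mu2_d^H P2 r, N x nt3
          s_r  <- t(mu2[[d]]) %*% q_r
          u_nr <- applyPH(tau4, s_nr)
          u_r  <- applyPH(tau4, s_r)
          ea_nr <- -colSums(Conj(W[, tau2, b]) * u_nr)
          ea_r  <- -colSums(Conj(W[, tau1, a]) * u_r)
          acc$nonrephasing$EA[i1, ] <- acc$nonrephasing$EA[i1, ] + wt * ea_nr
          acc$rephasing$EA[i1, ]    <- acc$rephasing$EA[i1, ]    + wt * ea_r
        }
      }
    }
  }
  nr <- length(starts)
  acc <- lapply(acc, function(p) lapply(p, function(m) m / nr))
  mk <- function(p, pw) structure(
    list(values = p$GB + p$SE + p$EA, pathway = pw, gb_kernel = "full",
         t2 = n2 * dt / 1000, dt1 = dt, dt3 = dt),
    class = "response_grid")
  list(nonrephasing = mk(acc$nonrephasing, "nonrephasing"),
       rephasing = mk(acc$rephasing, "rephasing"),
       diagrams = acc, t2_fs = n2 * dt, dt = dt)
}
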