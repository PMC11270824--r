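# Per-segment doorway functions of t1 and GB/SE/EA window functions of t3.
#
# The doorway function D_{ab}(t1) = < mu_b^T U^ee(t1) mu_a > prepares the
# one-exciton coherence during the first interval; the window functions
# detect it during the third interval: GB shares the doorway contraction,
# SE starts from the segment equilibrium density matrix, and EA involves
# the two-exciton manifold and carries the overall minus sign of the
# excited-state-absorption diagrams.  Ensemble averages run over starting
# points placed equidistantly along one long stochastic trajectory.

new_dw_table <- function(values, dt, segment_id, kind, pathway = NA_character_) {
  structure(list(values = values, times = (seq_len(dim(values)[1L]) - 1L) * dt,
                 dt = dt, segment_id = segment_id, kind = kind,
                 pathway = pathway),
            class = "dw_table")
}

# Starting frames for `realizations` stretches of `nt` frames, spaced
# `spacing` frames apart, offset by `offset` frames.
ensemble_starts <- function(realizations, spacing, offset = 0L) {
  if (realizations < 1L) stop_invalid("`realizations` must be >= 1")
  1L + offset + (seq_len(realizations) - 1L) * spacing
}

#' Trajectory length needed for an ensemble average
#'
#' @param realizations number of starting points
#' @param spacing frames between starting points
#' @param nt frames per stretch (grid length)
#' @param offset frame offset of the first starting point
#' @return minimum number of trajectory frames
#' @export
frames_needed <- function(realizations, spacing, nt, offset = 0L) {
  offset + (realizations - 1L) * spacing + nt
}

# Trajectory for a system model (internal default when none supplied)
default_trajectory <- function(system, n_frames, dt, seed) {
  generate_ou_trajectory(system$bath, system$means, n_frames, dt, seed)
}

# Single-pass engine over all realizations for one segment.
# Computes any of: "ge" table (doorway/GB contraction), "se" table
# (initialised from rho), "ea" table (two-exciton contraction).
dw_engine <- function(traj, J, seg, segment_id, starts, nt,
                      want = c("ge"), rho = NULL, basis = NULL) {
  sites <- segment_sites(seg, segment_id)
  D <- length(sites)
  dt <- traj$dt
  if (max(starts) + nt - 1L > nrow(traj$energies))
    stop_invalid("trajectory too short for requested realizations/grid")
  eps_all <- traj$energies[, sites, drop = FALSE]
  Jb <- J[sites, sites, drop = FALSE]
  EJ <- unitary_exp(Jb, dt)
  out <- list()
  dipm <- attr(starts, "dipoles")   # segment-local dipoles, set by caller
  if (is.null(dipm)) stop_invalid("internal: dipoles not attached")
  one_init <- NULL
  if ("ge" %in% want) one_init <- cbind(one_init, dipm + 0i)
  if ("se" %in% want) one_init <- cbind(one_init, rho %*% dipm)
  do_ea <- "ea" %in% want
  if (do_ea) {
    K <- nrow(basis$pairs)
    mu2a <- transition_dipole_ef(dipm, basis)      # K x D x 3
    mu2 <- lapply(1:3, function(a) matrix(mu2a[, , a], nrow = K))
    EJ2 <- unitary_exp(two_exciton_coupling_block(Jb, basis), dt)
    shift <- ifelse(basis$pairs[, 1L] == basis$pairs[, 2L],
                    basis$anharmonicity, 0)
    acc_ea <- array(0i, dim = c(nt, 3L, 3L))
  }
  if (!is.null(one_init)) acc_one <- array(0i, dim = c(nt, 3L, ncol(one_init)))
  for (s in starts) {
    if (!is.null(one_init)) V <- one_init
    if (do_ea) X <- lapply(1:3, function(g) mu2[[g]] %*% rho)
    for (i in seq_len(nt)) {
      if (!is.null(one_init))
        acc_one[i, , ] <- acc_one[i, , ] + t(dipm) %*% V
      if (do_ea) for (g in 1:3) for (d in 1:3)
        acc_ea[i, g, d] <- acc_ea[i, g, d] + sum(mu2[[d]] * X[[g]])
      if (i == nt) break
      f <- s + i - 1L
      ph <- half_phases(eps_all[f, ], dt)
      U1s <- ph * EJ * rep(ph, each = D)
      if (!is.null(one_init)) V <- U1s %*% V
      if (do_ea) {
        pe <- eps_all[f, basis$pairs[, 1L]] + eps_all[f, basis$pairs[, 2L]] + shift
        ph2 <- half_phases(pe, dt)
        U2s <- ph2 * EJ2 * rep(ph2, each = length(pe))
        U1h <- Conj(t(U1s))
        X <- lapply(X, function(x) U2s %*% x %*% U1h)
      }
    }
  }
  nr <- length(starts)
  if (!is.null(one_init)) {
    acc_one <- acc_one / nr
    if ("ge" %in% want) {
      # acc[i, b, a] = mu_b^T U mu_a ; reorder to [i, a, b]
      out$ge <- aperm(acc_one[, , 1:3, drop = FALSE], c(1L, 3L, 2L))
    }
    if ("se" %in% want) {
      off <- if ("ge" %in% want) 3L else 0L
      out$se <- aperm(acc_one[, , off + 1:3, drop = FALSE], c(1L, 3L, 2L))
    }
  }
  if (do_ea) out$ea <- -acc_ea / nr
  out
}

prep_starts <- function(system, segment_id, nt, realizations, spacing, offset,
                        traj, dt, seed) {
  if (is.null(spacing)) spacing <- nt
  if (is.null(traj)) {
    nf <- frames_needed(realizations, spacing, nt, offset)
    traj <- default_trajectory(system, nf, dt, seed)
  }
  starts <- ensemble_starts(realizations, spacing, offset)
  attr(starts, "dipoles") <- system$dipoles[segment_sites(system$seg, segment_id), ,
                                            drop = FALSE]
  list(traj = traj, starts = starts)
}

#' Doorway function of the first coherence time
#'
#' Ensemble average of \eqn{\mu_\beta^T U^{ee}(t_1) \mu_\alpha} over
#' trajectory starting points, restricted to one segment.  The rephasing
#' doorway is the elementwise complex conjugate of the nonrephasing one
#' (same realizations).
#'
#' @param system a [system_model()]
#' @param segment_id segment index
#' @param nt number of t1 grid points (grid starts at 0, spacing = `dt`)
#' @param realizations number of trajectory starting points
#' @param seed master seed for the internally generated trajectory
#' @param dt time step in fs (used when `traj` is NULL)
#' @param spacing frames between consecutive starting points (default `nt`)
#' @param offset frame offset of the first starting point
#' @param traj optional precomputed [generate_ou_trajectory()] trajectory
#' @param pathway `"nonrephasing"` or `"rephasing"`
#' @return `dw_table` whose `values` array is `[nt, alpha, beta]`
#' @export
doorway <- function(system, segment_id, nt, realizations = 100L, seed = 1L,
                    dt = 2, spacing = NULL, offset = 0L, traj = NULL,
                    pathway = c("nonrephasing", "rephasing")) {
  pathway <- match.arg(pathway)
  ps <- prep_starts(system, segment_id, nt, realizations, spacing, offset,
                    traj, dt, seed)
  tab <- dw_engine(ps$traj, system$J, system$seg, segment_id, ps$starts, nt,
                   want = "ge")$ge
  if (pathway == "rephasing") tab <- Conj(tab)
  new_dw_table(tab, ps$traj$dt, segment_id, "doorway", pathway)
}

#' Ground-state-bleach window function
#'
#' Identical contraction to the doorway function, evaluated on the t3
#' grid; carries no dependence on the equilibrium density matrix because
#' the system resides in the ground state during the waiting time.
#'
#' @inheritParams doorway
#' @return `dw_table` (kind `"GB"`)
#' @export
window_gb <- function(system, segment_id, nt, realizations = 100L, seed = 1L,
                      dt = 2, spacing = NULL, offset = 0L, traj = NULL) {
  ps <- prep_starts(system, segment_id, nt, realizations, spacing, offset,
                    traj, dt, seed)
  tab <- dw_engine(ps$traj, system$J, system$seg, segment_id, ps$starts, nt,
                   want = "ge")$ge
  new_dw_table(tab, ps$traj$dt, segment_id, "GB")
}

check_rho <- function(rho, D) {
  rho <- as.matrix(rho)
  if (nrow(rho) != D || ncol(rho) != D)
    stop_invalid("`rho` dimension does not match the segment")
  if (abs(sum(diag(rho)) - 1) > 1e-8)
    stop_invalid("`rho` must have unit trace")
  rho
}

#' Stimulated-emission window function
#'
#' Ensemble average of \eqn{\mu_\delta^T U^{ee}(t_3)\, \rho^{eq} \mu_\gamma},
#' the one-exciton coherence created by the third pulse acting on the
#' equilibrated excited-state population of the segment.
#'
#' @inheritParams doorway
#' @param rho segment equilibrium density matrix (unit trace), see
#'   [equilibrium_density()]
#' @return `dw_table` (kind `"SE"`) with `values[i, gamma, delta]`
#' @export
window_se <- function(system, segment_id, rho, nt, realizations = 100L,
                      seed = 1L, dt = 2, spacing = NULL, offset = 0L,
                      traj = NULL) {
  D <- length(segment_sites(system$seg, segment_id))
  rho <- check_rho(rho, D)
  ps <- prep_starts(system, segment_id, nt, realizations, spacing, offset,
                    traj, dt, seed)
  tab <- dw_engine(ps$traj, system$J, system$seg, segment_id, ps$starts, nt,
                   want = "se", rho = rho)$se
  new_dw_table(tab, ps$traj$dt, segment_id, "SE")
}

#' Excited-state-absorption window function
#'
#' Ensemble average of
#' \eqn{-\mathrm{Tr}[\mu_\delta^{ef\dagger} U^{ff}(t_3) \mu_\gamma^{ef}
#' \rho^{eq} U^{ee}(t_3)^\dagger]}: the third pulse promotes the
#' equilibrated one-exciton population into the two-exciton manifold and
#' the resulting f-e coherence is detected.  The overall minus sign of the
#' EA diagrams is included.  For a single two-level site in strict mode the
#' two-exciton manifold is empty and the window vanishes identically.
#'
#' @inheritParams window_se
#' @param basis a [build_two_exciton_basis()] for the segment (default:
#'   strict basis; empty manifold yields a zero table)
#' @return `dw_table` (kind `"EA"`)
#' @export
window_ea <- function(system, segment_id, rho, nt, basis = NULL,
                      realizations = 100L, seed = 1L, dt = 2, spacing = NULL,
                      offset = 0L, traj = NULL) {
  D <- length(segment_sites(system$seg, segment_id))
  rho <- check_rho(rho, D)
  if (is.null(basis) && D >= 2L) basis <- build_two_exciton_basis(D, "strict")
  if (is.null(basis) || nrow(basis$pairs) == 0L) {
    dt_use <- if (!is.null(traj)) traj$dt else dt
    return(new_dw_table(array(0i, dim = c(nt, 3L, 3L)), dt_use, segment_id, "EA"))
  }
  ps <- prep_starts(system, segment_id, nt, realizations, spacing, offset,
                    traj, dt, seed)
  tab <- dw_engine(ps$traj, system$J, system$seg, segment_id, ps$starts, nt,
                   want = "ea", rho = rho, basis = basis)$ea
  new_dw_table(tab, ps$traj$dt, segment_id, "EA")
}

#' Segment equilibrium density matrix
#'
#' At finite temperature, the Boltzmann operator of the instantaneous
#' segment Hamiltonian.  With `normalization = "ensemble"` (default) each
#' per-frame operator is divided by the trajectory-averaged trace, and the
#' returned matrix is the trajectory average (unit trace by construction);
#' `normalization = "frame"` normalises each frame by its own trace before
#' averaging.  A specific `frame` returns that frame's operator instead of
#' the average (then only `"frame"` normalisation guarantees unit trace).
#' In the HT limit (`temperature = Inf`) the result is exactly identity/D:
#' equal population of every site and zero coherence.
#'
#' @param traj a [generate_ou_trajectory()] trajectory
#' @param J coupling matrix
#' @param seg a [segmentation()]
#' @param segment_id segment index
#' @param temperature kelvin or `Inf`
#' @param frame frame index, or NULL for the trajectory average
#' @param normalization `"ensemble"` or `"frame"`
#' @param frame_stride use every `frame_stride`-th frame in averages
#' @return Hermitian positive-semidefinite matrix
#' @export
equilibrium_density <- function(traj, J, seg, segment_id, temperature = Inf,
                                frame = NULL,
                                normalization = c("ensemble", "frame"),
                                frame_stride = 1L) {
  normalization <- match.arg(normalization)
  sites <- segment_sites(seg, segment_id)
  D <- length(sites)
  if (is.infinite(temperature)) return(diag(D) / D)
  if (temperature <= 0) stop_invalid("`temperature` must be > 0 or Inf")
  beta <- 1 / (cg_constants$kB * temperature)
  frames <- if (!is.null(frame)) frame else
    seq(1L, nrow(traj$energies), by = frame_stride)
  eref <- min(traj$energies[, sites])     # common shift for numerical range
  boltz <- lapply(frames, function(f) {
    H <- segment_hamiltonian(traj, J, seg, segment_id, f)
    e <- eigen(H, symmetric = TRUE)
    e$vectors %*% (exp(-beta * (e$values - eref)) * t(e$vectors))
  })
  if (normalization == "frame") {
    B <- Reduce(`+`, lapply(boltz, function(b) b / sum(diag(b)))) / length(boltz)
  } else {
    ztr <- mean(vapply(boltz, function(b) sum(diag(b)), numeric(1)))
    B <- Reduce(`+`, boltz) / length(boltz) / ztr
  }
  (B + t(B)) / 2
}

#' Thermal-expectation energy of a segment
#'
#' Trajectory average of the thermal energy expectation of the
#' instantaneous segment Hamiltonian,
#' \eqn{E_{S_j} = \langle \mathrm{Tr}[H e^{-\beta H}]/\mathrm{Tr}[e^{-\beta H}] \rangle}.
#' In the HT limit the Boltzmann weights are uniform and the result is the
#' average of the mean instantaneous eigenvalue (trace/D).
#'
#' @inheritParams equilibrium_density
#' @return energy in cm^-1
#' @export
segment_energy <- function(traj, J, seg, segment_id, temperature = Inf,
                           frame_stride = 1L) {
  sites <- segment_sites(seg, segment_id)
  if (nrow(traj$energies) < 1L) stop_invalid("empty trajectory")
  frames <- seq(1L, nrow(traj$energies), by = frame_stride)
  if (is.infinite(temperature)) {
    return(mean(rowMeans(traj$energies[frames, sites, drop = FALSE])))
  }
  if (temperature <= 0) stop_invalid("`temperature` must be > 0 or Inf")
  beta <- 1 / (cg_constants$kB * temperature)
  vals <- vapply(frames, function(f) {
    H <- segment_hamiltonian(traj, J, seg, segment_id, f)
    lam <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    w <- exp(-beta * (lam - min(lam)))
    sum(lam * w) / sum(w)
  }, numeric(1))
  mean(vals)
}
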