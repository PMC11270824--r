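# Time-ordered propagation of one- and two-exciton wavefunctions over the
# fluctuating site-energy trajectory.  The production path uses a symmetric
# Trotter split exp(-i D dt/2) exp(-i J dt) exp(-i D dt/2): the static
# coupling exponential is precomputed once from the eigendecomposition of
# the segment's J block, and only the diagonal fluctuation phases change
# per frame.  A dense per-frame matrix exponential serves as the oracle.

# exp(-i * twopic * M * dt) for a real symmetric M, via eigendecomposition
unitary_exp <- function(M, dt) {
  if (nrow(M) == 1L)
    return(matrix(exp(-1i * cg_constants$twopic * M[1L, 1L] * dt), 1L, 1L))
  e <- eigen(M, symmetric = TRUE)
  ph <- exp(-1i * cg_constants$twopic * e$values * dt)
  e$vectors %*% (ph * t(e$vectors))
}

# half-step diagonal phase factors for energies eps (cm^-1)
half_phases <- function(eps, dt) exp(-1i * cg_constants$twopic * eps * dt / 2)

new_propagator <- function(U, frame_start, frame_end) {
  structure(list(U = U, frame_start = frame_start, frame_end = frame_end),
            class = "exciton_propagator")
}

#' Deviation of a matrix from unitarity
#' @param U complex square matrix
#' @return operator-norm deviation of `U^H U` from the identity
#' @export
unitarity_error <- function(U) {
  G <- Conj(t(U)) %*% U
  max(abs(G - diag(nrow(G))))
}

check_frames <- function(traj, frame_start, frame_end) {
  nf <- nrow(traj$energies)
  if (frame_start < 1L || frame_end > nf || frame_start > frame_end)
    stop_invalid("frames out of range: [", frame_start, ", ", frame_end,
                 "] with trajectory of ", nf, " frames")
}

#' One-exciton propagator over a segment
#'
#' Time-ordered product of per-frame steps mapping amplitudes at
#' `frame_start` to `frame_end` (one step per frame interval, using the
#' site energies at the left endpoint).  `method = "trotter"` (default)
#' splits diagonal fluctuation phases from the precomputed static-coupling
#' exponential; `method = "dense"` exponentiates the full instantaneous
#' Hamiltonian each frame.
#'
#' @param traj a [generate_ou_trajectory()] result
#' @param J coupling matrix
#' @param seg a [segmentation()]
#' @param segment_id segment index
#' @param frame_start,frame_end 1-based frame range, `frame_start <= frame_end`
#' @param method `"trotter"` or `"dense"`
#' @return `exciton_propagator` with complex matrix `U` (unitary to 1e-8)
#' @export
propagate_one <- function(traj, J, seg, segment_id, frame_start, frame_end,
                          method = c("trotter", "dense")) {
  method <- match.arg(method)
  check_frames(traj, frame_start, frame_end)
  sites <- segment_sites(seg, segment_id)
  D <- length(sites)
  U <- diag(D) + 0i
  if (frame_end > frame_start) {
    eps <- traj$energies[, sites, drop = FALSE]
    Jb <- J[sites, sites, drop = FALSE]
    if (method == "trotter") {
      EJ <- unitary_exp(Jb, traj$dt)
      for (f in frame_start:(frame_end - 1L)) {
        d <- half_phases(eps[f, ], traj$dt)
        U <- (d * EJ * rep(d, each = D)) %*% U
      }
    } else {
      for (f in frame_start:(frame_end - 1L)) {
        H <- Jb
        diag(H) <- eps[f, ]
        U <- unitary_exp(H, traj$dt) %*% U
      }
    }
  }
  new_propagator(U, frame_start, frame_end)
}

#' Two-exciton basis of site pairs
#'
#' In `"strict"` mode only distinct-site pairs (m < n) are kept, dimension
#' N(N-1)/2: hard-core two-level chromophores have no doubly excited site.
#' In `"paper"` mode same-site pairs (m, m) are included, dimension
#' N(N+1)/2, with an anharmonic shift `anharmonicity` added to the
#' same-site pair energies.
#'
#' @param N number of sites in the segment
#' @param mode `"strict"` or `"paper"`
#' @param anharmonicity energy shift Delta (cm^-1) for (m, m) states,
#'   paper mode only
#' @return object of class `two_exciton_basis` with `pairs` (K x 2 matrix,
#'   lexicographic order), `mode`, `anharmonicity`, `N`
#' @export
build_two_exciton_basis <- function(N, mode = c("strict", "paper"),
                                    anharmonicity = 0) {
  mode <- match.arg(mode)
  if (mode == "strict" && N < 2L)
    stop_invalid("strict mode needs N >= 2 (got ", N, ")")
  if (N < 1L) stop_invalid("N must be >= 1")
  pairs <- NULL
  for (m in seq_len(N)) {
    n0 <- if (mode == "strict") m + 1L else m
    if (n0 <= N) pairs <- rbind(pairs, cbind(m, n0:N))
  }
  dimnames(pairs) <- NULL
  structure(list(pairs = pairs, mode = mode,
                 anharmonicity = anharmonicity, N = as.integer(N)),
            class = "two_exciton_basis")
}

#' Two-exciton Hamiltonian of a segment at one frame
#'
#' Diagonal: pair energies \eqn{\epsilon_m + \epsilon_n} (plus the
#' anharmonic shift for same-site pairs).  Off-diagonal: `J[n, k]` between
#' pairs sharing exactly one site, with a sqrt(2) factor on every element
#' touching a same-site pair in paper mode.
#'
#' @param eps instantaneous site energies of the segment (length-N vector)
#' @param Jblock intra-segment coupling block (N x N)
#' @param basis a [build_two_exciton_basis()]
#' @return real symmetric K x K matrix (cm^-1)
#' @export
two_exciton_hamiltonian <- function(eps, Jblock, basis) {
  if (length(eps) != basis$N || nrow(Jblock) != basis$N)
    stop_invalid("dimension mismatch between energies/couplings and basis")
  P <- basis$pairs
  K <- nrow(P)
  H <- matrix(0, K, K)
  diag(H) <- eps[P[, 1L]] + eps[P[, 2L]] +
    ifelse(P[, 1L] == P[, 2L], basis$anharmonicity, 0)
  if (K > 1L) for (p in seq_len(K - 1L)) for (q in (p + 1L):K) {
    a <- P[p, ]; b <- P[q, ]
    shared <- intersect(a, b)
    # same-site pairs count their site twice when matching indices
    na <- c(a[1L], a[2L]); nb <- c(b[1L], b[2L])
    if (length(shared) != 1L) next
    s <- shared[1L]
    # sites left after removing one occurrence of the shared site
    ra <- na[-match(s, na)]
    rb <- nb[-match(s, nb)]
    if (length(ra) != 1L || length(rb) != 1L) next
    v <- Jblock[ra, rb]
    if (a[1L] == a[2L]) v <- v * sqrt(2)
    if (b[1L] == b[2L]) v <- v * sqrt(2)
    H[p, q] <- H[q, p] <- v
  }
  H
}

# static off-diagonal part of the two-exciton Hamiltonian (J-dependent only)
two_exciton_coupling_block <- function(Jblock, basis) {
  H <- two_exciton_hamiltonian(rep(0, basis$N), Jblock, basis)
  diag(H) <- 0
  H
}

#' Two-exciton propagator over a segment
#'
#' Default `method = "dense"` exponentiates the full instantaneous
#' two-exciton Hamiltonian each frame; `method = "trotter"` reuses the
#' precomputed static pair-coupling exponential with per-frame diagonal
#' phases (the off-diagonal part is static because J is).
#'
#' @inheritParams propagate_one
#' @param basis a [build_two_exciton_basis()] consistent with the segment
#' @return `exciton_propagator` over the pair basis
#' @export
propagate_two <- function(traj, J, seg, segment_id, basis, frame_start,
                          frame_end, method = c("dense", "trotter")) {
  method <- match.arg(method)
  check_frames(traj, frame_start, frame_end)
  sites <- segment_sites(seg, segment_id)
  if (basis$N != length(sites))
    stop_invalid("basis built for N = ", basis$N, " but segment has ",
                 length(sites), " sites")
  P <- basis$pairs
  K <- nrow(P)
  U <- diag(K) + 0i
  if (frame_end > frame_start) {
    eps <- traj$energies[, sites, drop = FALSE]
    Jb <- J[sites, sites, drop = FALSE]
    shift <- ifelse(P[, 1L] == P[, 2L], basis$anharmonicity, 0)
    if (method == "trotter") {
      EJ2 <- unitary_exp(two_exciton_coupling_block(Jb, basis), traj$dt)
      for (f in frame_start:(frame_end - 1L)) {
        pe <- eps[f, P[, 1L]] + eps[f, P[, 2L]] + shift
        d <- half_phases(pe, traj$dt)
        U <- (d * EJ2 * rep(d, each = K)) %*% U
      }
    } else {
      for (f in frame_start:(frame_end - 1L)) {
        H2 <- two_exciton_hamiltonian(eps[f, ], Jb, basis)
        U <- unitary_exp(H2, traj$dt) %*% U
      }
    }
  }
  new_propagator(U, frame_start, frame_end)
}

#' Transition dipoles between one- and two-exciton manifolds
#'
#' \eqn{\langle(mn)|\hat\mu|k\rangle = \mu_m \delta_{nk} + \mu_n \delta_{mk}}
#' for distinct-site pairs; same-site pairs (paper mode) couple as
#' \eqn{\sqrt2\,\mu_m \delta_{mk}}.
#'
#' @param dipoles N x 3 matrix of site dipole vectors (segment-local)
#' @param basis a [build_two_exciton_basis()]
#' @return K x N x 3 array; `[p, k, a]` is the Cartesian component `a` of
#'   the dipole connecting one-exciton state `k` to pair state `p`
#' @export
transition_dipole_ef <- function(dipoles, basis) {
  dipoles <- as.matrix(dipoles)
  if (nrow(dipoles) != basis$N || ncol(dipoles) != 3L)
    stop_invalid("`dipoles` must be an N x 3 matrix matching the basis")
  P <- basis$pairs
  K <- nrow(P)
  out <- array(0, dim = c(K, basis$N, 3L))
  for (p in seq_len(K)) {
    m <- P[p, 1L]; n <- P[p, 2L]
    if (m == n) {
      out[p, m, ] <- out[p, m, ] + sqrt(2) * dipoles[m, ]
    } else {
      out[p, n, ] <- out[p, n, ] + dipoles[m, ]
      out[p, m, ] <- out[p, m, ] + dipoles[n, ]
    }
  }
  out
}
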