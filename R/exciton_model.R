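# Segmented Frenkel-exciton system model: bath parameters, stochastic
# site-energy trajectories, couplings, dipoles, segmentation, and the
# fixture generators for the dimer and two-ring test systems.

#' Bath fluctuation parameters
#'
#' Overdamped-Brownian-oscillator (Ornstein-Uhlenbeck) bath acting on each
#' site energy, characterised by a fluctuation magnitude and a correlation
#' time.  The site-energy autocorrelation is
#' \eqn{C_m(t) = \sigma_m^2 \exp(-\Lambda_m t)}.
#'
#' @param sigma per-site root-mean-square fluctuation magnitude (cm^-1),
#'   all entries >= 0.
#' @param lambda_inv per-site correlation time \eqn{\Lambda_m^{-1}} (fs),
#'   all entries > 0.  Recycled against `sigma` if scalar.
#' @return object of class `bath_params`.
#' @export
bath_params <- function(sigma, lambda_inv) {
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop_invalid("`sigma` must be finite and >= 0")
  if (any(!is.finite(lambda_inv)) || any(lambda_inv <= 0))
    stop_invalid("`lambda_inv` must be finite and > 0")
  n <- max(length(sigma), length(lambda_inv))
  structure(list(sigma = rep_len(as.numeric(sigma), n),
                 lambda_inv = rep_len(as.numeric(lambda_inv), n)),
            class = "bath_params")
}

#' Site-to-segment assignment
#'
#' @param assignment integer vector mapping each site to a segment id;
#'   segment ids must cover `1:n_segments` with no empty segment.
#' @return object of class `segmentation` with elements `assignment`,
#'   `D` (per-segment site counts) and `N` (total sites).
#' @export
segmentation <- function(assignment) {
  assignment <- as.integer(assignment)
  if (length(assignment) < 1L || any(is.na(assignment)))
    stop_invalid("every site must be assigned to a segment")
  ids <- sort(unique(assignment))
  if (!identical(ids, seq_along(ids)))
    stop_invalid("segment ids must be consecutive integers starting at 1; ",
                 "missing: ", paste(setdiff(seq_len(max(ids)), ids), collapse = ", "))
  D <- tabulate(assignment, nbins = length(ids))
  structure(list(assignment = assignment, D = D, N = length(assignment)),
            class = "segmentation")
}

#' Sites belonging to one segment
#' @param seg a [segmentation()]
#' @param segment_id segment index
#' @return integer vector of site indices
#' @export
segment_sites <- function(seg, segment_id) {
  if (!segment_id %in% seq_along(seg$D))
    stop_invalid("unknown segment id: ", segment_id)
  which(seg$assignment == segment_id)
}

#' Validate a static coupling matrix
#'
#' @param J sites x sites symmetric matrix (cm^-1) with zero diagonal.
#' @return the matrix, with diagonal forced to exact zero.
#' @export
coupling_matrix <- function(J) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J) || any(!is.finite(J)))
    stop_invalid("`J` must be a finite square matrix")
  if (max(abs(J - t(J))) > 1e-9 * max(1, max(abs(J))))
    stop_invalid("`J` must be symmetric")
  diag(J) <- 0
  (J + t(J)) / 2
}

#' Assemble a segmented Frenkel-exciton system model
#'
#' @param means per-site mean excitation energies (cm^-1)
#' @param bath a [bath_params()]
#' @param J static coupling matrix (cm^-1), see [coupling_matrix()]
#' @param dipoles sites x 3 matrix of ground-to-excited transition dipole
#'   vectors (arbitrary consistent units)
#' @param seg a [segmentation()]
#' @param temperature temperature in kelvin, or `Inf` for the
#'   high-temperature (HT) limit
#' @return object of class `system_model`
#' @export
system_model <- function(means, bath, J, dipoles, seg, temperature = Inf) {
  N <- length(means)
  J <- coupling_matrix(J)
  dipoles <- as.matrix(dipoles)
  if (!inherits(bath, "bath_params")) stop_invalid("`bath` must be bath_params")
  if (!inherits(seg, "segmentation")) stop_invalid("`seg` must be a segmentation")
  if (length(bath$sigma) != N || nrow(J) != N || nrow(dipoles) != N ||
      seg$N != N || ncol(dipoles) != 3L)
    stop_invalid("inconsistent dimensions across system components")
  if (any(!is.finite(dipoles)))
    stop_invalid("dipole components must be finite")
  if (!is.infinite(temperature) && temperature <= 0)
    stop_invalid("`temperature` must be positive or Inf (HT limit)")
  structure(list(means = as.numeric(means), bath = bath, J = J,
                 dipoles = dipoles, seg = seg,
                 temperature = temperature, kB = cg_constants$kB),
            class = "system_model")
}

#' Generate a stochastic site-energy trajectory
#'
#' Each site's energy follows a stationary Gaussian Ornstein-Uhlenbeck
#' process with mean `means[m]`, variance `sigma[m]^2` and autocorrelation
#' `sigma[m]^2 * exp(-t/lambda_inv[m])`; sites are mutually independent.
#' The exact discrete update
#' \deqn{\epsilon(t+dt) = m + (\epsilon(t)-m) e^{-\Lambda dt}
#'       + \sigma \sqrt{1-e^{-2\Lambda dt}}\,\xi}
#' makes the sampled statistics independent of the time step.
#'
#' @param bath a [bath_params()]
#' @param means per-site mean energies (cm^-1)
#' @param n_frames number of frames (>= 1)
#' @param dt frame spacing (fs, > 0)
#' @param seed integer master seed; identical seeds give identical
#'   trajectories
#' @return object of class `site_trajectory`: list with `energies`
#'   (frames x sites), `dt` and `means`
#' @export
generate_ou_trajectory <- function(bath, means, n_frames, dt, seed) {
  check_scalar_positive(dt, "dt")
  if (!is.numeric(n_frames) || n_frames < 1)
    stop_invalid("`n_frames` must be >= 1")
  n_frames <- as.integer(n_frames)
  n <- length(means)
  if (length(bath$sigma) != n)
    stop_invalid("`means` length must match bath parameters")
  a <- exp(-dt / bath$lambda_inv)            # per-site decay factor
  b <- bath$sigma * sqrt(1 - a^2)            # innovation amplitude
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(as.integer(seed))
  dev <- matrix(0, n_frames, n)
  z0 <- stats::rnorm(n)
  dev[1L, ] <- bath$sigma * z0
  if (n_frames > 1L) {
    xi <- matrix(stats::rnorm((n_frames - 1L) * n), n_frames - 1L, n)
    for (m in seq_len(n)) {
      if (bath$sigma[m] == 0) next
      dev[-1L, m] <- stats::filter(b[m] * xi[, m], a[m],
                                   method = "recursive", init = dev[1L, m])
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  energies <- sweep(dev, 2L, as.numeric(means), "+")
  structure(list(energies = energies, dt = dt, means = as.numeric(means)),
            class = "site_trajectory")
}

#' Instantaneous Hamiltonian block of one segment
#'
#' Diagonal entries are the instantaneous site energies of the segment's
#' sites at the requested frame; off-diagonal entries are the static
#' couplings restricted to intra-segment pairs.
#'
#' @param traj a [generate_ou_trajectory()] result
#' @param J coupling matrix
#' @param seg a [segmentation()]
#' @param segment_id segment index
#' @param frame frame index (1-based)
#' @return real symmetric matrix (cm^-1)
#' @export
segment_hamiltonian <- function(traj, J, seg, segment_id, frame) {
  sites <- segment_sites(seg, segment_id)
  if (frame < 1L || frame > nrow(traj$energies))
    stop_invalid("frame out of range")
  H <- J[sites, sites, drop = FALSE]
  diag(H) <- traj$energies[frame, sites]
  H
}

#' Static coupling block between two segments
#'
#' @inheritParams segment_hamiltonian
#' @param segment_i,segment_j distinct segment indices
#' @return rectangular block of `J` (rows: sites of `segment_i`)
#' @export
intersegment_coupling <- function(J, seg, segment_i, segment_j) {
  if (segment_i == segment_j)
    stop_invalid("`segment_i` and `segment_j` must differ")
  si <- segment_sites(seg, segment_i)
  sj <- segment_sites(seg, segment_j)
  J[si, sj, drop = FALSE]
}

#' Dimer test system
#'
#' Two chromophores with mean energies 11500 and 12000 cm^-1, dynamic
#' disorder sigma = 198 cm^-1 and correlation time 220 fs on both sites,
#' and parallel unit transition dipoles (along x).  The single-segment
#' variant couples the sites at 100 cm^-1 and treats them as one coherent
#' segment; the double-segment variant reduces the coupling to 10 cm^-1
#' and treats each site as its own segment, so transfer between them is
#' incoherent.
#'
#' @param variant `"single_segment"` or `"double_segment"`
#' @param temperature kelvin, or `Inf` for the HT limit (default)
#' @return a [system_model()]
#' @export
make_dimer_fixture <- function(variant = c("single_segment", "double_segment"),
                               temperature = Inf) {
  variant <- match.arg(variant)
  means <- c(11500, 12000)
  bath <- bath_params(sigma = c(198, 198), lambda_inv = c(220, 220))
  dip <- rbind(c(1, 0, 0), c(1, 0, 0))
  if (variant == "single_segment") {
    J <- matrix(c(0, 100, 100, 0), 2, 2)
    seg <- segmentation(c(1L, 1L))
  } else {
    J <- matrix(c(0, 10, 10, 0), 2, 2)
    seg <- segmentation(c(1L, 2L))
  }
  system_model(means, bath, J, dip, seg, temperature)
}

#' LH2-like two-ring surrogate system
#'
#' Geometric surrogate for the LH2 antenna: an outer ring (B850-like,
#' default 18 sites) treated as one segment and an inner ring (B800-like,
#' default 9 sites) with each site its own segment.  Dipoles are tangential
#' to the rings.  Couplings follow the point dipole-dipole form and are
#' rescaled per ring so the largest outer-ring nearest-neighbour coupling
#' is `j_outer_nn` and the inner-ring one is `j_inner_nn`; inter-ring
#' couplings use the geometric mean of the two scales.  This surrogate is
#' synthetic: it is not the TrEsp Hamiltonian of the real complex.
#'
#' @param n_inner,n_outer ring site counts (>= 1)
#' @param r_inner,r_outer ring radii (arbitrary length units)
#' @param z_sep axial separation between ring planes
#' @param e_inner,e_outer mean site energies (cm^-1)
#' @param sigma_inner,sigma_outer bath fluctuation magnitudes (cm^-1)
#' @param lambda_inv bath correlation time (fs), shared by all sites
#' @param j_outer_nn,j_inner_nn target nearest-neighbour couplings (cm^-1)
#' @param temperature kelvin or `Inf`
#' @return a [system_model()]; sites ordered outer ring first, segment 1 is
#'   the outer ring, segments 2..(1+n_inner) are the inner sites
#' @export
make_two_ring_fixture <- function(n_inner = 9L, n_outer = 18L,
                                  r_inner = 31, r_outer = 25, z_sep = 17,
                                  e_inner = 12465, e_outer = 11955,
                                  sigma_inner = 169, sigma_outer = 256,
                                  lambda_inv = 150,
                                  j_outer_nn = 243, j_inner_nn = 30,
                                  temperature = Inf) {
  if (n_inner < 1L || n_outer < 1L) stop_invalid("ring counts must be >= 1")
  if (r_inner <= 0 || r_outer <= 0) stop_invalid("ring radii must be > 0")
  ring <- function(n, r, z, phase = 0) {
    th <- phase + 2 * pi * (seq_len(n) - 1L) / n
    list(pos = cbind(r * cos(th), r * sin(th), z),
         tan = cbind(-sin(th), cos(th), 0))
  }
  outer_ring <- ring(n_outer, r_outer, 0)
  inner_ring <- ring(n_inner, r_inner, z_sep, phase = pi / n_inner)
  pos <- rbind(outer_ring$pos, inner_ring$pos)
  dip <- rbind(outer_ring$tan, inner_ring$tan)
  N <- n_outer + n_inner
  Jraw <- matrix(0, N, N)
  for (a in seq_len(N - 1L)) for (b in (a + 1L):N) {
    r <- pos[b, ] - pos[a, ]
    d <- sqrt(sum(r^2))
    rh <- r / d
    Jraw[a, b] <- Jraw[b, a] <-
      (sum(dip[a, ] * dip[b, ]) - 3 * sum(dip[a, ] * rh) * sum(dip[b, ] * rh)) / d^3
  }
  idx_o <- seq_len(n_outer)
  idx_i <- n_outer + seq_len(n_inner)
  nn_max <- function(idx) {
    if (length(idx) < 2L) return(NA_real_)
    max(abs(Jraw[idx, idx]))
  }
  s_oo <- if (n_outer > 1L) j_outer_nn / nn_max(idx_o) else 1
  s_ii <- if (n_inner > 1L) j_inner_nn / nn_max(idx_i) else 1
  s_oi <- sqrt(abs(s_oo * s_ii))
  J <- Jraw
  J[idx_o, idx_o] <- Jraw[idx_o, idx_o] * s_oo
  J[idx_i, idx_i] <- Jraw[idx_i, idx_i] * s_ii
  J[idx_o, idx_i] <- Jraw[idx_o, idx_i] * s_oi
  J[idx_i, idx_o] <- Jraw[idx_i, idx_o] * s_oi
  means <- c(rep(e_outer, n_outer), rep(e_inner, n_inner))
  sig <- c(rep(sigma_outer, n_outer), rep(sigma_inner, n_inner))
  bath <- bath_params(sig, rep(lambda_inv, N))
  seg <- segmentation(c(rep(1L, n_outer), 1L + seq_len(n_inner)))
  system_model(means, bath, J, dip, seg, temperature)
}

#' Summarise coupling structure across a segmentation
#'
#' Reports, for every segment pair, the largest inter-segment coupling and
#' compares it with the largest intra-segment coupling of the two
#' segments, flagging pairs where the coarse-graining assumption of weak
#' inter-segment coupling is questionable.
#'
#' @param J coupling matrix
#' @param seg a [segmentation()]
#' @param flag_fraction pairs with inter-segment coupling exceeding this
#'   fraction of the intra-segment scale are flagged (default 0.5)
#' @return data.frame with one row per unordered segment pair
#' @export
segmentation_report <- function(J, seg, flag_fraction = 0.5) {
  S <- length(seg$D)
  intra <- vapply(seq_len(S), function(i) {
    s <- segment_sites(seg, i)
    if (length(s) < 2L) 0 else max(abs(J[s, s]))
  }, numeric(1))
  if (S < 2L)
    return(data.frame(segment_i = integer(), segment_j = integer(),
                      max_inter = numeric(), max_intra = numeric(),
                      ratio = numeric(), flagged = logical()))
  pairs <- utils::combn(S, 2L)
  rows <- apply(pairs, 2L, function(p) {
    blk <- intersegment_coupling(J, seg, p[1L], p[2L])
    mi <- max(abs(blk))
    scale <- max(intra[p])
    c(p, mi, scale, if (scale > 0) mi / scale else ifelse(mi > 0, Inf, 0))
  })
  out <- data.frame(segment_i = as.integer(rows[1L, ]),
                    segment_j = as.integer(rows[2L, ]),
                    max_inter = rows[3L, ], max_intra = rows[4L, ],
                    ratio = rows[5L, ])
  out$flagged <- out$ratio > flag_fraction
  out
}
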