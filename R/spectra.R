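# Assembly of the coarse-grained third-order response from doorway,
# transfer and window tables; isotropic orientational averaging; double
# Fourier transform to the (omega1, omega3) plane; cross-peak kinetics and
# pump-probe anisotropy.

#' Isotropic orientational weight tensor
#'
#' Weight factors connecting the four microscopic Cartesian dipole indices
#' with the lab-frame polarization sequence, for an isotropically oriented
#' sample.  The first index pair (alpha, beta) belongs to the doorway
#' (pump) interactions and the second pair (gamma, delta) to the window
#' (probe/emission) interactions:
#' \deqn{A^{\parallel} = (\delta_{\alpha\beta}\delta_{\gamma\delta}
#'  + \delta_{\alpha\gamma}\delta_{\beta\delta}
#'  + \delta_{\alpha\delta}\delta_{\beta\gamma})/15}
#' \deqn{A^{\perp} = (4\delta_{\alpha\beta}\delta_{\gamma\delta}
#'  - \delta_{\alpha\gamma}\delta_{\beta\delta}
#'  - \delta_{\alpha\delta}\delta_{\beta\gamma})/30}
#' Each scheme has exactly 21 nonzero components of the 81 possible.
#'
#' @param scheme `"parallel"` (all four lab polarizations equal) or
#'   `"perpendicular"` (probe pair rotated 90 degrees from the pump pair)
#' @return 3 x 3 x 3 x 3 numeric array
#' @export
orientational_weights <- function(scheme = c("parallel", "perpendicular")) {
  scheme <- match.arg(scheme)
  d <- diag(3)
  A <- array(0, dim = c(3, 3, 3, 3))
  for (a in 1:3) for (b in 1:3) for (cc in 1:3) for (dd in 1:3) {
    t1 <- d[a, b] * d[cc, dd]
    t2 <- d[a, cc] * d[b, dd]
    t3 <- d[a, dd] * d[b, cc]
    A[a, b, cc, dd] <- if (scheme == "parallel")
      (t1 + t2 + t3) / 15 else (4 * t1 - t2 - t3) / 30
  }
  A
}

# reshape the 81-tensor to the 9x9 matrix pairing (alpha,beta) rows with
# (gamma,delta) columns, matching the flattened dw_table layout
weights_as_matrix <- function(A) matrix(aperm(A, c(1, 2, 3, 4)), 9L, 9L)

flatten_dw <- function(tab) matrix(tab$values, dim(tab$values)[1L], 9L)

#' Assemble the coarse-grained response grid
#'
#' \deqn{R(t_1, t_3) = \sum_d \sum_{ij} \sum_{\alpha\beta\gamma\delta}
#'   A_{\alpha\beta\gamma\delta}\, W^d_{j,\gamma\delta}(t_3)\,
#'   T_{ji}(t_2)\, D_{i,\alpha\beta}(t_1)}
#' with the rephasing pathway using the conjugated doorway.  `gb_kernel`
#' selects whether the GB diagram is weighted by the transfer map (the
#' literal total-response expression) or by the identity (the ground-state
#' population cannot physically transfer).
#'
#' @param doorways list over segments of nonrephasing doorway `dw_table`s
#' @param windows list over segments; each element a list with components
#'   `GB`, `SE`, `EA` (`dw_table`s on the t3 grid)
#' @param transfer a [transfer_map()] (segments x segments)
#' @param weights orientational weight tensor from [orientational_weights()]
#' @param pathway `"nonrephasing"` or `"rephasing"`
#' @param gb_kernel `"eq17"` (transfer applied to GB) or `"identity"`
#' @return object of class `response_grid` with complex matrix `values`
#'   (`t1` rows, `t3` columns)
#' @export
assemble_response <- function(doorways, windows, transfer, weights,
                              pathway = c("nonrephasing", "rephasing"),
                              gb_kernel = c("eq17", "identity")) {
  pathway <- match.arg(pathway)
  gb_kernel <- match.arg(gb_kernel)
  S <- length(doorways)
  if (length(windows) != S || nrow(transfer) != S)
    stop_invalid("doorways, windows and transfer map disagree on the ",
                 "number of segments")
  nt1 <- length(doorways[[1L]]$times)
  nt3 <- length(windows[[1L]]$GB$times)
  A2 <- weights_as_matrix(weights)
  Tm <- unclass(transfer)
  Dm <- lapply(doorways, function(d) {
    M <- flatten_dw(d) %*% A2            # [nt1 x 9(gamma,delta)]
    if (pathway == "rephasing") Conj(M) else M
  })
  R <- matrix(0i, nt1, nt3)
  for (d in c("GB", "SE", "EA")) {
    Tk <- if (d == "GB" && gb_kernel == "identity") diag(S) else Tm
    for (j in seq_len(S)) {
      Wj <- flatten_dw(windows[[j]][[d]])
      if (nrow(Wj) != nt3) stop_invalid("window grids differ across segments")
      wsum <- Reduce(`+`, lapply(seq_len(S), function(i) Tk[j, i] * Dm[[i]]))
      R <- R + wsum %*% t(Wj)
    }
  }
  structure(list(values = R, pathway = pathway, gb_kernel = gb_kernel,
                 t2 = attr(transfer, "t2"),
                 dt1 = doorways[[1L]]$dt, dt3 = windows[[1L]]$GB$dt),
            class = "response_grid")
}

fft_dim <- function(M, dim, inverse = FALSE) {
  if (dim == 1L) apply(M, 2L, function(x) stats::fft(x, inverse = inverse))
  else t(apply(M, 1L, function(x) stats::fft(x, inverse = inverse)))
}

fft_axis_wn <- function(n, dt, ref) {
  k <- 0:(n - 1L)
  k[k >= n / 2] <- k[k >= n / 2] - n
  ref + k / (n * dt * cg_constants$c_cmfs)
}

#' Absorptive 2D spectrum from rephasing and nonrephasing response grids
#'
#' Both pathways are apodized (squared-cosine taper over the coherence
#' window, first time point half-weighted), demodulated at the carrier
#' frequency `ref_freq`, zero-padded and double-Fourier transformed.  The
#' rephasing pathway is transformed with the opposite omega1 sign so both
#' pathways share one positive frequency axis; the absorptive spectrum is
#' the real part of their sum.
#'
#' @param nonrephasing,rephasing `response_grid`s from [assemble_response()]
#' @param ref_freq carrier frequency (cm^-1) removed before the transform
#'   and added back to both axes
#' @param zero_pad integer padding factor (grid length multiplier)
#' @param apodize logical; apply the squared-cosine taper
#' @return object of class `spectrum2d`: `absorptive` (real matrix, omega1
#'   rows ascending), `omega1`, `omega3` (cm^-1), complex pathway spectra
#'   and normalization metadata
#' @export
spectrum_2d <- function(nonrephasing, rephasing, ref_freq,
                        zero_pad = 4L, apodize = TRUE) {
  if (!identical(dim(nonrephasing$values), dim(rephasing$values)))
    stop_invalid("pathway grids differ")
  nt1 <- nrow(nonrephasing$values); nt3 <- ncol(nonrephasing$values)
  dt1 <- nonrephasing$dt1; dt3 <- nonrephasing$dt3
  n1 <- as.integer(zero_pad) * nt1; n3 <- as.integer(zero_pad) * nt3
  w1 <- if (apodize) cos(pi * (0:(nt1 - 1L)) / (2 * nt1))^2 else rep(1, nt1)
  w3 <- if (apodize) cos(pi * (0:(nt3 - 1L)) / (2 * nt3))^2 else rep(1, nt3)
  w1[1L] <- w1[1L] / 2; w3[1L] <- w3[1L] / 2
  om0 <- wn_to_angfreq(ref_freq)
  t1 <- (0:(nt1 - 1L)) * dt1; t3 <- (0:(nt3 - 1L)) * dt3
  prep <- function(resp, sign1) {
    M <- resp$values * (w1 * exp(sign1 * 1i * om0 * t1))
    M <- M * rep(w3 * exp(1i * om0 * t3), each = nt1)
    P <- matrix(0i, n1, n3)
    P[seq_len(nt1), seq_len(nt3)] <- M
    P
  }
  # nonrephasing: e^{+i w1 t1}, e^{+i w3 t3}  (inverse FFT in both dims)
  Snr <- fft_dim(fft_dim(prep(nonrephasing, +1), 1L, inverse = TRUE),
                 2L, inverse = TRUE)
  # rephasing: e^{-i w1 t1}, e^{+i w3 t3}  (sign-flipped omega1)
  Sr <- fft_dim(fft_dim(prep(rephasing, -1), 1L, inverse = FALSE),
                2L, inverse = TRUE)
  ax1 <- fft_axis_wn(n1, dt1, ref_freq)
  ax3 <- fft_axis_wn(n3, dt3, ref_freq)
  o1 <- order(ax1); o3 <- order(ax3)
  absorptive <- Re(Snr + Sr)[o1, o3]
  structure(list(absorptive = absorptive,
                 nonrephasing = Snr[o1, o3], rephasing = Sr[o1, o3],
                 omega1 = ax1[o1], omega3 = ax3[o3],
                 ref_freq = ref_freq, zero_pad = as.integer(zero_pad),
                 apodize = apodize, t2 = nonrephasing$t2,
                 peak = max(abs(absorptive))),
            class = "spectrum2d")
}

#' Box-integrated intensity of a 2D spectrum
#'
#' @param spec a `spectrum2d`
#' @param w1_range,w3_range two-element ranges in cm^-1
#' @return sum of the absorptive signal over the box
#' @export
box_intensity <- function(spec, w1_range, w3_range) {
  i1 <- which(spec$omega1 >= min(w1_range) & spec$omega1 <= max(w1_range))
  i3 <- which(spec$omega3 >= min(w3_range) & spec$omega3 <= max(w3_range))
  if (length(i1) == 0L || length(i3) == 0L)
    stop_invalid("integration box outside the spectral axes")
  sum(spec$absorptive[i1, i3])
}

#' Cross-peak growth kinetics
#'
#' Integrates the absorptive signal over a spectral box for a sequence of
#' waiting times and fits the saturating exponential
#' \eqn{I(t_2) = A (1 - e^{-k t_2}) + C}.  The rate is found by profiling:
#' for each trial k, A and C follow by linear least squares; k minimises
#' the residual sum of squares (golden-section search on log k).
#'
#' @param spectra list of `spectrum2d` objects at increasing waiting times
#' @param t2_values waiting times (ps), aligned with `spectra`
#' @param w1_range,w3_range integration box (cm^-1)
#' @return list with `t2`, `intensity`, `k` (ps^-1), `A`, `C`, `fitted`,
#'   and `degenerate` (TRUE when the amplitude is indistinguishable from 0)
#' @export
cross_peak_kinetics <- function(spectra, t2_values, w1_range, w3_range) {
  if (length(spectra) < 3L) stop_invalid("need >= 3 waiting times")
  I <- vapply(spectra, box_intensity, numeric(1),
              w1_range = w1_range, w3_range = w3_range)
  fit <- fit_saturating_exponential(t2_values, I)
  c(list(t2 = t2_values, intensity = I), fit)
}

#' @rdname cross_peak_kinetics
#' @param t2 waiting times (ps)
#' @param I intensity series
#' @export
fit_saturating_exponential <- function(t2, I) {
  rss_of <- function(logk) {
    k <- exp(logk)
    X <- cbind(1, 1 - exp(-k * t2))
    co <- tryCatch(stats::lm.fit(X, I)$residuals, error = function(e) NULL)
    if (is.null(co)) return(Inf)
    sum(co^2)
  }
  span <- diff(range(t2[t2 > 0 | t2 == 0]))
  lo <- log(1e-3 / max(span, 1e-9)); hi <- log(1e3 / max(min(diff(sort(t2))), 1e-9))
  opt <- stats::optimize(rss_of, c(lo, hi), tol = 1e-10)
  k <- exp(opt$minimum)
  X <- cbind(1, 1 - exp(-k * t2))
  co <- stats::lm.fit(X, I)$coefficients
  fitted <- drop(X %*% co)
  scale <- max(abs(I), 1e-300)
  degenerate <- abs(co[2L]) < 1e-6 * scale
  list(k = if (degenerate) 0 else k, A = unname(co[2L]), C = unname(co[1L]),
       fitted = fitted, rss = opt$objective, degenerate = degenerate)
}

#' Pump-probe anisotropy
#'
#' \eqn{r(t_2) = (I_\parallel - I_\perp) / (I_\parallel + 2 I_\perp)}
#' elementwise over aligned waiting-time series.  A fixed isolated dipole
#' gives r = 0.4 at all waiting times; fully randomised dipole orientation
#' gives r = 0.
#'
#' @param I_parallel,I_perpendicular intensity series on the same t2 grid
#' @return anisotropy series; entries with (near-)zero denominator are NA
#' @export
anisotropy <- function(I_parallel, I_perpendicular) {
  if (length(I_parallel) != length(I_perpendicular))
    stop_invalid("intensity series must be aligned")
  den <- I_parallel + 2 * I_perpendicular
  r <- (I_parallel - I_perpendicular) / den
  r[abs(den) < 1e-12 * max(abs(c(I_parallel, I_perpendicular, 1)))] <- NA_real_
  r
}
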