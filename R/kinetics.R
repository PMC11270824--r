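# Segment-level kinetics: rate-matrix validation, detailed-balance thermal
# correction, equilibrium-population energy adjustment, transfer maps
# T(t2) = exp(K t2), stationary distributions and relaxation eigenmodes.
#
# Convention: K acts on column population vectors dp/dt = K p, entries in
# ps^-1, off-diagonals >= 0, every column sums to zero (the diagonal is
# the negative sum of the off-diagonal elements in its column).  K[j, i]
# is the rate of transfer from segment i to segment j.

#' Validate and normalise a rate matrix
#'
#' Recomputes the diagonal from the off-diagonal column sums and rejects
#' negative off-diagonal rates.
#'
#' @param K square matrix of rates (ps^-1); only off-diagonals are read
#' @param labels optional segment labels
#' @return object of class `rate_matrix` (a matrix with zero column sums)
#' @export
validate_rate_matrix <- function(K, labels = NULL) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K) || any(!is.finite(K)))
    stop_invalid("`K` must be a finite square matrix")
  off <- K; diag(off) <- 0
  if (any(off < 0))
    stop_invalid("off-diagonal rates must be >= 0")
  diag(off) <- -colSums(off)
  if (!is.null(labels)) dimnames(off) <- list(labels, labels)
  structure(off, class = c("rate_matrix", "matrix"))
}

#' Equilibrium-population energy adjustment
#'
#' \eqn{\Delta E_{S_j} = k_B T \ln(N P_{S_j} / D_{S_j})}: shifts the
#' segment energies used in the thermal correction so that the corrected
#' rates reproduce the target equilibrium populations P without changing
#' the effective pairwise rates.  When P is proportional to the site
#' counts (the HT-limit prediction) the adjustment vanishes.
#'
#' @param P target equilibrium populations (> 0, summing to 1)
#' @param D per-segment site counts
#' @param N total number of sites
#' @param temperature kelvin; `Inf` returns zeros (HT limit)
#' @return per-segment adjustment energies (cm^-1)
#' @export
delta_e <- function(P, D, N, temperature) {
  if (any(P <= 0)) stop_invalid("`P` must be strictly positive")
  if (any(D < 1)) stop_invalid("`D` must be >= 1")
  if (is.infinite(temperature)) return(rep(0, length(P)))
  cg_constants$kB * temperature * log(N * P / D)
}

#' Detailed-balance thermal correction of a rate matrix
#'
#' For every segment pair the corrected forward and backward rates keep
#' the raw pairwise sum \eqn{s = k_{ji} + k_{ij}} and satisfy Boltzmann
#' detailed balance in the (optionally \eqn{\Delta E}-adjusted) segment
#' energies:
#' \deqn{k_{j \leftarrow i} = \frac{s}{1 + e^{\beta (E_j - E_i)}}, \qquad
#'       k_{i \leftarrow j} = \frac{s}{1 + e^{-\beta (E_j - E_i)}}.}
#' In the HT limit both corrected rates equal s/2: uphill and downhill
#' transfer are equally probable.  Equal-energy pairs are unchanged at any
#' temperature when their raw rates are already symmetric.
#'
#' @param K_raw raw rate matrix (validated with [validate_rate_matrix()])
#' @param energies per-segment energies E_Sj (cm^-1), see [segment_energy()]
#' @param temperature kelvin or `Inf`
#' @param adjustment optional per-segment \eqn{\Delta E} (cm^-1), see
#'   [delta_e()]
#' @return corrected `rate_matrix`
#' @export
thermal_correction <- function(K_raw, energies, temperature,
                               adjustment = NULL) {
  K_raw <- validate_rate_matrix(K_raw)
  S <- nrow(K_raw)
  if (length(energies) != S)
    stop_invalid("`energies` must have one entry per segment")
  if (any(!is.finite(energies))) stop_invalid("segment energies missing")
  E <- energies + if (is.null(adjustment)) 0 else adjustment
  beta <- if (is.infinite(temperature)) 0 else 1 / (cg_constants$kB * temperature)
  out <- matrix(0, S, S)
  for (i in seq_len(S - 1L)) for (j in (i + 1L):S) {
    s <- K_raw[j, i] + K_raw[i, j]
    if (s == 0) next
    x <- beta * (E[j] - E[i])
    out[j, i] <- s / (1 + exp(x))     # i -> j
    out[i, j] <- s / (1 + exp(-x))    # j -> i
  }
  validate_rate_matrix(out, labels = rownames(K_raw))
}

# matrix exponential: eigendecomposition route with a scaling-and-squaring
# Taylor fallback for (near-)defective matrices
mat_exp <- function(A) {
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(ev)) {
    V <- ev$vectors
    cn <- tryCatch(kappa(V), error = function(e) Inf)
    if (is.finite(cn) && cn < 1e10) {
      E <- Re(V %*% (exp(ev$values) * solve(V)))
      return(E)
    }
  }
  # scaling and squaring with Taylor series
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-300, norm(A, "1")))))
  B <- A / 2^s
  E <- diag(n); term <- diag(n)
  for (k in 1:30) {
    term <- term %*% B / k
    E <- E + term
    if (max(abs(term)) < 1e-16) break
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

#' Transfer map over a waiting time
#'
#' \eqn{T(t_2) = e^{K t_2}}: `T[j, i]` is the probability that an
#' excitation that started equilibrated on segment i resides on segment j
#' after waiting time t2.  Column-stochastic for any valid K, with
#' `T(0) = I` and the semigroup property `T(a + b) = T(a) T(b)`.
#'
#' @param K a validated rate matrix (ps^-1)
#' @param t2 waiting time (ps, >= 0)
#' @return object of class `transfer_map` (column-stochastic matrix)
#' @export
transfer_map <- function(K, t2) {
  if (t2 < 0) stop_invalid("`t2` must be >= 0")
  K <- validate_rate_matrix(K)
  Tm <- mat_exp(unclass(K) * t2)
  Tm <- pmax(Tm, 0)
  Tm <- sweep(Tm, 2L, colSums(Tm), "/")
  structure(Tm, class = c("transfer_map", "matrix"), t2 = t2)
}

#' Stationary distribution of a rate matrix
#'
#' Null-space vector of K, normalised to a probability distribution.  For
#' a reducible K the distribution within each closed communicating class
#' is reported (null space dimension > 1 triggers a warning and the first
#' non-negative basis vector is returned).
#'
#' @param K a validated rate matrix
#' @return non-negative vector summing to 1 with `K %*% p = 0`
#' @export
stationary_distribution <- function(K) {
  K <- validate_rate_matrix(K)
  ev <- eigen(unclass(K))
  idx <- which(abs(ev$values) < 1e-8 * max(1, max(abs(ev$values))))
  if (length(idx) == 0L) idx <- which.min(abs(ev$values))
  if (length(idx) > 1L)
    warning("rate matrix is reducible; returning one stationary component")
  v <- Re(ev$vectors[, idx[1L]])
  if (sum(v) < 0) v <- -v
  v[v < 0 & v > -1e-12] <- 0
  v / sum(v)
}

#' Relaxation eigenmodes of a rate matrix
#'
#' Decay constants are the negated eigenvalues of K, sorted increasingly;
#' an irreducible K has exactly one zero mode (population conservation).
#' Each mode carries its eigenvector for identification, e.g. the
#' inter-ring mode of the LH2 fixture has a uniform sign on all B800
#' segments and the opposite sign on B850.
#'
#' @param K a validated rate matrix
#' @return list with `rates` (ps^-1, sorted) and `vectors` (columns
#'   aligned with `rates`)
#' @export
relaxation_eigenvalues <- function(K) {
  K <- validate_rate_matrix(K)
  ev <- eigen(unclass(K))
  rates <- -Re(ev$values)
  ord <- order(rates)
  rates <- rates[ord]
  rates[abs(rates) < 1e-12] <- 0
  list(rates = rates, vectors = Re(ev$vectors[, ord, drop = FALSE]))
}

#' LH2 segment rate-matrix fixture
#'
#' 10-segment rate matrix for the LH2 antenna: segment 1 is the B850 ring,
#' segments 2-10 are the nine individual B800 chromophores arranged on a
#' ring with nearest-neighbour transfer at 1.83 ps^-1 in each direction.
#' Each B800 segment transfers to B850 at 0.775 ps^-1 (HT) or 1.48 ps^-1
#' (RT); the back transfer from B850 to each B800 is 0.0431 ps^-1 (HT) or
#' 1.29e-3 ps^-1 (RT).  Diagonals follow the column-sum rule.
#'
#' @param regime `"HT"` or `"RT"`
#' @return a `rate_matrix` with labels `B850`, `B800_1` ... `B800_9`
#' @export
build_lh2_rate_fixture <- function(regime = c("HT", "RT")) {
  regime <- match.arg(regime)
  fw <- if (regime == "HT") 0.775 else 1.48       # B800 -> B850
  bw <- if (regime == "HT") 0.0431 else 1.29e-3   # B850 -> B800
  nn <- 1.83                                      # B800 ring neighbours
  S <- 10L
  K <- matrix(0, S, S)
  b800 <- 2:10
  K[1L, b800] <- fw
  K[b800, 1L] <- bw
  for (a in seq_len(9L)) {
    nxt <- if (a == 9L) 1L else a + 1L
    K[1L + a, 1L + nxt] <- K[1L + a, 1L + nxt] + nn
    K[1L + nxt, 1L + a] <- K[1L + nxt, 1L + a] + nn
  }
  validate_rate_matrix(K, labels = c("B850", paste0("B800_", 1:9)))
}

#' Double-segment dimer rate-matrix fixture
#'
#' Phenomenological 2x2 rate matrix for the weakly coupled dimer (two
#' single-site segments 500 cm^-1 apart).  In the HT regime forward and
#' backward rates are equal at `k0`; the RT regime applies the
#' detailed-balance thermal correction at 300 K and the 500 cm^-1 mean
#' energy gap, preserving the pairwise sum.
#'
#' @param regime `"HT"` or `"RT"`
#' @param k0 HT-limit rate in each direction (ps^-1)
#' @param gap segment energy gap (cm^-1)
#' @param temperature RT temperature (K)
#' @return a `rate_matrix`; segment 1 is the low-energy site
#' @export
build_dimer_rate_fixture <- function(regime = c("HT", "RT"), k0 = 0.05,
                                     gap = 500, temperature = 300) {
  regime <- match.arg(regime)
  K <- validate_rate_matrix(matrix(c(0, k0, k0, 0), 2L, 2L),
                            labels = c("low", "high"))
  if (regime == "HT") return(K)
  thermal_correction(K, energies = c(0, gap), temperature = temperature)
}

#' Read a rate matrix from a whitespace-delimited text file
#'
#' Format: one header row of segment labels, then the square matrix in
#' ps^-1 (column convention: entry j,i is transfer from i to j).  Lines
#' starting with `#` are comments.
#'
#' @param path file path
#' @return a validated `rate_matrix`
#' @export
read_rate_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  labels <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  vals <- lapply(lines[-1L], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
  K <- do.call(rbind, vals)
  if (nrow(K) != length(labels) || ncol(K) != length(labels))
    stop_invalid("rate-matrix file `", path, "`: matrix is ", nrow(K), "x",
                 ncol(K), " but header names ", length(labels), " segments")
  validate_rate_matrix(K, labels = labels)
}

#' Write a rate matrix to a whitespace-delimited text file
#' @param K a `rate_matrix`
#' @param path file path
#' @export
write_rate_matrix <- function(K, path) {
  labels <- rownames(K)
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(K)))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# segment rate matrix, ps^-1, columns sum to zero",
               paste(labels, collapse = " ")), con)
  utils::write.table(format(unclass(K), digits = 12), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
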