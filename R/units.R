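#' Physical constants and unit conventions
#'
#' All energies and couplings are wavenumbers (cm^-1), times are
#' femtoseconds for propagation and picoseconds for kinetics, rates are
#' ps^-1.  Phase accumulation converts wavenumbers to angular frequency
#' through 2*pi*c with the speed of light in cm/fs, so that a site with
#' energy e (cm^-1) acquires phase exp(-1i * 2*pi*c * e * t) over t fs.
#'
#' @format `cg_constants` is a list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, 0.695035 cm^-1/K.}
#'   \item{c_cmfs}{Speed of light, 2.9979e-5 cm/fs.}
#'   \item{twopic}{2*pi*c_cmfs, the cm^-1 to rad/fs conversion.}
#' }
#' @export
cg_constants <- list(
  kB     = 0.695035,
  c_cmfs = 2.9979e-5,
  twopic = 2 * pi * 2.9979e-5
)

#' Convert wavenumber to angular frequency
#'
#' @param wn energy in cm^-1
#' @return angular frequency in rad/fs
#' @keywords internal
wn_to_angfreq <- function(wn) cg_constants$twopic * wn

# shared argument checks -----------------------------------------------------

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("`", name, "` must be a single positive finite number")
  invisible(x)
}
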