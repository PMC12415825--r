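## Internal unit system: length Angstrom, time ps, charge e, energy eV.
## Dipoles are e*Angstrom; electric fields V/Angstrom (so mu*E is in eV).
## User-facing frequencies are linear (GHz); internally angular (rad/ps).

#' Physical constants used by chainrelax
#'
#' Constants in the package's internal unit system (Angstrom, ps, e, eV):
#' `kB` is Boltzmann's constant in eV/K and `eps0` the vacuum permittivity
#' in e V^-1 Angstrom^-1, so that a susceptibility
#' \eqn{\chi = \langle \delta M^2\rangle / (3 \epsilon_0 V k_B T)} built from a
#' box dipole in e*Angstrom, a volume in Angstrom^3 and a temperature in K is
#' dimensionless.
#'
#' @format A named list with elements `kB` (eV/K) and `eps0` (e/(V*Angstrom)).
#' @export
cr_constants <- list(
  kB   = 8.617333262e-5,     # eV / K
  eps0 = 5.526349406e-3      # e / (V * Angstrom)  [= e^2 eV^-1 Angstrom^-1]
)

#' Convert a linear frequency in GHz to an angular frequency in rad/ps
#'
#' 1 ps^-1 corresponds to 1000 GHz, so \eqn{\omega = 2\pi f_{GHz} 10^{-3}}
#' rad/ps.
#'
#' @param f_GHz numeric vector of linear frequencies in GHz.
#' @return angular frequencies in rad/ps.
#' @seealso [radps_to_ghz()]
#' @export
#' @examples
#' ghz_to_radps(0.5)   # 2*pi*5e-4
ghz_to_radps <- function(f_GHz) 2 * pi * f_GHz * 1e-3

#' Convert an angular frequency in rad/ps to a linear frequency in GHz
#'
#' @param omega numeric vector of angular frequencies in rad/ps.
#' @return linear frequencies in GHz.
#' @export
radps_to_ghz <- function(omega) omega / (2 * pi) * 1e3
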