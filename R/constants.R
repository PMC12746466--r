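## Physical constants in the package's working units.
## All energies are wavenumbers (cm^-1); k_B T is therefore a wavenumber.

## Boltzmann constant, cm^-1 per Kelvin.
.kB <- 0.695034800

## Speed of light in cm/fs, used to make nu[cm^-1] * dt[fs] dimensionless
## (linear frequency c*nu_tilde per fs).
.c_cm_fs <- 2.99792458e-5

## 1 eV in cm^-1; the default total-energy range for multicanonical runs.
.eV_cm <- 8065.543937

#' Thermal energy in wavenumbers
#'
#' Convenience helper returning \eqn{k_B T} in cm\eqn{^{-1}} for a
#' temperature in Kelvin (\eqn{k_B} = 0.695034800 cm\eqn{^{-1}}/K).
#'
#' @param temperature temperature in K.
#' @return \eqn{k_B T} in cm\eqn{^{-1}}.
#' @examples
#' kBT(300)  # ~208.5 cm^-1
#' @export
kBT <- function(temperature) {
  stopifnot(is.numeric(temperature), all(temperature >= 0))
  .kB * temperature
}
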