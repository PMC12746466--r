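## Dunham-expansion energetics.
##
## E(n) = sum_i nu_i (n_i + 1/2) + sum_{i<=j} X_ij (n_i + 1/2)(n_j + 1/2)
## with nu_i the scaled frequencies. All public functions work with the
## energy relative to the zero-point configuration, E_rel(n) = E(n) - E(0).

## sum_{i<=j} X_ij h_i h_j for symmetric X, with h = n + 1/2.
.dunhamQuad <- function(X, h) {
  0.5 * (sum(h * (X %*% h)) + sum(diag(X) * h * h))
}

#' Total vibrational energy of an occupation configuration
#'
#' Evaluates the Dunham expansion at the given occupation numbers and
#' returns the energy relative to the zero-point (all-zero) configuration,
#' in cm\eqn{^{-1}}. `totalEnergy(system, rep(0, N))` is exactly 0.
#'
#' @param system a [VibrationalSystem-class].
#' @param config vector of non-negative integer occupation numbers, one
#'   per mode.
#' @return energy above the zero point, in cm\eqn{^{-1}}.
#' @examples
#' sys <- vibrationalSystem(1000, xMatrix = matrix(-10, 1, 1))
#' totalEnergy(sys, 1)  # 1000 - 10*((3/2)^2 - (1/2)^2) = 980
#' @export
totalEnergy <- function(system, config) {
  .checkConfig(system, config)
  nu <- scaledFrequencies(system)
  X <- system@xMatrix
  h <- config + 0.5
  h0 <- rep(0.5, length(config))
  sum(nu * config) + .dunhamQuad(X, h) - .dunhamQuad(X, h0)
}

## Vectorized fundamental transition energies from configuration n:
## f_i = E_rel(n + e_i) - E_rel(n)
##     = nu_i + 2 X_ii (n_i + 1) + sum_{j != i} X_ij (n_j + 1/2),
## an algebraic identity with direct differencing of the Dunham expansion.
.fundamentalEnergies <- function(nu, X, dX, n) {
  h <- n + 0.5
  nu + 2 * dX * (n + 1) + drop(X %*% h) - dX * h
}

## Overtone and combination energies follow from the same f vector:
##   overtone_i   = 2 f_i + 2 X_ii
##   combination_ij = f_i + f_j + X_ij    (i != j)
.overtoneEnergies <- function(f, dX) 2 * f + 2 * dX

.combinationEnergy <- function(f, X, i, j) f[i] + f[j] + X[i, j]

#' Occupation-dependent transition energy
#'
#' Returns the transition energy for exciting the given band out of the
#' configuration `config`, computed by direct differencing of the Dunham
#' expansion: \eqn{\Delta E = E_{rel}(n') - E_{rel}(n)} where \eqn{n'}
#' increments \eqn{n_i} by 1 (fundamental), by 2 (first overtone), or
#' \eqn{n_i} and \eqn{n_j} each by 1 (1+1 combination). The result may be
#' negative for strongly anharmonic, highly excited configurations.
#'
#' Differencing is self-consistent with [totalEnergy()] for all three band
#' kinds, which is why it is used instead of a separate closed form per
#' band (the closed forms are recovered as algebraic identities and are
#' exercised in the unit tests).
#'
#' @inheritParams totalEnergy
#' @param kind one of `"fundamental"`, `"overtone"`, `"combination"`.
#' @param modes one mode index (fundamental/overtone) or two distinct
#'   indices (combination).
#' @return transition energy in cm\eqn{^{-1}}.
#' @examples
#' sys <- vibrationalSystem(1000, xMatrix = matrix(-10, 1, 1))
#' transitionEnergy(sys, 0, "fundamental", 1)  # 980
#' transitionEnergy(sys, 0, "overtone", 1)     # 1940
#' @export
transitionEnergy <- function(system, config,
                             kind = c("fundamental", "overtone",
                                      "combination"),
                             modes) {
  .checkConfig(system, config)
  kind <- match.arg(kind)
  N <- nModes(system)
  modes <- as.integer(modes)
  if (any(modes < 1L | modes > N)) stop("mode index out of range")
  nprime <- config
  if (kind == "fundamental") {
    if (length(modes) != 1L) stop("fundamental takes a single mode index")
    nprime[modes] <- nprime[modes] + 1L
  } else if (kind == "overtone") {
    if (length(modes) != 1L) stop("overtone takes a single mode index")
    nprime[modes] <- nprime[modes] + 2L
  } else {
    if (length(modes) != 2L || modes[1] == modes[2])
      stop("combination takes two distinct mode indices")
    nprime[modes] <- nprime[modes] + 1L
  }
  totalEnergy(system, nprime) - totalEnergy(system, config)
}

## Transition energies from the global all-zero configuration; the
## denominators of the intensity scaling rule.
.zeroTransitionEnergies <- function(system) {
  nu <- scaledFrequencies(system)
  X <- system@xMatrix
  dX <- diag(X)
  n0 <- rep(0, length(nu))
  f0 <- .fundamentalEnergies(nu, X, dX, n0)
  list(fund = f0,
       overtone = .overtoneEnergies(f0, dX),
       comb = outer(f0, f0, "+") + X)
}

#' Occupation-dependent IR line intensity
#'
#' Intensity of a band excited out of configuration `config`, following
#' the harmonic-oscillator occupancy scaling together with the ratio of
#' the occupation-dependent transition energy to the transition energy
#' from the global all-zero configuration (\eqn{\Delta E^0}):
#' \deqn{I_i = I_i^0 (n_i + 1) \,\Delta E / \Delta E^0}
#' for a fundamental; first overtones scale as
#' \eqn{(n_i+1)(n_i+2)/2} and 1+1 combinations as
#' \eqn{(n_i+1)(n_j+1)}, each times their own \eqn{\Delta E/\Delta E^0}.
#' Transitions with non-positive \eqn{\Delta E} (or non-positive
#' \eqn{\Delta E^0}) are assigned zero intensity. The occupancy factors
#' are strictly valid only for the harmonic oscillator and can be turned
#' off with `occupancyScaling = FALSE`.
#'
#' @inheritParams transitionEnergy
#' @param occupancyScaling logical; apply the harmonic occupancy factors
#'   (default `TRUE`).
#' @return a non-negative intensity in the units of the base intensities.
#' @examples
#' sys <- vibrationalSystem(1000, xMatrix = matrix(-10, 1, 1),
#'                          fundIntensities = 1)
#' lineIntensity(sys, 1, "fundamental", 1)  # 2 * 960/980
#' @export
lineIntensity <- function(system, config,
                          kind = c("fundamental", "overtone",
                                   "combination"),
                          modes, occupancyScaling = TRUE) {
  kind <- match.arg(kind)
  dE <- transitionEnergy(system, config, kind, modes)
  z <- .zeroTransitionEnergies(system)
  if (kind == "fundamental") {
    dE0 <- z$fund[modes]
    base <- system@fundIntensities[modes]
    occ <- config[modes] + 1
  } else if (kind == "overtone") {
    dE0 <- z$overtone[modes]
    base <- system@overtoneIntensities[modes]
    occ <- (config[modes] + 1) * (config[modes] + 2) / 2
  } else {
    dE0 <- z$comb[modes[1], modes[2]]
    base <- system@combIntensities[modes[1], modes[2]]
    occ <- (config[modes[1]] + 1) * (config[modes[2]] + 1)
  }
  if (dE <= 0 || dE0 <= 0) return(0)
  if (!occupancyScaling) occ <- 1
  base * occ * (dE / dE0)
}
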