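## Stick spectra and Gaussian convolution.

## Precomputed invariants for repeated stick-spectrum evaluation of one
## system (used heavily by the multicanonical and kinetic Monte Carlo
## drivers). Combination pairs are restricted to those with a non-zero
## base intensity.
.linePre <- function(system) {
  nu <- scaledFrequencies(system)
  X <- system@xMatrix
  dX <- diag(X)
  N <- length(nu)
  z <- .zeroTransitionEnergies(system)
  pairs <- which(upper.tri(X), arr.ind = TRUE)
  keep <- system@combIntensities[pairs] > 0
  pairs <- pairs[keep, , drop = FALSE]
  list(
    N = N, nu = nu, X = X, dX = dX,
    i0f = system@fundIntensities,
    i0o = system@overtoneIntensities,
    i0c = system@combIntensities[pairs],
    pairI = pairs[, 1], pairJ = pairs[, 2],
    xPair = X[pairs],
    dE0f = z$fund, dE0o = z$overtone, dE0c = z$comb[pairs]
  )
}

## All candidate lines for configuration n given precompute `pre` and the
## fundamental-energy vector f (from .fundamentalEnergies). Returns
## position/intensity/kind/mode indices; zero/negative-energy lines carry
## intensity 0 here and are filtered by the callers.
.allLines <- function(pre, n, f, occupancyScaling = TRUE) {
  posF <- f
  occF <- if (occupancyScaling) n + 1 else rep(1, pre$N)
  intF <- ifelse(posF > 0 & pre$dE0f > 0,
                 pre$i0f * occF * posF / pre$dE0f, 0)

  posO <- 2 * f + 2 * pre$dX
  occO <- if (occupancyScaling) (n + 1) * (n + 2) / 2 else rep(1, pre$N)
  intO <- ifelse(posO > 0 & pre$dE0o > 0,
                 pre$i0o * occO * posO / pre$dE0o, 0)

  if (length(pre$pairI)) {
    posC <- f[pre$pairI] + f[pre$pairJ] + pre$xPair
    occC <- if (occupancyScaling) (n[pre$pairI] + 1) * (n[pre$pairJ] + 1)
            else rep(1, length(pre$pairI))
    intC <- ifelse(posC > 0 & pre$dE0c > 0,
                   pre$i0c * occC * posC / pre$dE0c, 0)
  } else {
    posC <- numeric(0); intC <- numeric(0)
  }

  list(
    position = c(posF, posO, posC),
    intensity = c(intF, intO, intC),
    kind = rep(c("fundamental", "overtone", "combination"),
               c(pre$N, pre$N, length(posC))),
    mode_i = c(seq_len(pre$N), seq_len(pre$N), pre$pairI),
    mode_j = c(rep(NA_integer_, 2L * pre$N), pre$pairJ)
  )
}

#' Stick spectrum of an occupation configuration
#'
#' Enumerates all fundamentals, first overtones and 1+1 combination bands
#' whose transition energy falls inside the window, with intensities from
#' [lineIntensity()]. Zero-intensity lines (including all transitions with
#' non-positive energy, and overtone/combination bands whose base
#' intensities are zero) are omitted.
#'
#' @inheritParams totalEnergy
#' @param window numeric length-2, wavenumber window `c(lo, hi)` in
#'   cm\eqn{^{-1}} (default the whole axis).
#' @param occupancyScaling logical, see [lineIntensity()].
#' @return a data frame with columns `position` (cm\eqn{^{-1}}),
#'   `intensity`, `kind` (fundamental/overtone/combination), `mode_i`,
#'   `mode_j` (`NA` except for combinations).
#' @examples
#' sys <- vibrationalSystem(c(1000, 1500))
#' stickSpectrum(sys, c(0, 0), window = c(900, 1100))
#' @export
stickSpectrum <- function(system, config, window = c(-Inf, Inf),
                          occupancyScaling = TRUE) {
  .checkConfig(system, config)
  if (length(window) != 2L || window[1] >= window[2])
    stop("window must be c(lo, hi) with lo < hi")
  pre <- .linePre(system)
  f <- .fundamentalEnergies(pre$nu, pre$X, pre$dX, config)
  ln <- .allLines(pre, config, f, occupancyScaling)
  keep <- ln$intensity > 0 & ln$position >= window[1] &
    ln$position <= window[2]
  data.frame(
    position = ln$position[keep],
    intensity = ln$intensity[keep],
    kind = ln$kind[keep],
    mode_i = ln$mode_i[keep],
    mode_j = ln$mode_j[keep]
  )
}

## Accumulate line intensities onto a binned wavenumber axis
## (half-open bins [lo + (k-1)*bw, lo + k*bw), nearest-bin assignment of
## stick positions). Returns a length-nb intensity vector.
.binLines <- function(position, intensity, lo, bw, nb) {
  out <- numeric(nb)
  idx <- floor((position - lo) / bw) + 1
  keep <- idx >= 1 & idx <= nb & intensity > 0
  if (any(keep)) {
    acc <- rowsum(intensity[keep], idx[keep])
    out[as.integer(rownames(acc))] <- acc[, 1]
  }
  out
}

## Binned stick spectrum of one configuration; the hot-loop variant.
.stickRow <- function(pre, n, lo, bw, nb, occupancyScaling = TRUE) {
  f <- .fundamentalEnergies(pre$nu, pre$X, pre$dX, n)
  ln <- .allLines(pre, n, f, occupancyScaling)
  .binLines(ln$position, ln$intensity, lo, bw, nb)
}

#' Gaussian convolution of a stick spectrum
#'
#' Sums area-preserving Gaussians (unit-area density times line intensity)
#' centred at the line positions, evaluated on the grid. The numerically
#' integrated area of a fully covered line equals its stick intensity.
#'
#' @param lines a data frame with columns `position` and `intensity`
#'   (e.g. from [stickSpectrum()]), or a [Spectrum-class] whose binned
#'   values are treated as stick areas at the bin positions.
#' @param grid increasing wavenumber grid on which to evaluate.
#' @param fwhm full width at half maximum of the Gaussian, cm\eqn{^{-1}}
#'   (a typical presentation choice is 5 cm\eqn{^{-1}}).
#' @return a [Spectrum-class] on `grid` (intensity per cm\eqn{^{-1}}).
#' @examples
#' sticks <- data.frame(position = 1000, intensity = 2)
#' sp <- convolveSpectrum(sticks, seq(950, 1050, 0.5), fwhm = 5)
#' @export
convolveSpectrum <- function(lines, grid, fwhm) {
  if (length(grid) < 1L) stop("grid must be non-empty")
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (!is.numeric(fwhm) || fwhm <= 0) stop("fwhm must be positive")
  if (is(lines, "Spectrum"))
    lines <- data.frame(position = lines@grid, intensity = lines@values)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  values <- numeric(length(grid))
  keep <- lines$intensity != 0
  pos <- lines$position[keep]
  wt <- lines$intensity[keep]
  for (k in seq_along(pos))
    values <- values + wt[k] * dnorm(grid, mean = pos[k], sd = sigma)
  Spectrum(grid, values)
}
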