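#' DensityOfStates: binned vibrational state counts
#'
#' Counts of vibrational occupation configurations per energy bin, with
#' half-open bins \eqn{[b w, (b+1) w)} measured relative to the zero-point
#' energy. Bin 1 therefore always contains the ground configuration.
#'
#' @slot binWidth bin width \eqn{w} in cm\eqn{^{-1}}.
#' @slot counts numeric vector of non-negative state counts per bin
#'   (stored as doubles; counts grow combinatorially).
#' @name DensityOfStates-class
#' @aliases DensityOfStates
#' @exportClass DensityOfStates
setClass("DensityOfStates",
  representation(binWidth = "numeric", counts = "numeric")
)

setValidity("DensityOfStates", function(object) {
  msg <- character()
  if (length(object@binWidth) != 1L || object@binWidth <= 0)
    msg <- c(msg, "binWidth must be a positive scalar")
  if (length(object@counts) < 1L || any(object@counts < 0) ||
      any(!is.finite(object@counts)))
    msg <- c(msg, "counts must be non-negative and finite")
  if (length(object@counts) >= 1L && object@counts[1] < 1)
    msg <- c(msg, "bin 1 must contain the ground state")
  if (length(msg)) msg else TRUE
})

#' @describeIn DensityOfStates-class per-bin counts.
#' @param object a `DensityOfStates`.
#' @export
stateCounts <- function(object) object@counts

#' @describeIn DensityOfStates-class the bin width (cm\eqn{^{-1}}).
#' @export
binWidth <- function(object) object@binWidth

#' @describeIn DensityOfStates-class bin centre energies (cm\eqn{^{-1}}).
#' @export
binCenters <- function(object) {
  (seq_along(object@counts) - 0.5) * object@binWidth
}

setMethod("show", "DensityOfStates", function(object) {
  cat(sprintf(
    "DensityOfStates: %d bins of %g cm-1 (to %g cm-1), %.4g states total\n",
    length(object@counts), object@binWidth,
    length(object@counts) * object@binWidth, sum(object@counts)))
  invisible(object)
})

#' Single-mode anharmonic level ladder
#'
#' Level energies \eqn{\epsilon(n) = \nu n + X_{ii}(n^2 + n)} of one mode
#' (relative to its own zero point, so \eqn{\epsilon(0) = 0}), truncated
#' at `eMax` and at the anharmonic turnover: the ladder stops at the last
#' level for which the energy is still strictly increasing, since beyond
#' the turnover the bound-state picture of the Dunham expansion is
#' invalid.
#'
#' @inheritParams totalEnergy
#' @param mode mode index.
#' @param eMax maximum level energy to include, cm\eqn{^{-1}}.
#' @return numeric vector of level energies starting at 0.
#' @examples
#' sys <- vibrationalSystem(1000, xMatrix = matrix(-10, 1, 1))
#' modeLevels(sys, 1, 3000)  # 0 980 1940 2880
#' @export
modeLevels <- function(system, mode, eMax) {
  stopifnot(eMax > 0)
  nu <- scaledFrequencies(system)[mode]
  xii <- system@xMatrix[mode, mode]
  levels <- 0
  n <- 0
  repeat {
    n <- n + 1
    e <- nu * n + xii * (n^2 + n)
    if (e <= levels[length(levels)] || e > eMax) break
    levels <- c(levels, e)
  }
  levels
}

## Exact route: convolve the per-mode ladders keeping the exact total
## energies, binning only at the end. Cost is the number of states; bails
## out (returns NULL) when the running state count exceeds `cap`.
.countExact <- function(ladders, eMax, binWidth, cap) {
  energies <- 0
  for (lad in ladders) {
    energies <- as.vector(outer(energies, lad, "+"))
    energies <- energies[energies < eMax]
    if (length(energies) > cap) return(NULL)
  }
  nb <- ceiling(eMax / binWidth)
  counts <- numeric(nb)
  idx <- floor(energies / binWidth) + 1
  idx[idx > nb] <- nb  # guard energies within rounding of eMax
  tab <- table(idx)
  counts[as.integer(names(tab))] <- as.numeric(tab)
  counts
}

## Grained route: classic direct-count array convolution. Level energies
## are rounded to an integer number of `grain` units; counts accumulated by
## shift-and-add, then aggregated to the requested bin width.
.countGrained <- function(ladders, eMax, binWidth, grain) {
  sub <- max(1L, round(binWidth / grain))
  grain <- binWidth / sub
  nb <- ceiling(eMax / binWidth)
  nf <- nb * sub
  counts <- numeric(nf)
  counts[1] <- 1
  for (lad in ladders) {
    offs <- round(lad / grain)
    offs <- offs[offs > 0 & offs < nf]
    new <- counts
    for (o in offs)
      new[(o + 1):nf] <- new[(o + 1):nf] + counts[1:(nf - o)]
    counts <- new
  }
  colSums(matrix(counts, nrow = sub))
}

#' Exact state counting for separable anharmonic oscillators
#'
#' Counts the occupation configurations whose energy above the zero point
#' falls in each bin, treating the vibrations as separable anharmonic
#' oscillators (off-diagonal X ignored, as is standard for direct
#' state-counting densities). Per-mode ladders come from [modeLevels()]
#' (anharmonic-turnover truncated).
#'
#' Two routes are provided. The `"exact"` route convolves the exact
#' real-valued level energies mode by mode and bins only the final totals;
#' it is an exact direct count at any bin width, but its cost is the number
#' of states, so it is guarded by `maxExactStates`. The `"grained"` route
#' is the classic direct-count array convolution: level energies are
#' rounded to a fine grain (default 1 cm\eqn{^{-1}}) and counts accumulated
#' by shift-and-add, then aggregated to `binWidth`; it handles arbitrarily
#' large systems at the cost of grain-level rounding in bin assignment.
#' `method = "auto"` (default) tries the exact route and falls back to the
#' grained one.
#'
#' @inheritParams totalEnergy
#' @param eMax upper energy bound, cm\eqn{^{-1}}.
#' @param binWidth energy bin width, cm\eqn{^{-1}} (default 16).
#' @param method `"auto"`, `"exact"` or `"grained"`.
#' @param grain grain of the array method, cm\eqn{^{-1}} (default 1).
#' @param maxExactStates state-count cap for the exact route.
#' @return a [DensityOfStates-class].
#' @examples
#' sys <- vibrationalSystem(100)
#' stateCounts(countStates(sys, eMax = 550, binWidth = 100))  # 1 per bin
#' @export
countStates <- function(system, eMax, binWidth = 16,
                        method = c("auto", "exact", "grained"),
                        grain = 1, maxExactStates = 5e6) {
  stopifnot(eMax > 0, binWidth > 0)
  method <- match.arg(method)
  ## use the full binned range so partially covered top bins are complete
  eTop <- ceiling(eMax / binWidth) * binWidth
  ladders <- lapply(seq_len(nModes(system)), function(m)
    modeLevels(system, m, eTop))
  counts <- NULL
  if (method %in% c("auto", "exact")) {
    counts <- .countExact(ladders, eTop, binWidth, maxExactStates)
    if (is.null(counts) && method == "exact")
      stop("exact state count exceeds maxExactStates = ", maxExactStates,
           "; use method = \"grained\"")
  }
  if (is.null(counts))
    counts <- .countGrained(ladders, eTop, binWidth, grain)
  new("DensityOfStates", binWidth = binWidth, counts = counts)
}

#' Brute-force enumeration of occupation configurations
#'
#' Exhaustively enumerates configurations with `totalEnergy` (full X,
#' including off-diagonal couplings) below `eMax`. Candidate per-mode
#' occupations are bounded by the diagonal-only ladder at `eMax + slack`;
#' a positive `slack` widens the candidate set when negative off-diagonal
#' couplings can pull the full-X energy of larger configurations below
#' `eMax`. Intended as a test oracle for small systems; refuses to run
#' when the candidate grid exceeds `cap`.
#'
#' @inheritParams countStates
#' @param cap maximum number of candidate configurations (default 2e5).
#' @param slack pruning slack in cm\eqn{^{-1}} (default 0; increase for
#'   systems with appreciable off-diagonal X).
#' @return a list with `configs` (matrix, one row per configuration) and
#'   `energies` (full-X energies, cm\eqn{^{-1}}), sorted by energy.
#' @examples
#' sys <- vibrationalSystem(c(100, 150))
#' nrow(bruteForceStates(sys, 400)$configs)  # 10
#' @export
bruteForceStates <- function(system, eMax, cap = 2e5, slack = 0) {
  if (eMax < 0) stop("eMax must be non-negative")
  N <- nModes(system)
  nmax <- vapply(seq_len(N), function(m)
    length(modeLevels(system, m, max(eMax + slack, 1e-9))) - 1L,
    integer(1))
  total <- prod(nmax + 1)
  if (total > cap)
    stop("candidate grid has ", total, " configurations, above cap = ", cap)
  grids <- lapply(nmax, function(k) 0:k)
  configs <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(configs) <- NULL
  energies <- apply(configs, 1, function(n) totalEnergy(system, n))
  keep <- energies <= eMax
  ord <- order(energies[keep])
  list(configs = configs[keep, , drop = FALSE][ord, , drop = FALSE],
       energies = energies[keep][ord])
}

#' Boltzmann weights over energy bins
#'
#' Normalized canonical weights \eqn{w_b \propto \rho_b e^{-E_b/k_BT}}
#' with \eqn{E_b} the bin centre and \eqn{\rho_b} the per-bin state count.
#' Computed in log space for numerical safety.
#'
#' @param dos a [DensityOfStates-class].
#' @param temperature temperature in K (> 0).
#' @return numeric vector of weights summing to 1, one per bin.
#' @examples
#' sys <- vibrationalSystem(208.5)
#' w <- boltzmannWeights(countStates(sys, 2000, binWidth = 208.5), 300)
#' w[2] / w[1]  # ~ exp(-1)
#' @export
boltzmannWeights <- function(dos, temperature) {
  stopifnot(is(dos, "DensityOfStates"), temperature > 0)
  counts <- dos@counts
  if (all(counts == 0)) stop("density of states is empty")
  lw <- ifelse(counts > 0,
               log(counts) - binCenters(dos) / kBT(temperature),
               -Inf)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}
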