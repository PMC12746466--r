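#' VibrationalSystem: a molecule's anharmonic vibrational fingerprint
#'
#' S4 container for the per-mode harmonic/anharmonic frequencies
#' \eqn{\nu_i} (cm\eqn{^{-1}}), the symmetric anharmonicity matrix
#' \eqn{X_{ij}} (cm\eqn{^{-1}}), base IR intensities for fundamentals and
#' (optionally) first overtones and 1+1 combination bands, and a
#' multiplicative frequency scaling factor.
#'
#' The scaling factor multiplies the frequencies only, not the X matrix:
#' empirical scaling corrects calculated anharmonic frequencies, while the
#' anharmonicity constants are left untouched. A typical calibration against
#' solution IR spectra is a factor slightly below one (e.g. 0.992).
#'
#' @slot frequencies numeric, length-N vector of mode frequencies in
#'   cm\eqn{^{-1}}; strictly positive.
#' @slot xMatrix numeric N x N symmetric matrix of anharmonicity constants
#'   in cm\eqn{^{-1}} (diagonal: self-anharmonicities, off-diagonal:
#'   mode-mode couplings).
#' @slot fundIntensities numeric length-N, non-negative base intensities
#'   \eqn{I_i^0} of the fundamentals (km/mol or arbitrary units).
#' @slot overtoneIntensities numeric length-N, non-negative base intensities
#'   of the first overtones (default all zero).
#' @slot combIntensities numeric N x N symmetric non-negative matrix of
#'   base intensities of the 1+1 combination bands (upper triangle used;
#'   default all zero).
#' @slot freqScale positive scalar applied multiplicatively to the
#'   frequencies (default 1).
#'
#' @seealso [vibrationalSystem()] for the user-facing constructor,
#'   [totalEnergy()], [stickSpectrum()].
#' @name VibrationalSystem-class
#' @aliases VibrationalSystem
#' @exportClass VibrationalSystem
setClass("VibrationalSystem",
  representation(
    frequencies = "numeric",
    xMatrix = "matrix",
    fundIntensities = "numeric",
    overtoneIntensities = "numeric",
    combIntensities = "matrix",
    freqScale = "numeric"
  )
)

.validVibrationalSystem <- function(object) {
  msg <- character()
  n <- length(object@frequencies)
  if (n < 1L) msg <- c(msg, "at least one mode is required")
  if (any(!is.finite(object@frequencies)) || any(object@frequencies <= 0))
    msg <- c(msg, "frequencies must be finite and strictly positive")
  if (!all(dim(object@xMatrix) == c(n, n)))
    msg <- c(msg, "xMatrix must be N x N")
  else {
    tol <- 1e-8 * max(1, max(abs(object@xMatrix)))
    if (max(abs(object@xMatrix - t(object@xMatrix))) > tol)
      msg <- c(msg, "xMatrix must be symmetric")
  }
  if (length(object@fundIntensities) != n ||
      any(object@fundIntensities < 0))
    msg <- c(msg, "fundIntensities must be length N and non-negative")
  if (length(object@overtoneIntensities) != n ||
      any(object@overtoneIntensities < 0))
    msg <- c(msg, "overtoneIntensities must be length N and non-negative")
  if (!all(dim(object@combIntensities) == c(n, n)) ||
      any(object@combIntensities < 0))
    msg <- c(msg, "combIntensities must be N x N and non-negative")
  if (length(object@freqScale) != 1L || !is.finite(object@freqScale) ||
      object@freqScale <= 0)
    msg <- c(msg, "freqScale must be a positive scalar")
  if (length(msg)) msg else TRUE
}

setValidity("VibrationalSystem", .validVibrationalSystem)

#' Construct a VibrationalSystem
#'
#' @param frequencies length-N vector of mode frequencies in cm\eqn{^{-1}}
#'   (strictly positive).
#' @param xMatrix N x N symmetric anharmonicity matrix in cm\eqn{^{-1}};
#'   defaults to the zero matrix (harmonic system).
#' @param fundIntensities base fundamental intensities \eqn{I_i^0}
#'   (default all 1).
#' @param overtoneIntensities base first-overtone intensities (default all
#'   0, i.e. overtone lines are carried only when anharmonic intensities
#'   are supplied).
#' @param combIntensities N x N symmetric matrix of base 1+1 combination
#'   intensities (default all 0).
#' @param freqScale multiplicative scaling applied to the frequencies only
#'   (default 1).
#' @return a [VibrationalSystem-class] object.
#' @examples
#' sys <- vibrationalSystem(c(1000, 1500),
#'                          xMatrix = rbind(c(-10, -5), c(-5, -12)))
#' nModes(sys)
#' @export
vibrationalSystem <- function(frequencies,
                              xMatrix = NULL,
                              fundIntensities = NULL,
                              overtoneIntensities = NULL,
                              combIntensities = NULL,
                              freqScale = 1) {
  n <- length(frequencies)
  if (is.null(xMatrix)) xMatrix <- matrix(0, n, n)
  xMatrix <- as.matrix(xMatrix)
  if (is.null(fundIntensities)) fundIntensities <- rep(1, n)
  if (is.null(overtoneIntensities)) overtoneIntensities <- rep(0, n)
  if (is.null(combIntensities)) combIntensities <- matrix(0, n, n)
  new("VibrationalSystem",
      frequencies = as.numeric(frequencies),
      xMatrix = xMatrix,
      fundIntensities = as.numeric(fundIntensities),
      overtoneIntensities = as.numeric(overtoneIntensities),
      combIntensities = as.matrix(combIntensities),
      freqScale = as.numeric(freqScale))
}

#' @describeIn VibrationalSystem-class number of modes N.
#' @param object,x a `VibrationalSystem`.
#' @export
nModes <- function(object) length(object@frequencies)

#' @describeIn VibrationalSystem-class unscaled mode frequencies
#'   (cm\eqn{^{-1}}).
#' @export
modeFrequencies <- function(object) object@frequencies

#' @describeIn VibrationalSystem-class frequencies multiplied by
#'   `freqScale`; these enter every energy expression.
#' @export
scaledFrequencies <- function(object) object@frequencies * object@freqScale

#' @describeIn VibrationalSystem-class the anharmonicity matrix.
#' @export
xMatrix <- function(object) object@xMatrix

#' @describeIn VibrationalSystem-class base fundamental intensities.
#' @export
fundIntensities <- function(object) object@fundIntensities

#' @describeIn VibrationalSystem-class base first-overtone intensities.
#' @export
overtoneIntensities <- function(object) object@overtoneIntensities

#' @describeIn VibrationalSystem-class base 1+1 combination intensities.
#' @export
combIntensities <- function(object) object@combIntensities

#' @describeIn VibrationalSystem-class the frequency scaling factor.
#' @export
freqScale <- function(object) object@freqScale

setMethod("show", "VibrationalSystem", function(object) {
  n <- nModes(object)
  cat("VibrationalSystem with", n, "modes\n")
  cat(sprintf("  frequencies: %.1f - %.1f cm-1 (scale %.4g)\n",
              min(object@frequencies), max(object@frequencies),
              object@freqScale))
  cat(sprintf("  X matrix: diag %.3g .. %.3g, |offdiag| max %.3g cm-1\n",
              min(diag(object@xMatrix)), max(diag(object@xMatrix)),
              if (n > 1) max(abs(object@xMatrix -
                                 diag(diag(object@xMatrix), n))) else 0))
  nOt <- sum(object@overtoneIntensities > 0)
  nCb <- sum(object@combIntensities[upper.tri(object@combIntensities)] > 0)
  cat(sprintf("  intensities: %d fundamentals, %d overtones, %d combinations > 0\n",
              sum(object@fundIntensities > 0), nOt, nCb))
  invisible(object)
})

## Contract check for an occupation configuration paired with a system.
.checkConfig <- function(system, config) {
  if (length(config) != nModes(system))
    stop("occupation configuration length (", length(config),
         ") does not match the number of modes (", nModes(system), ")")
  if (any(!is.finite(config)) || any(config < 0) ||
      any(config != round(config)))
    stop("occupation numbers must be non-negative integers")
  invisible(TRUE)
}

#' Read / write a VibrationalSystem as JSON
#'
#' The on-disk document carries keys `frequencies_cm1`, `x_matrix_cm1`,
#' `intensities_fund`, optionally `intensities_overtone` and
#' `intensities_comb`, and `freq_scale`. The reader validates symmetry and
#' lengths through the class validity method.
#'
#' @param system a [VibrationalSystem-class].
#' @param path file path.
#' @return `readSystemJSON` returns a `VibrationalSystem`;
#'   `writeSystemJSON` returns `path` invisibly.
#' @examples
#' sys <- vibrationalSystem(c(1000, 1500))
#' f <- tempfile(fileext = ".json")
#' writeSystemJSON(sys, f)
#' identical(scaledFrequencies(readSystemJSON(f)), scaledFrequencies(sys))
#' @export
writeSystemJSON <- function(system, path) {
  stopifnot(is(system, "VibrationalSystem"))
  doc <- list(
    frequencies_cm1 = system@frequencies,
    x_matrix_cm1 = system@xMatrix,
    intensities_fund = system@fundIntensities,
    intensities_overtone = system@overtoneIntensities,
    intensities_comb = system@combIntensities,
    freq_scale = system@freqScale
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeSystemJSON
#' @export
readSystemJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$frequencies_cm1) || is.null(doc$x_matrix_cm1))
    stop("not a vibrational-system JSON document: ", path)
  vibrationalSystem(
    frequencies = doc$frequencies_cm1,
    xMatrix = doc$x_matrix_cm1,
    fundIntensities = doc$intensities_fund,
    overtoneIntensities = doc$intensities_overtone,
    combIntensities = doc$intensities_comb,
    freqScale = if (is.null(doc$freq_scale)) 1 else doc$freq_scale
  )
}
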