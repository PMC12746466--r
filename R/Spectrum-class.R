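#' Spectrum: intensities on a wavenumber grid
#'
#' Minimal S4 container pairing a strictly increasing wavenumber grid
#' (cm\eqn{^{-1}}) with finite intensity values. Produced by
#' [convolveSpectrum()], [assembleCanonicalSpectrum()] and the row
#' accessor of [SpectralMatrix-class].
#'
#' @slot grid strictly increasing numeric vector of wavenumbers.
#' @slot values numeric vector of intensities, same length as `grid`.
#' @name Spectrum-class
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  representation(grid = "numeric", values = "numeric")
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@values))
    msg <- c(msg, "grid and values must have the same length")
  if (length(object@grid) > 1 && any(diff(object@grid) <= 0))
    msg <- c(msg, "grid must be strictly increasing")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn Spectrum-class constructor.
#' @param grid strictly increasing wavenumber grid (cm\eqn{^{-1}}).
#' @param values intensities on the grid.
#' @export
Spectrum <- function(grid, values) {
  new("Spectrum", grid = as.numeric(grid), values = as.numeric(values))
}

#' @describeIn Spectrum-class the wavenumber grid.
#' @param object,x a `Spectrum`.
#' @export
spectrumGrid <- function(object) object@grid

#' @describeIn Spectrum-class the intensity values.
#' @export
spectrumValues <- function(object) object@values

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.1f - %.1f cm-1, max %.4g\n",
              length(object@grid),
              if (length(object@grid)) min(object@grid) else NA,
              if (length(object@grid)) max(object@grid) else NA,
              if (length(object@values)) max(object@values) else NA))
  invisible(object)
})

#' @describeIn Spectrum-class coerce to a two-column data frame.
#' @param row.names,optional,... passed through (ignored).
#' @export
as.data.frame.Spectrum <- function(x, row.names = NULL, optional = FALSE,
                                   ...) {
  data.frame(wavenumber = x@grid, intensity = x@values)
}

#' Read / write a spectrum as two-column TSV
#'
#' Columns are `wavenumber_cm1` and `intensity`; a `#`-prefixed comment
#' header records the units.
#'
#' @param spectrum a [Spectrum-class].
#' @param path file path.
#' @return `readSpectrumTSV` returns a `Spectrum`; `writeSpectrumTSV`
#'   returns `path` invisibly.
#' @export
writeSpectrumTSV <- function(spectrum, path) {
  stopifnot(is(spectrum, "Spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# vibcascade spectrum: wavenumber_cm1\tintensity", con)
  write.table(data.frame(spectrum@grid, spectrum@values), con,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTSV
#' @export
readSpectrumTSV <- function(path) {
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    colClasses = "numeric")
  Spectrum(tab[[1]], tab[[2]])
}
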