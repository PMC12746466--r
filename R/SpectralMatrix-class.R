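#' SpectralMatrix: stacked IR spectra indexed by energy or time
#'
#' Rows are indexed by energy-bin centre (multicanonical sampling) or by
#' time step (kinetic Monte Carlo cooling); columns are wavenumber bins.
#' `values` holds summed binned stick intensities and `samples` the number
#' of accumulated samples per row, so a normalized row spectrum is
#' `values[i, ] / samples[i]` (see [rowSpectrum()]). Rows with zero
#' samples are empty.
#'
#' @slot rowAxis numeric row coordinates (cm\eqn{^{-1}} bin centres or fs).
#' @slot colAxis numeric wavenumber-bin centres (cm\eqn{^{-1}}).
#' @slot values numeric matrix, `length(rowAxis)` x `length(colAxis)`,
#'   of summed intensities.
#' @slot samples numeric vector of per-row sample counts.
#' @slot rowType `"energy"` or `"time"`.
#' @slot metadata list of run metadata (parameters, seed, provenance).
#' @name SpectralMatrix-class
#' @aliases SpectralMatrix
#' @exportClass SpectralMatrix
setClass("SpectralMatrix",
  representation(
    rowAxis = "numeric",
    colAxis = "numeric",
    values = "matrix",
    samples = "numeric",
    rowType = "character",
    metadata = "list"
  )
)

setValidity("SpectralMatrix", function(object) {
  msg <- character()
  if (!all(dim(object@values) ==
           c(length(object@rowAxis), length(object@colAxis))))
    msg <- c(msg, "values must be length(rowAxis) x length(colAxis)")
  if (length(object@samples) != length(object@rowAxis))
    msg <- c(msg, "samples must have one entry per row")
  if (any(object@samples < 0))
    msg <- c(msg, "samples must be non-negative")
  if (!object@rowType %in% c("energy", "time"))
    msg <- c(msg, "rowType must be 'energy' or 'time'")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpectralMatrix-class constructor.
#' @param rowAxis,colAxis,values,samples,rowType,metadata see slots.
#' @export
spectralMatrix <- function(rowAxis, colAxis, values, samples,
                           rowType = c("energy", "time"),
                           metadata = list()) {
  new("SpectralMatrix", rowAxis = as.numeric(rowAxis),
      colAxis = as.numeric(colAxis), values = values,
      samples = as.numeric(samples), rowType = match.arg(rowType),
      metadata = metadata)
}

#' @describeIn SpectralMatrix-class row coordinates.
#' @param object a `SpectralMatrix`.
#' @export
rowAxis <- function(object) object@rowAxis

#' @describeIn SpectralMatrix-class wavenumber-bin centres.
#' @export
colAxis <- function(object) object@colAxis

#' @describeIn SpectralMatrix-class the raw summed-intensity matrix.
#' @export
spectralValues <- function(object) object@values

#' @describeIn SpectralMatrix-class per-row sample counts.
#' @export
sampleCounts <- function(object) object@samples

#' @describeIn SpectralMatrix-class run metadata list.
#' @export
smMetadata <- function(object) object@metadata

#' @describeIn SpectralMatrix-class normalized spectrum of row `i`
#'   (`values[i, ] / samples[i]`; all-zero when the row is empty).
#' @param i row index.
#' @export
rowSpectrum <- function(object, i) {
  s <- object@samples[i]
  v <- if (s > 0) object@values[i, ] / s else rep(0, ncol(object@values))
  Spectrum(object@colAxis, v)
}

setMethod("show", "SpectralMatrix", function(object) {
  cat(sprintf("SpectralMatrix (%s rows): %d x %d, %d empty rows\n",
              object@rowType, nrow(object@values), ncol(object@values),
              sum(object@samples == 0)))
  if (length(object@rowAxis))
    cat(sprintf("  row axis: %.6g .. %.6g %s\n", min(object@rowAxis),
                max(object@rowAxis),
                if (object@rowType == "energy") "cm-1" else "fs"))
  cat(sprintf("  col axis: %.6g .. %.6g cm-1\n",
              min(object@colAxis), max(object@colAxis)))
  invisible(object)
})

#' Read / write a SpectralMatrix as a headered TSV matrix
#'
#' Plain-text persistence: the first (non-comment) row is the wavenumber
#' axis preceded by a placeholder `0`, each following row starts with its
#' row coordinate. Comment lines carry the row type and the per-row sample
#' counts, so the round trip reproduces the object to full precision
#' (metadata other than samples/rowType is not persisted).
#'
#' @param sm a [SpectralMatrix-class].
#' @param path file path.
#' @return `readSpectralMatrixTSV` returns a `SpectralMatrix`;
#'   `writeSpectralMatrixTSV` returns `path` invisibly.
#' @export
writeSpectralMatrixTSV <- function(sm, path) {
  stopifnot(is(sm, "SpectralMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# vibcascade spectral matrix; rowType=", sm@rowType,
           "; rows: ", if (sm@rowType == "energy") "energy_cm1" else
             "time_fs", "; cols: wavenumber_cm1"),
    paste0("# samples: ",
           paste(format(sm@samples, digits = 17, trim = TRUE,
                        scientific = FALSE), collapse = " "))
  ), con)
  m <- rbind(c(0, sm@colAxis), cbind(sm@rowAxis, sm@values))
  write.table(m, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectralMatrixTSV
#' @export
readSpectralMatrixTSV <- function(path) {
  lines <- readLines(path)
  comments <- grep("^#", lines, value = TRUE)
  rowType <- if (any(grepl("rowType=time", comments))) "time" else "energy"
  sampLine <- grep("^# samples:", comments, value = TRUE)
  samples <- as.numeric(strsplit(sub("^# samples: *", "", sampLine[1]),
                                 " +")[[1]])
  m <- as.matrix(read.table(text = lines[!grepl("^#", lines)],
                            sep = "\t"))
  spectralMatrix(rowAxis = m[-1, 1], colAxis = m[1, -1],
                 values = unname(m[-1, -1, drop = FALSE]),
                 samples = samples, rowType = rowType)
}
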