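## Pipeline driver behind the command-line interface: each subcommand is
## a thin, deterministic wrapper over the package functions, writing
## text artifacts plus a machine-readable JSON summary.

#' Read / write a normal-mode set as JSON
#'
#' Document keys: `frequencies_cm1`, `vectors` (one 3N row per mode,
#' mass-weighted), `symbols`, `coords`, `masses` for the reference
#' geometry.
#'
#' @param modeset a [normalModeSet()].
#' @param path file path.
#' @return `readNormalModesJSON` returns a `NormalModeSet`;
#'   `writeNormalModesJSON` returns `path` invisibly.
#' @export
writeNormalModesJSON <- function(modeset, path) {
  stopifnot(inherits(modeset, "NormalModeSet"))
  doc <- list(
    frequencies_cm1 = modeset$frequencies,
    vectors = t(modeset$vectors),
    symbols = modeset$reference$symbols,
    coords = modeset$reference$coords,
    masses = modeset$reference$masses
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeNormalModesJSON
#' @export
readNormalModesJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- geometry(doc$symbols, doc$coords, doc$masses)
  normalModeSet(ref, doc$frequencies_cm1, t(doc$vectors))
}

.md5OrNA <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths)) return(list())
  sums <- tools::md5sum(unlist(paths))
  as.list(sums)
}

#' Run a pipeline subcommand
#'
#' Deterministic given `seed`: reruns with the same configuration produce
#' byte-identical outputs. Every run writes its artifacts plus
#' `<out>.summary.json` recording the subcommand, all effective
#' parameters, the seed, MD5 checksums of the inputs and the package
#' version. A failure leaves a `<out>.FAILED` marker file.
#'
#' Subcommands (`config$subcommand`):
#' \describe{
#'   \item{synth}{generate a fixture system (JSON) and hot initial
#'     configurations (TSV). Fields: `kind` ("cyan", "toy", "harmonic"),
#'     `seed`, `nConfigs`, `eTotal`, `out`.}
#'   \item{density}{state count of a system. Fields: `system`, `eMax`,
#'     `binWidth`, `out` (TSV: bin centre, count).}
#'   \item{spectrum}{canonical IR spectrum by multicanonical sampling.
#'     Fields: `system`, `temperature`, `eMax`, `nWindows`, `binWidth`,
#'     `nWalks`, `spectralWindow`, `fwhm`, `seed`, `out`.}
#'   \item{cool}{ensemble cooling simulation. Fields: `system`, `init`
#'     (configs TSV), `q`, `dt`, `tMax`, `nTrajectories`,
#'     `acceptanceMode`, `spectralWindow`, `seed`, `out` (spectral-matrix
#'     TSV).}
#'   \item{project}{project a surface-hopping XYZ onto occupations.
#'     Fields: `modes` (normal-mode JSON), `hop` (XYZ with
#'     `deltaE_cm1=` comment), `out` (configs TSV).}
#'   \item{analyze}{band metric trace from a spectral-matrix TSV.
#'     Fields: `matrix`, `band` (c(lo, hi)), `metric` ("expectation" or
#'     "integral"), optional `fitSequential` (list with `tau1`, `tau2`
#'     guesses), `out` (trace TSV; fit written into the summary).}
#' }
#'
#' @param config a named list; see Details.
#' @return (invisibly) a list of produced file paths plus the summary.
#' @export
runPipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$subcommand),
            !is.null(config$out))
  out <- config$out
  marker <- paste0(out, ".FAILED")
  if (file.exists(marker)) file.remove(marker)
  result <- tryCatch(
    .runSubcommand(config),
    error = function(e) {
      writeLines(conditionMessage(e), marker)
      stop(e)
    })
  summary <- list(
    subcommand = config$subcommand,
    parameters = config[setdiff(names(config),
                                c("subcommand", "out"))],
    seed = config$seed,
    inputs_md5 = .md5OrNA(config[intersect(
      names(config), c("system", "init", "modes", "hop", "matrix"))]),
    outputs = result$files,
    package_version = as.character(utils::packageVersion("vibcascade"))
  )
  if (!is.null(result$extra)) summary <- c(summary, result$extra)
  summaryPath <- paste0(out, ".summary.json")
  jsonlite::write_json(summary, summaryPath, digits = NA,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(c(result, list(summary = summaryPath)))
}

.runSubcommand <- function(config) {
  sub <- config$subcommand
  out <- config$out
  gv <- function(name, default) {
    if (is.null(config[[name]])) default else config[[name]]
  }
  if (sub == "synth") {
    seed <- gv("seed", 42)
    kind <- gv("kind", "cyan")
    if (kind == "cyan") {
      fix <- makeCyanLikeSystem(seed)
      sysFile <- paste0(out, ".system.json")
      writeSystemJSON(fix$system, sysFile)
      set.seed(seed)
      cfgs <- generateHotConfigs(fix$system, fix$activeModes,
                                 gv("eTotal", 18000),
                                 gv("nConfigs", 10))
      cfgFile <- paste0(out, ".configs.tsv")
      writeConfigsTSV(cfgs, cfgFile)
      return(list(files = c(sysFile, cfgFile),
                  extra = list(activeModes = fix$activeModes,
                               markerModes = fix$markerModes)))
    }
    sys <- if (kind == "toy") makeToyAnharmonic(seed = seed)
           else makeHarmonicSystem(gv("freqs", c(500, 1000, 1500)))
    sysFile <- paste0(out, ".system.json")
    writeSystemJSON(sys, sysFile)
    return(list(files = sysFile))
  }
  if (sub == "density") {
    sys <- readSystemJSON(config$system)
    dos <- countStates(sys, gv("eMax", 8065.54), gv("binWidth", 16))
    tab <- data.frame(energy_cm1 = binCenters(dos),
                      count = stateCounts(dos))
    f <- paste0(out, ".density.tsv")
    con <- file(f, "w")
    writeLines("# vibcascade state density: bin_center_cm1\tcount", con)
    write.table(tab, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
    return(list(files = f))
  }
  if (sub == "spectrum") {
    sys <- readSystemJSON(config$system)
    params <- mucaParams(
      nWalks = gv("nWalks", 6),
      spectralWindow = gv("spectralWindow", c(1350, 1850)),
      maxSteps = gv("maxSteps", 2e6))
    res <- mucaSpectrum(sys, gv("temperature", 300),
                        eMax = gv("eMax", 8065.54),
                        nWindows = gv("nWindows", 4),
                        binWidth = gv("binWidth", 16),
                        params = params, seed = gv("seed", 1))
    conv <- convolveSpectrum(res$spectrum, spectrumGrid(res$spectrum),
                             gv("fwhm", 5))
    f1 <- paste0(out, ".spectrum.tsv")
    writeSpectrumTSV(conv, f1)
    f2 <- paste0(out, ".matrix.tsv")
    writeSpectralMatrixTSV(res$matrix, f2)
    return(list(files = c(f1, f2),
                extra = list(allConverged = all(res$converged,
                                                na.rm = TRUE))))
  }
  if (sub == "cool") {
    sys <- readSystemJSON(config$system)
    init <- readConfigsTSV(config$init)
    params <- kmcParams(
      q = gv("q", 0.1), dt = gv("dt", 5), tMax = gv("tMax", 10000),
      TBath = gv("TBath", 300),
      acceptanceMode = gv("acceptanceMode", "as_printed"),
      nTrajectories = gv("nTrajectories", 576),
      spectralWindow = gv("spectralWindow", c(1350, 1850)))
    sm <- ensembleSpectra(sys, init, params,
                          thermalT = gv("thermalT", 300),
                          seed = gv("seed", 1))
    f <- paste0(out, ".cooling.tsv")
    writeSpectralMatrixTSV(sm, f)
    return(list(files = f))
  }
  if (sub == "project") {
    modes <- readNormalModesJSON(config$modes)
    hop <- hopRecord(readXYZ(config$hop))
    cfg <- projectHopOccupations(modes, hop)
    f <- paste0(out, ".projected.tsv")
    writeConfigsTSV(matrix(cfg, nrow = 1), f)
    return(list(files = f))
  }
  if (sub == "analyze") {
    sm <- readSpectralMatrixTSV(config$matrix)
    trace <- kineticTrace(sm, gv("band", c(1550, 1600)),
                          metric = gv("metric", "expectation"))
    f <- paste0(out, ".trace.tsv")
    con <- file(f, "w")
    writeLines(paste0("# vibcascade kinetic trace: time_fs\t",
                      gv("metric", "expectation")), con)
    write.table(trace, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    close(con)
    extra <- NULL
    fs <- config$fitSequential
    if (!is.null(fs)) {
      tr <- data.frame(time = trace$time, value = trace$value)
      fit <- fitSequential(tr, fs$tau1, fs$tau2)
      extra <- list(fit = list(tau1 = fit$tau1, tau2 = fit$tau2,
                               identifiable = fit$identifiable))
    }
    return(list(files = f, extra = extra))
  }
  stop("unknown subcommand: ", sub)
}
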