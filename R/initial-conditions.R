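## Nascent hot-ground-state initial conditions: normal-mode projection of
## surface-hopping geometries, thermal sampling, and rapid-exchange
## statistical sampling.

## Standard atomic weights (amu) for the elements that occur in organic
## chromophores; D is deuterium.
.atomicMasses <- c(
  H = 1.00794, D = 2.014102, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403, S = 32.06, P = 30.973762, Cl = 35.45, Br = 79.904,
  I = 126.90447, B = 10.81, Si = 28.085, Na = 22.98977, K = 39.0983
)

#' Molecular geometry
#'
#' Plain container for atom symbols, Cartesian coordinates and atomic
#' masses. Masses default to standard atomic weights looked up from the
#' symbols.
#'
#' @param symbols character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates
#'   (Angstrom).
#' @param masses optional numeric vector of masses (amu).
#' @return a list with class `"Geometry"`.
#' @export
geometry <- function(symbols, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3 || nrow(coords) != length(symbols))
    stop("coords must be an N x 3 matrix matching symbols")
  if (is.null(masses)) {
    masses <- .atomicMasses[symbols]
    if (any(is.na(masses)))
      stop("unknown element symbol(s): ",
           paste(unique(symbols[is.na(masses)]), collapse = ", "))
  }
  structure(list(symbols = as.character(symbols), coords = coords,
                 masses = as.numeric(masses)),
            class = "Geometry")
}

#' Read / write XYZ geometry files
#'
#' Standard XYZ: atom count, comment line, then `symbol x y z` rows. The
#' comment line may carry the available electronic energy of a
#' surface-hopping snapshot as `deltaE_cm1=<value>`; the reader exposes
#' it as the `"deltaE"` attribute.
#'
#' @param path file path.
#' @param geom a `Geometry` (for writing).
#' @param comment comment line content.
#' @return `readXYZ` returns a `Geometry` (with attributes `comment` and
#'   possibly `deltaE`); `writeXYZ` returns `path` invisibly.
#' @export
readXYZ <- function(path) {
  lines <- readLines(path)
  nAtoms <- as.integer(trimws(lines[1]))
  comment <- if (length(lines) >= 2) lines[2] else ""
  rows <- strsplit(trimws(lines[3:(2 + nAtoms)]), "[[:space:]]+")
  symbols <- vapply(rows, `[[`, character(1), 1)
  coords <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  g <- geometry(symbols, coords)
  attr(g, "comment") <- comment
  m <- regmatches(comment,
                  regexec("deltaE_cm1=([-0-9.eE+]+)", comment))[[1]]
  if (length(m) == 2) attr(g, "deltaE") <- as.numeric(m[2])
  g
}

#' @rdname readXYZ
#' @export
writeXYZ <- function(geom, path, comment = "") {
  stopifnot(inherits(geom, "Geometry"))
  lines <- c(length(geom$symbols), comment,
             sprintf("%-3s %18.10f %18.10f %18.10f", geom$symbols,
                     geom$coords[, 1], geom$coords[, 2],
                     geom$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Equilibrium normal-mode set
#'
#' Reference geometry plus mass-weighted normal-mode vectors (one column
#' per mode, orthonormal within tolerance) and mode frequencies.
#'
#' @param reference a [geometry()].
#' @param frequencies mode frequencies in cm\eqn{^{-1}}.
#' @param vectors numeric 3N x nModes matrix of mass-weighted normal
#'   vectors (columns orthonormal).
#' @param tol orthonormality tolerance.
#' @return a list with class `"NormalModeSet"`.
#' @export
normalModeSet <- function(reference, frequencies, vectors, tol = 1e-6) {
  stopifnot(inherits(reference, "Geometry"))
  vectors <- as.matrix(vectors)
  nCart <- 3 * length(reference$symbols)
  if (nrow(vectors) != nCart || ncol(vectors) != length(frequencies))
    stop("vectors must be 3N x nModes")
  if (ncol(vectors) > nCart)
    stop("more modes than Cartesian degrees of freedom")
  gram <- crossprod(vectors)
  if (max(abs(gram - diag(ncol(vectors)))) > tol)
    stop("normal vectors are not orthonormal within tolerance")
  structure(list(reference = reference,
                 frequencies = as.numeric(frequencies),
                 vectors = vectors),
            class = "NormalModeSet")
}

#' Surface-hopping snapshot record
#'
#' Pairs a hop geometry with the available electronic energy: the energy
#' difference between the excited state at the hopping geometry and the
#' ground-state equilibrium geometry, which is partitioned into
#' vibrational quanta by [projectHopOccupations()].
#'
#' @param geom hop [geometry()].
#' @param deltaE available electronic energy in cm\eqn{^{-1}}
#'   (\eqn{\ge 0}); defaults to the `deltaE` attribute read from the XYZ
#'   comment line.
#' @return a list with class `"HopRecord"`.
#' @export
hopRecord <- function(geom, deltaE = attr(geom, "deltaE")) {
  stopifnot(inherits(geom, "Geometry"))
  if (is.null(deltaE) || !is.finite(deltaE) || deltaE < 0)
    stop("deltaE must be a non-negative energy in cm-1")
  structure(list(geometry = geom, deltaE = as.numeric(deltaE)),
            class = "HopRecord")
}

## Mass-weighted rigid-body superposition (Kabsch): returns the mobile
## coordinates optimally rotated/translated onto the reference.
.superpose <- function(ref, mob, masses) {
  w <- masses / sum(masses)
  cr <- colSums(ref * w)
  cm <- colSums(mob * w)
  P <- sweep(ref, 2, cr)
  Q <- sweep(mob, 2, cm)
  C <- t(Q * w) %*% P
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(Q %*% t(R), 2, cr, "+")
}

#' Project a surface-hopping geometry onto occupation numbers
#'
#' The hop geometry is rigid-body superposed onto the equilibrium
#' reference (mass-weighted, so overall rotation and translation cannot
#' contaminate the projection), the mass-weighted displacement is
#' projected onto each normal vector giving normal coordinates
#' \eqn{q_i}, and the per-mode harmonic displacement energies
#' \eqn{e_i = \tfrac12 \omega_i^2 q_i^2} define the partition weights.
#' The available electronic energy is then distributed across the modes
#' proportionally to \eqn{e_i}, in integer quanta of \eqn{\nu_i}
#' (largest-remainder integerization), so that
#' \eqn{|\sum_i n_i \nu_i - \Delta E| \le \max_i \nu_i} over the
#' populated modes. Velocities at the hop are ignored.
#'
#' @param modeset a [normalModeSet()].
#' @param hop a [hopRecord()] with atoms ordered as in the reference.
#' @return integer occupation configuration, one entry per mode.
#' @export
projectHopOccupations <- function(modeset, hop) {
  stopifnot(inherits(modeset, "NormalModeSet"),
            inherits(hop, "HopRecord"))
  ref <- modeset$reference
  g <- hop$geometry
  if (!identical(ref$symbols, g$symbols))
    stop("hop geometry atoms do not match the reference")
  nModes <- length(modeset$frequencies)
  if (hop$deltaE == 0) return(integer(nModes))
  aligned <- .superpose(ref$coords, g$coords, ref$masses)
  disp <- sqrt(rep(ref$masses, each = 3)) *
    as.vector(t(aligned - ref$coords))
  q <- drop(crossprod(modeset$vectors, disp))
  e <- 0.5 * modeset$frequencies^2 * q^2
  ## guard against pure numerical noise from the superposition
  refScale <- sqrt(sum(ref$masses * rowSums(ref$coords^2)))
  if (all(e == 0) || sqrt(sum(disp^2)) < 1e-9 * (1 + refScale))
    stop("hop geometry is not displaced along any mode; ",
         "no direction to partition the energy")
  nu <- modeset$frequencies
  ideal <- hop$deltaE * (e / sum(e)) / nu
  n <- floor(ideal)
  deficit <- hop$deltaE - sum(n * nu)
  ## largest-remainder passes: add quanta where the fractional shortfall
  ## is largest, while each addition still reduces |deficit|
  repeat {
    rem <- ideal - n
    cand <- which(e > 0 & nu <= 2 * deficit)
    if (!length(cand)) break
    m <- cand[which.max(rem[cand])]
    n[m] <- n[m] + 1
    deficit <- deficit - nu[m]
  }
  as.integer(n)
}

#' Sample a thermal occupation configuration
#'
#' Independent per-mode geometric (harmonic Boltzmann) sampling:
#' \eqn{P(n_i) \propto e^{-n_i \nu_i / k_B T}}, whose mean is the
#' Bose-Einstein occupation \eqn{1/(e^{\nu_i/k_BT} - 1)}. At room
#' temperature and mid-IR frequencies the difference from the full
#' anharmonic canonical ensemble is negligible; the multicanonical
#' machinery exists for exactness when it is not.
#'
#' @inheritParams totalEnergy
#' @param temperature temperature in K (\eqn{\ge 0}; 0 returns the
#'   ground configuration).
#' @return integer occupation configuration.
#' @export
sampleThermalConfig <- function(system, temperature) {
  stopifnot(temperature >= 0)
  N <- nModes(system)
  if (temperature == 0) return(integer(N))
  nu <- scaledFrequencies(system)
  p <- 1 - exp(-nu / kBT(temperature))
  rgeom(N, p)
}

#' Sample statistical (rapid-exchange-limit) configurations
#'
#' For each target energy, draws a configuration approximately uniformly
#' from all configurations whose total energy lies within `tol` of the
#' target. This is the rapid-exchange limit: intramolecular energy
#' redistribution is assumed complete before any energy leaves the
#' molecule, so all configurations at the given internal energy are
#' equally likely. Sampling runs a Metropolis-Hastings walk with the
#' multicanonical whole-configuration proposal ([proposeConfig()]) and a
#' uniform target density (acceptance \eqn{\min[1, r^{\Delta n}]},
#' rejecting steps that leave the band); because every mode steps
#' independently, compensating up/down exchanges keep the walk mobile
#' inside a narrow band.
#'
#' For small systems (candidate state space within `enumCap`) the draw
#' is exactly uniform: the in-band configurations are enumerated with
#' [bruteForceStates()] and sampled directly. For large systems, where
#' enumeration is impossible, the Metropolis walk provides an
#' approximately uniform draw; note that for very narrow bands the walk
#' relies on compensating multi-mode exchanges to move between states.
#'
#' @inheritParams totalEnergy
#' @param eTargets vector of target total energies, cm\eqn{^{-1}}
#'   (positive).
#' @param tol half-width of the energy band around each target,
#'   cm\eqn{^{-1}}.
#' @param r up-proposal bias of the walk (default 1.08).
#' @param nBurn walk steps per draw (default `200 + 20 * N`).
#' @param maxTries random-search tries for the in-band starting
#'   configuration.
#' @param method `"auto"` (enumerate when feasible), `"enumerate"` or
#'   `"walk"`.
#' @param enumCap candidate-grid cap for the enumeration route.
#' @return matrix with one configuration per row (one per target).
#' @export
sampleStatisticalConfigs <- function(system, eTargets, tol,
                                     r = 1.08, nBurn = NULL,
                                     maxTries = 5000,
                                     method = c("auto", "enumerate",
                                                "walk"),
                                     enumCap = 5e4) {
  stopifnot(all(eTargets > 0), tol >= 0)
  method <- match.arg(method)
  N <- nModes(system)
  if (is.null(nBurn)) nBurn <- 200 + 20 * N
  nu <- scaledFrequencies(system)
  denom <- .proposalDenom(N, r)
  out <- matrix(0L, length(eTargets), N)

  if (method %in% c("auto", "enumerate")) {
    bf <- tryCatch(
      bruteForceStates(system, max(eTargets) + tol, cap = enumCap,
                       slack = 2 * tol),
      error = function(e) NULL)
    if (is.null(bf) && method == "enumerate")
      stop("state space too large to enumerate; use method = \"walk\"")
    if (!is.null(bf)) {
      for (t in seq_along(eTargets)) {
        inBand <- which(bf$energies >= eTargets[t] - tol &
                          bf$energies <= eTargets[t] + tol)
        if (!length(inBand))
          stop("no configuration within ", tol, " of target ",
               eTargets[t])
        pick <- if (length(inBand) == 1) inBand else sample(inBand, 1)
        out[t, ] <- bf$configs[pick, ]
      }
      return(out)
    }
  }

  for (t in seq_along(eTargets)) {
    lo <- eTargets[t] - tol
    hi <- eTargets[t] + tol
    ## ground configuration is the only state below the lowest level
    if (hi < min(nu) && lo <= 0) {
      next
    }
    n <- NULL
    for (k in seq_len(maxTries)) {
      cand <- integer(N)
      deficit <- runif(1, max(lo, 0), hi)
      repeat {
        elig <- which(nu <= deficit)
        if (!length(elig)) break
        m <- if (length(elig) == 1) elig else sample(elig, 1)
        cand[m] <- cand[m] + 1L
        deficit <- deficit - nu[m]
      }
      E <- totalEnergy(system, cand)
      if (E >= lo && E <= hi) { n <- cand; break }
    }
    if (is.null(n))
      stop("no configuration found in band [", lo, ", ", hi,
           "] after ", maxTries, " tries")
    E <- totalEnergy(system, n)
    for (s in seq_len(nBurn)) {
      prop <- proposeConfig(n, r, denom)
      if (all(prop$config == n)) next
      eProp <- totalEnergy(system, prop$config)
      if (eProp < lo || eProp > hi) next
      if (runif(1) < min(1, r^prop$deltaN)) {
        n <- prop$config
        E <- eProp
      }
    }
    out[t, ] <- n
  }
  out
}

#' Read / write occupation configurations as TSV
#'
#' One row per configuration, one integer column per mode, with a
#' comment header.
#'
#' @param configs matrix of configurations (rows) or a single vector.
#' @param path file path.
#' @return `readConfigsTSV` returns an integer matrix;
#'   `writeConfigsTSV` returns `path` invisibly.
#' @export
writeConfigsTSV <- function(configs, path) {
  if (is.null(dim(configs))) configs <- matrix(configs, nrow = 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(
    "# vibcascade occupation configurations: one row per configuration",
    con)
  write.table(configs, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeConfigsTSV
#' @export
readConfigsTSV <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", comment.char = "#"))
  storage.mode(m) <- "integer"
  unname(m)
}
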