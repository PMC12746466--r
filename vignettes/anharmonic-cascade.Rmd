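---
title: "The anharmonic cascade model: methods and design"
author: "vibcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The anharmonic cascade model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibcascade)
```

## The model

`vibcascade` simulates equilibrium and time-resolved infrared spectra of a
polyatomic molecule from its anharmonic vibrational fingerprint: per-mode
frequencies $\nu_i$ (cm$^{-1}$), the symmetric anharmonicity matrix
$X_{ij}$ (cm$^{-1}$), and base IR intensities. The intended application is
hot ground state cooling (HGSC): after ultrafast internal conversion, a
molecule returns to its electronic ground state carrying one to several eV
of vibrational energy, which it dissipates to the solvent over
picoseconds. In time-resolved IR spectra this appears as red-shifted,
reshaping bands that sweep blue as the molecule cools — behaviour that
static-spectrum kinetic models cannot describe, and that this package
reproduces from the anharmonic level structure directly.

The energy of an occupation configuration
$\mathbf{n} = (n_1, \dots, n_N)$ is the second-order (Dunham) expansion

$$E(\mathbf{n}) = \sum_i \nu_i\left(n_i + \tfrac12\right) +
  \sum_{i \le j} X_{ij}\left(n_i + \tfrac12\right)\left(n_j +
  \tfrac12\right),$$

and every quantity in the package is carried relative to the zero-point
configuration, $E_\mathrm{rel}(\mathbf{n}) = E(\mathbf{n}) -
E(\mathbf{0})$. All energies are wavenumbers; the Boltzmann constant is
$k_B = 0.695034800$ cm$^{-1}$/K and Planck's constant never appears
explicitly. A multiplicative `freqScale` (typically slightly below 1,
e.g. 0.992 for calibration against solution spectra) applies to the
frequencies only, never to $X$.

### Transition energies by differencing

Transition energies are computed by *differencing* the expansion:
$\Delta E = E_\mathrm{rel}(\mathbf{n}') - E_\mathrm{rel}(\mathbf{n})$,
where $\mathbf{n}'$ raises one mode by 1 (fundamental), one mode by 2
(first overtone), or two modes by 1 each (1+1 combination). Differencing
is self-consistent with the energy model by construction and yields the
closed forms

$$\Delta E_{\mathrm{fund},i} = \nu_i + 2X_{ii}(n_i + 1) +
  \sum_{j \ne i} X_{ij}\left(n_j + \tfrac12\right),$$

with $\Delta E_{\mathrm{ot},i} = 2\Delta E_{\mathrm{fund},i} + 2X_{ii}$
and $\Delta E_{\mathrm{comb},ij} = \Delta E_{\mathrm{fund},i} +
\Delta E_{\mathrm{fund},j} + X_{ij}$ as algebraic identities (exercised
in the unit tests). A commonly quoted closed form with the coefficient
$X_{ii}(n_i + 3/2)$ is *not* consistent with differencing the expansion
(at $\mathbf{n} = 0$ it gives $\nu + 1.5\,X_{ii}$ instead of
$\nu + 2X_{ii}$); the package adopts the differencing convention
throughout. Transitions with $\Delta E \le 0$ (possible for strongly
anharmonic, highly excited states) always carry zero intensity.

### Intensities

A fundamental's intensity follows the harmonic-oscillator occupancy
scaling times the ratio of the occupation-dependent transition energy to
the transition energy from the global all-zero configuration:

$$I_i = I_i^0\,(n_i + 1)\,\frac{\Delta E_{\mathrm{fund},i}}
 {\Delta E_{\mathrm{fund},i}^0}.$$

First overtones scale as $(n_i+1)(n_i+2)/2$ and 1+1 combinations as
$(n_i+1)(n_j+1)$ — the harmonic matrix-element factors — each with their
own $\Delta E/\Delta E^0$ ratio. Two conventions were genuinely open:
whether the ratio uses the global all-zero $\Delta E^0$ or the
current-configuration one (the global reading is implemented), and the
occupancy factors themselves, which are exact only for the harmonic
oscillator (they can be disabled with `occupancyScaling = FALSE`). Base
overtone and combination intensities default to zero — those lines are
carried only when the user supplies anharmonic values — and the fixture
generators can assign small fractions of the fundamental intensities so
that all three band kinds are exercised in tests.

## State counting

The vibrational density of states $\rho(E)$ treats the modes as
*separable* anharmonic oscillators ($X_{i\ne j} = 0$). Each mode
contributes a ladder $\epsilon_i(n) = \nu_i n + X_{ii}(n^2+n)$,
truncated at the last strictly increasing level: beyond that anharmonic
turnover the bound-state picture of the expansion is invalid, so higher
"levels" are not counted. `countStates()` offers two routes:

* **exact** — the per-mode ladders are convolved keeping exact
  real-valued total energies, which are binned only at the end. This is
  an exact direct count at any bin width; its cost is the number of
  states, so it is capped (`maxExactStates`, default $5\times10^6$).
* **grained** — the classic direct-count array convolution: level
  energies are rounded to a fine grain (default 1 cm$^{-1}$), counts
  accumulated by shift-and-add, then aggregated to the requested bin
  width (default 16 cm$^{-1}$). This handles arbitrarily large systems,
  at the cost of grain-level rounding in bin assignment (floor of a sum
  is not the sum of floors).

`method = "auto"` tries the exact route and falls back to the grained
one. The exact route is what makes integer-exact agreement with
brute-force enumeration possible in the test suite; the grained route is
what an 87-mode molecule at 1 eV needs. Counts are stored as doubles
(they grow combinatorially; ratios, which are all the sampler needs,
remain accurate).

## Multicanonical sampling

The 300 K spectrum is obtained by flat-histogram (multicanonical)
sampling of occupation space. The energy range of interest (about 1 eV
by default) is split into non-overlapping windows (default 4) of
16 cm$^{-1}$ bins; each window is sampled by independent walks (default
6) whose histograms and spectral rows are pooled.

Each proposal steps *every mode independently*: down one quantum with
probability $1/D$, up with probability $r/D$ ($r = 1.08$ accelerates
convergence by biasing against the pile-up at low quanta), otherwise
stay; a down-draw at $n_i = 0$ is a stay. $D$ defaults to the number of
modes $N$ but is floored at $\lceil 1+r \rceil$ so one- and two-mode
systems remain proposable ($D$ cancels from the Hastings ratio, so this
floor does not affect the stationary distribution). Proposals leaving
the window or violating $\Delta E_{\mathrm{fund}} > 0$ are rejected.
Valid proposals are accepted with

$$p_\mathrm{acc} = \min\!\left[1,\;
  \frac{\rho(E)}{\rho(E_\mathrm{prop})}\, r^{\Delta n}\right],$$

where $\Delta n$ is the current-minus-proposed total quanta — exactly
the forward/reverse generation ratio of the biased proposal, including
at the $n_i = 0$ boundary (suppressed down-moves contribute identically
to both directions). On *every* step the histogram bin of the current
energy is incremented and the binned stick spectrum of the current
configuration is accumulated into that bin's spectral row; the walk
stops when all reachable bins satisfy $|H_b - \langle H\rangle| /
\langle H\rangle < \alpha$ with $\alpha = 0.25$. Bins with
$\rho = 0$ are excluded from the flatness test as unreachable. Rows are
normalized by their sample counts, and the canonical spectrum at
temperature $T$ is the Boltzmann-weighted row sum with
$w_b \propto \rho_b\, e^{-E_b/k_BT}$ (bin centres, log-space
normalization).

Two small-system pathologies surfaced during validation and are worth
knowing about. First, the top level of a near-turnover ladder is counted
by $\rho$ but is invalid under the $\Delta E_\mathrm{fund} > 0$ rule
(its upward fundamental is non-positive), leaving a reachable-looking
bin that can never be visited, so the flatness condition cannot
terminate. Second, with off-diagonal couplings the *full* energies shift
relative to the separable density by $\sum_{i<j} X_{ij}(n_i n_j + \dots)$,
which can move a bin's only state across a 16 cm$^{-1}$ boundary with
the same effect. Both are finite-size artifacts — at realistic mode
counts every bin holds many states — but they dictate the oracle used in
the acceptance tests: a 3-mode *separable* toy with small
anharmonicities (145 states below 1600 cm$^{-1}$), for which the density
is exact, all windows flatten, and the reweighted 300 K spectrum can be
compared against untruncated exact enumeration (observed integrated
absolute deviation about 1.4%, within the 2% band asserted). A coupled
toy exercises the sampler at looser Monte-Carlo tolerance in the
module tests.

## Kinetic Monte Carlo cooling

Time-dependent spectra come from a kinetic Monte Carlo walk with time
step $dt = 5$ fs. Per step and mode, a downward move is proposed with
$p_{\mathrm{down},i} = q\, n_i\, \nu_i c\, dt$ and an upward move (energy
back-transfer from the bath) with $p_{\mathrm{up},i} = q\,(n_i+1)\,
\nu_i c\, dt\, e^{-\nu_i/k_BT}$, where $c = 2.99792458\times10^{-5}$
cm/fs makes $\nu_i\,dt$ dimensionless and $T = 300$ K is the bath
temperature under the isothermal-bath approximation (the first solvation
shell stays at the bulk temperature). The dimensionless factor
$q = 0.1$ is the model's single adjustable parameter: it scales the
overall cooling rate and nothing else, and per-mode overrides $q_i$ are
supported. Modes are visited in random order; a mode's own proposal
probabilities depend only on its own occupation, so proposal generation
is exact under vectorized drawing, while acceptance is applied per
single-quantum move with the energy updated immediately. Validity bounds
are deliberately *not* enforced: projected nascent configurations can
start outside the bound-state range and must still evolve. Every step
stores the current configuration's binned stick spectrum in the row of
the current time, and negative transition energies contribute zero.

### The acceptance convention

The acceptance factor is where this model family is genuinely ambiguous,
so all three readings are implemented (`acceptanceMode`):

* `as_printed` — $\min[1, e^{-(E - E_\mathrm{prop})/k_BT}]$ with the
  sign exactly as stated in the formulation this package follows. Note
  what it does: an *uphill* move has $E_\mathrm{prop} > E$ and is always
  accepted, while a *downhill* (cooling) move is damped by
  $e^{-\Delta E/k_BT}$ — about $5\times10^{-4}$ for a 1570 cm$^{-1}$
  quantum — so high-frequency cooling stalls, and in the harmonic limit
  the stationary occupation is not thermal.
* `metropolis` — the conventional $\min[1, e^{-(E_\mathrm{prop} -
  E)/k_BT}]$. Because $p_\mathrm{up}$ *already* contains the Boltzmann
  factor, this double-counts the uphill penalty and equilibrates
  colder than the bath.
* `none` — accept every proposed move. The proposal rates alone satisfy
  detailed balance in the harmonic limit
  ($p_\mathrm{up}(n)/p_\mathrm{down}(n+1) = e^{-\nu/k_BT}$), giving
  exactly the Bose-Einstein stationary occupation at the bath
  temperature.

The package default is `as_printed` for fidelity to the source
formulation, but the cooling demonstrations and acceptance tests run
with `none`, the only convention that is provably correct in the
harmonic limit; this choice was made from the analysis above, before any
simulation was scored. With anharmonicity, `none` still uses the
harmonic $\nu_i$ in the rates while the actual level spacing is
$\Delta E_\mathrm{fund}$, so the stationary state is per-mode
Bose-Einstein in the occupations rather than exactly canonical in the
anharmonic energies — consistent with the thermal-sampling reference
used in the tests.

Per-step probabilities above 1 (too-large $dt$ or $q$) are clipped with
a warning rather than an error; at the defaults all realistic modes sit
far below 1. Ensembles average many trajectories (default 576; the
bundled demonstrations use 48 at correspondingly higher noise) per
initial configuration, and a fresh 300 K thermal configuration is added
element-wise to the initial configuration of *every* trajectory,
representing the molecule's pre-excitation thermal content.

## Initial conditions

Three generators produce nascent hot-ground-state configurations:

* **Surface-hopping projection** (`projectHopOccupations`): the hop
  geometry is superposed onto the equilibrium reference by mass-weighted
  rigid-body alignment (Kabsch) — without it, overall rotation would
  contaminate the projections — and the mass-weighted displacement is
  projected onto the equilibrium normal vectors. The available
  electronic energy is partitioned across modes proportionally to the
  harmonic displacement energies $\frac12\omega_i^2 q_i^2$, in integer
  quanta of $\nu_i$ by largest-remainder rounding, so the assigned
  energy lands within one quantum of the target. Velocities at the hop
  are ignored, and the partition rule is one defensible reading among
  several (e.g. direct rounding of $e_i/\nu_i$); it is kept behind a
  single function so alternatives can be swapped.
* **Thermal sampling** (`sampleThermalConfig`): independent per-mode
  geometric (harmonic Boltzmann) draws; at 300 K and mid-IR frequencies
  the difference from the full anharmonic ensemble is negligible, and
  the multicanonical machinery exists where it is not.
* **Statistical (rapid-exchange) sampling**
  (`sampleStatisticalConfigs`): configurations drawn uniformly at a
  given total energy, the limit in which intramolecular redistribution
  completes before any energy leaves the molecule. For small systems the
  in-band states are enumerated and sampled exactly uniformly; for large
  systems a Metropolis walk with the multicanonical proposal and a
  uniform target is used instead (a narrow band is only ergodic through
  compensating multi-mode exchanges, which the whole-configuration
  proposal provides, so bands should be generous for small systems).

## Band analysis

Transient spectra are analyzed per band window: trapezoidal band
integrals (window edges interpolated onto the grid) and the band
expectation frequency $\langle\nu\rangle = \int \nu S\,d\nu / \int
S\,d\nu$, whose rise in time quantifies HGSC reshaping.
$\langle\nu\rangle$ is defined on non-negative net intensity only;
windows dominated by bleach raise an error rather than returning a
sign-corrupted mean. Stick tables use the discrete weighted mean, and
`intensityBreakdown()` reports the fundamental/combination/overtone
intensity fractions of a window.

Kinetics are fitted with the sequential two-step scheme $S_1
\rightarrow S_0^* \rightarrow S_0$ whose populations are closed-form
(including the degenerate $\tau_2 \to \tau_1$ limit, switched at a
relative rate difference of $10^{-9}$ and realized through a split-rate
evaluation accurate to $O(\epsilon^2)$). Fitting uses variable
projection: the amplitudes (and optional baseline) enter linearly and
are solved by pivoting least squares at every evaluation, while
Levenberg-Marquardt searches over $\log\tau_1, \log\tau_2$ — positivity
by construction and no amplitude/lifetime trade-off plateaus. Because
$S_0 = 1 - S_1 - S_0^*$, a free baseline *plus* all three amplitudes is
aliased for data at $t \ge 0$; the default keeps the baseline off and
any aliased column is dropped with the fit flagged. Lifetime standard
errors are conditional on the projected amplitudes; a vanishing
lifetime sensitivity (constant trace) suppresses them. An optional
Gaussian instrument response (a typical ultrafast cross-correlation is
about 200 fs FWHM) is applied analytically via exponentially modified
Gaussians; it is off by default for simulated data, whose trajectories
all start at $t = 0$.

## Synthetic fixtures

No experimental or electronic-structure data ship with the package;
seeded generators stand in for them. `makeToyAnharmonic()` produces
small oracle systems for exact enumeration. `makeCyanLikeSystem()`
emulates the *structure* of a mid-size photoisomerizing chromophore: 87
modes spanning about 50-3200 cm$^{-1}$; 14 active modes carrying the
photoisomerization energy; two dominant marker fundamentals placed at
1570 and 1465 cm$^{-1}$ (C=C- and C-C-stretch-like, centred in the
1550-1600 and 1440-1490 cm$^{-1}$ analysis windows, with the marker
frequencies back-corrected for their own anharmonic shifts so the
ground-state transitions land on the nominal positions); all-negative
diagonal anharmonicities and negative active-block couplings so that
cooling blue-shifts the markers; weak overtone/combination intensities
(3% and about 1% of fundamentals) so all band kinds populate the
window; and the 0.992 frequency scaling. None of its numbers are a real
molecule's data — the fixture reproduces qualitative structure
(marker-band reshaping, active-vs-spectator separation, the
distinguishability of projected vs statistical initial conditions), not
any published spectrum, and passing tests demonstrate correctness of
the machinery on systems of realistic size, not agreement with any
particular molecule. Default demonstration conditions, chosen once: hot
energy 18000 cm$^{-1}$ (the order of a 400 nm photon less prompt
losses) distributed over the active modes, 300 K thermal background,
$q = 0.1$, $dt = 5$ fs, 16 ps of cooling.

Reproducibility relies on R's base Mersenne-Twister with fixed seeds
and call order (same seed, same stream on every platform R supports);
generators are pure functions of their seed.

## Numerical choices and problem sizes

* Half-open energy bins $[bw, (b+1)w)$ relative to the zero point; bin
  centres for Boltzmann weights; nearest-bin assignment of stick
  positions onto the wavenumber axis (default 1 cm$^{-1}$ over
  1350-1850 cm$^{-1}$); Gaussian convolution (default presentation
  width 5 cm$^{-1}$ FWHM) only at presentation time.
* Degenerate line positions are kept as separate sticks; convolution
  handles the overlap.
* The test suite sizes its simulations for exhaustive cross-checking:
  3-4-mode oracles with full enumeration, $10^6$-step single-mode
  equilibrium runs, and 48-trajectory cooling ensembles of the 87-mode
  fixture over 16 ps; the full suite and the acceptance script each
  complete in a few minutes on one core.
* Spectral-matrix persistence is plain TSV (first row the wavenumber
  axis, first column the row coordinate) with sample counts in the
  header; systems and normal modes are JSON; geometries are XYZ. Write
  followed by read reproduces every object to full precision.

## Limitations

* No intramolecular redistribution (IVR) is modelled explicitly; the
  single rate parameter $q$ absorbs the combined IVR+IET kinetics, which
  is adequate exactly when the two have similar time scales. Mode-
  specific $q_i$ are the supported refinement.
* The separable state density ignores mode-mode couplings; below about
  1 eV this is a good approximation for level densities, but it is an
  approximation.
* Upstream quantities — frequencies, the X matrix, anharmonic
  intensities, surface-hopping geometries — must come from external
  electronic-structure calculations; the package neither computes nor
  validates them.
* Solvent effects (hydrogen-bond shifts, the vibrational Stark effect)
  and transient-absorption cross-section corrections are out of scope;
  simulated intensities are gas-phase-like.
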