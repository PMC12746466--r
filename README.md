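# vibcascade

Anharmonic cascade simulation of equilibrium and time-resolved infrared
(IR) spectra of polyatomic molecules, from anharmonic vibrational data
alone.

## The problem

When a photoexcited molecule returns to its electronic ground state
through ultrafast internal conversion (for example after a twisting
photoisomerization), it arrives with one to several eV of vibrational
energy. Over the following picoseconds this *hot ground state* cools into
the solvent, and in time-resolved IR (TR-IR) spectroscopy the energized
bands appear red-shifted and reshape continuously toward higher
wavenumber as cooling proceeds. Kinetic analyses built on static spectral
basis functions cannot describe such moving bands. `vibcascade` addresses
this by simulating the spectra mechanistically from the molecule's
anharmonic vibrational structure, for spectroscopists who have VPT2-level
data (frequencies, the anharmonicity **X** matrix, band intensities) and
want to predict or interpret HGSC transients.

## What it computes

For an occupation configuration **n** = (n₁, …, n_N), energies follow the
Dunham expansion

E(**n**) = Σᵢ νᵢ(nᵢ + ½) + Σ_{i≤j} X_{ij}(nᵢ + ½)(nⱼ + ½)   [cm⁻¹],

with transition energies of fundamentals, first overtones and 1+1
combination bands obtained by direct differencing, and intensities scaled
by the harmonic occupancy factors times ΔE/ΔE⁰. On top of this energetics
layer the package provides:

* **Exact state counting** for separable anharmonic oscillators
  (Stein–Rabinovitch direct count; an exact energy-list route for small
  systems and the classic grained array for large ones) and Boltzmann
  weighting.
* **Multicanonical (flat-histogram) sampling** of occupation space —
  biased per-mode proposals (r = 1.08), Metropolis–Hastings acceptance
  min[1, ρ(E)/ρ(E′)·rᐞⁿ], flatness threshold α = 0.25 — reweighted to
  canonical IR spectra at any temperature.
* **Kinetic Monte Carlo cooling** to an isothermal 300 K bath with a
  single rate parameter q (p_down = q·n·ν·c·dt, p_up with the Boltzmann
  factor), producing time × wavenumber spectral matrices.
* **Initial conditions**: projection of surface-hopping geometries onto
  equilibrium normal modes, thermal sampling, and rapid-exchange-limit
  statistical sampling.
* **Band analysis**: band integrals, the band expectation frequency
  ⟨ν⟩(t) that quantifies reshaping, intensity breakdown by band kind, and
  sequential S₁ → S₀* → S₀ lifetime fits (variable projection).
* **Seeded synthetic fixtures**, including an 87-mode chromophore-like
  system with 14 active modes and marker bands at 1570 / 1465 cm⁻¹.

See the methods vignette (`vignettes/anharmonic-cascade.Rmd`) for the
model, its assumptions, and every numerical choice.

## Worked example

```r
library(vibcascade)

## a two-mode anharmonic system
sys <- vibrationalSystem(
  frequencies    = c(1000, 1500),          # cm-1
  xMatrix        = rbind(c(-10, -5),
                         c( -5, -12)),     # cm-1
  fundIntensities = c(1, 2))

totalEnergy(sys, c(1, 1))                  # 2446  (2500 - 20 - 24 - 10)
transitionEnergy(sys, c(0, 0), "fundamental", 1)   # 977.5

## a hot configuration red-shifts and strengthens the band
stickSpectrum(sys, c(3, 0), window = c(800, 1600))
#   position intensity        kind mode_i mode_j
# 1    917.5  3.754476 fundamental      1     NA
# 2   1458.5  1.979640 fundamental      2     NA

sum(stateCounts(countStates(sys, eMax = 5000, binWidth = 16)))  # 14 states
```

The 917.5 cm⁻¹ line is the fundamental of mode 1 out of n₁ = 3: red-shifted
from 977.5 by 2X₁₁·3 = −60 plus the cross-coupling, and carrying
(n+1) ≈ 4 times the base intensity times the energy ratio — exactly the
signature a hot band shows in TR-IR.

Cooling the 87-mode fixture (reduced sizes for a quick run):

```r
fix <- makeCyanLikeSystem(42)
set.seed(1)
hot <- generateHotConfigs(fix$system, fix$activeModes, 18000, 2)
params <- kmcParams(q = 0.1, dt = 5, tMax = 8000, acceptanceMode = "none",
                    nTrajectories = 8, spectralWindow = c(1350, 1850))
sm <- ensembleSpectra(fix$system, hot, params, thermalT = 300, seed = 7)
kineticTrace(sm, fix$markerWindows$nu15)[c(1, 401, 801, 1201, 1601), ]
#      time  value
# 1       0 1573.9
# 401  2000 1560.1
# 801  4000 1560.3
# 1201 6000 1562.2
# 1601 8000 1562.6
smMetadata(sm)$meanEnergy[c(1, 1601)]      # 19010 -> 2664 cm-1
```

The ensemble-mean energy decays from ~19000 cm⁻¹ toward the 300 K thermal
plateau, and the ⟨ν⟩(t) of the 1550–1600 cm⁻¹ marker band — after the hot
band re-enters the window — climbs monotonically back toward its
equilibrium position: the band-reshaping signature of hot ground state
cooling.

A command-line interface wrapping the same functions ships at
`inst/scripts/vibcascade` (subcommands `synth`, `density`, `spectrum`,
`cool`, `project`, `analyze`; see its header for examples).

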