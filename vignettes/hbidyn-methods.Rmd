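---
title: "Methods: a branching-plane multiple-spawning model of the HBI anion's UV response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a branching-plane multiple-spawning model of the HBI anion's UV response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbidyn)
```

## The physical problem

UV excitation of the deprotonated GFP chromophore (HBI) in the gas
phase promotes the anion to a cluster of metastable excited states: an
optically bright pi-pi* state, a *shape* resonance (the bright doorway
state at the Franck-Condon geometry, trapped above the detachment
threshold by a centrifugal-type barrier) and a *Feshbach* resonance
(bound with respect to its parent neutral configuration and therefore
nearly dark to one-photon ionization into the neutral ground state D0).
The shape and Feshbach states interconvert through a conical
intersection whose branching plane — the gradient-difference direction
`x` and the coupling direction `y` — hosts a Mexican-hat-shaped lower
sheet, the hallmark of a Jahn-Teller-like peaked intersection.  What an
experiment sees in time-resolved photoelectron spectroscopy (TRPES) is
the interplay of three processes on overlapping ~20-50 fs time scales:
internal conversion between the adiabatic states, largely
character-preserving (diabatic) passage through the intersection, and
vibrational relaxation that lowers the anion-neutral gap and shifts the
photoelectron spectrum to lower electron kinetic energy (eKE).

This package reimplements that analysis chain at desk scale.  A
two-coordinate diabatic vibronic model, calibrated to the published
energy gaps, stands in for the ab initio surfaces; everything
downstream — Wigner sampling, multiple-spawning wavepacket dynamics,
state-character bookkeeping, TRPES synthesis, critical-point searches —
is implemented against that model with the same conventions a
full-dimensionality simulation would use.

## The model

With `u = x - fc_offset` (angstrom, relative to the displaced
Franck-Condon reference), all diabats share one harmonic force constant
`k` and differ in origin energy and slope:

$$V_i(u, y) = E_i + a_i u + \tfrac{k}{2}(u^2 + y^2), \qquad
  W(y) = c\,y,$$

for `i` in {shape, feshbach, bright, D0}; the anion ground state is the
undisplaced paraboloid.  The shape/Feshbach block is diagonalized
analytically: with $\Delta = (V_s - V_f)/2$ and $r = \sqrt{\Delta^2 +
W^2}$ the pair adiabats are $M \pm r$, the mixing angle is $\theta =
\tfrac12\,\mathrm{atan2}(2W, V_f - V_s)$, and the nonadiabatic coupling
vector $d = (W\nabla\Delta - \Delta\nabla W)/(2r^2)$ diverges like
1/gap at the intersection.  Oscillator strengths and Dyson norms are
fixed per diabat (the published property table: bright 1.540/0.721,
Feshbach 0.0874/0.345, shape 0.195/0.607) and mix into the adiabats by
eigenvector weight, so their pairwise sums are conserved at every
geometry — this is what lets a single classifier (`classify_states()`)
relabel states consistently anywhere on the surface.

### Calibration

Four printed energy differences pin the model
(`calibrate_from_energies()`):

* shape-Feshbach vertical gap at the FC point: 0.2 eV;
* shape reorganization energy (FC vertical shape energy minus the shape
  minimum energy): 0.66 eV, giving $a_s = \sqrt{2k\lambda}$ and the
  shape minimum at $x^* = \mathrm{fc\_offset} - a_s/k$;
* shape-to-D0 gaps of 1.53 eV at the FC point and 0.75 eV at the shape
  minimum, fixing the D0 origin and slope.

The shape-D0 gaps are quoted on the experiment-aligned scale, i.e. with
the +2.0 eV shift applied to the neutral state; the model stores the
raw neutral surface and applies its `delta_ev` in `gap_report()` and in
the TRPES module, so the same shift is never applied twice.

Several quantities are *conventions*, not constraints, because no
published number pins them.  They were chosen once, on
physical grounds, and are recorded in the model hash:

* `k = 14` eV/A^2 — the order of an aromatic stretch.  With the 1 amu
  mass convention this gives a vibrational period of ~17 fs, consistent
  with the reported ~20 fs transfer time scale.
* `a_f = -a_s` — the Jahn-Teller-like choice; it produces the
  Mexican-hat lower sheet with two inequivalent wells of opposite
  character (shape well on the FC side, Feshbach well beyond the seam),
  matching the reported pair of S2 minima.
* `c = 2` eV/A — strong enough that the interconversion is ultrafast,
  weak enough that the shape well remains a true 2D minimum
  ($k > c^2/|\Delta|$ there).
* The absolute energy origin: the shape diabat at the FC point is
  placed at the pump-window center, 0.216 hartree = 5.8777 eV above the
  anion ground state, so the vertical-gap filter is centered on the FC
  gap.
* The bright spectator sits 1.3 eV below the Feshbach diabat,
  uncoupled and sloped like the ground state; it exists so the
  three-way classifier is exercised and never gains population.

## Initial conditions

`sample_wigner()` draws positions and momenta from the ground-state
harmonic Wigner distribution in mass-weighted coordinates (effective
mass 1 amu; $q \sim N(0, 1/2\omega)$, $p \sim N(0, \omega/2)$ in atomic
units).  `filter_energy_window()` then applies rejection sampling,
keeping draws whose vertical gap to the upper pair adiabat lies within
0.216 +/- 0.0005 hartree — the pump-pulse window, applied to the
optically dominant state.  Draw-and-filter was chosen over constrained
sampling for transparency: the retained fraction is directly comparable
to a brute-force Monte-Carlo estimate, which is exactly how the test
suite checks it.  The number of draws preceding the filter is
configuration (default 4000; the retention fraction, typically ~3%, is
reported).

`initialize_ensemble()` promotes the first 20 retained samples to the
*upper* adiabat — the pump-selected state.  Where the sampled geometry
reverses the shape/Feshbach ordering, the TBF therefore starts with
Feshbach character; on default runs this fraction comes out near 15-25%
at t = 0, mirroring the reported ~20%.  (The alternative rule
`initial_state = "max_f"`, occupying whichever pair adiabat carries the
larger mixed oscillator strength, is also provided; it can never
produce Feshbach-character starts, which is why it is not the default.)
Amplitudes are weighted by the square root of the occupied state's
oscillator strength and normalized so the total population is exactly
1; each TBF founds its own family (independent first-generation
approximation).

## Dynamics

`propagate()` advances each family independently.  Centroids follow
velocity Verlet on the occupied adiabat.  The outer step (default 20
au) is diagnostic and adaptive: a step is rejected, and repeated with
half the time step, if the occupied adiabat's energy changes by more
than 0.16 eV or the frame-to-frame overlap of the 2x2 mixing matrix
drops below 0.7 in absolute value; after 10 consecutive halvings (or a
step-count/underflow backstop) the TBF is discarded and counted — the
analogue of the discarded initial conditions in on-the-fly dynamics.
Inside each accepted outer step the integrator substeps at 0.25 au,
refined further (up to 16x) wherever the pair gap is small, because the
adiabat curvature grows like 1/gap near the intersection; this keeps
per-TBF total-energy drift below ~2e-6 eV over 50 fs on default runs,
and makes the discrete oscillation period match $2\pi\sqrt{m/k}$ to
much better than 0.1%.

Spawning monitors the effective coupling $\Lambda = |d \cdot v|$.  At a
local maximum of $\Lambda$ above 0.2 fs^-1 (a default set so that a
symmetric Jahn-Teller transit spawns at least once, then frozen), a
child is placed on the other adiabat at the parent geometry, with
momentum rescaled along the NAC direction to conserve classical energy;
energetically frustrated attempts are recorded as data.  Children may
spawn back — the model's interconversion is reversible and the
anticorrelated population oscillations depend on it.  A 2 fs per-TBF
cooldown and a family cap of 12 keep the basis finite.

Amplitudes evolve by $i S \dot c = (H - i\dot S)c$ in the nonorthogonal
frozen-Gaussian basis: analytic overlap and kinetic elements, bra-ket
averaged second-order Taylor potential elements at pair midpoints, and
first-order NAC coupling between states (the NAC magnitude is capped at
300/bohr so that measure-zero near-apex midpoints cannot stiffen the
ODE arbitrarily).  Between outer-step endpoints the matrices are
interpolated linearly, with the Hermitian part of $\dot S$ replaced by
the exact derivative of the interpolated overlap — this makes the
propagator exactly unitary in the overlap metric for the interpolated
system, so family-norm error is pure integration error; substep counts
adapt to the generator norm at both endpoints.  Measured family-norm
deviations on default 50 fs runs are below 1e-10.  Near-singular
overlap matrices (condition number above 1e8, e.g. stacked twins after
repeated back-spawning) trigger basis collapse: the younger of the
offending pair is removed and the amplitudes are renormalized, with the
event logged.

Populations are Mulliken-partitioned, $n_j =
\mathrm{Re}[c_j^*(Sc)_j]$, truncated at zero (small negative shares are
a known artifact of Mulliken partitioning in nonorthogonal bases) and
renormalized.  Adiabatic curves are labeled S1 (bright spectator), S2
and S3 (lower/upper pair adiabat) by surface identity, so they remain
continuous even where the relaxing pair sheet transiently crosses the
spectator at large displacements.

## TRPES

Each live TBF contributes one point per frame at its frame delay, with
eKE from $\mathrm{eKE} = h\nu_{probe} - (E_{neut} - E_{anion} +
\Delta)$ (defaults: probe 1.55 eV, shift +2.0 eV) and weight equal to
its Mulliken norm times the occupied state's squared Dyson norm — the
sudden-approximation cross-section proxy; the power is configurable (1
or 2) because published protocols differ on it.  On the calibrated
model this puts the FC-region signal at 3.08 eV and the relaxed shape
signal at 2.30 eV, and suppresses Feshbach-character intensity by
(0.345/0.607)^2 = 0.32 — the quantitative form of "the Feshbach state
is dark".

`convolve_spectrum()` deposits points as separable Gaussians (defaults
20 fs x 0.2 eV fwhm; the temporal resolution is kept at the theoretical
20 fs rather than the 75 fs experimental cross-correlation).  Each
point's *temporal* kernel is renormalized to its mass inside the delay
span: the span is the observation window and every point lies within
it, so truncating kernels at its edges would bend flat signals downward
near the boundaries and corrupt every decay fit downstream.
Energy-axis truncation, by contrast, is genuine loss (points may fall
outside the eKE grid) and is reported as such.

`window_decays()` integrates the spectrum over eKE windows and fits
$I(t) = B + A f(t)$ where $f$ is a trial exponential deposited through
the *same* temporal kernel — forward-model fitting rather than naive
exponential fitting, so the recovered tau is deconvolution-aware and
recovers fixture decay constants of 10, 30 and 55 fs essentially
exactly.  A free onset time is admitted as a second stage when the
zero-onset fit is poor (a window the signal sweeps into rises before it
decays).  Windows with no positive decay amplitude return the sentinel
`tau_fs = Inf` with a flag, never a silent number.

## Critical points

`minimize_surface()` accepts an adiabatic index or a character label;
character tracking re-classifies the three states at each iterate and
follows the requested label, which is how the "S2 shape minimum" is
reached from the FC point where shape is still the upper adiabat.
`find_meci()` minimizes the pair mean energy under an increasing
quadratic penalty on the squared gap; for this model both terms are
exactly quadratic, so each penalty subproblem is solved by a single
Newton step and the gap closes to below 1e-5 eV within a handful of
penalty increments.  The penalty method was preferred over an
analytic-NAC projection variant as simpler and sufficient in 2D.
`mixing_angle_winding()` accumulates half-period-wrapped increments of
the mixing angle around a loop: pi when the loop encloses the
intersection, 0 otherwise.

## Synthetic fixtures

The fixtures bypass dynamics entirely so that analysis-stage
correctness is testable in isolation.  `make_population_fixture()`
switches TBFs from the upper to the lower adiabat at independent
exponential times, making the expected upper population exactly
$e^{-t/\tau}$ while the total norm stays exactly 1.
`make_spectrum_fixture()` drifts the anion-neutral gap linearly (the
synthetic analogue of vibrational relaxation: the default 0.5 eV / 30
fs drift mirrors the reported 2.6 -> 2.1 eV peak displacement) and can
impose a deterministic intensity decay by modulating the per-frame
Dyson norms as $d_0 e^{-t/2\tau}$ — chosen over decaying the norms
because the schema requires unit total population at every frame.

What the fixtures deliberately do *not* emulate: spawning genealogy
beyond parent links, coherences between TBFs (each is its own family),
and any geometry dependence of the drift.  Tests that pass on fixtures
therefore validate the analysis stages, not the propagator; the
propagator is validated separately against closed forms and an exact
split-operator grid solution of the same two-state Hamiltonian.

## Numerical choices at a glance

| Quantity | Default | Why |
|---|---|---|
| force constant `k` | 14 eV/A^2 | aromatic-stretch order; free convention |
| coupling slope `c` | 2 eV/A | ultrafast but bound interconversion |
| effective mass | 1 amu | mass-weighted coordinate convention |
| Gaussian width alpha | m omega / 2 | coherent-state width of the model modes |
| outer step | 20 au | the published default, carries rejection rules |
| VV substep | 0.25 au, gap-refined | 1e-5 eV energy bound near intersections |
| energy-discontinuity threshold | 0.16 eV | published rejection rule |
| mixing-overlap threshold | 0.7 | published diagonal-dominance rule, realized on the 2x2 mixing matrix |
| spawn threshold | 0.2 fs^-1 | >= 1 spawn per JT transit |
| Wigner draws | 4000 | ~3% retention leaves >100 candidates for 20 TBFs |
| eKE grid | 2.0-3.5 eV | published display range |
| convolution | 20 fs x 0.2 eV | published widths |

Problem sizes used by the shipped tests and the acceptance script — 20
TBFs per ensemble, 50 fs horizons, a 96^2-point grid for the exact
benchmark, 4000 Wigner draws — are the package's reference
configuration; they reproduce all conservation targets comfortably and
run in minutes on one core.

## Known limitations

* **No vibrational energy sink.** The model is exactly the 2D branching
  plane, and harmonic.  Intramolecular vibrational redistribution into
  the other 3N-6 modes — the mechanism held mainly responsible for the
  fast decay of the *high*-eKE TRPES window in HBI — has
  no in-scope counterpart: a wavepacket here revisits the Franck-Condon
  region every ~17 fs instead of relaxing permanently, so
  window-integrated intensities plateau rather than decay, and the
  qualitative high-vs-low window decay ordering does not emerge from
  default runs of this model.  The window-ordering machinery is fully
  implemented and demonstrably correct on fixtures with prescribed
  drift; reproducing the ordering from dynamics would require a
  dissipative bath, which is deliberately out of scope.
* Electronic-continuum effects (autodetachment widths, eKE-dependent
  cross sections) are not treated.
* The bright spectator never gains population by construction; only the
  coupled pair hosts dynamics.
* Families never couple (independent first-generation approximation),
  so interference between different initial conditions is absent.
* Mulliken truncation makes per-TBF populations slightly conservative
  when TBFs overlap strongly; family totals are unaffected.
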