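---
title: "Field-cable modelling of epiretinal stimulation with retfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-cable modelling of epiretinal stimulation with retfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An epiretinal prosthesis drives retinal ganglion cells (RGCs) with current
pulses from disc electrodes resting on the inner retinal surface.  Which
cells fire, and at what amplitude, depends on the electrode's distance to
the retina, the state of the tissue under it, and the geometry of the RGC
axons sweeping beneath the array.  `retfield` models this with the
field-cable decomposition used throughout bioelectric modelling:

1. **Field stage.**  The tissue is a passive volume conductor, so the
   potential of a stimulating electrode obeys Laplace's equation
   $\nabla \cdot (\sigma \nabla V) = 0$ with a current source on the
   electrode face.  The stage is linear in the injected current: one
   *unit-field* solution per electrode (V/A) serves every stimulus
   amplitude, which is what makes the later amplitude search cheap.
2. **Cable stage.**  Each RGC is a multi-compartment cable.  The
   extracellular potential at compartment $i$ is
   $V_e^i(t) = A\,w(t)\,u_i$, where $u_i$ is the unit field interpolated at
   the compartment centre, $w(t)$ the dimensionless pulse waveform and $A$
   the amplitude.  Membrane dynamics follow a Fohlmeister–Miller-type
   five-conductance formulation (fast Na, Ca, delayed-rectifier K, A-type
   K, Ca-activated K, plus leak) with internal calcium setting the Ca
   reversal through the Nernst relation.  A neuron "fires" when any
   compartment crosses 0 mV upward.
3. **Threshold and phosphene stage.**  Per-neuron activation thresholds are
   found by bisection to 0.1 µA.  An electrode's threshold is the minimum
   over its target population; the retinal area activated at $k\times$
   threshold is the convex hull of the activated somata, converted to
   square degrees at 288 µm/degree.

## Geometry and its synthetic generator

Patient geometry enters the model through three per-electrode quantities
measured from OCT in clinical practice: electrode–retina distance, retinal
thickness, and fibrotic tissue thickness.  Since no patient imaging ships
with the package, `make_synthetic_retina()` generates a virtual patient as
a 2.5-D height-field: a lateral grid (default 25 × 17 mm at 0.1 mm) with an
inner-surface height, a thickness field and a fibrosis field, plus the pose
of the array substrate plane.  The representation is deliberately layered
rather than a general mesh — the anatomy being modelled is a stack of
retina, RPE, choroid under vitreous, and a height-field voxelizes exactly.

Key generator parameters:

* `standoff_um` (default 100): the *minimum* electrode-face-to-retina gap
  over the array footprint.  Together with `tilt` this reproduces the
  clinically observed spread of electrode-retina distances across one
  array; a tilt of ~0.05 mm/mm spans roughly 50–300 µm over ten columns.
* `thickness_mean_um` (default 200): healthy-ish degenerate retina;
  degeneration patches lower it toward a floor with a smooth cosine edge.
* Fibrosis patches sit on the array surface and are clipped to the local
  gap, so an apposed electrode reports distance = fibrosis thickness, the
  same convention used when reading B-scans of apposed arrays.
* Smooth random fields (Gaussian-filtered white noise, correlation length
  `roughness_scale_mm`) add realistic low-frequency variability; all
  randomness is seeded and reproducible.

What the generator does *not* emulate: OCT speckle and segmentation error,
cystoid edema dynamics, the curved globe (coordinates are a flat retinal
plane), and eccentricity-dependent magnification (a single 288 µm/deg
factor is used).  Tests that pass on this geometry therefore validate the
computational pipeline, not the fidelity of any individual patient model.

## The voxel field solver

`voxelize()` rasterises the geometry onto a uniform cubic grid (default
25–50 µm) with domain labels vitreous (1.5 S/m), retina (0.100 S/m),
fibrosis (0.15 S/m), choroid (0.503 S/m), platinum (9.43 × 10⁶ S/m) and
insulating substrate (0 S/m).  The retinal pigment epithelium is too thin
to resolve, so it enters as a contact impedance: every retina/choroid face
carries a thin-sheet conductance $g = \sigma_{RPE}/t_{RPE} =
0.001/10^{-5} = 100$ S/m² in series with the voxel half-cells.

`solve_unit_field()` discretises with finite volumes: face conductances are
harmonic means of adjacent voxel conductivities, which handles the 4
orders-of-magnitude contrast between layers exactly in the 1-D limit.  Two
numerical choices deserve comment:

* **Electrode supernodes.**  All platinum voxels of an electrode are merged
  into one unknown.  For the active electrode this makes the terminal an
  equipotential disc carrying the injected current; for inactive electrodes
  it imposes the floating-potential condition (one potential, zero net
  current) *exactly*, rather than approximating it with a high-conductivity
  region, and it removes the platinum conductivity from the system
  entirely, which would otherwise dominate the condition number of the
  conjugate-gradient solve.
* **Boundaries.**  The patient model grounds the outer choroid face
  (Dirichlet 0 V) and insulates everything else; the far-field ground
  position is known not to matter for epiretinal sources.  For validation
  against the analytic equipotential-disc solution
  $V(z) = \frac{I}{2\pi\sigma a}\arctan(a/z)$ — which lives in an unbounded
  half-space — a compact grid with insulating walls adds a spurious series
  resistance.  `solver_config(boundary = "open")` therefore ties every
  bottom/side boundary face to ground through the ballistic far-field
  conductance $\sigma A / r$, emulating an unbounded medium.  With it, a
  1.8 mm / 25 µm grid matches the oracle within 5% on-axis beyond two
  voxels, the electrode access resistance converges monotonically under
  grid refinement (≈20% → 5% → 0.8% at 100/50/25 µm), and discrete current
  conservation holds to the linear-solver tolerance.  The residual few
  percent at larger depths is the remaining truncation error of the
  validation domain, not of the discretisation.

The system is symmetric positive definite and solved with
Jacobi-preconditioned conjugate gradients (default relative residual
10⁻⁶; the validation suite uses 10⁻⁸).  Voxels with no conductive
path to ground (e.g. vitreous sealed above a full-width substrate slab) are
detected by connected components and excluded; an active electrode without
a path to ground is an error.

## Neurons

Each electrode receives a target population of 250 somata (100 in the
desk-scale sweeps) spread quasi-uniformly over a 700 µm disc by Lloyd
relaxation — implemented as the discretised centroidal-Voronoi iteration on
a dense uniform sample of the disc, which keeps points strictly inside and
is deterministic under a seed.

Axon trajectories follow the Jansonius nerve-fiber-bundle description: in
polar coordinates around the optic disc (15° nasal, 2° superior of the
fovea), a bundle launched at angle $\phi_0$ follows $\phi(r) = \phi_0 +
b(\phi_0)(r - r_0)^{c(\phi_0)}$ with hemisphere-specific coefficient
functions and $r_0 = 4°$.  The package ships the mean coefficient set used
by common phosphene-modelling software (`beta_sup = -1.9`,
`beta_inf = 0.5`); every constant is exposed in `trajectory_params()`.
Somata exactly on the raphe are assigned to the inferior hemisphere
(deterministic tie-break), and trajectories are truncated if they reach
$|\phi| = 180°$, where the underlying fits are no longer constrained.
`soma_to_path()` inverts the map by a bracketed root-find over $\phi_0$ and
reproduces launch angles to well under 0.1°.

A neuron is an unbranched chain: equivalent-cylinder dendrite (a
documented run-time stand-in for a full arbor), spherical soma 55 µm below
the inner surface, axon hillock, a 40 µm high-sodium-density band (the
axon initial segment — where spikes initiate under extracellular drive),
and an axon that follows the bundle trajectory at 15 µm depth all the way
to the disc circle.  Compartments are ≤10 µm proximally and ≤25 µm along
the axon.  Where the retina has thinned below 100 µm, neurons are removed
by *soma* position — the finest reading of a region-based exclusion rule —
as the model's proxy for ganglion-cell dropout.

Membrane densities per section live in `rgc_membrane_params()`.  The leak
reversal of every section is solved at initialisation (including the
self-consistent resting calcium) so the configured resting potential
(−65 mV) is an exact equilibrium: an unstimulated 200 ms run drifts by
≈10⁻¹³ mV, so resting drift can never masquerade as stimulation.

## Numerics of the cable stage

Integration is semi-implicit with default dt = 10 µs: gating variables
advance by their exact exponential update at the current voltage, then the
voltage solves a backward-Euler step with conductances frozen, i.e. one
tridiagonal (Thomas) solve per step along the compartment chain — the
stepper is compiled (Rcpp) and costs microseconds per step.  Halving dt
changes thresholds by well under 2%.  Extracellular drive enters through
the axial coupling terms of the intracellular potential $V_m + V_e$, so a
uniform $V_e$ correctly produces no drive.

Threshold search uses a single biphasic cathodic-first 0.45 ms pulse by
default rather than the five-pulse 250 ms clinical train: the membrane
model is deterministic and the first pulse decides the threshold, while the
shorter simulation is ~5× cheaper; passing a full train via `waveform`
reproduces the clinical stimulus exactly.  Bisection on [0, 1000] µA to
0.1 µA costs 14 spike evaluations plus two bracket checks; an upper
bracket that never spikes (after geometric expansion to 4× the cap) yields
an `inexcitable` sentinel that downstream maps exclude.  Bisection assumes
activation is monotone in amplitude; upper thresholds / anodal block are
outside the model.

Compartments beyond the solved field subdomain (the distal axon several
millimetres from the electrode) receive $V_e = 0$.  The neglected
potential there is two orders of magnitude below the near-field values
that set the activating function, but it does mean very distal axonal
stimulation is not represented.

## Phosphene sweep and statistics

At amplitude $A = k \times$ threshold the activated set is, under monotone
activation, exactly the neurons with threshold ≤ $kA_{min}$ — no
re-simulation is needed across the 1.2–6× grid.  Hull areas use soma
positions only (the convention of drawing hulls around activated cell
bodies); degenerate sets of fewer than three non-collinear points have
area 0.  The slope of hull area (deg²) against $k$ is the model's
counterpart of the psychophysical growth of phosphene size with amplitude.

On the synthetic standoff sweep (50–300 µm, 100 neurons each) the growth
is strongly linear at small standoffs (R² ≈ 0.995 at 50–100 µm, slopes
1.6–2.5 deg²/×), but at ≥150 µm the activated region fills the entire
700 µm population disc by about 4× threshold and the curve saturates at
the population-hull ceiling (~15.5 deg² for 100 somata), lowering the fit
R² and inflating the fitted slope toward ceiling/Δk ≈ 3.2.  The
compression of the threshold landscape that causes this is the
axon-bundle mechanism itself: somata far from the electrode fire through
their passing axons at only 1.5–2× the central threshold (verified as
regenerative, propagating spikes, not measurement artifacts).  Slopes
reported for this model class (1.05–2.72 deg²/× threshold) correspond to
the non-saturating regime; a larger target population, or electrodes
closer to the retina, keeps the sweep inside it.

The statistical stage mirrors electrode-level practice: electrodes enter
the analysis if visible and below the 677 µA safety cutoff.  The cutoff is
kept as the literal operational constant even though the direct
charge-density computation (1.0 mC/cm²/phase on a 200 µm disc at 0.45 ms)
gives 698 µA — the small difference presumably reflects device amplitude
quantisation, and both numbers are exposed (`max_safe_amplitude()`,
`charge_density()`).  OLS fits (per covariate and multiple) delegate to
`stats::lm`; covariates with no variation (e.g. fibrosis-free arrays) are
reported as n/a, matching how such participants appear in clinical tables.
Linear mixed models with random intercept and slope delegate to
`lme4`/`lmerTest` behind `lmm_threshold()` — re-implementing REML would be
out of proportion to their role here.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run desk-scale configurations
chosen as the package's defaults for interactive use: 50 µm voxels over
2.5 mm subdomains (≈10⁵ unknowns, seconds per electrode), 100-neuron
populations, and a 6-standoff phosphene sweep; production-scale runs
(25 µm, 250 neurons, all 60 electrodes) use the same code paths.  Every
stochastic stage takes an explicit seed, `run_pipeline()` caches unit
fields and thresholds keyed by the parameters that affect them (so
changing only the amplitude grid re-uses everything), and a manifest
records the configuration hash.

## Known limitations

* Thresholds are absolute predictions of a cell-physiology model and sit
  well below clinical perceptual thresholds, as multi-compartment RGC
  models are known to do; comparisons against perceptual data should be
  correlational, not absolute.
* The raphe of the trajectory model is the horizontal through the optic
  disc, and its coefficient functions are not symmetric about it; bundle
  geometry within ~1° of the raphe is the least reliable part of the map.
* No inner-retinal network (bipolar/amacrine/horizontal cells): the model
  assumes direct RGC activation, appropriate for epiretinal but not
  subretinal geometries.
* The insulating-wall patient domain slightly inflates absolute potentials
  on compact subdomains; activating-function differences, which set
  thresholds, are much less affected.
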