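---
title: "Models and methods behind deerscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deerscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deerscape)
```

`deerscape` chains five analyses that together map the conformational
landscape of a two-domain, hinge-bending protein: structure handling and
spin-tag modelling, DEER trace simulation and inversion, state
classification, oligomer tag-dilution statistics, and Michaelis–Menten
kinetics. This vignette explains the models, the tunable parameters and the
judgement calls, in enough detail that a user can decide when to trust the
defaults and when not to.

## Structures, numbering and geometry

Coordinates are held internally in Å (the PDB native unit); every distance a
user sees is in nm. Parsing goes through bio3d with a stricter pre-scan:
malformed fixed-column records fail with the offending line number,
insertion codes are rejected (none of the structures this workflow targets
use them), and alternate locations collapse to the highest-occupancy
conformer (first wins on ties). Residue numbers are shifted onto the
ancestral-alignment convention by `renumber()`; the built-in table maps
3KBR by −25 and 5HPQ/6BQE/5T0W/5TUJ/5JOS/6WUP by −11, and re-applying an
offset is an error rather than a silent double shift.

The geometric primitives are a signed IUPAC dihedral and NeRF placement of
an atom from a bond length, bond angle and torsion. Both are exact inverse
operations of each other (tested over 1,000 random frames at 1e-6°).
The radius of gyration is mass-unweighted over non-hydrogen atoms — the
convention is configurable via a selection predicate because different
simulation packages weight differently, and nothing downstream depends on
the choice beyond an overall offset of the compactness axis.

## The rigid tag model

The propargyl-DO3A-Gd(III) tag is built as a rigid rotamer on an
azidophenylalanine (AzF) site from an internal-coordinate template: the
aromatic ring, the 1,2,3-triazole formed by the click ligation, a short
linker into the cyclen cage, and the Gd ion as a pseudo-atom. The
chemistry-defining torsions are the published convention: χ1/χ2 chosen by a
least-clash scan of the ring, χ6 = 180°, and χ9 = −140°, χ10 = 70° so the
ion folds back towards the coordinating triazole nitrogen. All other
torsions are frozen at template values; bond lengths and angles are
idealized (aromatic C–C 1.39 Å, C–N 1.40 Å, Gd 2.4 Å from its coordinating
nitrogen). The two frozen cyclen torsions were calibrated once so that the
Cα→Gd arm is ≈ 1.04 nm with the ion ≈ 4 Å from the triazole nitrogen, inside
the 1.0–1.1 nm range that rigid Gd tags of this family span; the deposited-
structure checks in the acceptance suite exist to validate exactly this
calibration whenever the coordinate files are locally available.

The clash rule is deliberately force-field-free: a probe heavy atom within
2.5 Å of any protein heavy atom outside the tag residue counts one clash,
and the (χ1, χ2) pair minimising the count wins, ties broken by the smaller
χ1 then χ2 on a 10° grid. This mimics choosing the least-clashing rotamer in
an interactive mutagenesis tool while remaining exactly reproducible.
Ensemble mode sweeps χ9 on a 10° grid (the spec of "any angle" needs a
resolution; 10° makes the Gd circle positionally converged well below the
0.02 nm distance grid) crossed with χ10 ∈ {−60°, 60°, 180°}, excludes
conformers with any clash, and if that excludes everything relaxes the
threshold to the observed minimum with a warning — a site tight enough to
clash in every rotamer still deserves a prediction, just a flagged one.

## DEER forward model and inversion

The weak-coupling kernel uses D = 52.04 MHz nm³ (free-electron g for both
spins; the <1% Gd(III) deviation is far below the distance-grid
resolution), and neglects pseudo-secular S = 7/2 terms, as is standard for
W-band Gd–Gd work above 2.5 nm. The orientation integral is evaluated by
composite Gauss–Legendre quadrature whose node count scales with the
dipolar phase (at least 216 nodes; ~16 rad per 24-node panel). A fixed
201-point rule would be accurate only out to moderate phases: at r = 1.5 nm
and t = 8 µs the integrand sweeps ~2,300 rad and a fixed rule is wrong by
~0.2, which is why the node count adapts. Kernels are cached per grid, so
the cost is paid once per analysis.

Default grids: r from 1.5 to 8.0 nm in 0.02 nm steps, t sampled at 8 ns.
Traces are assumed pre-corrected (t = 0 first point, real part); a third
input column is ignored with a warning.

Background correction fits `A · exp(−(k t)^(d/3))` to the final 60% of the
trace with d fixed at 3 (homogeneous 3D). Fitting d jointly is offered but
off by default: on a dipolar-contaminated tail, (A, k, d) are effectively
collinear and the joint fit wanders (we measured it converging to d ≈ 1
with a vanishing modulation depth on unremarkable synthetic traces). The
modulation depth comes from the fitted plateau, λ = 1 − A.

`tikhonov_invert()` minimises ‖Kp − F‖² + α²‖Lp‖² under p ≥ 0, where L is
the second-difference operator. The stacked problem is reduced through its
normal equations and solved by Lawson–Hanson NNLS (pracma); the solution is
renormalised to a unit-integral density. α comes from the maximum-curvature
corner of the (log residual, log seminorm) L-curve over a log-spaced grid
spanning 1e-2 to 1e3. The upper end is a considered choice: far beyond the
noise-floor elbow the non-negative solution collapses towards the smoothest
vector and the L-curve develops a second, artifactual bend whose curvature
can exceed the genuine corner; bounding the grid at the elbow keeps the
corner detection on the fidelity–smoothness trade-off it is meant to find.

A single refinement pass follows (`deer_analyze()`): given the inverted
dipolar shape, λ and k are re-fitted jointly on the whole trace, and the
refined form factor is inverted again. This removes a measurable bias —
long-period oscillations from distances near 4.4 nm leak into any tail-only
background fit, and on two-Gaussian benchmarks the refinement brings the
recovered weight ratio from as far as 1.24 back into [0.96, 1.11] across
seeds.

### Uncertainty band and its semantics

`validate_uncertainty()` re-runs background correction and inversion over a
grid of background windows (default 8 between 35% and 75% of the trace),
background dimensions {2.5, 3, 3.5} and noise replicates, holding α fixed
at the point estimate's value, and reports the pointwise mean ± 2 s.d.,
clipped at zero and widened where needed to contain the point estimate.
This is a *dispersion* band — it answers "how sensitive is the distribution
to the analysis choices and the noise" — not a confidence band for the true
density. Because Tikhonov smoothing biases peak tops down and shoulders
out, a sharp true density will sit outside the band at a sizeable minority
of grid points no matter how the perturbations are widened; in our
simulations (two 0.15–0.2 nm Gaussians, snr 20–50) pointwise truth coverage
plateaus near 80%. The tests assert that measured behaviour rather than a
nominal confidence level.

Reliability zones mark where a trace of length t_max can support the
recovered features, each threshold scaling as t_max^(1/3) with constants
(3.2, 4.0, 4.6, 5.2) nm µs^(−1/3) — calibrated to the rule of thumb that a
2 µs trace supports a reliable distribution *shape* to about 4 nm, hence a
4 µs trace to about 5 nm, with width, mean and detectability extending
progressively further.

## State classification

States are windows on the inter-site Cα–Cα axis (and, for distributions, on
the modelled Gd–Gd axis); membership is closed on both ends, a distance in
more than one window is `ambiguous`, in none `unassigned`. Overlaps are
surfaced rather than resolved by first match because the one overlap that
matters in the motivating system (open vs wide-open between ~3.3 and
3.7 nm) is genuinely unresolvable from one distance and needs the PCA step.
`pca_disambiguate()` takes the ambiguous frames' Cα coordinates, superposed
on the fixed (large) domain by least-squares rigid fit, runs PCA on the
flattened coordinates and splits along PC1 with a deterministic 2-means
initialised at the extreme scores; clusters map to states by comparing
their mean Cα–Cα distance with the unambiguous state means. What exact
features the original analysis fed to PCA is unstated; superposed Cα
coordinates are the assumption recorded here, and with 6σ-separated
synthetic clusters the split recovers the generating labels at ≥98%.

For distributions, the population of a state is the integral of the density
over its Gd–Gd window; mass under overlapping windows is split equally
among them (the qualitative window-versus-peak comparison in the source
analysis does not prescribe a rule; equal split is the least-informative
formalisation) and out-of-window mass is reported as `unassigned`.

## Oligomer statistics and kinetics

A trimer whose monomers are tagged independently with probability p carries
k tagged monomers with probability C(3,k)·p^k·(1−p)^(3−k); at the tenfold
dilution used for the trimeric enzyme (p = 0.1) this gives 24.3%, 2.7% and
0.1% for k = 1, 2, 3 — the arithmetic behind diluting away inter-chain
distances. Independence assumes monomer exchange equilibrates before
freezing; no cooperativity parameter is offered.

Kinetics follows the assay's quantitation: A320 → product concentration via
Beer–Lambert with ε = 17,500 M⁻¹cm⁻¹, rates as least-squares slopes over
points below 20% substrate conversion (a regression rather than a two-point
difference; both are compatible with an end-point protocol and the
regression uses all compliant aliquots), blank slope subtracted.
Michaelis–Menten fits are unweighted nonlinear least squares (the source
table's own weighting is unstated) with starts KM₀ = median(S),
vmax₀ = 1.2·max(v); standard errors come from the Jacobian-based covariance
and kcat/KM errors propagate in quadrature. On noiseless data the fit is
exact to 1e-6 relative for any positive truth; on 5% additive noise the
reported SEs track the Monte-Carlo spread within ~10%.

## The synthetic-data generators

The generators exist so that every stage has ground truth. They emulate the
*observables* of the study system, not its physics:

* `make_two_domain_structure()` builds two rigid Cα helices whose inter-site
  distance follows the closed form d(θ) = |s₁ − R_y(θ)s₂|, strictly
  increasing from 2.6 nm (θ = 0) to ~5.5 nm (θ = 120°) — covering closed
  through wide-open. Tag sites carry real backbone so the tag model runs its
  genuine code path. There are no side chains, no sequence, no solvent.
* `make_trajectory()` drives the hinge with a Markov chain (initialised from
  its stationary distribution) plus Gaussian jitter on the inter-site
  distance; the radius of gyration comes from the same rigid geometry in
  closed form. Defaults mirror the study's sampling: 0.1 ns stride, 5,000
  frames (the scale at which occupancy recovery to ±0.05 is tested).
* `make_deer_dataset()` draws traces from Gaussian-mixture truths with
  defaults matching the measurement regime: t_max = 4 µs, 8 ns steps,
  λ = 0.4, k = 0.1 µs⁻¹, d = 3, snr 50.

Passing tests on these generators therefore demonstrates correctness of the
analysis chain under known truth — kernel accuracy, inversion resolution at
1.2 nm peak separation, population recovery, split accuracy — but not
robustness to the things real data add: orientation effects, multispin
contributions in concentrated oligomers, imperfect phase/zero-time
correction, tag mobility beyond the rotamer model, and force-field realism
of trajectories. The deposited-structure comparisons are the one bridge to
real data and run whenever those files are supplied locally.

## Degenerate inputs and numerical edges

Collinear frames make dihedrals and NeRF placement undefined and raise
errors rather than returning garbage. Distances exactly on a window edge
belong to the window (closed intervals). The L-curve falls back to the
median α with a warning when no positive-curvature corner exists. NNLS
guarantees a non-negative density; a zero-integral solution (all mass
rejected) is an error. Markov specifications are validated row-stochastic;
generator outputs are bit-reproducible functions of (spec, seed).
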