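---
title: "From etch pits to absorbed dose: methods behind alphadosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From etch pits to absorbed dose: methods behind alphadosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphadosim)
```

## The measurement problem

Diffusing alpha-emitter radiation therapy (Alpha-DaRT) uses interstitial
sources loaded with Ra-224.  The source surface releases the short-lived
daughter Rn-220, whose progeny (Pb-212, Bi-212, Po-212, Tl-208) diffuse
millimetres into tissue and kill cells through their alpha decays.  An
in-vitro surrogate replaces the spatial gradient with a *daughter medium*
(DM): culture medium incubated with Ra-224 sources until it carries
Pb-212 and its progeny in secular equilibrium, then applied to a cell
monolayer at known dilutions.

The dosimetric chain this package implements answers: given that a CR-39
track detector under the monolayer records a mean of $p$ etch pits per
nucleus footprint, how many alpha particles actually traversed each
nucleus, what absorbed dose did the nucleus receive, and what does the
clonogenic survival curve look like on that dose axis?

Three facts make the conversion non-trivial:

1. CR-39 registers only a fraction of the alphas that strike it
   (about 50–60% for etched detectors; shallow-incidence tracks leave no
   countable pit);
2. some alphas hit the nucleus but never reach the detector (they stop
   inside, or travel upward); and
3. emitters diffuse everywhere, including into the nucleus itself.

## Decay-chain kinetics

Atom counts along the chain obey the linear system
$\dot N_i = -\lambda_i N_i + \sum_j b_{ji}\lambda_j N_j$ with decay
constants $\lambda = \ln 2/T_{1/2}$ and branching fractions $b$.
`bateman_activities()` evaluates the closed-form Bateman solution
path-by-path.  For a path with constants $\lambda_1,\dots,\lambda_k$ the
classic sum $\sum_j e^{-\lambda_j t}/\prod_{m\ne j}(\lambda_m-\lambda_j)$
is, up to sign, a divided difference of $e^{-xt}$ over the $\lambda$'s.
We evaluate that divided difference in its generalized (confluent) form:
nodes equal to within $10^{-9}$ relative use the derivative rule
$f^{(m)}(\lambda)/m!$ instead of the divided quotient.  This keeps
degenerate and near-degenerate chains (equal half-lives) numerically
stable without special-casing, and handles the stable end member as an
ordinary node at $\lambda = 0$.  The unit tests pin this solver against
an independent stiff ODE integration (`deSolve::lsoda`) of the same rate
equations to four significant digits, across eleven orders of magnitude
in $\lambda$.

Nuclear data (half-lives, branchings, alpha energies keyed to the NuDat3
evaluation) ship as an editable table, `ra224_chain()`:
Ra-224 (3.63 d) → Rn-220 (55.6 s) → Po-216 (0.145 s) → Pb-212 (10.64 h)
→ Bi-212 (60.55 min), which branches 36% to Tl-208 (alpha, treated as a
single 6.05 MeV line) and 64% to Po-212 (0.299 µs; 8.785 MeV alpha), all
terminating at stable Pb-208.  The 0.145 s member is Po-216 — chain
descriptions occasionally misprint it as "Po-226".  Because every
unstable path ends at Pb-208, total atoms are conserved, which the tests
verify at each time point.

Two simplifications, both deliberate:

* alphas emitted during the 6-h DM *preparation* (Rn-220/Po-216 decays
  inside the stock) are excluded from the exposure inventory — those
  nuclides are gone long before the medium reaches the cells, so the
  cells see the post-Pb-212 part of the chain;
* the beta emissions (Pb-212, Bi-212, Tl-208) are carried in the
  inventory but not transported.  The low-LET contribution to cell
  killing is negligible next to the alpha component at these doses, and
  this package documents that omission rather than modelling it.

With Bi-212/Po-212 in equilibrium with Pb-212, exactly one alpha follows
each Pb-212 decay (branch split 0.6406 : 0.3594 between the 8.785 and
6.05 MeV lines), so the exposure inventory integrates the decaying
Pb-212 activity:
$N_\alpha = c\, a_0 V (1 - e^{-\lambda_{Pb} T})/\lambda_{Pb}$
for dilution $c$, initial concentration $a_0$, volume $V$, window $T$
(`dm_alpha_inventory()`).  The absolute $a_0$ of the 1× medium is never
measured directly; it enters the analysis only as a scale anchored by
the measured pit counts, and all pit-to-dose conversions are
density-independent ratios.

In a medium continuously fed by a source, Pb-212 activity approaches its
asymptote as $1 - e^{-\lambda_{Pb} t}$ (`pb212_buildup_fraction()`):
50% at one half-life, 79% at 24 h — the exposure conditions stabilize
roughly one day after the source is introduced.

## Monte-Carlo microdosimetry

### Geometry and transport

The model is a water-equivalent slab ($\rho = 1$ g/cm³, default depth
2000 µm) with the CR-39 plane at $z = 0$ and the nucleus as a right
circular cylinder of footprint area 280 µm² resting on the plane.
Decay positions are uniform in the slab *including the nucleus volume*;
directions are isotropic; energies are drawn from the two-line spectrum.
Tracks are straight lines transported in the continuous-slowing-down
approximation from an embedded range–energy table (8.785 MeV → ≈86 µm,
6.05 MeV → ≈47 µm in water); no straggling or scattering, which is a
sub-percent effect at these scales.  Energy deposited in the nucleus is
$E(\text{entry}) - E(\text{exit})$ along the chord, with $E = 0$ if the
track stops inside.

Two numerical choices matter:

* **Exact inverse ranges.**  A monotone (Hyman) spline through the
  embedded table is sampled onto a dense grid once per session, and both
  $R(E)$ and $E(R)$ interpolate linearly on that same grid, so they are
  exact mutual inverses and residual-range transport satisfies the
  semigroup identity to $10^{-6}$ MeV.
* **Importance restriction in depth.**  A decay more than one alpha
  range above both the detector and the nucleus can contribute to no
  tally, so sampling is restricted to the union of the two relevant $z$
  bands and every extensive tally is rescaled by the sampled length.
  This is exact (not approximate) and buys a ~20× effective speedup for
  the default 2-mm slab.

### Registration model and calibration

CR-39 does not record every alpha that strikes it.  The package uses
the simplest solid-state track detector criterion: a pit registers iff
the dip angle (track vs. detector surface) is at least a critical angle,
optionally with an arrival-energy window.  For a thick uniform slab the
plane-crossing tracks have $\sin(\text{dip})$ distributed with density
$2u$, so the registered fraction is $1-\sin^2\theta_c$ in closed form —
the Monte Carlo reproduces this, which doubles as a self-test.

Two model knobs are deliberately *calibrated* rather than measured,
because the reference analysis states its outputs (registration
efficiency 50–60%; total hits ≈ 3× detected pits; 1.10 ± 0.23 Gy at
4.7 pits/nucleus) but not its internal mechanism:

* `critical_dip_angle = 40°`, giving a registered fraction of 0.59,
  inside the stated 50–60% band;
* `nucleus_thickness = 5.25` µm (a realistic height for an adherent
  HeLa nucleus of 280 µm² footprint), fixed on a simulation grid so that
  the hit-to-pit ratio (≈3.3) and the absorbed dose at 4.7 detected
  pits (≈1.10 Gy) land jointly on the reference values.

Both are exposed in `geometry_config()` / `registration_model()` and the
calibration is reported here, not hidden.  The etched-layer thickness of
the real detector is not modelled explicitly; it is absorbed into the
critical angle.

### Tallies

`run_microdose()` reports, with standard errors: hits per nucleus
(including tracks stopping inside and upward movers), detected pits per
nucleus — defined, as in the bench analysis, as pit areal density ×
nucleus footprint area, with the direct within-footprint count as a
cross-check — the hit-to-pit ratio, energy per nucleus, specific energy
per hit, absorbed dose, and the registration efficiency among
plane-reaching tracks.  `dose_per_detected_pit()` turns a tally into the
two conversion factors (Gy/pit and hits/pit) with delta-method errors.

The tally layer is validated against closed-form oracles rather than
against itself: the Cauchy hit rate on a convex body
($n_v \bar R S/4$ entries plus $n_v V$ internal emitters), the one-sided
plane-crossing rate $n_v \bar R/4$, the deep-medium equilibrium dose
$n_v \bar E/\rho$ (within 2%), the half-equilibrium dose at the
non-emitting bottom boundary (within 5%), and the Poisson dispersion of
hits across exposures (index within [0.9, 1.1]).

## Calibration fits and survival

Dilution calibrations (`fit_linear_calibration()`) are origin-constrained
by default — zero activity means zero excess response, matching the null
result of sham-source exposures — with `r2` reported as the squared
correlation of observed vs. fitted response so it stays in [0, 1] for
either constraint.  Background subtraction is supported but defaults to
zero.

Survival curves of high-LET exposures are shoulderless, so
`fit_exponential_survival()` regresses $\ln SF$ on dose through the
origin: one parameter $k$, $D_0 = 1/k$, with a 95% CI from the
regression and $r^2$ on the log scale.  A weighted variant (inverse
delta-method variances) sits behind a flag; the default is unweighted,
matching the one-parameter form the assay is usually summarized by.
Uncertainty propagation throughout is first-order delta method, with a
parametric bootstrap as the validation oracle in the tests (agreement
within 5%).

`run_full_pipeline()` chains the stages: calibration slope → pits per
nucleus per dilution → MC conversion to hits and dose → plating
efficiency from the sham limb → pooled surviving fractions → exponential
fit → $D_0$ and average dose rate.  An all-zero pit table is refused
before any conversion rather than propagating zeros.

## The synthetic-data generator

`generate_experiment()` produces the three tables the pipeline consumes,
from known truth (`truth_params()`):

* **pit counts** per observation field (98,826 µm²): Poisson with mean
  linear in dilution.  The per-field noise model is not dictated by the
  assay, so Poisson — independent registrations of independent decays —
  is the assumed default;
* **focus counts** per nucleus: Poisson with mean = hits × foci-per-hit,
  with nucleus areas drawn from the measured distribution
  (280 ± 39 µm²).  Focus formation is modelled phenomenologically
  (foci ∝ hits), not by damage-track structure, because the empirical
  relation is linear.  A negative-binomial option exists because the
  observed focus SD (14.5 at mean 47.2) exceeds Poisson — partly
  explained by area variability alone;
* **colony counts** per dish: Binomial(plated, PE × exp(−D/D₀)), with
  plated numbers scaled so each dish expects ≈300 colonies (capped at
  2×10⁶ cells), and a sham limb at dilution 0.

`paper_like_defaults()` anchors the truth to the reference conditions:
the 1/2× limb averages 4.7 pits and 47.2 foci per nucleus (≈10 foci per
detected pit, ≈3 per hit), dose/pit 1.10/4.7 Gy, $D_0 = 1/5.09$ Gy.  The
plating efficiency, which the assay description never states, is set to
0.70 — typical for HeLa clonogenic assays.  Datasets are byte-identical
under a fixed seed.

What the generator does *not* emulate — and therefore what passing
recovery tests do not establish about real data: spatial dose gradients
around a physical source (no governing spatial model is implemented),
microscopy and segmentation artefacts, pit overlap saturation near the
source, day-to-day source-activity drift (handled separately by
`decay_correct_activity()`), and any bystander or dose-rate biology.
Recovery tests show the *statistical* chain is unbiased and
correctly-sized noise propagates sanely; they cannot validate the
physics calibration, which rests on the oracle checks above.

## Problem sizes and determinism

The default simulation is $10^6$ decays (seconds on one core; conversion
factors stable to ~1–2%).  The test suite uses $10^6$ for the
calibrated-geometry checks, $6{-}8 \times 10^6$ for the 2%-level
fluence/equilibrium oracles, and 25 generator seeds for pipeline
recovery (observed $D_0$ error ≤ ~5%, asserted ≤ 15%).  All randomness
flows through R's generator seeded once per run; identical
configuration and seed reproduce tallies exactly, chunking included.

## Known limitations

* Straight-track CSDA transport in pure water; no straggling, no
  scattering, no medium/plastic interface physics at the detector.
* The registration model compresses all etch physics into one angle
  (plus an optional energy window); efficiencies are reproduced, pit
  morphology is out of scope.
* The low-LET (beta/gamma) dose is documented as negligible, not
  computed.
* Dose is averaged over a single nucleus geometry; nucleus-to-nucleus
  area variation enters the generator but not the transport.
* The survival model is purely exponential by construction; shoulder
  (linear-quadratic) behaviour is out of scope.
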