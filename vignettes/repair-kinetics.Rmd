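---
title: "Modelling double-strand-break repair dynamics across scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling double-strand-break repair dynamics across scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbr)
```

`dsbr` models an inducible double-strand-break (DSB) repair assay in budding
yeast in which successful repair reconstitutes a GFP gene. This vignette is
the package's account of the science behind the code: the model and its
assumptions, the inference machinery, what the synthetic generators do and
do not emulate, the numerical choices, and the design decisions that were
genuinely open.

## The three-state mean model

After endonuclease induction a cell is in one of three states: *modified*
(intact cassette, count $m$), *broken* (cut chromosome, count $b$) or
*repaired* (reassembled GFP gene, count $g$). Four assumptions define the
kinetics:

1. modified and repaired cells divide at the same constant per-capita rate
   $\alpha$ (the insert does not hinder replication);
2. modified cells switch to the broken state at rate $\beta$;
3. broken cells are checkpoint-arrested — they do not divide — and leave
   the state only by repair, at rate $\rho$;
4. during a lag $\tau$ after induction (the metabolic switch from glucose
   to galactose), nothing happens: no growth, breakage or repair.

The expected counts then satisfy, on the shifted clock $s = t - \tau$:

$$
\frac{dm}{dt} = (\alpha-\beta)\,m, \qquad
\frac{db}{dt} = \beta m - \rho b, \qquad
\frac{dg}{dt} = \alpha g + \rho b .
$$

Because the system is linear, the same equations describe both the ensemble
average over many small founder populations and the large-population limit
of one culture — this is what licenses using rates fitted on bulk molecular
data to predict single-lineage statistics. Two constants connect states to
observations: a delay $\gamma$ (default 3 h) between completed repair and
detectable fluorescence, and a Gaussian noise scale $\sigma$ on measured
band fractions. All rates are per hour, all times in hours.

Constant per-capita division is a deliberate coarse-graining: real cell
division is age- and size-structured. For the population moments and the
qualitative fluctuation structure studied here it is sufficient, and it is
what keeps the model linear.

## Solving the model: two independent routes

`repair_solution()` evaluates the exact solution through explicit
exponential formulas; `solve_repair_ode()` integrates the same system with
`deSolve::lsoda` at relative tolerance $10^{-9}$ and absolute tolerance
$10^{-12}$. The duplication is intentional: the two routes are algorithmically
independent, so their agreement (checked in the test suite over random
kinetics to better than $10^{-6}$ relative error, and against a
matrix-exponential oracle) validates both.

The closed form requires care where exponential modes collide. Writing
$\delta = \alpha - \beta + \rho$, the broken and repaired counts contain
divided differences of exponentials that degenerate when $\delta \to 0$.
All such terms are evaluated through `expm1`-based stable forms, and below
$|\delta| < 10^{-8}$ the divided difference is replaced by its analytic
derivative limit at the midpoint exponent, exact to second order in
$\delta$ — far below the accuracy demanded anywhere else. The lag is
implemented by time-shifting the clock, never by ramping rates, and at
$t = \tau$ exactly the state equals the initial condition (closed-interval
convention).

The default initial composition is $(m, b, g) = (1, 0, 0)$ in fraction
units; a nonzero initial repaired fraction `g0` (e.g. 0.4) emulates strains
whose leaky promoter completes some repair before induction.

## Bayesian inference of the rates

The data are Southern-blot-style fraction time courses: at each sampling
time (default 0–12 h every 2 h) the observed broken and repaired fractions
of the population. The likelihood assumes each observed fraction is the
model prediction plus independent Gaussian error with one shared scale
$\sigma$. Two concretizations deserve note:

* **Which components are scored.** The three fractions sum to one, so they
  carry two degrees of freedom. We score the two measured bands (broken,
  repaired) and treat the modified fraction as the implied complement;
  scoring all three would triple-count the compositional constraint. The
  independence assumption is, strictly, false for renormalised band data —
  robustness to that misspecification is tested explicitly (below).
* **No clipping.** Observed fractions outside $[0,1]$ (possible under
  band-level noise) are scored as-is; the Gaussian has unbounded support.

Priors are independent gammas parameterised by mean and coefficient of
variation (shape $= 1/\mathrm{CV}^2$, scale $= \text{mean}\cdot\mathrm{CV}^2$):
$\alpha \sim (\ln 2/3\ \mathrm{h^{-1}},\ \mathrm{CV}\ 1)$ around a 3 h
doubling time; $\beta$ and $\rho \sim (\ln 2/6\ \mathrm{h^{-1}},\ \mathrm{CV}\ 2)$,
identical so that neither breaking nor repair is presumed rate-limiting;
$\tau \sim (4\ \mathrm{h},\ \mathrm{CV}\ 0.1)$, narrow because the lag is
known independently; $\sigma \sim (\ln 2/3,\ \mathrm{CV}\ 2)$,
dimensionless. The lag is assumed common to all conditions:
`propagate_tau_prior()` moment-matches a fitted $\tau$ marginal into a
gamma prior for reuse (CV floored at $10^{-3}$ to avoid degenerate
distributions); we fit it on the efficient reference condition, a choice
that is arbitrary among well-identified conditions.

`fit_repair_model()` samples with an adaptive random-walk Metropolis chain
in log-parameter space (positivity by transform, with the exact Jacobian).
After a fixed-proposal warm-up the proposal covariance tracks the running
empirical covariance scaled by $2.38^2/5$. Defaults: 4 chains, 10,000
iterations each, first half discarded, leaving 5,000 retained draws per
chain. Diagnostics are split-$\widehat{R}$ and effective sample size
computed from the standard formulas (Geyer initial positive sequence);
thresholds $\widehat{R} \le 1.05$ and ESS $\ge 200$ per parameter. A fit
that misses them is returned with `converged = FALSE` and a warning —
never silently.

What to expect from such fits, as reproduced by the calibration study in
`scripts/acceptance.R`: $\beta$ and $\rho$ are strongly constrained (the
posterior SD typically several-fold below the prior SD) and their 95%
intervals cover generating values at the nominal rate; $\alpha$ is poorly
determined, because fractions contain no absolute-number information. One
caveat the study surfaces honestly: in occasional replicates (roughly one
in twenty at $\sigma = 0.05$) noise flattens the broken-band transient, the
data then bound $\rho$ only from below, and the tail-conditioned posterior
of the heavy-tailed $\rho$ prior comes out *wider* than the prior. "The
posterior shrinks" is a typical-case property, not a guarantee per dataset.

Robustness to the error model is tested by generating data where noise hits
the band intensities before renormalisation (`noise_mode = "band"`), which
induces correlated, non-Gaussian fraction errors; interval coverage under
this misspecification stays within a few points of the correctly-specified
case.

## The stochastic lineage model

A microwell holds a handful of cells, where demographic fluctuations
dominate; the ODE is replaced by the continuous-time Markov jump process
with per-capita event rates $\alpha m$ (modified division), $\beta m$
(break), $\rho b$ (repair), $\alpha g$ (repaired division), simulated
exactly with the direct Gillespie algorithm (`sim_lineage()`). Populations
stay below a few hundred cells over 24 h, so exact simulation is cheap and
tau-leaping would buy nothing. Frames are sampled by
last-event-before-frame (piecewise-constant interpolation), matching how
time-lapse counting works; the default grid is 73 frames every 20 min over
24 h. The linearity of the process makes the ODE its exact expectation,
which the suite verifies: over 20,000 lineages the ensemble mean stays
within three Monte-Carlo standard errors of the ODE at essentially every
frame.

**GFP observation.** The delay $\gamma$ was estimated at the population
level, so the simplest observation layer is the count shift
$N_\mathrm{GFP}(t) = g(t-\gamma)$. Implementing it revealed a structural
flaw: dividing the delayed numerator by the undelayed denominator caps the
local GFP+ fraction of a fully converted well at $e^{-\alpha\gamma}
\approx 0.5$ and generates spurious decreases, contradicting the observed
saturation of well fractions near 1. The package therefore defaults to
per-cell tracking (`mode = "lineage"`): each repair event founds a clone,
the clone (cells and descendants) becomes fluorescent $\gamma$ hours after
its founding repair, and daughters of already-fluorescent mothers are
fluorescent at birth — which is how inherited fluorophores behave. The
count shift remains available (`mode = "shift"`). In lineage mode the
deterministic analogue of the pooled fraction is
$e^{\alpha\gamma} g(t-\gamma) / N(t)$, the comparator used in the tests.

Per-well summaries follow the assay's verbal definitions: `t_lag` is the
first frame at which the total count exceeds its initial value, `t_gfp` the
first frame with at least one GFP+ cell; neither is constrained to precede
the other.

## Synthetic data: what is emulated, what is not

The generators produce every input the pipeline consumes, under the
statistical structure the analysis assumes, with seeded determinism end to
end.

`sim_southern()` draws fraction time courses under either noise mechanism
with the generating truth attached. `sim_wells()` emulates one microwell
experiment: Poisson($\lambda$) loading of a 1032-well chip, retention of
single-founder wells, exact lineage simulation per well, GFP observation.
Two lineage-level knobs reproduce phenomena the kinetic model does not
contain, each anchored to an observed behaviour: `p_escape` founders never
break (the persistent $R^{local}=0$ peak), and `p_arrest` removes each
newly repaired cell from the dividing pool with fixed probability (the
error-prone fitness-loss phenotype, implemented per cell as the simplest
mechanism that slows or stops division after repair).

Numbers worth flagging:

* $\lambda = 1.5$ by default. At that loading a 1032-well chip yields about
  345 single-founder wells — more than the 80–150 usable wells of a real
  experiment, where contamination and bubbles disqualify many. The
  generator therefore subsamples to `n_wells_target`, drawn uniformly from
  80–150 when unspecified. (The nominal cell concentration of the physical
  protocol does not pin $\lambda$; it is configurable.)
* The GFP call threshold is strict: a cell is GFP+ only when its intensity
  exceeds 1.5× background, never at equality. `sim_intensity()` builds
  per-cell traces around that rule so the calling step itself can be
  exercised.
* Eight named condition presets (NR/CGG/GAA/CTG × Cas9/Cpf1) ship with the
  package. Their rate values are **invented plausible regimes**, constrained
  only by coarse published characterisations (efficient conditions break at
  $\beta > 0.1\,\mathrm{h^{-1}}$, intermediate ones near $0.09$, Cas9 breaks
  repair faster than Cpf1 breaks, one strain starts ~40% repaired from leaky
  induction). They are illustrative defaults for simulation studies, not
  measured rates.

What passing tests on these synthetics does *not* show: robustness to
segmentation/tracking errors in real images, to age- or size-structured
division, to crowding-limited growth in small wells, or to
condition-specific biology beyond the two knobs. The generators match the
model's assumptions by construction (plus the two controlled violations),
so recovery results bound what real data could show from above.

## Population statistics and the three-regime classifier

`global_fraction()` pools wells frame-wise — a size-weighted mean of local
fractions, deliberately distinct from the unweighted well mean (small
never-repairing wells barely move it). `delay_distribution()`,
`final_fraction_histogram()` (bimodality summarised simply as the mass
below 0.1 and above 0.9, not a formal dip test) and `heatmap_matrix()`
(rows ranked by final colony size, ties broken lexicographically on the
count trajectories so ranking is order-independent; colour anchors at the
10th/90th percentiles; zero counts at a sentinel below the log colour
floor) reproduce the standard displays.

`classify_condition()` assigns one of three repair behaviours from
features: F1, the median division-to-GFP delay among GFP+ wells; F2, the
final pooled GFP+ fraction; F3, a growth-impairment score (median ratio of
post- to pre-`t_gfp` log-linear growth over 2 h windows, requiring four
usable frames a side and a normalisable pre-rate); and the fraction of
wells whose local fraction ever drops by more than 0.05 between frames.
The rule: early onset (F1 ≤ 8 h) with high conversion (F2 ≥ 0.3) is
high-efficacy error-free; early onset with low conversion — repair starts
promptly but the repaired population fails to take over, the fitness-loss
signature — or overt impairment (F3 < 0.4, or >35% non-monotone wells) is
error-prone; late, rare repair with normal growth is low-efficacy
error-free. A condition with fewer than five GFP+ wells is labelled
low-efficacy with a low-confidence flag rather than guessed at.

The feature *structure* came first (it mirrors the verbal phenotype
descriptions); the thresholds are heuristics placed mid-gap between the
feature distributions of the three synthetic regime presets measured over
independent seeds, then validated on fresh seeds (20/20 per regime). They
are exposed as arguments, and they are validated **only** on synthetic
ensembles — applying them to a new experimental setup should start with
re-examining the feature distributions, not trusting the defaults.

## Problem sizes and reproducibility

The shipped studies use sizes chosen to make Monte-Carlo error comfortably
smaller than the effects tested: 100 random parameter sets for solver
cross-validation; 20,000 lineages for the mean-field check; 20 replicate
datasets × 4 chains × 10,000 iterations (5,000 retained) for each
calibration study; ensembles of 80–150 wells and 20 seeds per regime for
the phenomenology and classifier checks. Every stochastic entry point
takes an explicit seed and is bit-reproducible under it; the command-line
pipeline records seeds in its outputs. `scripts/acceptance.R` re-runs all
of the above from scratch against the installed package and writes the
resulting numbers to JSON.

## Known limitations

* The division process is memoryless; real budding yeast division is not.
* Arrest and escape are phenomenological switches, not mechanisms; in
  particular escape lineages grow indefinitely at $\alpha$, whereas real
  never-repairing lineages often slow after a few cycles.
* The per-cell GFP mode inherits fluorescence instantaneously at division;
  partially matured daughters are not modelled.
* $\sigma$ is shared across components and times; band-specific noise
  scales would need a straightforward but unimplemented likelihood
  extension.
* The classifier thresholds are synthetic-regime calibrations (see above).
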