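---
title: "Models and methods behind multikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind multikin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multikin)
```

multikin is an analysis toolchain for characterising multivalent peptide
binders — dimers, tetramers and octamers presenting copies of a receptor
epitope on a branched PEG scaffold — against a protein target. It covers four
measurement modalities (real-time biosensor kinetics, competitive
displacement, direct titration, and peptide-microarray competition) plus a
machine-learning layer that predicts binding parameters from the peptide
architecture. Because every analysis stage has a matching simulator with
planted ground truth, the entire pipeline is testable end to end without any
external data. This vignette explains the models, the defaults and the
numerical choices.

## 1. The binding model and trace simulation

All kinetics assume a reversible 1:1 interaction between one immobilised
target and the analyte at concentration $C$:

$$\frac{d\,\theta}{dt} = k_{on} C\,(1-\theta) - k_{off}\,\theta,$$

whose association transient is a single exponential with observed rate
$k_{obs} = k_{on} C + k_{off}$ and equilibrium occupancy $C/(C+K_D)$,
$K_D = k_{off}/k_{on}$. A multivalent compound binding a surface is of course
not microscopically 1:1; the package, like the instrument software it
mirrors, reports *apparent* rates of the single-exponential model, which is
how avidity-driven rate maps are constructed in this field.

`simulate_fps_trace()` produces four channels (measurement, real-time
reference, and the two channels of a blank buffer run). The measurement
channel carries the binding signal

$$S(t) = A\,\frac{C}{C+K_D}\left(1-e^{-k_{obs} t}\right)$$

during association and $S_{end}\,e^{-k_{off} t}$ during dissociation; the
equilibrium-occupancy amplitude scaling makes association levels fall with
$K_D$ at fixed concentration, as observed across real multivalent series.
All four channels share a linear drift and i.i.d. Gaussian noise — the
simplest model consistent with published sensorgrams; it deliberately omits
mass-transport limitation, rebinding, heterogeneous ligand populations and
photophysics, so passing round-trip tests demonstrates correctness of the
fitting machinery, not robustness to those real-world artefacts.

Defaults: 1 Hz sampling, 30 s baseline, 300 s association, 600 s
dissociation, amplitude 100 a.u. The sampling rate and durations are
configuration choices (typical for chip-based fluorescence kinetics), not
protocol facts. An optional phenomenological concentration dependence of the
apparent on-rate, $k_{on,app} = k_{on} (C/C_{ref})^{\beta}$, is available for
robustness studies; $\beta = 0$ (the clean model) is the default because no
mechanism justifies another value.

### Double referencing and fitting

`double_reference()` applies the standard correction
$(\text{meas} - \text{ref}) - (\text{blank}_{meas} - \text{blank}_{ref})$ and
refuses misaligned time grids rather than silently interpolating. The exact
arithmetic used by vendor software is unpublished; this contract is the
conventional one and is what the simulator inverts.

Exponential fits are initialisation-sensitive, so `fit_single_curve()`
multi-starts the association fit on a log-spaced $k_{obs}$ grid over
$[10^{-4}, 10]\,\mathrm{s^{-1}}$, keeps the best residual sum of squares and
breaks ties toward the smaller rate. `fit_global()` fits all concentrations
jointly — shared $k_{on}$, $k_{off}$ on the log scale, one free amplitude per
curve, with the dissociation branch continuing from each curve's association
end level so that off-rate information is pooled across phases and curves.
Standard errors come from the Gauss–Newton covariance via the delta method.
Unweighted least squares is used throughout because no variance model for
the fluorescence readout is available.

Flags: a compound is *not determinable* when its fitted amplitude does not
exceed three times the residual noise SD (or is exactly constant), or when a
relative standard error exceeds 100%; such compounds are excluded from rate
maps, which annotate iso-affinity diagonals at $K_D$ = 10 µM, 1 µM and
100 nM. When the standard error of $k_{off}$ exceeds the estimate itself,
$K_D$ is flagged as an upper bound rather than a point value. These
thresholds are package choices; published rate maps exclude compounds
without determinable rates but do not state a criterion.

The *association level* is reported two ways: the mean of the final 10% of
association-phase points (primary — it needs no model) and the fitted
plateau amplitude (secondary). Whether published "association levels" are
raw plateaus or fitted amplitudes is ambiguous; reporting both sidesteps the
question.

## 2. Competitive displacement and $K_i$

In the displacement assay a fixed complex of target (total $[T]_t$) and
fluorescent tracer (total $[C]_t$, dissociation constant $K_D$) is challenged
with a competitor dilution series. The no-competitor bound-tracer fraction is

$$\gamma = \frac{[T]_t+[C]_t+K_D-\sqrt{([T]_t+[C]_t+K_D)^2-4[T]_t[C]_t}}{2[C]_t},$$

implemented in the algebraically identical form
$2[T]_t/\big(S+\sqrt{S^2-4[T]_t[C]_t}\big)$ with $S = [T]_t+[C]_t+K_D$,
which avoids the catastrophic cancellation the textbook numerator suffers
when $[C]_t \ll [T]_t, K_D$. The fitted displacement midpoint $EC_{50}$
converts to the competitor's true dissociation constant by the exact
correction

$$K_i = \frac{K_D}{2-\gamma}\left(\frac{EC_{50}}
 {\frac{[T]_t}{\gamma}-\frac{K_D}{2-\gamma}-\frac{[C]_t}{2}}-\gamma\right).$$

`solve_competitive_equilibrium()` is the package's independent oracle for
this algebra: it solves the ternary equilibrium by monotone root bracketing
on free target (numerically robust for extreme constants, unlike a cubic
closed form) and is used both to validate $\gamma$/$K_i$ on random inputs
and to generate displacement curves with planted $K_i$
(`simulate_tric_plate()`). The simulated normalised fluorescence maps the
bound-tracer fraction affinely between configurable endpoints, because the
physics of the temperature-jump readout itself is out of scope. A
20,000-setup numeric scan indicates the $K_i$ denominator above is strictly
positive for every valid two-species setup; the "assay window violated"
error is retained as a defensive guard.

Defaults mirror the assay protocol: a 16-point 1:1 dilution series whose
final concentrations run 1 mM → 30.52 nM (a 2 mM pre-dilution mixed with an
equal volume of target–tracer complex), 20 nM target, 10 nM tracer, plus an
explicit zero-competitor condition. The tracer's own $K_D$ is determined in
a direct titration (500 → 0.015 nM target at 1 nM tracer) fitted with the
tight-binding quadratic isotherm — the hyperbolic form would be biased when
$K_D$ is comparable to the tracer concentration. The synthetic tracer is
assigned $K_D$ = 25 nM, a representative low-nanomolar value for a dimeric
tracer peptide.

### The Hill fit

`fit_hill()` fits the four-parameter logistic
$y = bottom + (top-bottom)/(1+(c/EC_{50})^h)$ with $EC_{50}$ on the
log10 scale, slope bounded to $[0.3, 5]$ and bottom to
$[0, 1.5\,\min y]$ (stabilises sparse 16-point fits), the slope left free
(there is no ground to fix it at 1), and both curve orientations handled by
reflection. Working in linear concentration lets the zero-competitor
condition enter as a real data point that anchors the top plateau — without
it, curves whose transition touches the dilution floor are severely
misestimated.

An exact competitive-displacement curve is *not* a logistic, and the
mismatch biases a one-stage 4PL midpoint by up to ~2% in round-trip $K_i$
when the $EC_{50}$ sits at the grid edge. The fit therefore refits in a
second stage restricted to the transition window — points where the
*stage-one fitted curve* lies between 10% and 90% of its span (judging the
window on the fitted curve rather than the noisy data keeps the kept-point
set stable under noise) — plus the zero- and top-concentration anchors.
With this procedure the simulate → Hill fit → $K_i$ round trip recovers
planted values within 1% across $K_i$ = 10 nM – 10 µM on the standard grid.
Residual noise sensitivity is intrinsic to having ~7 points in the
transition; the assay protocol's duplicate wells bring the $EC_{50}$
scatter under 2% at 0.5%-of-range noise.

## 3. Microarray competition quantification

Spot tables carry raw intensity and a local background per spot, printed as
internal left/right duplicates. Processing follows the standard chain:
background subtraction floored at zero (clips are counted and reported);
per-spot duplicate deviation as the population SD of the pair,
$\sqrt{\sum(x-\bar x)^2/n}$ — note that a printed variant of this formula
omitting the square is dimensionally inconsistent (its radicand can be
negative) and is treated as a typographical slip, not implemented; summation
of all spots per condition; and normalisation to the zero-competitor
condition, which is therefore exactly 1. Neutralisation IC50s reuse the Hill
machinery — one tested implementation — on relative binding versus
competitor concentration. The simulator plants a logistic decrease in
log-concentration with per-spot lognormal brightness heterogeneity and
optional relative Gaussian noise; image segmentation is upstream of the
package and out of scope.

## 4. Architecture encoding and prediction

The predictive layer asks whether the peptide's *architecture* — epitope
sequence and linker topology — determines its binding parameters.

* **Responses.** Rows missing any of $K_D$, $k_{on}$, $k_{off}$ are
  removed; repeated measurements of the same peptide (identical epitope and
  linker tokens) collapse to medians. $K_D$ and $k_{off}$ are transformed as
  $\log(x)^2$ (natural log), which compresses their decade-spanning range;
  $k_{on}$ is regressed untransformed (the stated workflow transforms only
  the other two). Since molar $K_D < 1$, $\log K_D < 0$ and the transform is
  invertible on that branch via $x = e^{-\sqrt y}$ — this is why the
  transform is pinned to molar units.
* **Features.** Amino-acid composition $f(t) = N(t)/N$ over the 20
  canonical residues (sums to 1), plus a positional one-hot of the linker
  token string: per position, the branching linker `J` → `[1,0]`, the PEG
  spacer `O` → `[0,1]`, gaps → `[0,0]`, with capacity 7 positions → 14 bits;
  34 features in total. Zero-variance columns are removed on the full matrix
  *before* cross-validation — faithful to the stated workflow, at the cost
  of a (documented, benign for variance-based filters) departure from
  strict leakage purism; the kept-feature mask is recorded.
* **Model and evaluation.** A random forest with package defaults
  (500 trees), evaluated by leave-one-out cross-validation so each peptide
  is predicted by a model that never saw it. Folds run in a canonical
  (locale-independent radix) id order and each fold's RNG stream derives
  from the master seed and fold rank, so results are reproducible and
  invariant to input row order. Reported: total and per-valency-group $R^2$
  (including the combined tetramer+octamer group), Pearson correlation, and
  a 1000-resample percentile bootstrap CI for the total $R^2$.

## 5. The synthetic library generator

`generate_library()` expands 3 valencies × 4 epitope lengths × 9 linker
plans = 108 architectures, echoing the scale of a real combinatorial
multimer library (>100 compounds). Epitopes are N-terminal prefixes of a
**synthetic** parent sequence `FSIVGSLPKE` — the genuine FSIVG receptor core
motif extended with invented flanking residues, since the full flanking
sequence is not reproduced here. Linker plans are valency-agnostic token
strings truncated to the tiers a scaffold has.

`plant_kinetics()` assigns ground truth by a multiplicative rule chosen to
reproduce the qualitative structure reported for such libraries: on-rates
grow 4× per valency doubling, 2× per epitope residue beyond the 5-residue
core and 1.15× per outer-tier PEG unit, spanning ≥100-fold across the
default library; off-rates shrink only mildly (0.75× per doubling, 0.95×
per residue), staying within 5-fold. Per-compound lognormal scatter
(σ = 0.2 on $\ln k_{on}$, 0.05 on $\ln k_{off}$) models batch variability.
Under these defaults the LOOCV forest reaches a total $R^2 \approx 0.63$
and $\approx 0.52$ for the tetramer+octamer group on the transformed $K_D$;
the subgroup ceiling (~0.54 even with zero planted scatter) reflects the
forest's inability to extrapolate at the architecture extremes under LOOCV,
not the noise level.

What the generator does *not* emulate: correlated measurement error across
a concentration series, mass-transport effects, compound aggregation or
impurity, and any mechanistic configurational-network model of
multivalency. Passing round-trip tests therefore validates the estimators
against their own forward models, which is the intended scope.

## 6. Problem sizes and determinism

The shipped test-suite and the acceptance script use: noiseless global-fit
oracles on 3-concentration series; 100-seed Monte Carlo at 1% relative
noise for rate recovery; 10⁴ random setups for the bound-fraction oracle
comparison; a 7-point log grid over $K_i$ = 10 nM – 10 µM for the
displacement round trip; the 108-architecture default library (84 unique
peptides after replicate collapse) with 3 planted replicates for the LOOCV
criterion, whose median damps the ±0.02 single-draw jitter of the group
$R^2$; and 200 random spot pairs for the duplicate-deviation check. Every
stochastic step takes an explicit integer seed; identical seeds give
bitwise-identical outputs (simulators draw through isolated RNG scopes that
do not disturb the caller's stream).

Interfaces are R functions plus CSV/JSON readers and writers
(concentrations are molar in memory and nanomolar with `_nM` suffixes on
disk — one internal unit prevents the silent mM/µM/nM mix-ups the source
protocols invite); a shell wrapper is deliberately not shipped, as analyses
in this domain are driven from R scripts.

## 7. Known limitations

* Apparent 1:1 rates only; no biphasic or mass-transport models.
* The displacement analysis covers the F_norm-vs-concentration layer, not
  the underlying fluorescence traces.
* The $K_i$ correction assumes the competitor acts through simple
  competition at a single site.
* Forest hyperparameters are deliberately left at package defaults; no
  tuning, alternative encoders or feature-importance analysis.
* The microarray module starts from spot-intensity tables; image
  quantification is upstream.
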