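---
title: "Models and methods in PlateSynergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in PlateSynergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PlateSynergy)
```

PlateSynergy implements the statistical core of a drug-combination screening
campaign: plate normalization and quality control, hit-combination calling,
median-effect/combination-index synergy quantification with
sequential-deletion intervals, the Webb fractional-product classification,
and well-level high-content metrics. This vignette explains the models, the
parameters that matter, the numerical decisions, and what the synthetic-data
generators do and do not emulate.

## HTS scores and plate QC

A 384-well screen plate carries negative controls (cells + vehicle),
positive controls (cells + a fully cytotoxic reference), and one library
compound per well. Raw fluorescence is an increasing function of viable cell
mass, so cytotoxicity is expressed as the control-anchored score

$$\mathrm{score}(w) = \frac{\overline{S}_{neg} - S(w)}
                           {\overline{S}_{neg} - \overline{S}_{pos}},$$

which is 0 at the negative-control mean and 1 at the positive-control mean
and is invariant under rescaling of the raw signal (gain settings cancel).
Scores are deliberately *not* clipped to [0, 1]: a compound more cytotoxic
than the positive control scores above 1, and a growth-stimulating well
scores below 0; both are informative for QC. Clipping happens only at the
conversion to fraction affected (`scoreToFa()`, default clamp
[0.001, 0.999]) where the log-linearization requires an open interval.

On a combination plate the backbone (Pt) drug at a fixed concentration is
present in every well, controls included, so the identical formula
normalizes each compound to the effect of the backbone drug alone. A
compound whose combination score exceeds its score alone therefore shows
more-than-cumulative cytotoxicity.

Quality control is the screening-window coefficient
$Z' = 1 - 3(\sigma_{pos} + \sigma_{neg})/|\mu_{pos} - \mu_{neg}|$, computed
on raw control signals. $Z' \le 1$ always; the pass threshold defaults to
0.4 (the lower end of the conventional 0.4–0.5 band) and is configurable.
Plates with equal control means are rejected as degenerate rather than
scored.

**Hit calling.** A combination is *considered* only when its mean score
clears the plate noise floor — the negative-control score mean (0 by
construction) plus three negative-control score standard deviations; wells
below it are indistinguishable from untreated controls. The default
`"as_printed"` rule calls a hit when
$\bar{x}_{combo} + s_{combo} > \bar{x}_{alone} - s_{alone}$ *and*
$\bar{x}_{combo} > \bar{x}_{alone}$. The first inequality alone is
near-vacuous (it tolerates overlap of a full standard deviation on each
side), so the higher-mean requirement, stated alongside the rule, is
enforced as well. A `"strict"` variant
($\bar{x}_{combo} - s_{combo} > \bar{x}_{alone} + s_{alone}$) is available;
a strict hit is always an as-printed hit. The floor is applied to mean
scores, not individual replicates. Replicate SDs use the sample (n − 1)
definition throughout.

## The median-effect model

Dose-response series are modelled by the median-effect equation

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m, \qquad f_u = 1 - f_a,$$

with $D_m$ the median-effect dose (the IC50) and $m$ the sigmoidicity. Its
logarithmic form is linear, and the fit is ordinary least squares of
$\log_{10}(f_a/f_u)$ on $\log_{10} D$: slope $m$, intercept
$-m \log_{10} D_m$. Replicates are averaged per dose before regression (the
convention of the reference software; per-replicate regression is available
via `perReplicate = TRUE`). Dose levels with mean $f_a \le 0$ or $\ge 1$
leave the response undefined and are excluded and recorded in the fit
object. Fewer than two usable dose levels, or a response with zero variance,
is an error rather than a silent degenerate fit.

Goodness of fit is the Pearson correlation $r$ of the regressed pairs,
reported as a positive number; a fit is valid when $r > 0.85$ (configurable)
*and* the slope is positive — a cytotoxic dose-response must rise with dose,
so negative slopes are invalid regardless of $r$. Invalid fits refuse
downstream use unless `force = TRUE`.

The model is inverted exactly: $D_x = D_m (f_a/(1-f_a))^{1/m}$
(`doseForEffect()`), with `effectAtDose()` its inverse; the round trip is
tested to $10^{-9}$ relative. Because the log-linearization is exact for
this family, noiseless simulated data recovers $(D_m, m)$ to $10^{-6}$
relative with $r = 1$ — the basic correctness oracle for the fitting code.

## Combination index, DRI, and grading

The constant-ratio ("diagonal") design fixes the concentration ratio of two
drugs and dilutes the mixture like a single agent; doses of the mixture are
total concentrations, and the weights $w_A + w_B = 1$ give each component's
share. At effect level $f_a$ the two-term (mutually exclusive) combination
index is

$$CI = \frac{d_A}{D_{x,A}} + \frac{d_B}{D_{x,B}},$$

where $D_{mix}$ producing $f_a$ comes from the mixture fit,
$d_i = w_i D_{mix}$, and $D_{x,i}$ from the single-agent fits. The
mutually-nonexclusive variant with a cross term is intentionally not
implemented; the two-term sum is the cited method's default. The
dose-reduction index is $DRI_i = D_{x,i}/d_i$, and
$CI = 1/DRI_A + 1/DRI_B$ holds algebraically — verified to $10^{-9}$ as an
internal-consistency test. Effect levels outside the observed $f_a$ range of
any of the three series are still computed (high-effect CIs are routinely
reported beyond the data) but flagged `extrapolated`.

The level-weighted summary is $CI_{wt} = (CI_{50} + 2 CI_{75} + 3 CI_{90} +
4 CI_{95})/10$, emphasizing the therapeutically relevant high-effect levels,
and is graded on the conventional symbol scale: below 0.1 `+++++`, [0.1,
0.3) `++++`, [0.3, 0.7) `+++`, [0.7, 0.85) `++`, [0.85, 0.90) `+`, [0.90,
1.10] `±`, (1.10, 1.20] `-`, (1.20, 1.45] `--`, (1.45, 3.3] `---`, above
3.3 `----`. Synergy bands are closed on their lower end and the
near-additive band is closed on both ends, so every boundary value has one
unambiguous grade and the grade is a non-increasing step function of
$CI_{wt}$.

**Sequential deletion intervals.** CI variability is estimated by deleting
one concentration level of one series at a time — across all three series,
so a 3×5-dose design yields 15 deletions — refitting the affected series,
and recomputing CI at each requested level. The deletion universe
(single-agent series included) is a package decision; the method's sources
do not fix it. Over the deletion set we report the mean and a 95% half-width
based on the delete-one jackknife standard error
$\sqrt{\tfrac{n-1}{n} \sum_i (CI_{(i)} - \overline{CI})^2}$ with the
$t_{0.975,\,n-1}$ quantile. The naive $s/\sqrt{n}$ form is wrong here:
delete-one replicates share all but one observation and are strongly
correlated, and $s/\sqrt{n}$ shrinks the interval roughly four-fold below
its nominal coverage. With the jackknife form, Monte-Carlo runs at the assay
conditions (5 doses, 4 replicates, cv 0.05) cover the ground-truth CI in
≈99% of runs. On exact model data every deletion reproduces the same CI and
the half-width is 0. Deletions producing invalid or inestimable refits are
dropped and counted out of $n$.

**Isobolograms and the Fa–CI curve.** Per level, the additivity line runs
between the single-agent intercepts $(D_{x,A}, 0)$ and $(0, D_{x,B})$, and
the combination point is $(w_A D_{mix}, w_B D_{mix})$; the point lies below
the line exactly when $CI < 1$. Isobologram levels default to the classical
IC50/IC75/IC90 triple (0.5, 0.75, 0.9). The Fa–CI curve samples CI over a
grid with per-point extrapolation flags.

## Webb fractional product

Where the median-effect fit is impossible — flat dose-response curves, fixed
single-concentration designs — combinations are classified against the
Bliss-independence expectation $f_u^{calc} = f_{u,A} \times f_{u,B}$.
Strong synergy: $0.7 f_u^{calc} - \overline{f_u^{det}} \ge 3\,SD$; weak
synergy at $1\,SD$; strong antagonism:
$\overline{f_u^{det}} - 1.3 f_u^{calc} \ge 3\,SD$; weak at $1\,SD$;
otherwise additive. The weak (1 SD) tiers supply a middle grade between
strict additivity and the strong 3 SD calls. The 0.7/1.3 factors mean a combination must beat the
expectation by 30% *and* by three replicate SDs to be called strongly
interacting, which keeps Bliss-consistent noisy data ≥95% additive. No
p-values are attached: the margins are a screening heuristic, not a
hypothesis test.

## High-content metrics

From a per-nucleus object table (Hoechst, PI, Calcein mean intensities per
segmented nucleus) the well-level metrics are the object count $N_{cells}$,
the mean PI intensity $\bar{I}_{PI}$, and $Q_{PI/Ho}$, the Pearson
correlation of Hoechst and PI across the objects of a well. $Q_{PI/Ho}$ is
computed at the object level, not the pixel level — the package starts from
segmentation output, and pixel data is out of scope; this interpretation is
recorded rather than asserted as the original pipeline's. The correlation
needs at least 3 objects and variance in both channels, otherwise it is NA.
Fields of view are pooled per well. Normalized forms divide by the
negative-control well at the same timepoint: $\%N_{cells}$ and
$nI(PI) = \bar{I}_{PI}(drug)/\bar{I}_{PI}(ctrl)$. A decrease in
$\%N_{cells}$ without PI elevation (default threshold 1.2) below 50% of
control flags a cytostatic rather than cytotoxic response; a combination
exceeding both single agents in $Q_{PI/Ho}$ and $nI(PI)$ is flagged
supra-single-agent.

## The synthetic-data generators

The generators exist so that every downstream stage can be tested against a
known truth; their defaults are the reference assay conditions: 384-well
plates with controls in the first/last two columns (the confirmation layout
is edge-free), 2000 cells/well-scale signals, library compounds at 10 µM,
backbone agent cisplatin with $D_m$ = 15 µM and $m$ = 1.5 (the PANC-1
IC50), five two-fold doses from 1/4× to 4× $D_m$, four replicates, duplicate
plates. Replicate noise is multiplicative lognormal with unit mean; cv
defaults to 0.05, a free parameter with no claimed fidelity to any
particular instrument. For raw plates the signal model is
$S = b + (S_{ctrl} - b)(1 - \mathrm{score})$ with background floor $b$ = 2%
of the control signal, and noise is applied to the raw signal (fluorescence
noise scales with intensity); for dose-response series noise multiplies
$f_a$ directly and the result is clamped to [0, 1].

Mixture ground truth comes in two modes. `loewe_additive` constructs the
mixture's underlying curve so the Loewe sum
$w_A D/D_{x,A}(f_a) + w_B D/D_{x,B}(f_a) = 1$ holds exactly at every level
(closed form when the agents share $m$, numeric root otherwise). `fixed_ci`
scales the additive mixture's $D_m$ by the target CI, pinning CI at the 50%
level exactly; with a shared $m$ the construction is level-independent, so
one parameter gives a sharp recovery test. When slopes differ the additive
mixture is no longer exactly median-effect and the downstream log-linear fit
carries a few percent of deterministic bias — visible in the tests as a
widened tolerance for unequal-slope additive designs. The default mixing
ratio is equipotent ($D_{m,A} : D_{m,B}$), the usual IC50:IC50 design.

What the generators do *not* emulate: spatial plate artefacts (edge
evaporation, dispensing gradients — the package deliberately has no B-score
or loess correction), compound solubility failures, intrinsic compound
fluorescence, cell-line pharmacokinetics, or image-level noise. Passing
tests therefore demonstrate correctness of the estimators under the stated
statistical model, not robustness to every real-plate pathology.

## The pipeline and its synergy call

`runPipeline()` chains screen → confirmation → synergy → HCA over a seeded
configuration; stages write CSVs, are individually re-runnable against the
CSVs of earlier stages, and fail with an orchestration error naming any
missing upstream artifact. A JSON manifest records the package version,
seeds, configuration, and per-plate QC. In the synthetic screen the
ground-truth score of each inert compound is identical alone and in
combination (additivity on the combination plate's normalization scale),
while planted pairs receive a combination boost and a `fixed_ci` truth at
stage 3.

Stage 3 labels a pair `synergistic` only when its grade is a synergy grade
*and* the S.D.A. 95% intervals at the 75% and 90% effect levels lie entirely
below 1. The point estimate alone is not enough: at cv = 0.05 with four
replicates, $CI_{wt}$ on truly additive pairs scatters into the slight- and
moderate-synergy bands roughly 15% of the time — a spread comparable to real
screening campaigns — and synergy determinations with high
sequential-deletion variability are unreliable. Requiring
interval support reduces the false-synergy rate on additive truth below 5%
while leaving a planted CI = 0.3 pair called in every seeded run.

## Numerical and interface decisions

- Wells are 1-based (row, col) pairs internally, the R matrix idiom; files
  use the "A1" convention. All files are plain CSV (UTF-8, "." decimal),
  and every reader/writer pair round-trips exactly.
- Layout validation is strict: duplicate wells, unknown roles, compounds in
  control wells, loaded empty wells, and mixed backbone-drug annotation on a
  combination plate are all construction-time errors. Edge wells are
  allowed in layouts (the primary screen uses them; the confirmation layout
  avoids them), so both conventions are supported.
- Generator determinism: every simulation accepts a seed, restores the
  caller's RNG state, and derives sub-seeds arithmetically, so a pipeline
  run is byte-identical given its configuration.
- Test problem sizes are chosen to exercise the estimators at the assay's
  own scale while keeping the default suite fast: 200 seeds for
  parameter-recovery error, 100 runs for interval coverage, 200 pairs for
  the Webb additivity rate, and eight full pipeline runs (100 compounds
  each) for planted-hit recovery.

## Known limitations

The package fits only the median-effect family — four-parameter logistics
are out of scope, and flat responders are routed to the Webb classifier
instead. Non-constant-ratio (checkerboard) response surfaces, ZIP/HSA-style
models, and p-valued Bliss-excess tests are not implemented. Mixture ratios
must be supplied (or taken from the generator); they are never inferred from
data. Plot *data* is produced (isobologram, Fa–CI, DRI tables); rendering is
left to the user's plotting layer.
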