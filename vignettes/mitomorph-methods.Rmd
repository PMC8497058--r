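---
title: "Methods: models, parameters and design choices in mitomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mitomorph}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind each stage of the
pipeline, the parameters a user may want to touch, and the design
decisions that were genuinely open — so that results can be interpreted
(and disagreed with) precisely.

## 1. Per-cell shape metrics

A cell is a multiset of mitochondrial component lengths
$\ell_1,\dots,\ell_n$ in μm, the summary level produced by confocal
skeletonization. The metrics are

$$\mathrm{Fission} = \frac{n}{\sum_i \ell_i} \quad (\mu m^{-1}), \qquad
  \mathrm{Fusion}_k = 100\,\frac{\sum_{i \in \text{top-}k} \ell_i}
                               {\sum_i \ell_i} \quad (\%).$$

These quantify the *contribution* of fission/fusion to the steady-state
shape, not kinetics. Properties the implementation guarantees (and the
suite tests): scale invariance of $\mathrm{Fusion}_k$ and
$1/c$-scaling of Fission under $\ell \mapsto c\ell$; monotonicity of
$\mathrm{Fusion}_k$ in $k$ with $\mathrm{Fusion}_n = 100$; and the
fragmentation property — splitting any component raises Fission and
never raises $\mathrm{Fusion}_1$. Ties among equal lengths cannot
change a top-$k$ *sum*, so no tie-break rule is needed. Readers reject
nonpositive, missing or non-finite lengths outright instead of dropping
them: silent filtering would shift every metric distribution, and
quality control belongs upstream.

## 2. The fission–fusion simulator

The generator stands in for raw microscopy: it produces length
partitions whose statistical structure matches what the metrics assume.
State is a partition of a conserved `total_length`; dynamics are a
Markov jump process:

* **Fission**: component $i$ splits at rate $k_{fis}\,\ell_i$ with a
  uniform breakpoint on $(0, \ell_i)$. A split that would create a
  daughter shorter than `min_len` is *rejected* — the proposal is
  discarded, not absorbed — which mimics the optical resolution floor
  without destroying mass conservation.
* **Fusion**: every unordered pair fuses at rate $k_{fus}$
  (well-mixed mass action). No kinetic measurements exist to justify
  anything richer; these are the simplest kernels consistent with
  linear tubule geometry.

Event types are chosen proportional to total rates (the fission total
$k_{fis} \cdot \text{total\_length}$ is constant by conservation), and
the chain runs for `n_events` *accepted* events from a single fused
component. Burn-in is counted in events rather than simulated time so
that compute cost is deterministic; 5000 events is the default, far
past relaxation for the parameter ranges used (equilibrium component
counts here are ≲ 50, and tests that sweep many cells use 800–1500
events after checking the same steady-state statistics are reached).
Only the ratio $k_{fis}/k_{fus}$ matters for stationary shape; the
equilibrium component count scales like
$\sqrt{2\,k_{fis}\,L/k_{fus}}$. The rates are calibration knobs and
make no biological rate claims.

Default archetypes used throughout tests and the acceptance script, on
a 100 μm cell with a 0.5 μm floor: a fusion-dominant archetype
($k_{fis}/k_{fus} = 0.05$) whose cells are reliably hyperfused
(Fusion5 > 80), and a fragmentation archetype (ratio 3) that lands in
the intermediate box (Fission ≈ 0.15–0.3, Fusion5 ≈ 40–70). These
values were chosen so that each archetype occupies one gate with high
purity, making mixture weights interpretable as planted gate fractions.

**Seeding.** One master seed per population; each cell's stream is
derived by a counter offset, so output is reproducible and independent
of evaluation order.

**Stratified planting.** `simulate_population()` and
`simulate_intensities()` default to realizing mixture weights as exact
per-archetype counts (largest-remainder rounding, order shuffled)
rather than i.i.d. draws. This is a variance-reduction choice: recovery
experiments then measure the error of the *gating method*, not the
binomial noise of archetype assignment. `method = "multinomial"`
restores i.i.d. assignment where sampling noise itself is under study.

**What the generator does not emulate.** Components are linear length
masses: no branching topology, no spatial embedding, no width/volume,
no imaging noise or segmentation error, no cell-to-cell variation in
total mitochondrial mass within an archetype. Passing recovery tests
therefore shows the statistics are correct and well-calibrated *under
the assumed mixture structure* — not that real confocal data meet that
structure.

## 3. Bivariate gating

Gate constants: HF is `Fusion5 > 80` (strict), Int is the closed box
`Fission ∈ [0.15, 0.4]` × `Fusion5 ∈ [40, 80]`. The printed ranges in
the field are stated without bracket conventions; we declare the Int
box closed and the HF bound open, so a cell at Fusion5 = 80 exactly is
Int and the gates partition every cell into exactly one of
HF/Int/Other. Everything outside the two boxes is one "Other" class —
subdividing it would imply structure the gating does not claim.

Compositions are compared with Pearson's chi-square on the
gates × populations table, *without* continuity correction (the
generic two-or-more-sample chi-square usage); an expected count below 5
triggers a warning rather than an automatic switch to an exact test,
leaving that judgement to the analyst. Gate rows empty in every
population are dropped before testing, with degrees of freedom
following the reduced table.

The "scatter about the inverse correlation" is operationalized as the
residual standard deviation $\sqrt{RSS/(n-2)}$ from the OLS fit of
Fusion5 on Fission (together with Pearson's $r$, which is
orientation-free). The regression orientation is a convention fixed
here; the residual SD is in Fusion5 percent units.

## 4. Quadrant gating

Per channel, the signal threshold is the robust cut
$\mathrm{median} + 1.5 \times \mathrm{MAD}$ with MAD *unscaled* (median
of absolute deviations, with no 1.4826 normal-consistency factor, as
this threshold is conventionally defined for dot-plot gating). "hi" means strictly above
the threshold, so when MAD = 0 (constant channel) ties remain "lo"
instead of flooding the hi quadrants. Because the threshold is at least
the median, at most half of the sample it was computed on can be "hi"
in a channel — quadrant percentages are bounded by construction.

Whether thresholds should come from each population or from a common
reference is genuinely underdetermined; cross-population percentage
comparisons are only meaningful against a common cut, so
`mode = "reference"` (thresholds from the control/parental sample,
applied to all) is the default, with `mode = "per_population"`
available. Note one systematic consequence tested explicitly: in a
unimodal "lo" population the cut sits ≈ 1 robust-SD above the median,
so ~14–16% of lo cells exceed it per channel; with independent channel
noise ~2% of lo-lo cells land in hi-hi. Planted double-hi fractions are
therefore recovered with a small positive bias — within the ±4
percentage points the recovery tests assert — and immunocytochemistry
quadrant percentages should generally be read as comparative, not
absolute.

## 5. Cell-cycle reciprocity

Phases are consumed as the three-level labels (G0/G1, S, G2M) an
upstream scoring step emits; this module never recomputes scores. For
clusters A and B the per-population reciprocity is
$(G1\%/S\%)_A \,/\, (G1\%/S\%)_B$; within-cluster denominators cancel,
so the statistic is invariant to each population's sequencing depth and
inverts exactly under cluster swap. A zero S count makes the ratio
undefined: this raises an error naming the offending group, because a
silently regularized headline ratio would mislead. An explicit
`pseudocount = TRUE` flag adds 0.5 per phase count for users who want
the regularized version. When a population is compared against two
others, fold-changes against the chosen reference are reported per
population — minimum and mean across comparators are both trivially
available from the returned table, since which summary is "the"
fold-change is not standardized.

## 6. Limiting-dilution frequency

Single-hit Poisson model: a well at dose $d$ is negative with
probability $e^{-fd}$, i.e. a binomial GLM with complementary log-log
link and $\log d$ offset. The MLE is found as the root of the analytic
score equation (the log-likelihood is strictly unimodal in $\log f$
for interior data; the score is strictly decreasing), bracketed
geometrically and solved with `uniroot` at tolerance $10^{-14}$ — the
single-dose closed form $\hat f = -\log(\text{neg fraction})/d$ is
reproduced to $10^{-10}$. The 95% CI is the profile-likelihood
interval (deviance cutoff $\chi^2_1 = 3.841$), preferred to Wald
because 24 wells per dose leaves visible likelihood skew. Boundary
data give one-sided results: all-negative → $\hat f = 0$ with an upper
bound only; all-positive → no finite MLE, lower bound only. Groups are
compared by the likelihood-ratio test of a shared $f$ against separate
frequencies ($\chi^2_1$). Frequencies print both as a per-cell rate and
in "1 in N" form.

Calibration is checked by simulation under the standard assay design
(doses 1/10/100/1000, 24 wells each) at a planted frequency of 1/150:
median estimate within 10% and ≥ 93% profile-CI coverage over 500
replicates, and ≥ 95% power at 0.05 for a 10-fold frequency
separation over 200 replicates. Goodness-of-fit testing of the
single-hit assumption itself is out of scope.

## 7. Problem sizes and numerical notes

Test and acceptance runs use: 10,000 random cells for metric-oracle
equivalence; 200 cells per point on a 6-point rate-ratio grid (800
accepted events per cell) for simulator monotonicity; 200 cells per
population for gate recovery (1000 events per cell); 500 cells per
population for quadrant recovery; $10^4$ cells per cluster for
reciprocity convergence; 500 + 200 replicates for limiting-dilution
calibration and power. These sizes put Monte-Carlo noise comfortably
below the asserted tolerances.

Numerical choices: mass conservation is exact up to floating-point
summation (asserted at $10^{-9}$ relative); `log(-expm1(-fd))` is used
for the positive-well log-probability to avoid cancellation at small
$fd$; chi-square statistics come from `stats::chisq.test(correct =
FALSE)` and are cross-checked in the suite against a direct
$\sum (O-E)^2/E$ oracle; profile-CI endpoints are verified to sit on
the deviance cutoff.

## 8. Known limitations

* The simulator's fission/fusion kernels are the simplest consistent
  choices, not fitted kinetics; only steady-state shape statistics are
  meaningful.
* Quadrant percentages inherit the MAD-threshold's fixed false-hi rate
  in unimodal samples (section 4); treat them comparatively.
* Reciprocity consumes upstream phase labels as truth; label noise
  propagates unmodelled.
* The limiting-dilution machinery assumes the single-hit model; it
  estimates under it, it does not test it.
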