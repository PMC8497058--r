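# mitomorph

Single-cell mitochondrial fission/fusion morphometrics and the
subpopulation statistics built on them.

## The problem

Mitochondrial shape in a cell is the steady state of two opposing
processes — fission (driven by the dynamin-related GTPase Drp1) and
fusion. Studies of stem/progenitor-cell priming quantify this steady
state per cell from confocal z-stacks: skeletonization software reduces
each cell's stained mitochondria to a set of components with measured
lengths, and everything downstream is statistics on those lengths.
`mitomorph` implements that downstream machinery as a tested, reusable
pipeline:

* **Shape metrics.** For a cell with components of lengths
  ℓ₁,…,ℓₙ (μm):

  * `Fission = n / Σℓᵢ` (μm⁻¹) — components per unit length; higher
    means more fragmented.
  * `Fusion_k = 100 · (sum of the k largest ℓᵢ) / Σℓᵢ` — the percent of
    mitochondrial mass in the *k* largest networks. `Fusion5` and
    `Fusion1` are the k = 5 and k = 1 cases; 100 means fully fused at
    that level.

* **Bivariate gating.** Cells are classified on the (Fission, Fusion5)
  plane: **HF** (hyperfused, `Fusion5 > 80`), **Int** (intermediate,
  `Fission ∈ [0.15, 0.4]` and `Fusion5 ∈ [40, 80]` — smaller fused
  networks coexisting with fragments), **Other**. Gate compositions are
  compared across populations with a Pearson chi-square test, alongside
  the `Fusion1 > 80` cell fraction and the scatter (residual SD) about
  the Fusion5-on-Fission regression line.

* **Quadrant gating.** Two-channel immunofluorescence dot plots
  (e.g. Sox2 × Krt15) are split at the robust per-channel threshold
  `median + 1.5 · MAD` (MAD unscaled), computed on a reference
  population and applied to all, giving hi-hi / hi-lo / lo-hi / lo-lo
  percentages and a chi-square comparison.

* **Cell-cycle reciprocity.** For two scRNA-seq clusters A and B, the
  G1-to-S reciprocity per population is
  `(G1% / S%)_A ÷ (G1% / S%)_B` — large values mean cluster A sits in
  G0/G1 exactly where cluster B sits in S — with fold-changes versus a
  reference population.

* **Limiting-dilution frequency.** From spheroid-formation well
  outcomes (doses 1/10/100/1000 cells, 24 wells per dose), the
  frequency *f* of self-renewing cells under the single-hit Poisson
  model `P(well negative | dose d) = exp(−f·d)`: maximum-likelihood
  estimate via the analytic score equation, profile-likelihood 95% CI,
  and a likelihood-ratio test between groups.

* **A generative model for validation.** A stochastic
  fragmentation–coagulation simulator (length-proportional fission with
  uniform breakpoints and a resolution floor; mass-action fusion)
  produces cells with known archetype mixtures, plus log-normal
  two-channel intensity mixtures, multinomial cluster×phase tables and
  binomial well outcomes — every input format with planted ground
  truth.

## Worked example

```r
library(mitomorph)

archetypes <- list(
  hf  = sim_params(total_length = 100, k_fis = 0.05, k_fus = 1,
                   min_len = 0.5, n_events = 1000),
  int = sim_params(total_length = 100, k_fis = 3, k_fus = 1,
                   min_len = 0.5, n_events = 1000)
)
weak   <- population_spec("weak_kd", 200, archetypes, weights = c(0.38, 0.62))
strong <- population_spec("strong_kd", 200, archetypes, weights = c(0.77, 0.23))
cells  <- c(simulate_population(weak, seed = 1),
            simulate_population(strong, seed = 2))

metrics <- metrics_table(cells)
gate_table(metrics)
#> Fission/fusion gate composition (fraction of cells)
#>        population
#> gate    weak_kd strong_kd
#>   HF       0.38     0.770
#>   Int      0.58     0.215
#>   Other    0.04     0.015
#>
#> Chi-square = 62.24, df = 2, p = 3.05e-14
#> ...
```

The two simulated knockdown-like populations were planted with
hyperfused fractions 0.38 and 0.77; the gate recovers them exactly, and
the chi-square test confirms the compositions differ. A
limiting-dilution assay at a planted frequency of 1 in 150:

```r
wells <- simulate_lda_wells(1 / 150, doses = c(1, 10, 100, 1000),
                            wells_per_dose = 24, seed = 3)
lda_fit(wells)
#> Limiting-dilution frequency (single-hit Poisson model)
#>   frequency: 0.006956 (1 in 143.8)
#>   95% profile CI: [0.004104 (1 in 243.6), 0.01127 (1 in 88.73)]
```

The point estimate (1 in 143.8) sits close to the planted 1 in 150,
which the profile interval covers.

## Command line

A thin CLI over the same functions lives at `inst/cli/mitomorph.R`
(subcommands `simulate`, `metrics`, `gate`, `quadrant`, `reciprocity`,
`lda`; see the header comment for the YAML config schema):

```sh
Rscript inst/cli/mitomorph.R metrics --in cells.csv --out metrics.csv
Rscript inst/cli/mitomorph.R lda --in wells.csv --compare control,kd
```
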