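# popcode

Analysis of motor-cortical population activity during unimanual and
bimanual food handling in head-fixed mice — and for anyone who needs a
tested, reusable implementation of the full analysis chain: behavioral
ethogramming from 3D hand/nose kinematics, transport-to-mouth event
detection, peri-event firing statistics, population geometry, correlation
structure, and kinematic decoding, with a synthetic-data generator that
makes every stage verifiable without any recordings.

## What it computes

Mice handle food in three conditions — **ipsilateral**, **contralateral**
(one hand, relative to the recorded hemisphere) or **bimanual** — and the
question at every level is whether neural activity depends on laterality
(which hand) and manuality (how many hands):

* **Ethogram** — per-hand states (holding/chewing, oromanual/ingestion,
  other) from thresholded hand–nose distances, combined into a seven-state
  ethogram; transitions refined by sigmoid (transport-to-mouth) and
  exponential (lowering) least-squares fits.
* **PETHs** — 20 ms bins over ±1 s around transport onsets; significance by
  a sham-event bootstrap (1000 uniform re-draws of the event times,
  statistic = max trial-mean rate over ±0.5 s, p < 0.001).
* **Preference statistics** — per-unit preference index
  `PI = (A − B)/(A + B)` on 100 ms response areas; strong preferences by
  uncorrected Mann-Whitney tests; area comparisons by Kolmogorov–Smirnov
  distance on hierarchically averaged CDFs and by earth-mover's distance on
  the 3×3 preference grid (exact transportation LP), both with label
  permutation tests.
* **Population geometry** — soft-normalized PCA (`x/(max + 5)`),
  participation ratio `tr(C)²/tr(C²)`, first principal angle and top-10
  alignment index between condition subspaces, with bootstrap predictions
  of what "perfectly invariant" and "perfectly orthogonal" encoding would
  look like at the recorded trial counts.
* **Correlation structure** — pairwise Pearson correlations of 5 ms binned
  counts within each condition's food-handling epochs; between-condition
  similarity of the vectorized upper triangles.
* **Decoding** — ridge-regularized linear readout of hand position from
  lagged spike windows (−200…+50 ms), contiguous tuning/training/testing
  thirds, cross-validated R², and cross-condition generalization
  `ΔR²/R²₀` (0% = perfect transfer, −100% = none) with perfect/no-
  generalization bootstrap nulls.

The synthetic generator produces kinematics with the plateau–sigmoid–
exponential structure of real food handling plus Poisson populations whose
condition dependence is controlled (`invariant`, `laterality_dependent`,
`manuality_dependent`, `fully_dependent`), so each pipeline stage has a
known answer. See `vignettes/methods.Rmd` for models, parameters and design
choices.

## Worked example

```r
library(popcode)

beh <- generate_kinematics(behavior_config(cycles_per_condition = 16), seed = 7)
st  <- stage_events(beh$kinematics, hemisphere = "left")
table(st$events$condition)
#>      bimanual contralateral   ipsilateral
#>            16            16            16

sp <- generate_spikes(beh$kinematics, st$events,
                      population_config(n_units = 24, mode = "laterality_dependent",
                                        gain_hz = 15, noise_gain_hz = 2),
                      seed = 8)
sp$recording
#> <recording m1/d1/p1: flM1 left hemisphere, 24 units, 210.9 s>

pst <- stage_peth(sp$recording, st$events, st$oro_epochs, n_boot = 1000, seed = 9)
sum(apply(pst$flags, 1, any))      # significantly responsive units
#> [1] 3
round(pst$responsiveness$proportions, 3)
#>      none   ipsi_only contra_only     bi_only ipsi_contra     ipsi_bi
#>     0.875       0.042       0.042       0.042       0.000       0.000
#> contra_bi         all
#>     0.000       0.000

prefs <- stage_prefs(pst$peths, pst$flags)
head(subset(prefs, responsive & !is.na(pi_laterality),
            c(unit_id, A_ipsi, A_contra, A_bi, pi_laterality, pi_manuality)))
#>    unit_id A_ipsi A_contra A_bi pi_laterality pi_manuality
#> 2     u002    2.4     0.27 1.34          0.80        -0.29
#> 12    u012    2.3     1.59 3.55          0.17         0.22
#> 16    u016    1.6     2.36 0.17         -0.18        -0.86

cr <- stage_corr(sp$recording, st$epochs, st$events)
cr$similarity
#>          cond_a        cond_b    rho
#> 1   ipsilateral contralateral -0.055
#> 2   ipsilateral      bimanual  0.213
#> 3 contralateral      bimanual  0.172
```

Reading the output: the ethogram recovered all 16 transports per condition;
three units pass the sham-event bootstrap, one per Venn category; unit
`u002` responds ~9× more strongly to ipsilateral than contralateral
transports (`PI = 0.80`, where +1 is fully ipsilateral-preferring); and the
correlation-structure similarity between the two unimanual conditions is
~0 — exactly what a `laterality_dependent` population (orthogonal loadings
across hands) should produce, while each unimanual condition retains some
similarity to bimanual (whose loadings mix both).

## Command line

```sh
Rscript inst/cli/popcode.R simulate --scenario flM1_like --seed 1 --out-dir sim/
Rscript inst/cli/popcode.R ethogram --in-dir sim/ --out-dir out/
Rscript inst/cli/popcode.R peth     --in-dir sim/ --out-dir out/
Rscript inst/cli/popcode.R decode   --in-dir sim/ --out-dir out/
```

Stages: `simulate | ethogram | peth | prefs | geometry | corr | decode |
report`, with common flags `--config cfg.json`, `--seed`, `--out-dir`,
`--log-level`. The JSON config carries every numeric constant of the
methods (see `default_config()`).
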