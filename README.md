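# digitME

Measurement error (ME) in landmark-based geometric morphometrics, with a
focus on *time lags*: what happens to Procrustes shape analyses when the
same landmarks are digitized in sessions separated by hours, days, or years,
and the operator's eye drifts so that some landmarks are placed in a
consistently different spot. digitME is aimed at morphometricians who want
to quantify digitization error in their own repeated-digitization designs,
and at methodologists studying how session bias propagates into tests of
biological signal.

## What it computes

For a complete individual × session (REP) grid of 2D landmark
configurations:

* **Shape variables** — TPS input/output, grid assembly and validation,
  generalized Procrustes superimposition (rotation-only, unit centroid
  size), tangent-space diagnostics, shape PCA, outlier ranking, UPGMA/NN
  phenograms.
* **Error decomposition** — the hierarchical Procrustes ANOVA
  (sex → individual → total ME, Goodall-type F on df × (2L − 4)) and the ME
  ANOVA, which centers each individual's REPs on its own mean and splits the
  remainder into systematic ME (the session bias), its interaction with
  groups, and random ME, each tested by the signal-to-noise ratio
  SNR = SS(effect)/SS(randME) with design-respecting permutations. EV
  ordination displays the bias subspace (R − 1 axes for R REPs); a planned
  pairwise series compares the first session against every later one, by
  increasing time lag.
* **Per-landmark precision** — raw-coordinate X+Y variances across REPs per
  individual and landmark (mm²), standardized medians and 90th percentiles,
  a combined imprecision index, threshold-based "precise" (both > 1.5
  dropped) and "most precise" (both > 1.0 dropped) configurations, and
  deviation-cloud plot data.
* **Signal robustness** — per-REP permutation tests of sexual dimorphism and
  static allometry, leave-one-out bgPCA classification (hit rate), PC1 and
  distance-matrix congruence between REPs, REP averaging, and the
  "visiting scientist" simulation: each sex digitized in a different
  session, re-superimposed and re-tested.
* **Synthetic data** — a generator with known ground truth emulating the
  design (58 individuals, 32 F / 26 M, 26 landmarks, 8 REPs at day offsets
  1, 1, 2, 4, 11, 41, 121, 7300), used for parameter recovery, power and
  type-I error studies.

`run_study()` orchestrates the whole pipeline from one seeded
configuration; the numbered scripts in `analysis/` run it stage by stage and
write tables under `results/`.

## Worked example

```r
library(digitME)

sim <- generate_dataset(synth_params(seed = 1))   # emulated study data
sh  <- gpa(sim$dataset)
tangent_diagnostic(sh)                            # r = 1.000000, slope = 0.999576
me  <- me_anova(sh, n_perm = 999, seed = 2)
me
#> ME ANOVA (type II SS; SNR = SS(effect)/SS(randME); 999 permutations)
#>      effect  df       SS        MS     SNR     p      Rsq
#>  individual  57 1.990440 0.0349200 7.21144 0.001 0.859027
#>      systME   7 0.046582 0.0066545 0.16877 0.001 0.020104
#>  systME:sex   7 0.004053 0.0005790 0.01468 0.977 0.001749
#>      randME 392 0.276011 0.0007041      NA    NA 0.119120
#>      total 463 2.317086        NA      NA    NA 1.000000
```

Individual variation dominates (Rsq 86%), random digitization error is an
order of magnitude smaller (12%), and the session bias is small (2%) but —
because it is tested against random ME, not against individual variation —
highly significant (SNR 0.17, p = 0.001). The bias does not differ between
the sexes (interaction p = 0.98). The time-lag series shows where the bias
lives:

```r
ts <- pairwise_timelag_series(sim$dataset, n_perm = 999, seed = 3)
ts$comparisons[ts$comparisons$effect == "systME",
               c("rep", "lag_days", "SNR", "p", "Rsq")]
#>     rep lag_days    SNR     p     Rsq
#>  d0001b        0 0.0253 0.040 0.00178
#>   d0002        1 0.0979 0.001 0.00646
#>   d0004        3 0.0588 0.001 0.00416
#>   d0011       10 0.0861 0.001 0.00603
#>   d0041       40 0.0675 0.001 0.00469
#>   d0121      120 0.0834 0.001 0.00592
#>   d7300     7299 0.3096 0.001 0.02110
```

Two sessions digitized on the same day are mutually unbiased (Rsq 0.2%);
any later session carries a small but significant bias (~0.5%), and the
session separated by 20 years carries about three times more (2.1%) — the
"visiting scientist effect". `mixed_design_test()` then shows its practical
consequence: sampling females from the old session and males from the rest
roughly doubles the apparent sex effect, while the (much larger) allometric
signal barely moves.

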