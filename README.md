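# painvar

Moment-to-moment neural variability of the stimulus-evoked EEG — not just
its average amplitude — may carry information about how well a person can
tell a strong painful stimulus from a weak one. `painvar` implements that
analysis end to end for single-channel (Cz) epoched EEG: windowed
variability metrics, rating-based discriminability scores, point-by-point
(partial) correlation inference with FDR and Bayes factors, dominance
decomposition, noise-injection and bootstrap robustness procedures, and
cross-modality rating matching — together with a synthetic multi-subject
generator with planted effects, so every stage is testable without any
restricted cohort data. It is aimed at EEG/pain researchers and at anyone
who needs a tested reference implementation of these statistics.

## The quantities at the core

For each trial, a 100 ms window slid in 1 ms steps over the epoch
(−500…+999 ms at 1 kHz) yields

* **temporal SD** — `sqrt(sum((x_i - mean(x))^2) / n)` (population
  divisor), the variability metric;
* **permutation entropy** — Shannon entropy of ordinal patterns of
  `m = 4`, `tau = 1` embeddings (97 vectors per 100-point window);
* **windowed amplitude** — the window mean, the classical companion.

Per subject, tracks are trial-averaged within intensity condition and
differenced (high − low: ΔSD, ΔAmplitude); discriminability is
ΔRating = mean high rating − mean low rating on the 0–10 NRS (AUC and d′
variants included). Across subjects, at every window center,

```
r(t) = corr(ΔSD(t), ΔRating)            — or partial, given ΔAmplitude(t)
```

with two-tailed p values, Benjamini–Hochberg FDR over post-stimulus
centers, and Jeffreys–Zellner–Siow Bayes factors (Cauchy scale
`sqrt(2)/2`). The contribution split uses total dominance,
`td_var = (R²_full − R²_amp + R²_var) / 2`, which sums with `td_amp` to
`R²_full` exactly.

## Worked example

```r
library(painvar)

cfg <- generator_config(n_subjects = 40, n_trials_per_condition = 10,
                        seed = 7)             # planted rho = 0.5
sim <- generate_cohort(cfg)

scores <- discrim_scores(sim$ratings)         # per-subject ΔRating
dvar <- cohort_diff_tracks(sim$epochs, "tempSD")
damp <- cohort_diff_tracks(sim$epochs, "amplitude")

track_association(dvar, scores, covariate_tracks = damp)
#> <association_track> partial, n = 40, 1401 points, 641 FDR-significant (alpha = 0.05)

roi <- roi_association(dvar, scores, covariate_tracks = damp)
#> ROI 325.5..345.5 ms: partial r = 0.545, p = 0.00033, BF = 82.7 (strong)
```

The generator planted a 0.5 correlation between each subject's
induced-variability gain and rating difference; the partial correlation at
the ΔSD peak (controlling ΔAmplitude) recovers 0.55 in this 40-subject
sample, with a Bayes factor in the "strong evidence" band. A large
post-stimulus cluster survives FDR; pre-stimulus points are never part of
the correction family.

The numbered scripts under `analysis/` run the full narrative on a
simulated 60-subject study — simulation, metric tracks, association,
dominance, robustness, matching, band profiles — writing tables and
figures under `results/analysis/`:

```sh
Rscript analysis/01_simulate.R 1 && Rscript analysis/02_variability_metrics.R
Rscript analysis/03_association.R && Rscript analysis/04_dominance.R
Rscript analysis/05_robustness.R 1 && Rscript analysis/06_matching.R 1
Rscript analysis/07_spectral.R
```

## Layout

* `R/` — the package: generator, epochs store + filters, windowed metrics,
  discriminability scores, association statistics, dominance, robustness,
  matching, band profiles, pipeline orchestration, figure helpers.
* `analysis/` — numbered narrative drivers over the package.
* `tests/testthat/` — unit, property and acceptance suites (oracle-checked
  estimators, planted-effect recovery, null calibration).
* `vignettes/neural-variability-methods.Rmd` — the methods vignette:
  model assumptions, parameter meanings and defaults, numerical choices,
  what the synthetic cohorts do and do not show.
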