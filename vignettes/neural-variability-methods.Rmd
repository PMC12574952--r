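---
title: "Windowed neural variability and intensity discriminability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed neural variability and intensity discriminability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painvar)
```

## The scientific question

Across people, the ability to tell a strong painful stimulus from a weak
one varies widely. The analyses in this package ask whether that
*intensity discriminability* — operationalised as the difference between a
subject's mean 0–10 ratings of high- and low-intensity stimuli
(ΔRating) — is encoded in the moment-to-moment *variability* of the
stimulus-evoked EEG at the vertex (Cz), over and above the classical
evoked-potential amplitude.

The pipeline therefore couples three layers:

1. **Windowed metrics** on epoched single-channel EEG
   (−500…+999 ms around stimulus onset at 1 kHz): temporal standard
   deviation, permutation entropy, and windowed mean amplitude in 100 ms
   sliding windows stepped by 1 ms.
2. **Between-subject inference**: point-by-point (partial) correlations of
   high-minus-low metric tracks with per-subject discriminability, with
   Benjamini–Hochberg FDR over post-stimulus window centers and JZS Bayes
   factors; dominance decomposition of the explained variance; Steiger /
   Fisher tests for comparing correlations.
3. **Robustness procedures**: noise injection sampled from each subject's
   own baseline, bootstrap power maps over subject and trial counts,
   cross-modality rating matching, and band-limited (delta/theta/alpha/
   beta) re-analysis.

Because the motivating cohort data are access-restricted, a first-class
synthetic generator with *planted* effects stands in for them: every
downstream stage is validated by recovering structure the generator is
known to contain.

## Windowed variability metrics

**Temporal SD.** For a window `x_1..x_n`,
`tempSD = sqrt(sum((x_i - mean(x))^2) / n)` — note the divisor `n`
(population form), which we keep deliberately and pin with tests against a
two-pass oracle. Windows are full only (no padding) and time stamps refer
to *window centers*, so a 1,500-sample epoch yields 1,401 centers from
−450.5 to +949.5 ms. Centered stamps keep variability peaks comparable
with evoked-component latencies; which alignment the field uses is rarely
stated, so we fix and document this one.

**Permutation entropy.** With embedding dimension `m = 4` and delay
`tau = 1`, a 100-point window yields 97 embedding vectors; each is coded
by the ordinal pattern of its ranks and PE is the Shannon entropy (natural
log) of the pattern distribution, bounded by `log(4!)`. Ties are ranked by
order of appearance: real-valued EEG makes exact ties measure-zero, but
integer-valued test signals need a deterministic rule. Because PE is
rank-based it is invariant to monotone amplitude transforms — it
complements rather than duplicates the SD.

**CV.** The coefficient of variation divides the SD by the window mean and
is unstable whenever the mean approaches zero, which baseline-corrected
EEG does constantly; it is provided for completeness, returns an `Inf`
sentinel near zero means, and is not used by the main analyses.

**Induced responses.** Subtracting the condition's trial-averaged waveform
from each trial leaves only phase-inconsistent activity. The windowed SD
of induced responses isolates the variability channel from evoked
amplitude; `induced_epochs()` enforces a zero trial average by
construction.

**Peak ROI.** Scatter-level statistics average each subject's difference
track over a ±10 ms interval (21 centers at 1 kHz) around the extremum of
the *subject-averaged* difference track, searched over post-stimulus
centers only; SD differences use the maximum, PE differences the trough.

## Discriminability scores

ΔRating (mean high − mean low) is the primary score: any constant
per-subject rating bias cancels. The AUC alternative is the Mann–Whitney
probability of superiority over all (high, low) trial pairs with ties
counted one half; it is invariant to any monotone rescaling of the
ratings and guards against subjects using the scale differently. d′
normalises the mean difference by the root mean of the two per-condition
variances (divisor `n − 1`). Rank-based AUC and half-credit ties are
choices the source material leaves open; both are pinned by brute-force
pair-counting tests.

## Inference machinery

**Point-by-point correlations.** At each window center the high-minus-low
metric value is correlated across subjects with the score — Pearson by
default, Spearman for small multi-level designs — and, in the partial
variant, adjusted for the amplitude difference *at the same time point*
through the standard three-correlation identity. p values are two-tailed
throughout. The FDR family is the post-stimulus centers of one track at
one channel; pre-stimulus points are excluded and never flagged.

**JZS Bayes factors.** Evidence is quantified by the Bayes factor of the
one-predictor linear model under the Jeffreys–Zellner–Siow prior: a
Cauchy prior of scale `sqrt(2)/2` on the standardised slope, implemented
as the Zellner–Siow inverse-gamma mixture over Zellner's g and integrated
adaptively over `log g` with asymptotic-safe log terms. The scale is
exposed (`rscale`) because toolbox defaults differ. A fine-grid
log-sum-exp quadrature serves as the independent oracle (agreement within
1%); partial correlations use the residual degrees of freedom. Bayes
factors are binned per Kass–Raftery (1–3.3 barely worth mentioning,
3.3–10 substantial, 10–100 strong, >100 decisive; reciprocals reported
below 1), with boundary values assigned to the upper bin.

**Comparing correlations.** Two dependent correlations sharing a variable
on the same cases use Steiger's z with the pooled-correlation covariance
term; correlations from disjoint groups (as after cross-modality
matching, where the two subsets contain different people) use the
independent-groups Fisher z test. Both are exposed; `matched_contrast()`
selects the independent-groups form.

**Dominance.** With exactly two predictors the general
averaging-over-orderings definition collapses to the closed form
`td_var = (R2_full − R2_amp + R2_var) / 2` (and symmetrically), whose
shares sum to `R2_full` exactly; the closed form is used and oracle-checked
against the ordering average at 1e−10. Negative shares can occur with
suppressor structure and are reported, not clamped.

## Robustness procedures

**Noise injection** builds a noise trace per trial from baseline segments
of randomly drawn trials of the *same subject* (with replacement),
preserving the subject's residual-noise structure. The baseline (500 ms)
is shorter than the post-stimulus stretch (1,000 ms), so two independent
segments are concatenated and trimmed — a choice the procedure leaves
open. Scales run 0–2 in steps of 0.2 (11 values); scale 0 is the exact
identity and pre-stimulus samples are never modified. Support is flagged
at `log10(BF) >= 0.5`.

**Power maps** bootstrap (with replacement) along one axis — subjects with
all trials, or trials with all subjects — and report, per resample size
and time point, the fraction of 100 resamples in which that point is
FDR-significant, with the 80% contour and the smallest size reaching it.
Per-trial metric tracks are computed once and re-averaged per resample.
One calibration caveat is inherent to the with-replacement design: at
sizes near the full sample, duplicated subjects make the per-resample
correlation tests mildly anticonservative, so the null-cohort rate sits
somewhat above the nominal 0.05 rather than at it. We keep the
with-replacement convention and test the null rate against a widened
bound rather than silently switching to subsampling.

**Rating matching** pairs each pain subject with an other-modality subject
whose high- and low-condition mean ratings both lie within ±0.5 NRS
(the worked rule: means of 6 and 4 admit candidates in 5.5–6.5 and
3.5–4.5), keeping the candidate with the smallest total absolute error,
breaking ties uniformly at random under the given seed. Greedy matching is
order-dependent; pain subjects are visited in ascending id order so
results are reproducible. Matching quality is validated by the hard error
bound, injectivity, and a two-sample t test on the matched groups' rating
differences. The greedy window rule does leave a small density-gradient
bias (matched partners drift ~0.1 NRS toward the offset modality's mean),
detectable by a paired test at large n but immaterial between subjects —
a known limitation of the procedure itself.

**Oscillatory profiling** filters single trials into delta (1–4), theta
(4–8), alpha (8–12) and beta (12–30 Hz) — shared band edges, no overlap
correction — and repeats both partial-correlation directions per band.
Slow-band windows (a 100 ms window sees a fraction of a delta cycle)
carry little within-window variance, so delta effects are assessed at the
peak-ROI level where point-by-point FDR lacks power.

## The synthetic generator

Per subject `i`, condition `c`, trial `k`:

```
x(t) = a_ic * ERP(t) + (sigma_b + [c = high] * dsigma_i) * g(t) * w_k(t) + eps_k(t)
r_ick = mu_i + [c = high] * D_i + eta,   eta ~ N(0, rating_noise_sd), clipped to [0, 10]
```

* `ERP(t)`: biphasic template — negative deflection at 200 ms (width
  45 ms), positive at 400 ms (width 55 ms, 4/3 the depth), scaled to a
  6 µV N2-like depth; zero pre-stimulus. Any biphasic template with these
  latencies would do; this one is fixed for reproducibility.
* `a_ic = 1 + gamma_i [c = high]`: the per-subject amplitude gain
  (mean 0.3, SD 0.15) models a 30% evoked enhancement for strong stimuli.
* `w_k(t)`: 1–30 Hz band-limited unit-SD Gaussian noise built in the
  frequency domain, fresh per trial, so its phase is random and its trial
  average cancels — the induced channel. `g(t)` is a post-stimulus
  Gaussian envelope centered at 300 ms (SD 150 ms), zero before onset.
* `eps_k(t)`: 1–30 Hz background noise (SD 1.2 µV) present in baseline
  and post-stimulus alike, matching the analysis filter band so the
  generator's spectrum is consistent with the preprocessing conventions.
* Per-subject parameters `(D_i, dsigma_i, gamma_i)` are drawn from a
  shared-factor Gaussian construction (equivalent to a Cholesky factor)
  that realises the planted correlations `rho_var_discrim` (default 0.5)
  and `rho_amp_discrim` (default 0.3) with `D_i ~ N(2, 1)` NRS units and
  `dsigma_i ~ N(1.5, 1.5)` µV (truncated below at `-sigma_b`; truncations
  are counted in the ground truth, as is rating clipping, because both
  bias recovery at the scale ends).

**Why these SNR defaults.** The windowed SD is a biased, noisy functional
of the planted gain: the square root compresses the gain against the
background (`sqrt((sigma_b + dsigma)^2 g^2 + noise^2)`), and a 100 ms
window of 1–30 Hz activity holds only ~6 effective degrees of freedom, so
a single trial's window SD carries ~30% sampling error. Averaged over 15
trials and differenced across conditions this still attenuates
between-subject correlations by ~10%. The defaults
(`sigma_b = 2`, `dsigma ~ 1.5 ± 1.5`, background 1.2 µV, rating noise
0.8) keep that attenuation small enough that a planted correlation of 0.5
is recovered within ±0.1 at 200 subjects — the regime in which the
recovery suites are meaningful. With a weaker variability spread or
heavier background noise the same code recovers a proportionally
attenuated coefficient; that is a property of the measurement model, not
a bug, and the recovery tests are explicit about the conditions they
assume. Within-subject rating noise (0.8 NRS) is a free parameter of the
model — empirical per-trial rating SDs for this paradigm are not
published — and stays configurable.

**What the generator does not emulate.** Volume conduction and multichannel
topography, artifacts (blinks, muscle), non-Gaussian rating distributions,
habituation/sensitisation across trials, and any nonlinear coupling
between amplitude and variability channels. Passing recovery tests on
this generator therefore shows the *pipeline* is correct and calibrated,
not that real cortices behave this way.

```{r tiny-example}
sim <- generate_cohort(generator_config(n_subjects = 8,
                                        n_trials_per_condition = 6,
                                        seed = 1))
dv <- cohort_diff_tracks(sim$epochs, "tempSD", step_ms = 10)
da <- cohort_diff_tracks(sim$epochs, "amplitude", step_ms = 10)
sc <- discrim_scores(sim$ratings)
roi_association(dv, sc, covariate_tracks = da, compute_bf = FALSE)$r
```

## Numerical choices

* **Filtering.** The band-pass is a 4th-order Butterworth applied forward
  and backward (zero phase, so N2/P2 latencies are not shifted). Rather
  than running a recursive filter twice, the squared magnitude of the
  bilinear-designed Butterworth is evaluated in closed form from the
  prewarped analog prototype and applied spectrally. The recursive
  realization amplifies rounding at a 1 Hz edge on 1 kHz data to ~1e−4
  relative error and its transfer polynomials are ill-conditioned for
  narrow low bands such as delta; the spectral form is the exact
  zero-phase cascade, linear to machine precision, at the cost of treating
  the epoch as circular (the outermost few samples of a filtered epoch
  should not be over-interpreted).
* **Epoch geometry.** Whether the +1,000 ms endpoint is inclusive is
  unstated in the conventions we follow; we fix 1,500 samples
  (−500…+999 ms) and document it. t = 0 is stimulus onset.
* **Rolling SD** uses the cumulative-sum identity with a non-negativity
  clamp; at EEG magnitudes (tens of µV over 100-sample windows) the
  cancellation error is far below the 1e−12 oracle tolerance.
* **BF quadrature** integrates over `log g` with `log1p` asymptotics so
  extreme abscissae cannot overflow; failure raises an error with the
  (r, n) diagnostics rather than returning a silent NA.
* **Degenerate inputs.** Constant tracks have no unique peak (first
  extremum, with a warning); subjects without rating variance are excluded
  from intra-individual analysis with a warning; collinear dominance
  predictors and zero-variance covariates are errors; `z` identical to
  `y` in a partial correlation returns the 0/0 limit 0.
* **Seeds.** Every stochastic routine (generator, matching tie-breaks,
  noise injection, bootstrap) takes an explicit integer seed and restores
  the caller's RNG state, so identical configuration and seed reproduce
  results bit-exactly.

## Problem sizes

The validation suites run at sizes chosen to finish on a single CPU while
leaving the statistical claims testable: cohorts of 12–70 subjects with
8–15 trials per condition for property and scenario tests; 200 subjects
for parameter-recovery and matching suites; 20 seeds for Monte-Carlo
claims; 40–100 bootstrap repetitions per power-map size. The analysis
drivers under `analysis/` use a 60-subject, 12-trial cohort. All sizes are
parameters, and the same code paths scale to the 100+-subject,
15-trial-per-condition regime of real studies.

## Known limitations

* Single-channel by design: the pipeline never models spatial structure.
* The amplitude covariate is the windowed mean at the same time point;
  evoked energy that expresses itself in the window's *variance* (steep
  slopes around component transitions) is not fully captured by that
  covariate, so partial correlations control amplitude in the windowed-mean
  sense only.
* Trial-axis power maps at one trial per condition use that trial's track
  directly; SD-of-trial-average variants are meaningless there.
* The greedy matcher is order-dependent (documented, seeded) and is not an
  optimal-assignment matcher, by design.
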