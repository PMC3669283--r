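---
title: "glovekin: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glovekin: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glovekin)
```

# The measurement problem

Repetitive thumb-to-finger opposition (index → medium → ring → little,
cycling) is a sensitive probe of fine hand motor function. A sensor-engineered
glove sampling at 1 kHz records each thumb-finger contact as an onset/offset
pair, from which four parameters are extracted per 60-s trial:

* **TD** (touch duration, ms): contact time `t_off − t_on`, per touch;
* **ITI** (inter-tapping interval, ms): gap between the end of one contact
  and the start of the next on the same hand;
* **RATE** (Hz): `1000 / (mean TD + mean ITI)` — the defining formula is
  applied to the trial means, not averaged per cycle (the two differ under
  jitter; the count-based alternative is exposed via
  `movement_rate(method = "count")` but is not the default);
* **IHI** (inter-hand interval, ms; bimanual trials): mean absolute
  difference between corresponding left- and right-hand touch onsets. IHI is
  a cost — larger values mean worse bimanual coordination.

Trials come in four conditions: self-paced at spontaneous (SV) and maximal
(MV) velocity with the dominant (right) hand, metronome-paced at 2 Hz
unimanually (2HZ) and bimanually (2HZ_BIM).

The package covers the full analysis chain: validated event-stream I/O,
kinematic extraction, test-retest reliability (ICC / SEM / SRD), group
comparison and clinical correlation for a multiple-sclerosis (MS) vs
healthy-control (HC) cohort, a stepwise-logistic **finger motor impairment
score** with ROC and leave-one-out evaluation, and a calibrated synthetic
cohort generator that stands in for raw recordings (none were deposited).

# Kinematic conventions

Timestamps are integer milliseconds (the acquisition is 1 kHz); fractional
inputs are rejected rather than rounded, keeping extraction bit-exact.
Contact occupies the closed interval `[t_on, t_off]`, trial-relative and
0-based. Same-hand overlapping contacts are physically impossible and are
rejected at validation; `repair = TRUE` merges same-finger overlaps of at
most 5 ms and truncates different-finger ones (a full merge across fingers
would fabricate a contact that never happened).

**IHI pairing.** "Corresponding touch" is not operationally defined when the
hands desynchronize by a whole cycle, so pairing is by cycle position after
alignment on finger identity: two pointers walk the hands' event lists, a
pair is emitted when the current fingers match, and on mismatch the earlier
onset advances (and is counted in `n_excluded`). This is deterministic,
order-preserving, and re-aligns after a dropped touch. Partial first/last
cycles are kept for TD and excluded only where a successor or partner is
required (ITI, IHI). Negative gaps surviving repair are clamped to 0 and
counted in `n_excluded`. Out-of-order finger touches are retained for timing
statistics — subjects practice until they produce the sequence without
errors, so this mainly affects synthetic stress tests.

# Reliability statistics

Test-retest agreement over a subjects × sessions matrix uses the two-way
random-effects, absolute-agreement ICC (McGraw-Wong A,1 and A,k) computed
from ANOVA mean squares; negative estimates are reported as computed. The
average-measure column of a two-session design numerically equals the
Spearman-Brown step-up of the single-measure column (`spearman_brown()`),
which the tests verify on the published table.

The smallest real difference uses the SEM route:

$$\mathrm{SEM} = \mathrm{SD_{pooled}}\sqrt{1-\mathrm{ICC}},\qquad
  \mathrm{SRD} = 1.96\sqrt{2}\,\mathrm{SEM},$$

with the pooled SD the root-mean-square of the two session SDs. The source
table never prints its formula; this choice reconstructs four of its five
SRDs within ~2%. The RATE(SV) row is a documented exception (the formula
gives ≈ 0.63 against a printed 0.51); the discrepancy is asserted in the
acceptance suite, not forced into agreement. IHI enters all reliability
analysis on the natural-log scale — the published log-scale session means of
≈ 3.0 match `ln` of a ~20 ms IHI, confirming the natural logarithm.

# Group statistics

Group contrasts use a two-sided Mann-Whitney U: exact enumeration of rank
assignments for `n1 + n2 ≤ 12` (tie-aware), otherwise a tie-corrected normal
approximation with continuity correction. The identity AUC = U/(n₁n₂) is
tested across modules with the same midrank tie convention.

Clinical correlations are partial Spearman: rank-transform the parameter,
the scale and age, then the partial Pearson correlation of the ranked
variables given ranked age, with a t-based p value on n − 3 df. The 5 × 9
grid is reported with unadjusted p values and a significance flag at 0.05 —
no multiplicity correction, matching the source's reporting convention (the
output carries a note to that effect).

Disability strata follow the published bins exactly — HC, EDSS {0}, [1, 2],
[2.5, 4], (4, 7] — note EDSS 0.5 falls in no bin and is excluded from strata
analysis. The trend test is a one-way-ANOVA linear contrast with equally
spaced stratum scores; pairwise stratum-vs-HC contrasts use the pooled ANOVA
error, unadjusted for age or multiplicity (the source does not state either
adjustment; this is documented rather than guessed).

# The impairment score

Candidate features RATE(SV), RATE(MV), TD(2 Hz), ITI(2 Hz) and ln IHI enter
a forward stepwise logistic regression with a likelihood-ratio entry test at
α = 0.05; age is forced into the model and never tested ("stepwise" alone
does not fix a direction — forward/LR is the conservative reading). The
**finger motor impairment score** is the linear predictor over the selected
*motor* features only: age serves as an adjustment covariate during fitting
but is excluded from the score, since the score is compared across strata of
all ages. Higher scores are more impaired; with the published odds ratios
(0.17 for RATE(SV), 23.17 for log IHI) the score decreases in rate and
increases in asynchrony, which the tests assert as sign/monotonicity
properties.

Complete separation is flagged and coefficients fall back to a lightly
ridge-penalized fit (quadratic penalty, BFGS) — separation is expected only
at toy sample sizes.

ROC analysis uses the empirical curve with midpoint tie handling; the AUC
comes from the rank identity and its CI and p value against 0.5 from the
DeLong variance. Leave-one-out cross-validation refits the **fixed** final
feature set on each n−1 subset and scores the held-out subject with the full
linear predictor; re-running selection inside each fold is available
(`reselect = TRUE`) but the default evaluates the final model, which is what
the published 0.89-vs-0.88 comparison describes. A caveat the tests
document: LOO scoring of a *null* feature is pessimistically biased below
AUC 0.5 (the refit coefficient anti-correlates with the held-out label), so
"≈ 0.5 under the null" is not a sound assertion for LOO — only an upper
bound is.

# The synthetic cohort: a stated world

The generator's defaults are the published cohort, fixed once:

* **Group laws.** Cross-sectional feature distributions per group come from
  the printed means ± SEM with SEM → SD via √n (80 HC, 40 MS): RATE(SV)
  2.40 ± 0.05 vs 1.93 ± 0.09 Hz, RATE(MV) 3.25 ± 0.06 vs 2.67 ± 0.10 Hz,
  TD 213.82 ± 4.68 vs 246.67 ± 10.30 ms, ITI 279.63 ± 5.10 vs
  269.24 ± 10.92 ms, IHI 18.87 ± 0.87 vs 41.92 ± 4.48 ms. Rates/TD/ITI are
  Gaussian; IHI is a mean/SD-matched lognormal (it is skewed, which is why
  the analysis logs it).
* **Asynchrony model.** Signed per-cycle inter-hand asynchrony is zero-mean
  Gaussian with a subject- and session-specific scale σ, so the extracted
  IHI is half-normal-mean `σ√(2/π)`. The source defines only the absolute
  difference; zero-mean Gaussian is the minimal generative law consistent
  with it.
* **Between/within split.** The printed SEMs give the *total* cross-sectional
  SD; how it splits into stable subject traits vs session-to-session
  variation is a free parameter (the source reports no decomposition). The
  split uses the published single-measure ICCs (between share = ICC), which
  simultaneously reproduces the cross-sectional laws and the reliability
  table. The session effect is additive Gaussian for the Gaussian-margin
  traits and additive on the log scale for σ — exact-margin choices, rather
  than a uniformly multiplicative effect, so that group means stay unbiased.
* **Paced trials.** Onsets lock to the subject's own period lattice
  (TD + gap, mean ≈ 493 ms) with Gaussian tone-locking jitter, not to the
  500 ms tones: the printed 2 Hz-condition means imply subjects tap slightly
  fast relative to the metronome, and hard tone-locking could not reproduce
  them. Trial-level jitters (cycle 25 ms, touch 12 ms, tone-locking 20 ms)
  are realistic magnitudes chosen once; they contribute ~1–3 ms to trial
  SEs, negligible against between-subject spread.
* **Clinical covariates.** Age, sex, EDSS (on the 0–7 half-point grid with a
  median-2 probability table; 0.5 given weight 0 so every patient falls in a
  published stratum), disease duration, MSFC, 9-HPT, T25W, PASAT and MFIS
  subscales, with marginals from the cohort description and plausible values
  where unreported (9-HPT 24 ± 9 s, T25W 6.5 ± 3 s, PASAT 44 ± 10,
  MFIS subscales summing to the reported 26.8 ± 13.7 total).

**Copula calibration.** Latent motor traits and clinical covariates are
linked by a Gaussian copula. Targets are *observed-scale* Spearman
correlations (what a correlation table on extracted data reports): the
significant published cells (e.g. IHI-EDSS 0.56) plus a plausible
clinical-scale block (EDSS-MSFC −0.65, MSFC and its components, MFIS
subscale inter-correlations). Two calibrations map targets to the latent
correlation: division by √ICC for the measurement attenuation of each motor
trait, and a numeric-integration solve for the rank-correlation attenuation
caused by EDSS's discreteness. Cells not pinned by a target are *completed*
by alternating projection between the PSD cone and the fixed-cell
constraint — deterministic, and an error is raised if no PSD completion
exists (mutually inconsistent targets) or a single target is unattainable
after attenuation (|ρ| ≥ 1). Monte-Carlo checks recover the IHI-EDSS target
within ±0.01 at large n.

**What a green test does not establish.** The generator reproduces marginal
laws, one rank-correlation structure, and test-retest variance components.
It does not model sequence errors or learning, per-finger differences,
fatigue within a trial, non-Gaussian asynchrony tails, or any biomechanics;
agreement of downstream statistics with the published values shows the
*pipeline* behaves correctly under the stated world, not that the world is
complete.

# Numerical choices and degenerate inputs

* ICC of a constant matrix is an error (undefined), as is a rate for a
  trial with fewer than two touches; one-hand-empty bimanual trials error at
  IHI; fewer than three IHI pairs warns.
* Exact Mann-Whitney enumerates `choose(n, n1)` assignments up to n = 12;
  beyond that the tie-corrected normal approximation with continuity
  correction matches `wilcox.test(correct = TRUE, exact = FALSE)`.
* A constant covariate degrades partial Spearman to plain Spearman (n − 2
  df); constant x or y is an error.
* Ties in ROC scores use midpoints (trapezoidal curve); a perfectly
  separated sample reports a zero-width DeLong CI and p = 0.
* Provenance headers on every output carry the package version, seed and a
  config hash but deliberately no timestamp, so identical config + seed
  reproduce outputs byte-for-byte.

# Known limitations

* The RATE(SV) SRD of the published reliability table cannot be reproduced
  by the SEM route (≈ 0.63 vs printed 0.51); the original computation for
  that row is unknown and intentionally not imitated.
* Subject-level published results (exact p values, the fitted ORs 0.17 and
  23.17, individual correlation cells) are not reproducible without the
  original data; they are covered by distribution-matched stochastic checks
  and sign/monotonicity assertions.
* The half-point EDSS 0.5 falls outside every published stratum; such
  subjects are excluded from strata analysis (the default EDSS table
  assigns it probability 0).
* Stepwise selection at n = 120 with correlated candidates is unstable by
  nature; ln IHI is selected almost always, while the second slot can
  alternate between the two rate measures across replicates.
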