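---
title: "Methods: IMU-based classification of NIOSH lifting-risk classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU-based classification of NIOSH lifting-risk classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`liftrisk` implements a complete chain for classifying repeated manual
lifting into the two risk classes of the Revised NIOSH Lifting Equation
(RNLE) from a single sternum-mounted inertial measurement unit. This
vignette is the package's account of the underlying models, the tunable
parameters and their defaults, the numerical choices, and the limits of
what the synthetic-data tests demonstrate.

## 1. The RNLE scoring model

The RNLE gives a Recommended Weight Limit as a product of a load constant
and six attenuation multipliers,

$$\mathrm{RWL} = LC \cdot HM \cdot VM \cdot DM \cdot AM \cdot FM \cdot GM,$$

and the Lifting Index $LI = \mathrm{AWL}/\mathrm{RWL}$ with the actual
weight lifted in the numerator. The load constant is sex- and age-specific
(25/20 kg for men under/over 45 years, 20/15 kg for women). The package
uses the standard metric multiplier forms

* horizontal: $HM = 25/H$ for hand-to-ankle distance $H$ in cm, 1 when
  $H \le 25$, 0 beyond the 63 cm validity envelope;
* vertical: $VM = 1 - 0.003\,|V - 75|$ for origin height $V$;
* displacement: $DM = 0.82 + 4.5/D$, with the conventional 25 cm floor so
  that no or small vertical travel gives $DM = 1$; 0 beyond 175 cm;
* asymmetry: $AM = 1 - 0.0032\,A$, 0 beyond 135 degrees;
* frequency ($FM$) and coupling ($GM$) from the published lookup tables,
  shipped as versioned CSVs under `inst/extdata/` and recorded in every
  result via `table_version`. Frequencies between tabulated rows are
  rounded **up** to the next row, the conservative direction.

All multipliers are clamped to $[0, 1]$, hence
$\mathrm{RWL} \le LC$ always. A task whose geometry drives RWL to zero has
an undefined LI; it is reported as `li = Inf` with `li_defined = FALSE`
and classified RISK rather than silently producing a number. The boundary
case $LI = 1$ is classified RISK, the conservative reading of an
"acceptable below 1, at risk above 1" rule.

Recomputing the study-style light task (6.5 kg, $H = 40$, $V$ 70→120 cm,
4 lifts/min, short duration, good coupling) with these tables gives
$LI \approx 0.55$; published analyses of the same configuration print
0.57, a discrepancy attributable to national variants of the multiplier
tables (some discretise $HM$/$VM$). The package documents both values and
relies only on the classification (both are NO_RISK), which is robust to
the table variant for all six study configurations.

## 2. Segmentation of lifts

The detector operates on one reference channel (default `ax`, the vertical
acceleration, where the lifting movement is most expressed):

1. **Band-pass** 1–50 Hz, 8th-order Butterworth, applied forward-backward
   (`signal::filtfilt`) so the envelope is not phase-shifted — a phase lag
   would bias every detected boundary in one direction. The upper cutoff
   is clamped to $0.45\,f_s$ when the sampling rate cannot support it
   (a 20 Hz recording cannot carry a 50 Hz edge); the clamp is emitted as
   a classed warning and lands in the run manifest. The sampling rate is
   required metadata, never assumed.
2. **Rectification and Savitzky–Golay smoothing** (order 3). The classic
   frame of 1001 samples is the default. At 128 Hz that is a 7.8 s window,
   comparable to the 15 s lift period, and it measurably blurs burst
   edges (about 0.6 s median boundary error on synthetic sessions); the
   `"auto"` mode instead sets the frame to the nearest odd number of
   samples to $0.4\,f_s\,(60/\text{lifts per min})$ — 40% of the lift
   period, 769 samples at the defaults — which brings the median boundary
   error to about 0.15 s. Synthetic-cohort pipelines use `"auto"`;
   the numeric default remains for legacy 20 Hz field recordings, where
   1001 samples (50 s) must be shrunk explicitly by the user or via
   `"auto"`. Savitzky–Golay smoothing of a rectified signal can overshoot
   below zero near sharp edges; the envelope is clipped at zero to honour
   its non-negativity contract.
3. **Thresholding.** Runs where the envelope exceeds
   $\theta = \alpha \cdot P_{95}(\text{envelope})$ are candidate lifts;
   runs closer than `min_gap_s` (default 2 s) are merged, then runs
   shorter than `min_duration_s` (default 1 s) discarded. The relative
   threshold makes $\theta$ invariant to overall amplitude. The defaults
   ($\alpha = 0.3$) are an explicit design choice — the empirical
   threshold of the original procedure is not specified anywhere — and
   when the number of lifts in a trial is known (`expected_count`), a
   bisection over $\alpha \in [0.05, 0.95]$ matches the run count, with
   the closest solution and a classed warning when no $\alpha$ matches
   exactly. A contrast guard precedes all of this: if the envelope's 95th
   percentile is not at least twice its median, the recording has no
   lift-like quiet baseline (e.g. it is noise only, or activity fills most
   of the trial) and no regions are returned rather than one spurious
   all-covering run.

Intervals are 0-based and half-open, disjoint and sorted; the same
intervals index all six channels.

## 3. The feature catalogue

Nineteen features per lift and channel; names are feature + channel
(`RSAax` … `PFvz`), 114 columns in total. Numerical conventions that are
not forced by the definitions:

* **MEAN** is the mean of the *rectified* segment. A zero-phase band-passed
  segment has signed mean ~0 by construction, which would carry no
  information and is inconsistent with published per-class MEAN values
  being positive while the 25th percentile is negative. SD and the
  percentiles are computed on the signed segment.
* **HM** (harmonic mean) on a signed zero-crossing signal is numerically
  explosive — single near-zero samples dominate $n/\sum 1/x_i$. Samples
  with $|x| < 10^{-12}$ are excluded and the instability is left visible
  (screening consistently finds HM non-discriminative, which is itself
  informative) rather than patched away.
* **FD** is Katz's waveform fractal dimension computed on the planar
  sample-index curve (unit abscissa step per sample):
  $\mathrm{FD} = \log_{10} n \,/\, (\log_{10} n + \log_{10}(d/L))$ with
  $L$ the path length and $d$ the maximal excursion from the first point.
  This yields values just above 1 for near-sinusoidal lifts, the range
  published analyses report. The cost is that FD is only approximately
  invariant under amplitude scaling (exactly invariant variants give
  values near 1.7 for oscillatory segments, far from the published
  range); the property tests therefore check FD stability under scaling
  within a tolerance of 0.02 over a two-octave range. A degenerate flat
  segment returns exactly 1.
* **Spectrum**: raw unwindowed FFT periodogram of the segment, one-sided,
  DC bin excluded, $P_k = |X_k|^2/N^2$ at $f_k = k f_s / N$. **EN** is
  the Shannon entropy of the normalised spectrum divided by $\log K$, so
  $EN \in [0,1]$ with 0 for a one-bin spectrum and 1 for a uniform one;
  an all-zero segment takes EN = 0 and zero for the remaining spectral
  features, by convention. **KU**/**SK** are plain moment kurtosis and
  skewness of the *spectrum-value distribution* $\{P_k\}$ — the reading
  consistent with the very large published magnitudes (order $10^2$) —
  not spectral-shape moments over frequency. **MDF** is the lowest
  frequency reaching 50% cumulative power; **PF** the lowest frequency at
  the spectrum maximum on ties.

## 4. Statistical screening

Features are compared between classes on *paired* lifts: the $i$-th lift
of a subject's NO_RISK trial against the $i$-th lift of the same
subject's RISK trial (260 pairs in the full design). Normality of each
class's paired values is tested with Shapiro–Wilk at the same
$\alpha = 0.05$; two normal classes get a two-tailed paired $t$-test,
anything else the Wilcoxon signed-rank test. No multiple-testing
correction is applied by default, matching the original protocol;
Benjamini–Hochberg is available (`p_adjust = "BH"`), as are per-subject
mean pairing (13 pairs) and normality assessment on the paired
differences.

A caveat the synthetic experiments expose: per-lift pairing treats the 20
lifts of a trial as exchangeable replicates. Any session-level effect
(e.g. day-to-day amplitude differences) is shared by all 20 pairs of a
subject, so the effective sample size is nearer the number of subjects
than the number of pairs and the per-feature type-I rate on *session-level*
null effects is inflated. On exchangeable null pairs the tests are
calibrated (the acceptance suite verifies ≈5% empirically); per-subject
pairing is the remedy when session effects are suspected.

## 5. Classifier chain

* **Correlation pruning** (`prune_correlated`): greedy scan in catalogue
  order; a feature joins the kept set only if its absolute Pearson
  correlation with every kept feature is ≤ 0.7. Deterministic; an option
  scans in ascending screening-p order instead. Constant columns are
  dropped with a classed warning.
* **Outlier removal** (`remove_outliers`): one pass, never iterated, on a
  preliminary logistic fit with all kept features. Cutoffs are Cook's
  distance > 0.5 and leverage > $4(k+1)/n$. The frequently quoted OLS
  rules (4/n and $2(k+1)/n$) were evaluated and rejected: on clean
  simulated logistic data they flag 10–18% of instances, an order of
  magnitude more than this screen removes in practice (≈1%); the chosen
  cutoffs flag ~1–2% on clean data while always catching an injected
  label-inconsistent gross outlier. Both are arguments. A guard refuses
  the procedure when $n < 5k$.
* **Logistic regression and backward pruning** (`fit_risk_model`): RISK
  coded 1, maximum likelihood via `glm`. Pruning removes, one feature per
  round (stepwise; a batch mode exists), the weakest feature whose
  per-feature *likelihood-ratio* p-value exceeds $\alpha$, or failing
  that a feature whose odds ratio is within `or_epsilon = 0.01` of 1, and
  refits until stable. Likelihood-ratio rather than Wald p-values drive
  the decisions because the Wald statistic collapses to non-significance
  exactly when a feature separates the classes (the Hauck–Donner effect)
  — under Wald pruning a perfectly discriminative feature would be the
  first one discarded. The coefficient table still reports Wald
  statistics, the convention of standard software output. (Quasi-)
  separation is flagged and reported, not treated as an error; IRLS
  non-convergence without separation is an error.
* **Evaluation**: 2×2 confusion matrix with NO_RISK as the first row;
  sensitivity is the NO_RISK recall and specificity the RISK recall
  (this row convention matches how the reference analyses tabulate their
  results). Percentages are rounded half-up to one decimal. Metrics are
  *apparent* (resubstitution) — the protocol being reproduced fits and
  evaluates on the same instances and the report labels them as such. An
  honest generalisation estimate would need subject-wise cross-validation,
  which is deliberately not the replication path.

The events-per-variable ratio (smallest class size over the number of
final features) is reported with the model; values above 10 indicate the
fit is not overparameterised by the usual rule of thumb.

## 6. The synthetic generator

`synth_config()` encodes the emulated study design: 13 subjects × 2 trials
(one per class) × 20 lifts at 4/min over 300 s, sampled at 128 Hz (20 Hz
is supported; the generator refuses rates that cannot carry its
oscillation band). Each lift is a Hann-windowed burst of 3–5 s centred on
the metronome grid (±0.2 s timing jitter) containing a dominant tone
drawn from 1.2–1.6 Hz per subject plus a half-amplitude second tone one
octave up, on all six channels, over a Gaussian baseline at 5% of each
channel's burst amplitude. Channel amplitudes (ax 2.0, ay 0.8, az 1.6
m/s²; vx 0.23, vy 0.67, vz 0.17 rad/s) are set to half the peak-to-peak
magnitudes typical of sternum recordings of squat lifts.

The RISK class differs from NO_RISK by a single mechanism: every burst
amplitude is multiplied by `class_gain` (default 1.2). This reproduces
the *direction* of the published class effects for amplitude- and
power-type features (RSA, SD, POW, CL, PPA rise with class gain) and
nothing else — no kinematic forward model, no load-dependent tempo or
spectral shift, no fatigue.

Because the class effect is a pure gain, the cohort's discriminability is
set entirely by the amplitude dispersions: an inter-subject lognormal
scale (sdlog 0.13, shared by both trials of a subject — the paired
design), a session-level scale (sdlog 0.05, test–retest variability
between the two trials) and independent per-lift, per-channel jitter
(sdlog 0.1, technique variation). These were calibrated so that the full
pipeline at `class_gain = 1.3` operates in the apparent-accuracy regime
the sternum-IMU literature reports (mid-80s percent), and then frozen.
They are deliberately *not* chosen to reproduce published per-feature
means or SDs: the real data's within-class spread includes effect
structure (load-dependent kinematics) that a pure amplitude model cannot
carry, and matching those SDs while keeping a single latent gain would
cap attainable accuracy near 70%. Consequently the synthetic tests
demonstrate that the *pipeline machinery* — segmentation, features,
screening, pruning, fitting, evaluation — behaves correctly and
discriminates when a class effect of realistic size is present; they do
not validate the biomechanical claim that real lifting signals carry such
an effect, which only the original recordings could.

All randomness flows from one master seed through fixed per-subject,
per-trial substreams; identical seeds give bit-identical cohorts.

## 7. Problem sizes and reproducibility

The package's own verification uses: 1000 random tasks for the RNLE
property checks; 50 seeded sessions for segmentation recovery (expecting
≥95% with exactly 20 detected lifts and sub-half-second median boundary
error); 200 replicates × 6 features × 260 pairs for the screening type-I
calibration and 100 seeds for its power check; and 20 full-cohort
pipeline runs at `class_gain = 1.3` (expecting ≥75% apparent accuracy in
at least 18) plus 3 null runs at `class_gain = 1` (expecting ≤60%,
i.e. chance-level behaviour after pruning). `scripts/acceptance.R` reruns
the main computations at a user-supplied seed and writes the resulting
quantities as JSON.

## 8. Known limitations

* The multiplier-table variant used by any particular national RNLE
  adaptation may differ from the standard tables shipped here; printed LI
  values from such variants can differ by a few hundredths.
* The segmentation threshold policy (relative $P_{95}$ threshold, merge
  and duration rules, count-matching bisection) is this package's design;
  the original procedure says only that an empirical threshold was used.
* Whether lift regions should include the lowering phase is ambiguous in
  the source protocol; the detector returns whatever exceeds the envelope
  threshold, which for rhythmic lift-and-lower cycles is the full
  movement burst.
* Resubstitution metrics overstate generalisation; subject-wise
  cross-validation is the honest estimate and is intentionally outside
  the replication path.
* The generator's single-gain class model cannot (and does not try to)
  reproduce frequency-domain class shifts (MDF/MNF) seen in real data.
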