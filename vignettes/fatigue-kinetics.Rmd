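---
title: "Individual-based exponential kinetics of neuromuscular fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-based exponential kinetics of neuromuscular fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatkin)
```

## The measurement and the model

During repeated maximal contractions, three variables are tracked at
interspersed isometric neuromuscular tests, each expressed in percent of its
pre-fatigue baseline:

* **IMVC** — the isometric maximal voluntary torque plateau, quantified as
  the mean torque over the 500 ms preceding the superimposed stimulus;
* **VA** — voluntary activation by corrected twitch interpolation,
  $VA = \left[1 - \frac{ST \cdot (T_{stim}/T_{max})}{Q_{tw}}\right] \times 100$,
  where $ST$ is the torque increment evoked by a doublet delivered during the
  contraction, $T_{stim}$ the torque at the stimulation, $T_{max}$ the maximal
  torque of that contraction, and $Q_{tw}$ the potentiated resting twitch.
  The $T_{stim}/T_{max}$ weight corrects for stimuli delivered slightly off
  the true peak;
* **Q_tw** — the evoked torque of the relaxed, potentiated muscle, an index
  of peripheral (contractile) function.

Each subject's time course of each variable against accumulated contraction
time $t$ (seconds of maximal effort) is modeled as a mono-exponential
decline toward a stable state:

$$DV(t) = A + (100 - A)\,e^{-t/\tau}$$

with asymptote $A$ (percent of baseline; interpreted as the individual's
critical threshold for that variable) and curvature constant $\tau$
(seconds). The model passes through 100 at $t = 0$ by construction, and 95%
of the total decline $100 - A$ is completed by $\tau \ln 20 \approx 3\tau$,
independently of $A$.

Because time can be eliminated between two such models fitted to the same
subject and condition, VA and Q_tw admit a closed form in the torque level
itself:

$$t = -\tau_{IMVC}\ln\frac{IMVC - A_{IMVC}}{100 - A_{IMVC}}
\qquad\Rightarrow\qquad
DV = A_{DV} + (100 - A_{DV})
\left(\frac{IMVC - A_{IMVC}}{100 - A_{IMVC}}\right)^{\tau_{IMVC}/\tau_{DV}}$$

`dv_at_imvc()` implements the closed form directly; a property test verifies
that it coincides with `predict()` composed with `invert_imvc()` to $10^{-9}$
over a thousand random parameter draws. Torque decrements of 10, 20 and 30%
are interpreted as IMVC levels of 90, 80 and 70% of baseline. A subject whose
fitted $A_{IMVC}$ lies at or above the target level never reaches that
decrement; such estimates are flagged unreachable and excluded from cohort
means (in the packaged reference cohort, subject S09's low-force torque
asymptote of 76% makes the 30% decrement unreachable, and five high-force
asymptotes at or above 70% do the same there).

## Fitting

`fit_exponential()` minimises the sum of squared errors with bounded
Levenberg-Marquardt (A in [0, 100], tau in (0, 10^4]), from a deterministic
multi-start protocol: $A_0 = \min(\text{values})$, $\tau_0$ the first time
the series drops below $A_0 + (100-A_0)/e$ (the model's value at $t=\tau$),
five starts jittered by up to ±50%. A quasi-Newton box-constrained search is
the fallback if every Levenberg-Marquardt start fails. Goodness of fit is
$R^2 = 1 - SSE/SST$ about the series mean and an F-test of the model against
the constant-mean model on $(1, n-2)$ degrees of freedom — the individual
regressions on realistic simulated data are significant by this test.

Two details were genuinely open and are package decisions:

* **The $t = 0$ point is included by default.** The model passes through it
  structurally, so it constrains nothing, but it stabilises $SST$;
  `include_t0 = FALSE` fits only the post-baseline tests and noiseless
  recovery is identical either way.
* **Boundary asymptotes are flagged, not rejected.** A series constant at
  100 carries no information about $\tau$; it is pinned at $A = 100$, marked
  degenerate, and excluded from downstream inversion (which requires
  $A < 100$).

Tests compare the optimiser against an independent brute-force oracle — SSE
minimisation over a 0.1-step $(A, \tau)$ lattice — and require the
continuous fit to match or beat every lattice point. Parameters themselves
are not compared against the lattice: with only nine noisy observations the
SSE surface has a flat valley along which quite different $(A, \tau)$ pairs
are nearly equivalent, which is a property of the design, not of the
optimiser.

## The synthetic cohort generator

The generator exists so every downstream stage has known ground truth. Its
defaults are the study conditions of the reference cohort:

* 13 subjects; neuromuscular tests at $t = 0, 20, \ldots, 160$ s of
  accumulated contraction time (a test every twenty 1-s contractions over
  eight sets);
* latent parameter means and SDs from the reference cohort's summary rows
  (e.g. high-force IMVC: $A = 64 \pm 9$%, $\tau = 31 \pm 14$ s; low-force
  VA: $A = 74 \pm 13$%, $\tau = 90 \pm 45$ s);
* correlation structure: the VA and evoked-torque asymptotes correlated at
  −0.70 within each condition and the evoked-torque asymptotes at +0.67
  across conditions, all other cross-correlations zero. This raw matrix is
  slightly indefinite (minimum eigenvalue −0.11); it is projected to the
  nearest correlation matrix before sampling, which relaxes the three
  couplings to about −0.66/+0.61 — still qualitatively reproducing the
  observed relationships;
* observation noise: homoscedastic Gaussian with SD 4 percent points on the
  percent scale. No noise magnitude is reported for the source data; 4 was
  chosen once because it yields individual fit $R^2 \approx 0.9$, matching
  the spread of the reference cohort's printed $R^2$ column (median
  simulated fit $R^2 \approx 0.92$). The $t = 0$ observation is exactly 100
  regardless of noise, because normalization to baseline defines it.

Latent draws come from a multivariate normal truncated by redrawing any
subject violating $A \in (0, 100]$ or $\tau > 0$. Redrawing preserves the
configured correlations only approximately: with the default means,
appreciable truncation mass (e.g. $A_{VA} = 82 \pm 11$ against the 100%
ceiling) attenuates a configured −0.70 to about −0.64 and shifts means by
about one percent point. Monte-Carlo recovery tests therefore run at
settings where truncation is negligible.

Raw 2-kHz torque traces are simulated as a quarter-sine rise to a plateau,
a hold through the superimposed stimulus, exponential voluntary relaxation
(time constant 0.15 s, beginning 0.8 s after the stimulus), and a resting
doublet 2 s after the superimposed one. Twitch transients use
$f(t) = a\,(t/T_c)\,e^{1 - t/T_c}$ — single-peaked, zero at onset, maximum
$a$ exactly at the contraction time $T_c$ (default 70 ms, typical of a
100-Hz doublet). The generator records the exact landmark values used in
construction, and a roundtrip test requires `extract_nm_metrics()` to
recover all of them within 0.5% on noiseless traces (measured maximum error
is below 0.1%, dominated by sampling-grid quantisation of the twitch peak).

What the generator does **not** emulate: isokinetic (moving) contractions,
EMG/M-waves, heteroscedastic or autocorrelated measurement error, fatigue
of the twitch response within a test, and any physiological coupling between
VA, Q_tw and IMVC — the three variables' latent parameters are coupled only
through the configured correlation matrix. Passing tests therefore
demonstrate the correctness of the estimation machinery, not the adequacy
of the exponential model for any particular real muscle.

## Extraction choices

* Post-stimulus search windows are 0.3 s (superimposed) and 0.5 s (resting)
  — long enough for a 100-Hz doublet twitch to peak — and configurable.
* The superimposed-twitch window opens just after the stimulation sample:
  the twitch is zero at onset, and this lets a trace already in relaxation
  produce a negative raw increment, which is clamped to zero with a warning
  while the raw value is retained for audit. VA is likewise clamped to
  [0, 100] with a warning, raw value retained.
* $T_{max}$ is the maximum over the current contraction only (searched back
  to the last crossing below 10% of the stimulation-time torque), not the
  whole trace.
* The resting-twitch baseline is the mean over the 100 ms before the
  stimulus, because dynamometer zero offsets drift; a resting stimulus is
  rejected unless torque is below 10% of the plateau.
* Marker-free stimulus detection ranks the second difference of the torque
  signal (the jerk): twitch onsets are abrupt breaks in the derivative,
  whereas the voluntary rise, however steep, is smooth. Detection is exact
  to within two samples on clean traces; noisy traces should carry hardware
  markers, as real recordings do.
* Torque is treated in N·m throughout, including where source material
  mixes N and N·m for dynamic peak torques.

## Cohort statistics

Paired HF-versus-LF t-tests cover the six parameter contrasts ($A$ and
$\tau$ for each variable) and, when decrement estimates are supplied, the
six decrement contrasts. Raw and Bonferroni-corrected p-values are always
reported side by side; the family size defaults to the number of tests in
the battery call, since the published values appear uncorrected and no
family size is stated. Regressions report the signed Pearson $r$, $R^2$,
and the slope's t-test p-value on $n - 2$ degrees of freedom. Shapiro-Wilk
diagnostics on the paired differences are available (`normality_report()`)
but never gate computation.

On the packaged reference cohort — printed integer parameters of 13
subjects — the recomputed headline statistics agree with the published ones
within the slack that integer rounding introduces: $R^2$ values within
±0.02, the paired IMVC-asymptote p-value 0.0054 against a printed 0.005,
and the (non-significant) evoked-torque $\tau$ p-value 0.532 against a
printed 0.544. The across-condition evoked-torque asymptote correlation is
reported inconsistently in the source (0.43 in the results, 0.49 in the
abstract); recomputation from the printed parameters gives 0.449, and
`reproduce` reports the computed value without claiming either printed one.
Similarly, the printed low-force evoked-torque asymptote mean (63) differs
from the mean of its printed column (64.08), presumably rounding before
averaging; `summarize_cohort()` reports the recomputed value. The
decrement-level paired contrasts are reported for completeness but are
under-powered on the rounded fixture after reachability exclusions; no
printed values are claimed for them.

## Problem sizes and determinism

All randomness flows from single integer seeds; identical seeds give
bit-identical outputs, and generator functions restore the caller's RNG
state. The test suite uses cohorts of 500 subjects for recovery properties,
2000 for Monte-Carlo moment checks, 1000 draws for the composition
identity, and 50 noisy instances against the lattice oracle — sizes at
which Monte-Carlo error is far below the tolerances being asserted while
the whole suite stays fast.

## Known limitations

* The mono-exponential is the only decline model offered; no bi-exponential
  or linear alternatives, and no hierarchical pooling across subjects — the
  analysis is deliberately individual-based.
* Asymptote estimates from 160 s of contraction time are extrapolations
  whenever $\tau$ is large (several low-force VA fits have $\tau > 100$ s,
  so the stable state was not approached within the protocol).
* The fallback stimulus detector is for clean or lightly filtered traces;
  it is not a general-purpose event detector.
* Decrement estimates are model-based only; observed series are never
  interpolated to decrement levels.
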