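---
title: "Analysing TMS masking experiments with tmsight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing TMS masking experiments with tmsight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsight)
```

## The experimental problem

`tmsight` analyses behavioural data from visual masking experiments in
which occipital TMS is used to probe when, relative to stimulus onset,
cortical processing supports conscious detection and residual "unseen"
perception.  The design it targets crosses four stimulus conditions (a
left arrow, a right arrow, a non-arrow control, and a stimulus-absent
noise frame) with five temporal TMS conditions: a masking pulse around
110 ms intended to suppress conscious detection, delivered either in
isolation or together with an extra pulse at 30, 70, 150 or 190 ms.
Early extra pulses disrupt the feed-forward sweep relatively more;
late ones target recurrent processing.  Every active block is paired
with sham stimulation, and after each trial the participant answers
three mandatory questions: *did you see the arrow?* (yes/no), *did you
see something?* (yes/no), and *was it pointing left or right?* (forced
choice).

Each block repeats all 20 stimulus-by-TMS-time cells four times (80
trials); a participant completes 12 active and 12 sham blocks — 1920
trials — with the six question orders rotating in runs of four blocks.

## Measures

All primary measures are non-parametric signal detection quantities
computed from raw counts, never from smoothed rates.  Given hit rate
$H$ and false-alarm rate $F$ under the allocation scheme described in
`?classify_trials`:

* **PrC** $= H - F$: conscious-detection sensitivity.  The allocation
  reflects how participants describe the task — detection of the
  *arrow* — so a non-arrow answered "something: yes, arrow: no" is a
  correct rejection, and response patterns that the allocation table
  does not list contribute to no class at all (strict reading; a
  permissive completion is available via `strict_table1 = FALSE`).
* **BrC** $= F / (1 - \mathrm{PrC})$: the companion criterion measure;
  larger values mean a more liberal disposition to report awareness.
* **PcU**: proportion correct on the left/right judgement restricted to
  arrow trials on which the participant answered "no" to *both*
  detection questions — residual capacity without reported awareness.
  Above chance means PcU > 0.5.
* **PCm**: trials with awareness acknowledged on both questions but the
  direction judged incorrectly, over all arrow trials — detection
  without identification, the response profile associated with
  phenomenal awareness outstripping access.  The numerator and
  denominator are configurable predicates for variant analyses.
* **PrA/BrA, PrS/BrS**: sensitivity/criterion computed from the arrow
  question or the something question alone.  The single-question
  allocations are a documented reconstruction: arrow-question measures
  treat arrow trials as signal and stimulus-absent trials as noise
  (non-arrows fall outside the definition); something-question measures
  treat arrow and non-arrow trials as signal.
* **d′/c** (optional): the classical parametric analogues, provided for
  concordance checks.  Extreme rates are clamped to
  $[1/2N,\,1 - 1/2N]$; the non-parametric measures need no such rule,
  which is one reason they are preferred here.

The illogical response pattern — "arrow: yes, something: no" — enters
no measure numerator or denominator.  It exists only to drive an
exclusion rule, because the allocation logic has no interpretation for
it.

## Inference

Measures are computed per participant × TMS-mode × TMS-time cell
(`measure_table()`), sham-normalized within participant
(`sham_normalize()`), and summarized by the early-vs-late contrast: the
mean delta at 30/70 ms minus the mean delta at 150/190 ms
(`early_late_contrast()`).  The package stores the sign convention
(early minus late) in the contrast metadata and reports it in the
printed header, because published summaries of this design are not
always internally consistent about sign; comparisons against published
t values should be made on $|t|$.  When one member of an epoch pair is
undefined the default policy averages the defined members (logged);
a strict drop-the-participant policy is a configuration switch.

Each contrast vector receives a two-sided one-sample t-test with 95%
CI and Cohen's $d = \bar{x}/s$, and three families of Bayes factors:

* **BF_main** — a half-normal prior starting at zero.  Small changes
  from sham are more plausible than large ones, and the scale of
  plausible change is informed by the *orthogonal* active-vs-sham
  contrast: the prior SD is half the absolute mean active−sham
  difference for that measure.  (A variance cannot equal a signed
  difference, so the figure is interpreted as the SD, with
  `sd^2 = |diff|/2` available for sensitivity analysis.)  Both prior
  directions are always evaluated, so unpredicted effects in the
  opposite direction are visible.
* **BF_uni** — a uniform prior over the maximum conceivable change:
  width 0.5 for PrC (threshold level 0.5 down to 0) and
  peak-to-chance for PcU, where the peak is the maximum group-mean PcU
  over all ten mode×time cells.
* **BF_jzs** — the default Cauchy (JZS) prior at scale 0.707.

The likelihood for BF_main/BF_uni is a shifted, scaled t density of
the observed mean at the hypothesized effect (honouring small-sample
uncertainty in the SE); a normal likelihood is a configuration switch
since calculator lineages differ on this point and the original choice
is not documented.  All engines use adaptive quadrature to a relative
tolerance of 1e-6; the half-normal integrates over ten prior SDs and
results are invariant (tested) to doubling that limit.  The JZS factor
uses the standard single-integral form marginalizing the g prior; the
test suite checks it against an independent integration of the
noncentral-t likelihood under the Cauchy prior, and checks the other
engines against brute-force Riemann sums.

`sequential_stop()` implements the pre-registration-style optional
stopping rule: stop at the first BF_main ≥ 3 (support) or ≤ 1/3
(null), both bounds inclusive.

Fine-grained contrasts between single onsets (default 30 vs 190 ms)
are computed only when the coarse contrast is reliable
(p < 0.05 or BF_main outside [1/3, 3]) — `run_report()` enforces the
gate and logs its decisions.

Figure-style condition summaries use Cousineau subject-centred
standard errors with the Morey $\sqrt{k/(k-1)}$ correction across the
$k = 10$ mode×time conditions (`within_subject_se()`).

## Exclusion rules and their scopes

Rules are applied in pre-registered order and, critically, at their
own scope:

1. **Trial scope.** Blink trials (pupil shift > 1° followed by a
   transitory, sub-second signal loss coincident with the stimulus, or
   a precomputed flag) are removed first.
2. **Participant scope.** Same-button strategy (one direction on ≥ 75%
   of double-denied trials, boundary inclusive), all-negative
   responding under a condition, and illogical responses on strictly
   more than 2.5% of trials each remove the participant from all
   analyses.
3. **Measure scope.** A one-tailed z-test of baseline (sham, pooled
   over times) PcU against chance at α = 0.05 — using the null
   binomial SE $\sqrt{0.25/n}$, a documented interpretation of the
   "cumulative normal" rule — removes non-demonstrators from PcU
   analyses *only*.
4. **Vector scope.** Chauvenet's criterion on each analysis vector:
   fit a normal (sample mean and SD, candidate included, single pass),
   exclude points whose two-tailed exceedance probability times n is
   below 0.5.  The exclusion affects that vector alone.  "Likelihood"
   is read as tail probability (classical Chauvenet); a density-based
   reading is available as a switch.  The alternative of refitting
   without the candidate point is noted but not implemented; the
   single-pass form is the documented choice.

The test suite asserts scope containment directly: toggling the PcU
screen leaves every non-PcU report row bit-identical.

## The synthetic observer

Because the deposited data cannot be redistributed with the package,
every stage is validated against a generative observer
(`observer_params()`, `simulate_cohort()`):

* one evidence sample per trial, $e \sim N(\mu, 1)$, with $\mu$ the
  arrow strength (default calibrated so sham PrC ≈ 0.5, mirroring the
  luminance calibration loop; `calibrate_signal()` redoes the
  calibration against the analytic expectation), a separate non-arrow
  strength, and 0 when no stimulus is present;
* two ordered report criteria — "something" at 1.6 and "arrow" at 2.0
  evidence units — chosen to give the low false-alarm rates
  characteristic of this paradigm (≈ 0.15 pooled) while keeping
  roughly 30% of arrow trials double-denied so PcU is well numerated;
* an independent left/right channel with $P(\text{correct}) =
  \Phi(d'_{dir}/\sqrt{2})$, default $d'_{dir} = 0.954$, i.e. baseline
  unseen accuracy ≈ 0.74 falling to ≈ 0.65 under the masking pulse —
  the simplest structure that produces above-chance unseen
  discrimination without modelling any dual-route theory;
* independent per-response lapses (default 2%), which are the sole
  source of illogical responses (the criterion ordering forbids them
  otherwise), at a rate comfortably below the 2.5% exclusion boundary;
* additive active-TMS effects per time condition on the evidence mean
  of stimulus-present trials, on both criteria, and on the direction
  d′.  The default map (`tms_effects_signature()`) encodes the study
  signature this pipeline is meant to detect: detection suppression on
  every active condition, stronger sensitivity suppression early, and
  a criterion shift concentrated late.  Its magnitudes were solved
  analytically, once, to land the group-level expectations near the
  published effect sizes (PrC suppression ≈ −0.08 at the masking
  pulse, early-vs-late PrC ≈ −0.06, active PcU ≈ 0.65 with ≈ −0.09
  suppression);
* between-participant variation as independent normal deviations of
  signal strength (SD 0.15), a joint criterion shift (SD 0.15) and
  direction sensitivity (SD 0.25) — free settings logged per run,
  since the study reports no individual-difference distributions;
* a 0.2% blink rate, matching the order of magnitude of reported
  blink exclusions (hundreds out of ~10^5 trials).

What the generator does *not* emulate: session/day structure and
recalibration drift, sequential dependencies, response times, any
coupling between the detection and direction channels, and non-Gaussian
evidence.  Passing recovery tests therefore show that the pipeline
measures what the generative model encodes — not that the model is a
faithful account of real observers.

`recovery_experiment()` repeats cohort simulation → pipeline and
tallies sign and significance recovery.  Under the default signature
with cohorts of n = 40, the early-vs-late contrasts for PrC and PcU
and the late-dominant BrC shift recover their signs in well over 95%
of cohorts, and null cohorts show ≈ 5% false positives per contrast at
α = 0.05; the acceptance suite runs 100 cohorts of each kind
(~2 minutes).  One caveat discovered during design: because BrC's
denominator contains PrC, a pure early *sensitivity* suppression also
depresses early BrC, so the negative BrC contrast is driven jointly by
the early sensitivity effect and the late criterion shift.  The
generator makes no attempt to disentangle them — neither can the
measure.

## Numerical and degenerate-input choices

* Rates with empty denominators, Br at Pr = 1, PcU with no qualifying
  trials and PCm with no arrow trials are *undefined* (`NA` with
  `defined = FALSE`), never errors and never smoothed.
* A degenerate (zero-variance) contrast vector yields an infinite t
  with a `constant_vector` flag; a zero orthogonal contrast degenerates
  the half-normal prior and flags the BF as undefined.
* Chauvenet needs n ≥ 3 and flags zero-SD vectors; quadrature failures
  raise explicit errors rather than returning partial values.
* All randomness is seeded; `generate_design()` shuffles within block
  via a single vectorized ordering, and cohort c of a recovery run
  uses `seed + c`.

## Problem sizes

The shipped tests simulate cohorts of 2–20 participants for unit
checks and 100 cohorts of 40 for the recovery study; the acceptance
script analyses one cohort of 50 (96,000 trials), the deposited-study
scale, in a few seconds.

## Reproducing a published-scale analysis

`run_report()` on a trial table in the canonical CSV layout (or any
layout adapted through a column-mapping config) emits the full
publication-style table: per measure, the early-vs-late t, p, df, mean
and CI, Cohen's d, both directional BF_main values, BF_uni where a
bounded range is defined (PrC, PcU), BF_jzs, and the number of
Chauvenet outliers removed.  The `analyze` CLI subcommand wraps this
with CSV/log output; `simulate` and `bf` complete the toolchain.
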