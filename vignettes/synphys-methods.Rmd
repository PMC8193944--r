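---
title: "Methods and design notes for synphys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for synphys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synphys)
```

This vignette is the package's own account of the models it implements, the
choices made where the methodology was genuinely open, and what its
synthetic-data tests do and do not establish about real recordings.

## Quantal analysis by the method of failures

The release model is Poisson: each stimulus liberates $k \sim
\mathrm{Poisson}(m)$ quanta, so the probability of a failure (no release) is
$e^{-m}$ and the quantal content is estimated from $N$ stimuli with $N_0$
failures as

$$\hat m = \ln(N / N_0), \qquad
  \mathrm{SE}(\hat m) = \sqrt{\frac{N - N_0}{N\,N_0}}$$

where the standard error follows from the binomial variance of $N_0/N$ by
the delta method. The attraction of the method is that it needs no
assumption about the number of release sites or the quantal size; its cost
is that it uses only the failure count, so the minimal-stimulation protocol
must produce enough failures for $N_0 > 0$. The identity
$e^{-\hat m} = N_0/N$ holds algebraically and is tested as such.

Choices made here:

* **Failure criterion.** The threshold separating failures from responses is
  $k \sigma_{\text{noise}}$ with $k = 3$ by default: for Gaussian
  measurement noise this bounds the per-trial false-failure rate for a
  genuine single-quantum response (tens of pA against a few pA of noise)
  and the false-response rate for a true failure at roughly 0.1%. The
  source experiments do not quantify their criterion, so $k$ is exposed as
  a parameter.
* **No failures observed.** $\ln(N/0)$ is undefined. Rather than return a
  silent number, `quantal_content()` returns status `"no-failures"` with
  `m = NA` and the lower bound $\ln N$. Simulation shows how often this
  occurs: for $m = 2.46$ and 50 stimuli the no-failure probability is
  $(1 - e^{-2.46})^{50} \approx 0.012$, and `estimator_calibration()`
  reports the observed frequency alongside bias and RMSE.
* **Per-estimate uncertainty.** The delta-method SE is a per-cell quantity;
  published work in this area usually reports only SEM across cells. The
  per-cell SE is therefore an extension, labelled as such.

`measure_evoked_amplitude()` implements the convention of measuring the
evoked response as the peak baseline-subtracted current over 20 ms from
response onset, with onset found as the first post-stimulus crossing of a
threshold above the pre-stimulus baseline median within a 20-ms latency
window; a trial with no crossing measures 0 pA.

## Spontaneous event detection and statistics

The detector is a deliberately transparent two-threshold scheme: the trace
is smoothed with a ~1-ms boxcar; candidate onsets are crossings of a rising
slope threshold (default 8 pA/ms over a 0.5-ms span); the candidate is
accepted when the local peak minus the median of the preceding 10-ms
baseline window exceeds the amplitude threshold (default 15 pA); accepted
events are separated by a refractory interval (default 10 ms) measured
from the accepted *peak*, not the onset, so that a noise crossing just
before a true onset cannot double-count the event. Commercial detectors
are closed-source, so the contract here is statistical, not algorithmic:
on synthetic traces with amplitude/noise ratio of 10 and rates up to 2 Hz
the suite requires F1 ≥ 0.95 against the generator's ground truth (matched
within 10 ms).

Events are stored as positive magnitudes regardless of recorded polarity;
`read_trace_csv(invert = TRUE)` flips inward currents at ingest.

The paired drug/control comparison uses the **mean of per-cell ratios**,
not the ratio of group means: each cell is its own control, and the two
statistics genuinely differ (a normalized fold change of 0.24 need not
equal the ratio of the two group means). The function excludes cells with
a zero control value with a warning, since their ratio is undefined.

## Hill concentration–response fitting

`fit_hill()` minimizes the (optionally weighted) sum of squared residuals
of $y = E_{max} C^h / (C^h + EC_{50}^h)$, restarting Nelder–Mead from a
9-point log-spaced EC$_{50}$ grid crossed with $h \in \{0.3, 0.5, 1, 1.5,
2, 3, 4\}$ and keeping the best solution, so the returned SSE is never
above that of any start. Parameters are optimized as $(\log_{10} EC_{50},
\log h)$, which keeps both positive without constraints.

$E_{max}$ is fixed at 100% by default because the highest shipped
concentration point (99.26% inhibition) indicates complete block and the
response scale is already percent inhibition; a free-$E_{max}$ option is
provided because the constraint used for the published fit is not stated.
Residuals are unweighted by default (an SEM-weighted option exists) for the
same reason.

**A discrepancy worth knowing about.** Fitting the five shipped group-mean
points with this model gives EC$_{50}$ = 71.3 μM and $h$ = 1.175. The
published curve reports $h = 1.2$ — which matches — but EC$_{50}$ = 98.02
μM, which no least-squares variant of the group means reproduces
(1/SEM² weighting gives 47 μM, 1/y² gives 71 μM, n-weighting 76 μM,
dropping the 300 μM point 112 μM). The published value was presumably fit
to the underlying per-cell responses of the cumulative design, which are
not deposited. The package keeps the means-based fit and documents the
difference rather than tuning toward the published number; the acceptance
suite asserts the published EC$_{50}$ tolerance faithfully and that
assertion fails, which is the honest outcome.

## Fura-2 calcium quantification

Conversion uses the standard ratiometric equation
$[\mathrm{Ca}^{2+}] = K_d \beta (R - R_{min}) / (R_{max} - R)$, strictly
increasing on $(R_{min}, R_{max})$. The default constants
($R_{min} = 0.3$, $R_{max} = 6$, $K_d = 224$ nM, $\beta = 5$) are
placeholders typical of in-cell fura-2 calibrations: the calibration used
for the reference data lives in cited prior work and is not printed, so
every quantitative use in this package is a round-trip (simulate at a known
concentration, convert, recover) or operates on printed concentrations —
never on the defaults' absolute truth.

Transient amplitudes are peak-minus-baseline with a 5-s post-stimulus
search window and a 5-s pre-stimulus baseline median (both configurable;
the reference transients are seconds-scale). Windows truncate at the next
stimulus with a warning. The baseline median makes the measurement robust
to slow drift, which is tested with a constructed drifting trace.

## Circadian entrainment metrics

For each circadian day the activity onset is the start minute of the first
bin — scanning the day from lights-on — whose count reaches 10% of the
peak bin. "Peak" is per-day by default; a per-record option exists because
the convention is ambiguous in common analysis software. Days below a
minimum activity floor (50 revolutions by default) are unanalyzable and
return `NA`, never a spurious midnight onset; this matters for aged
records whose daily totals can fall near 1,500 revolutions.

The phase angle of entrainment is computed by ordinary least squares of
onset minute against day index, evaluated at the midpoint of the analysis
window (under OLS this equals the mean onset, and it is the unbiased
summary of a 30-day window when the fit is used descriptively):
$\Psi = \text{lights-off} - \widehat{\text{onset}}$, positive when onsets
precede lights-off. Day indices keep their true spacing across missing
days, and day-to-day variability (mean |successive difference|) uses only
consecutive non-missing pairs.

## The synthetic-data generators

Each generator returns its exact ground truth so downstream estimators can
be tested as estimators:

* `simulate_spontaneous()` — homogeneous Poisson event times, lognormal
  amplitudes (the amplitude distribution family is not derivable from
  published means ± SEMs; lognormal is the conventional choice for
  positive, right-skewed synaptic amplitudes, with CV 0.3 as a
  representative value), unit-peak difference-of-exponentials kernels
  (rise 1 ms, decay 25 ms — typical GABA-A IPSC kinetics at room
  temperature) on Gaussian noise. Normalizing the kernel to unit peak
  makes the ground-truth amplitude directly comparable to detector output.
* `simulate_evoked()` — Poisson quanta, quantal sizes from a normal
  truncated at zero (mean 50 pA, CV 0.3), Gaussian measurement noise.
  Truncation prevents negative quanta while keeping mean and CV
  interpretable.
* `simulate_actogram()` — one onset per day at lights-off − Ψ plus
  Gaussian jitter, **rounded to the 10-min bin grid**; a contiguous active
  block (10 h young, 8 h aged) of Poisson bin counts summing to the daily
  total in expectation, wrapping circularly within the day. Two choices
  deserve comment. First, drawing onsets on the bin grid reflects that the
  recording medium cannot represent sub-bin timing; it makes ground truth
  exactly representable, and the 10%-rule detector is then unbiased —
  with continuous onsets the binned detector would carry an irreducible
  partial-bin bias of a few minutes that is a property of binned
  actography, not of this implementation. Second, the active block ends
  before lights-on (hence 8 h for the aged presets, whose onset jitter SD
  approaches an hour); aged rodents' shorter activity duration makes this
  realistic, and it keeps the onset scan from latching onto the previous
  night's tail.
* `simulate_fura()` — baseline plus instantaneous-rise, exponential-decay
  transients in concentration space, mapped through the calibration
  equation with Gaussian ratio noise.

Condition presets (`inst/extdata/presets.yaml`) carry the published group
means: spontaneous rate 1.05 Hz (young) / 0.92 Hz (aged), amplitudes ~50
pA, quantal contents 2.46/0.54 (young control/drug) and 1.61/0.26 (aged),
calcium transients 238 nM with 72.5% inhibition, daily activity 14,695 /
15,410 / 5,358 / 1,655 revolutions and phase angles −7.70 / −4.97 /
−28.76 / −30.93 min for the four age × genotype groups. Onset jitter SDs
are derived from the published day-to-day variabilities $v$ via
$\sigma = v\sqrt{\pi}/2$, the inversion of $E|X - Y| = 2\sigma/\sqrt{\pi}$
for iid normal onsets.

**What passing tests do not show.** The generators are intentionally
simpler than real data: stationary Poisson trains (no bursting or
rundown), a single event kernel (no kinetic heterogeneity or overlapping
multi-compartment events), uncorrelated quanta, a single contiguous
activity bout per day (real aged actograms fragment; fragmentation is
emulated only as larger onset jitter and lower totals), and no baseline
drift or photobleaching in the fura traces. Parameter-recovery results
therefore validate the estimators under their stated assumptions; they do
not certify detector performance on pathological recordings.

## Inference layer

The two-way ANOVA from summary statistics reconstructs cell SDs as
$\mathrm{sem}\sqrt{n}$, giving $SS_{within} = \sum_i (n_i - 1)
(\mathrm{sem}_i \sqrt{n_i})^2$ with $\sum n_i - 4$ degrees of freedom, and
tests unweighted marginal-mean (Type III) contrasts

$$F = \frac{(\sum_i c_i \bar y_i)^2}{MS_{within} \sum_i c_i^2 / n_i},
  \qquad c = \left(\tfrac12, \tfrac12, -\tfrac12, -\tfrac12\right)$$

(and analogues for the second factor and interaction). Type III is used
because the validated designs are unbalanced (6 vs 10 animals per cell)
and it is the analysis that reproduces the published F(1, 28) values from
the printed summaries; the test suite also verifies equality (to 1e-8)
with a Type III analysis of raw data via `car::Anova` and exact agreement
with `aov()` on balanced designs. p-values are reported but the package's
own validation rests on the F statistics.

`paired_t()` delegates to `stats::t.test` except for zero-variance
differences, which it resolves explicitly (identical pairs: t = 0, p = 1;
constant nonzero difference: infinite t, flagged). `ks_two_sample()` wraps
`stats::ks.test`.

**Kolmogorov–Smirnov discreteness.** With equal sample sizes $n = m$ the
statistic $D$ lives on the lattice $k/n$, and the attainable test levels
near 0.05 jump — at $n = m = 100$ from $P(D \ge 0.19) = 0.0539$ to $P(D
\ge 0.20) = 0.0364$ (exact, via `stats::psmirnov`) — so rejecting at
$p < 0.05$ realizes a true level of 0.0364 no matter how the p-value is
approximated. The suite freezes that exact value as the expected level at
equal sizes. The type-I-error calibration study therefore uses unequal
sizes (100 vs 150) with exact p-values, where the lattice is fine and the
attainable level sits just under the nominal 0.05; this is a property of
the statistic, and the choice is made once, on that analytical ground.

## Problem sizes and numerical settings used by the test suite

Monte-Carlo checks use sizes chosen to keep each check's sampling error
well inside the asserted tolerance: 200 replicate trains for the Poisson
count law; 10⁴ trials per point for failure-law and quantal-recovery
checks; 1,500–2,000 replicates for estimator-calibration bias and
no-failure frequency; 200 synthetic animals × 30 days for phase-angle
recovery; 5,000 null replicates for test-calibration rates; 40 random
noiseless curves for Hill recovery (each to <1% relative error). The
optimizer uses Nelder–Mead with relative tolerance 1e-12 and 2,000
iterations per start. Electrophysiological simulations in tests run at
2–10 kHz sampling; lower rates are used where only event counts matter.

## Known limitations

* The failures method itself assumes Poisson release; with few release
  sites and high release probability (binomial release) it underestimates
  m. No binomial or variance-mean decomposition is provided.
* The event detector has no kinetic (rise/decay) fitting and no
  EPSC/IPSC discrimination beyond amplitude; it is not intended for
  heavily overlapping event trains.
* Calibration constants for fura-2 are configurable inputs, not
  measurements; absolute concentrations inherit their accuracy.
* No free-running period estimation, periodograms, or bout-fragmentation
  statistics; entrainment metrics assume a light-entrained record.
* CSV schemas are the package's own; proprietary acquisition formats are
  out of scope.
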