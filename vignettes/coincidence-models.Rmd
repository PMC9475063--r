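---
title: "Modeling audio-visual capture of sound-source distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling audio-visual capture of sound-source distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avcapture)
```

## The scientific problem

When a sound and a plausible visual source are presented at different
distances, the sound tends to be perceived at the visual target's distance —
visual capture in depth, the distance analogue of the ventriloquist effect.
The capture is asymmetric: sounds *beyond* the visual target are captured
more strongly than sounds *in front of* it (the "proximity-image effect").
`avcapture` implements a complete analysis chain for studying this effect
with yes/no coincidence judgments: a generative observer for simulation,
the empirical discriminability statistic, power-law distance-perception
fits, three probabilistic coincidence models, constrained model fitting,
and RMS model comparison.

## The empirical statistic

For each auditory distance within a block (one fixed visual target), the
proportion of "coincident" responses $pc$ is converted to

$$d' = z(pc_{max}) - z(pc),$$

where $z$ is the standard-normal quantile and $pc_{max}$ is the largest
proportion in the block. $d'$ is zero at the point of strongest capture and
grows with perceptual mismatch. Two numerical decisions are needed where
the definition is silent:

* **All-or-none cells.** $z$ is infinite at $pc \in \{0, 1\}$. Each $pc$ is
  clamped to $[1/(2n),\, 1 - 1/(2n)]$ with $n$ the number of trials in the
  cell — the standard half-count correction. With $n = 330$ the largest
  attainable $d'$ is $z(1 - 1/660) - z(1/660) \approx 5.93$.
* **Ties in $pc_{max}$.** The reference is the tied distance closest to the
  visual target (remaining ties: the smaller distance), since the reference
  should be the most plausible capture point.

Confidence intervals are subject-level percentile bootstrap: subjects are
resampled with replacement, trials within a subject kept intact, and the
whole curve — including the $pc_{max}$ reference — is recomputed per
resample. Defaults: $B = 1000$, 95% percentile intervals.

## Distance perception: power-law scaling

Mean perceived distance is modeled as $y = k x^a$ per modality. Fits are
ordinary least squares of $\ln y$ on $\ln x$ ($a$ = slope,
$k = e^{\text{intercept}}$). The log-space fit is exactly linear, has a
unique solution, and matches the multiplicative error structure of
magnitude-estimation data and the geometric-mean group averaging used
throughout; a linear-space nonlinear option is available behind
`method = "linear"`. Group fits operate on geometric means across subjects
per target distance; per-subject fits on raw single judgments.

## The three coincidence models

All variants treat a coincidence judgment as a comparison of two internal
distributions of perceived distance and evaluate their overlap with the
sensitivity index

$$d' = \frac{|\mu_{aud} - \mu_{vis}|}
{\sqrt{\sigma_{aud}^2 + \sigma_{vis}^2 - 2 r \sigma_{aud} \sigma_{vis}}},$$

where $r \in [0, 1]$ is the correlation between the two percepts. The
variants differ in the scale on which the percepts are normal:

* **M1 — linear scale, constant variance.** $\mu = k x^a$ per modality;
  $\sigma$ fixed at the value implied by a 3 m reference target:
  $\sigma_{aud} = 1.6982 \cdot k\,3^{a}$ and
  $\sigma_{vis} = 1.4125 \cdot k\,3^{a}$, each modality using its own power
  law. The factors $10^{0.23}$ and $10^{0.15}$ are multiplicative
  variability ratios of distance estimates from large-sample absolute
  judgment studies.
* **M2 — linear scale, scaled variance.** As M1, but
  $\sigma = \text{factor} \times k x^a$ evaluated at each target's own
  distance (auditory over $0 < x < 10$ m).
* **M3 — logarithmic scale.** Percepts are normal in log distance:
  $m = \ln(k x^a)$, $s = \ln(\text{factor})$ per modality. Equivalently the
  linear-space percepts are log-normal; their moments
  $\mu = \exp(m + s^2/2)$,
  $\sigma^2 = (e^{s^2} - 1)\exp(2m + s^2)$ are fed into the same $d'$
  expression.

For the M3 moment conversion the package defaults to the standard
log-normal formulas, which are the only self-consistent reading of the
published transform equations (whose printed mean, $\exp(m + s^2)$, and a
self-referential spread equation appear to be typographical slips);
`printed_formula = TRUE` reproduces the printed mean literally for
comparison. Natural logarithms are used throughout; because the factors are
stored as linear ratios, the choice of log base cancels.

### A consequence of the moment transform worth knowing

Because $\exp(s^2/2)$ differs between modalities ($s_{aud} > s_{vis}$), the
linear-moment M3 places its predicted coincidence point at
$x^\ast = v\,\bigl(e^{(s_{vis}^2 - s_{aud}^2)/2}\bigr)^{1/a}$, slightly
*nearer* than the visual target $v$ even when the two power laws are
identical. Two things follow, both verified by the test suite:

* M3's near/far asymmetry $d'(v - \Delta) > d'(v + \Delta)$ holds robustly
  for offsets beyond the shift (roughly $\Delta/v \gtrsim 0.4$ at the
  default spreads) but *reverses* for small offsets. Had $d'$ been computed
  directly from the log-space parameters ($|m_{aud} - m_{vis}|$ over the
  log-space spread of the difference), the asymmetry would be exact at
  every offset; the package follows the published linear-moment pathway.
* When model fits are driven by the $z$-referenced empirical $d'$ of the
  simulated observer (below), the fitted $k_{aud}$ absorbs the shift
  ($\ln \hat k_{aud} \approx \ln k_{aud} - (s_{aud}^2 - s_{vis}^2)/2$), and
  the fitted $r$ compensates for the scale difference between the two $d'$
  definitions. The 2-parameter fit is therefore *not* a consistent
  estimator of the generating observer's $(k_{aud}, r)$; the acceptance
  script quantifies the achieved recovery rates rather than assuming them.

## Model fitting

Models are fit per visual-target block (no parameter sharing across
blocks) by minimizing unweighted squared error between observed and
predicted $d'$, under bound constraints, with `optim(method = "L-BFGS-B")`
(gradient tolerance $10^{-10}$, up to 500 iterations per start). Free
parameters: 1-parameter fits estimate $k_{aud} \in [0.05, 20]$; 2-parameter
fits add $r \in [0, 1]$; 3-parameter fits add the auditory variability
factor $\in (1, 10]$ (for M3, the factor whose log is $s_{aud}$). The
objective is non-convex in $k_{aud}$, so each fit runs from a deterministic
multi-start grid ($k_{aud} \in \{0.5, 1, 2\}$, $r \in \{0, 0.5, 0.9\}$,
factor $\in \{1.3, 1.7, 2.5\}$ as applicable) plus the fixed defaults and —
for 2- and 3-parameter fits — the solution of the next-simpler fit padded
with the extra parameter's default. The last start guarantees that reported
RMS error is non-increasing in the number of free parameters on the same
data. Non-convergence of every start is reported via `converged = FALSE`
with the best point retained.

`compare_models()` tabulates RMS error per model and block, and
`rms_summary()` reduces per-subject tables to mean ± standard error per
model × distance — the descriptive summary that downstream inferential
comparisons of fit error would consume (those mixed-model comparisons are
deliberately out of scope).

## The synthetic observer

The generator exists so every downstream stage is testable without human
data. Log percepts are bivariate normal,

$$\begin{pmatrix} A \\ V \end{pmatrix} \sim
N\!\left(\begin{pmatrix} \ln(k_{aud} x_{aud}^{a_{aud}}) \\
\ln(k_{vis} x_{vis}^{a_{vis}}) \end{pmatrix},
\begin{pmatrix} s_{aud}^2 & r\, s_{aud} s_{vis} \\
r\, s_{aud} s_{vis} & s_{vis}^2 \end{pmatrix}\right),$$

and the observer responds "coincident" iff $|A - V| \le c$. The difference
criterion was chosen because it reduces to the $d'$ structure of the
analysis: the difference distribution's mean and spread in log space are
exactly the sensitivity-index numerator and denominator of the
log-scale model, and the implied proportion coincident has the closed form
`predict_pc()` — the analytic oracle the simulator is tested against.

Default parameters, chosen once as a realistic listener:

| parameter | default | why |
|---|---|---|
| `k_aud`, `a_aud` | 1.32, 0.54 | canonical compressive auditory distance scaling (overestimation near, underestimation far) |
| `k_vis`, `a_vis` | 1.00, 0.98 | near-veridical visual distance perception |
| `s_aud`, `s_vis` | ln 1.6982, ln 1.4125 | the same variability ratios the models use |
| `r` | 0.5 | mid-range percept correlation under concurrent bimodal stimulation |
| `criterion_c` | 0.6 log-units | a ±1.8× distance-ratio acceptance region; yields peak coincidence proportions near 0.8, typical of pooled yes/no data |

The default design mirrors the standard experiment: 11 subjects, visual
targets at 1.5/3.0/4.5 m, 11 auditory distances per block in 0.25 m steps
centered on the visual target and shifted inward to the 1–5 m renderable
range (which auditory distances actually surrounded each visual target is
not recoverable from the published description; the centered-and-shifted
grid is this package's choice and is fully configurable), 30
trials/stimulus, auditory absolute judgments at 1–5 m in 0.5 m steps and
visual at 1/2/3 m. Reproducibility: one root seed; per-(subject, block)
substreams are derived arithmetically so subject subsets replay exactly.

What the generator does *not* emulate: response biases and lapses,
criterion drift over trials, learning, head-movement artifacts, and any
deviation of real percepts from joint log-normality. Passing tests
therefore certify the pipeline's correctness on data *from this model*,
not the model's fidelity to human listeners.

## Acoustic cue module

Room-acoustic distance cues (broadband level, direct-to-reverberant energy
ratio) are summarized by OLS fits of the cue in dB on $\log_2(\text{distance})$
— slope in dB per doubling — and the critical distance solves the fitted
DRR for its 0 dB crossing, $x_c = 2^{-\text{intercept}/\text{slope}}$,
flagged when extrapolated beyond the fitted range. Computing cue tables
from impulse responses is out of scope; `synthetic_cue_table()` builds an
inverse-square-direct/constant-reverb table whose crossing is known by
construction for testing.

## Problem sizes and known limitations

* Simulation-based checks in the test suite use up to $10^5$ trials per
  cell for oracle comparisons (3 binomial SEs), $10^6$ draws for moment
  checks (0.5%), and 100 pipeline replicates at the standard design scale
  for the recovery analysis.
* The percentile bootstrap resamples 11 subjects; percentile intervals at
  that sample size tend to run slightly narrow, a generic small-$n$
  property worth remembering when reading the intervals.
* As derived above, the linear-moment M3 is intentionally faithful to its
  published form, including the nearward shift of its minimum and the
  resulting bias of pipeline parameter recovery; users wanting an exact
  log-space analysis can compute it directly from `predict_pc()` and the
  log-space parameters.
* With $k_{aud}$ and $r$ free, the three variants can be hard to
  distinguish on single-subject curves (11 points, 30 trials each); pooled
  curves or wide distance ranges separate them better, and offsets small
  relative to the target distance carry little asymmetry information on a
  log scale.
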