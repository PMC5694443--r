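---
title: "The Digital Arthritis Index: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Digital Arthritis Index: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daindex)
```

## The problem

Rodent collagen-induced arthritis (CIA) studies score disease by handling
each animal: caliper measurements of the tibiotarsal (ankle) joints, an
ordinal 0-4 redness/swelling rubric per hind paw, body weights, and — at
necropsy — histopathology of the joints. Handling is labour-intensive,
observer-dependent and itself a stressor. Continuous home-cage monitoring
offers a hands-off alternative: arthritic rats move less, and they lose in
particular the fast locomotion that healthy rats show during the dark
cycle.

`daindex` turns per-animal speed traces (mm/s, sampled once per minute)
into a per-day **Digital Arthritis Index (DAI)** and puts that index
through exactly the same incidence/onset/severity machinery as the
conventional measures, so the three assessment routes can be compared
animal by animal and used side by side to rank candidate compounds.

## The index

For animal $i$ on study day $d$ the pipeline extracts a *salient feature*
$f_{i,d}$: by default the 99th percentile (nearest-rank) of the per-minute
dark-cycle speeds of the night that begins at lights-off on day $d$. The
99th percentile tracks "maximum speed of motion" while resisting
single-sample outliers; `max` and `mean` are available alternatives.

Each animal is its own control. The baseline
$b_i$ is the arithmetic mean of $f_{i,d}$ over study days $-2$ to $5$,
always excluding induction day $0$ (injection-day handling depresses
activity) and any night with less than half of its expected samples. At
least 3 usable baseline days are required; otherwise the animal is
excluded with a warning rather than normalised against noise.

The index is the scaled activity deficit relative to baseline,

$$\mathrm{DAI}_{i,d} \;=\; \max\!\Big(0,\; K\big(1 - f_{i,d}/b_i\big)\Big),
\qquad K = 20 .$$

A literal feature/baseline *ratio* would fall as disease progresses; the
deficit form rises with disease, which is the orientation the published
index family uses (higher DAI = less activity). $K = 20$ places the scale
so that the disease threshold of 5 corresponds to a 25% activity loss and
a fully arthritic animal (a 43-48% loss) scores about 9-10, the magnitude
reported for diseased vehicle animals at endpoint. $K$ is a calibration
choice, not a biological constant; it cancels out of any comparison made
at a fixed $K$.

Nights are attributed backwards: the dark period that starts at 18:00 on
day $d$'s date belongs to day $d$ even after midnight, so each dosing day
is paired with the following night's behaviour. Days whose dark-cycle
coverage falls below 50% propagate as missing DAI values — never as zeros.

## Disease calls

All three metrics (DAI, per-day maximum of the two ankle sizes, total
hind-paw arthritis score) pass through the same rules:

* **Incidence** — the animal exceeded the metric's threshold (strictly)
  on any study day 0-17. Thresholds: 0.25 in joint size, score 4, DAI 5.
* **Onset** — the earliest day *consistently* above threshold. We
  operationalise "consistently" as above-threshold on day $d$ and $d+1$
  (or $d$ being the last observed day): one day admits blips, while longer
  runs could not call onsets near the end of a 17-day study.
* **Severity** — the metric value on day 17 or at the humane endpoint;
  for joint size, the change from induction day 0.
* **Cumulative burden** — $\sum_d \max(0, x_d - \tau)$ over observed days.
* **Humane endpoint** — censoring at the earliest of: joint $\ge$ 0.4 in
  (note the non-strict comparison, unlike the disease thresholds), a paw
  score of 4 sustained for more than 48 h (3 consecutive daily
  observations; two span at most 48 h), or weight loss beyond 20% of the
  day-0 weight.

Incidence and onset deliberately use different rules, so an animal with a
single-day excursion is counted in incidence yet has no onset day; group
summaries report onset statistics over animals with an onset only.

## The synthetic cohort generator

No public activity datasets exist for this design, so the generator *is*
the test bed, and its defaults are the study conditions every test and
the acceptance script use:

* **Latent severity.** Each induced animal draws a clinical onset day
  $\sim \mathcal N(13, 1)$ (rounded) and an endpoint severity
  $e \in [0,1]$, truncated $\mathcal N(0.95, 0.1)$. Severity ramps
  piecewise-linearly over 4 days and then stays flat. The ramp starts 3
  days *before* the nominal onset: pathology builds subclinically, and
  positioning the ramp this way makes the measured metrics cross their
  thresholds at about the nominal onset day, which is what "onset day 13"
  means operationally in this literature. Treated groups multiply $e$ by
  `treatment_effect`; controls have severity identically zero.
* **Activity.** Dark-cycle speeds are truncated-Gaussian with mean
  $22\,(1 - 0.45\, s(d))$ mm/s and constant coefficient of variation
  $2.4/22$; light-cycle speeds are 30% of the dark mean. The constant-CV
  choice makes the expected value of any scale-equivariant feature fall
  *proportionally* with the mean, so the DAI's ratio normalisation
  recovers the latent reduction. Days are conditionally independent given
  $s(d)$; no within-animal autocorrelation is modelled.
* **Clinical measures.** Joint size $= 0.22 + 0.12\,s(d) +
  \varepsilon$ in (caliper SD 0.006 in — measurement repeatability scale,
  which also keeps the 0.25-in threshold 5 SD away from a healthy joint);
  paw scores are $\mathrm{round}(4 s + \varepsilon)$ clamped to 0-4;
  weight declines by at most 8% of a 250 g baseline. Five histopathology
  subscores grow with $e$ under fixed loadings (inflammation heaviest,
  periosteal bone formation lightest), giving endpoint totals near 10 of
  25 for untreated disease.

With these defaults an induced cohort loses 35-50% of its dark-cycle
activity by endpoint, reaches endpoint DAI ≈ 8-9, Δ joint size ≈ 0.11 in,
score ≈ 7 and histopathology ≈ 10 — the envelope of the published
magnitudes this family of studies prints.

What the generator does **not** emulate: the mild (~14%) activity decline
real *control* rats show late in a study (habituation/ageing), sensor
dropout, day-to-day behavioural autocorrelation, and independent noise
sources per measure. Because one latent factor drives every measure,
cross-metric correlations in simulation (r ≈ 0.95+) are *higher* than in
animal data (r ≈ 0.8-0.9); passing simulation tests shows the pipeline's
arithmetic and calling rules are right, not that real data will be this
clean.

## Numerical choices

* Nearest-rank percentile (`sort(x)[ceiling(p n)]`): reproducible across
  implementations, always an observed value.
* Truncation at physical bounds by inverse-CDF sampling for speeds (exact
  truncated normal) and clamping for rubric-bounded scores.
* Reported integer percentages round halves away from zero.
* Strict `>` for disease thresholds; `>=` only for the 0.4-in humane
  limit.
* Competition ranking for compounds (ties share the minimal rank, the
  next rank is skipped: 1, 2, 2, 4), matching how tied therapeutic-response
  means are annotated in practice. Ranks are ascending in the severity
  mean: rank 1 = largest attenuation.
* Zero-variance inputs make correlations undefined; they are reported
  missing, never coerced to 0 or 1.
* Every pipeline artifact carries a configuration hash on its first line,
  and identical reruns are byte-identical.

## Problem sizes

The test suite simulates cohorts of 2-20 animals per group over study
days $-3$ to $17$ at one sample per minute (30,240 samples per animal);
the parameter-recovery checks use 10 seeds of 20 induced + 20 control
animals, and oracle-equivalence checks run on 1,000 random series. The
acceptance script reruns a 9 + 9 validation-style study from scratch.
These sizes mirror the published experiments (7-16 animals per group)
while keeping a full run in tens of seconds on a laptop.

## Known limitations

* The salient-feature set is a single configurable feature; published
  indices hint at aggregating several. The surface (`method` argument)
  leaves room, but only `q99`/`max`/`mean` are implemented.
* Onset tolerance to interior gaps is a convention (forward-looking over
  two days); alternatives would shift onsets by about a day.
* Inferential statistics (ANOVA families, post-hoc tests, significance
  stars) are deliberately out of scope; the pipeline exports tidy tables
  for whatever inference machinery the analyst prefers.
* The humane-endpoint score criterion (score 4 sustained > 48 h) fires
  for a substantial fraction of severely diseased simulated animals near
  the study end; severity is then read at the censor day, as it would be
  in a live study.
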