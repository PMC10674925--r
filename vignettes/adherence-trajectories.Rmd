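---
title: "Modeling longitudinal adherence trajectories from dispensing records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal adherence trajectories from dispensing records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(adheretraj)
library(dplyr)
```

## The estimation problem

Pharmacy dispensing data give, per patient, a sequence of fill dates and
days of supply for a drug of interest. Adherence over a fixed observation
window must be reconstructed from these refills. `adheretraj` implements the
continuous-medication-availability estimator CMA9 and builds a longitudinal
analysis on top of it: patients are characterized not by one number but by a
12-point trajectory of monthly availability, clustered into behaviorally
distinct groups whose determinants are then modeled.

The intended cohort design is incident use: the index date is the first
fill of the target drug inside an enrolment window, with no earlier fill in
the available history, and each patient is observed for 365 days from
index. Patients who leave the database region after index, lack a full year
of potential follow-up, or die inside the window are excluded (in that
precedence order, each patient logged with one reason) — trajectory
clustering requires complete 12-month vectors, which is also why death is
an exclusion rather than a censoring event.

## CMA9: definition and numerical choices

Let fills occur at days $t_1 < t_2 < \dots < t_m$ inside the half-open
window $[0, T)$, $T = 365$, with supplies $s_i$ (30 days per fill in the
primary analysis). For each inter-fill interval (the last runs from $t_m$
to $T$), the available supply is the fill plus carryover from the left:

$$a_i = s_i + \max(0, a_{i-1} - (t_i - t_{i-1})), \qquad
  r_i = \min\!\left(1, \frac{a_i}{t_{i+1} - t_i}\right).$$

Every day of interval $i$ receives the ratio $r_i$; days before $t_1$
receive 0; supply still unconsumed at $T$ is discarded (end-period
exclusion). Overall CMA9 is the mean daily ratio, and the trajectory is the
daily-ratio mean over 12 contiguous, non-overlapping 30-day windows. The
five residual days 360–364 enter only the overall figure; windowing a
365-day year is necessarily ragged somewhere and a 13th 5-day "window"
would have far higher variance than the rest.

Numerical conventions, all tested against a brute-force day-by-day supply
simulation: intervals are half-open so day arithmetic is exact on integers;
same-day duplicate fills are merged by summing supplies (there is no
intra-day order); the ratio is capped at 1 with the excess carried forward,
which is what makes a day's value interpretable as availability. Two
consequences give useful invariants: when no interval caps and no supply
crosses $T$, overall CMA9 equals total supply divided by $T$ exactly; and
adding a fill can never decrease it.

A companion helper reassigns refill durations for sensitivity analyses —
either all fills at 30 days (the primary choice, matching the typical
delivery period) or the first at 30 and subsequent fills drawn uniformly
from 30/60/90 days under a seed.

## Trajectory clustering

Trajectories are clustered with k-means on the raw 12-dimensional window
vectors: all coordinates already share the $[0,1]$ scale, so no
standardization or smoothing is applied. The implementation is Lloyd's
algorithm with squared Euclidean distance, k-means++ seeding, 20
independent starts (k-means is initialization-sensitive), iteration until
assignments stabilize (at most 100), and empty clusters re-seeded from the
point farthest from its centroid. The number of groups is selected by
maximizing the Calinski–Harabasz criterion over $k = 2\ldots6$ — a range
that brackets the plausible number of behavioral patterns with margin —
with ties broken toward the smaller $k$ and a degenerate zero-scatter
solution scoring $+\infty$.

Labels are assigned to centroids by deterministic rules: a centroid
averaging at least 0.7 over windows 1–4 and at most 0.35 over windows 9–12
is `partial_drop_off`; the remaining clusters are ranked by overall mean
into `high` / `moderate` / `low`, surplus middle clusters becoming `other`
(rank-based, so exact ties cannot flip labels). The thresholds encode the
qualitative description of the drop-off pattern — high early adherence,
roughly 10% late availability — with a wide safety margin: on the
synthetic cohorts the drop-off centroid's late mean is ≈ 0.15 and the
nearest competitor (moderate, flat ≈ 0.54) is far from both cut-offs.

## Covariate profiles and outcomes

Patient complexity is summarized by the age-adjusted Charlson comorbidity
index (standard 1/2/3/6 condition weights; age points +1 per decade from
50–59, capped at +4) classified low (0–1) / mild (2–3) / severe (≥4), and
by polypharmacy classes: none (≤4 distinct drugs), polypharmacy (5–9),
excessive (≥10). The class boundaries are exact integer thresholds and are
tested as such.

Persistence is operationalized with a grace rule, since dispensing data
never record an explicit stop: a patient discontinues when the next fill
arrives more than 30 days (the grace parameter) after the current supply is
exhausted, and days on treatment run from index to that exhaustion, capped
at 365. Switching is the first fill of an alternative heart-failure class —
diuretics (C03), beta blockers (C07), renin–angiotensin agents (C09) — at
or after discontinuation, binned by time from *index* at ≤30 / ≤60 / ≤180
days / later. The bins are disjoint; cumulative figures can be derived at
summary time. Bin edges are closed on the right (day 30 is "within 1
month"), a convention fixed here because the tabular convention upstream
is ambiguous.

## The membership model

Group membership is modeled with maximum-likelihood multinomial logistic
regression against the high-adherence reference, fitted by `nnet::multinom`
(tight convergence tolerance, 500-iteration cap) behind the package's
interface; with two groups it agrees with an ordinary binomial logit to
$10^{-6}$. Continuous covariates enter untransformed; categorical ones are
dummy-coded against their most prevalent level. Confidence intervals are
Wald ($\exp(\hat\beta \pm 1.96\,\mathrm{se})$), matching the symmetric
intervals conventional in this literature; rank-deficient designs and
apparent perfect separation (huge coefficients with degenerate standard
errors) are refused with an explanatory error rather than silently
reported.

Stepwise selection is forward with backward pruning on likelihood-ratio
tests: add the candidate with the smallest LR p-value below 0.05, then drop
any included covariate whose removal p-value rises to or above the
threshold, until nothing changes. Candidates are scanned alphabetically so
the procedure is fully deterministic. "Stepwise" alone underdetermines the
algorithm; at the effect sizes relevant here the directional variants
rarely disagree, and this one is reproducible.

## The synthetic cohort

No regional claims database can ship with the package, so all testing and
calibration run on a generator that emulates the statistical structure the
analysis assumes — four refill archetypes mixed in known proportions, with
covariates linked to membership through a multinomial logit.

Inter-refill gaps are lognormal with coefficient of variation 0.15,
truncated at 1 day and rounded to integer days: strictly positive,
right-skewed, and tight enough that the four archetypes stay well separated
(component separation of several within-component standard deviations in
trajectory space). The archetypes:

| archetype | gap process | target mean CMA9 |
|---|---|---|
| high | mean gap 33 d all year | 0.91 |
| partial_drop_off | mean gap 30 d through month 6, then one fill per month with probability 0.21 | 0.63 |
| moderate | mean gap 58 d all year | 0.54 |
| low | mean gap 35 d, no refills after month 2 | 0.17 |

Gap means were calibrated by an independent Monte-Carlo (2000 replicates
per archetype) before the pipeline was built, and the calibration is
re-checked by a test asserting each archetype's mean overall CMA9 sits
within 0.03 of its target. For the drop-off archetype the late-phase refill
probability is the calibrated parameter: with monthly 0.1 the archetype's
mean lands near 0.58, so it was set to 0.21 to reach the 0.63 target while
keeping the centroid's late-window mean (≈ 0.15) safely inside the
labeling rule.

Default mixture weights are the exact published group counts
(1898/874/862/821 of 4455). Covariates are drawn independently per patient
(no joint distribution is available to emulate): sex M with probability
0.70, age $\mathcal N(69.1, 12^2)$ clipped to 18–100, polypharmacy class
multinomial (30.6/31.6/37.1 %), hospitalization counts Poisson with rates
chosen to match the published exceedance frequencies
($P(\ge 1\ \text{HF hosp}) = 0.334$,
$P(\ge 2\ \text{other hosp}) = 0.196$), and comorbidity flags at their
published prevalences (every patient carries the heart-failure flag).
Planted membership effects are log odds on three binary covariates
(polypharmacy ≥5 drugs, ≥1 HF hospitalization, ≥1 other hospitalization);
given the planted slopes, group intercepts are solved by exact enumeration
over the $2^3$ covariate cells and a log-scale fixed point, so the marginal
group proportions equal the mixture weights regardless of the effects.
Patients who discontinue may pick up an alternative heart-failure class
(C03/C07/C09) with probability 0.5 shortly after their supply runs out,
giving the switching analysis realistic material.

What the generator deliberately does not emulate: dose titration across
strengths, in-hospital free samples, death and censoring (excluded by the
cohort design), correlated covariates, and seasonal or calendar effects.
Passing tests therefore demonstrate that the estimator, the clustering and
the models recover planted structure of the assumed form — not that real
dispensing data satisfy those assumptions.

## Reproducibility and problem sizes

Every stochastic stage takes a seed; the pipeline fans a single seed out to
per-stage seeds by hashing the stage name, so a stage re-run in isolation
sees the stream it saw inside the full run, and identical configurations
produce byte-identical outputs. The packaged checks use cohorts of
n = 2000 (trajectory-group recovery; 100 seeded replicates for the
selection-of-k study) and n = 4455 with 25-replicate averaging for
odds-ratio recovery — sizes at which the recovered quantities' Monte-Carlo
error is comfortably below the tolerances being asserted while the whole
suite runs in minutes on one core.

## A complete run

```{r, eval = FALSE}
res <- run_pipeline(generator = generator_config(2000, seed = 7), seed = 7)
res$group_summary
res$clusters$ch_by_k
autoplot(res$clusters, res$trajectories)
if (!is.null(res$model$fit)) autoplot(res$model$fit)
```

## Known limitations

CMA9 is one member of a family of availability estimators; other carryover
or end-handling conventions exist, and the dialect implemented here — cap
at 1, carry the excess, discard end-overflow — is documented and
oracle-tested rather than asserted identical to any other implementation.
The clustering is plain k-means: it assumes roughly spherical groups in
trajectory space and will split or merge strongly non-spherical patterns;
model-based latent-class growth modeling is out of scope. The stepwise
procedure inherits the usual caveats of data-driven selection (optimistic
p-values in the final model). Printed odds-ratio confidence intervals in
small published tables are sometimes inconsistent with the stated sample
size; only point estimates are treated as recoverable quantities here.
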