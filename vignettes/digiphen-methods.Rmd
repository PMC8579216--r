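---
title: "Passive sensing of internalizing symptoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive sensing of internalizing symptoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digiphen)
```

## The problem

Anxiety and depression in youth are usually assessed with self-report
instruments at discrete clinic visits. Passive smartphone sensing offers a
complementary, continuous measurement channel: GPS, call logs, screen events
and the ambient-light sensor record behavior — mobility, social interaction,
phone use and a sleep proxy — without any user action. `digiphen` implements
an analysis pipeline for such studies: stream ingestion and validation, daily
feature extraction, instrument scoring, covariate-adjusted association
analysis, and a synthetic cohort generator that makes the whole stack
testable without access to any participant data.

The design emulates a 14-day observational protocol in youth aged 10–21:
streams are collected on the phone (GPS fixes logged only when displacement
exceeds 20 m, event-based call and screen logs, light samples logged on
change), anxiety is measured with the 33-item SCARED, depression with the
20-item CES-DC, and ADHD symptoms with the 18-item ASRS as a
discriminant-validity comparator.

## Feature extraction

All feature windows are computed on the participant's local clock; a "day" is
the half-open interval between consecutive local midnights. Timestamps are
stored as UTC instants plus a per-participant offset.

**Mobility (GPS).** Distances are great-circle (Haversine) on a sphere of
radius 6,371 km. The displacement filter keeps the first fix and every fix
strictly more than 20 m from the previously kept one — the same rule the
collecting app applies, so re-applying it at extraction time is idempotent.
Fixes are grouped into *location clusters* by greedy sequential assignment:
a fix joins the first existing cluster (by creation order) whose running-mean
centroid lies within 150 m, else founds a new cluster. This is deliberately
order-dependent and cheap; because running means drift, membership is
guaranteed at assignment time, and the test suite asserts members stay within
twice the radius of the final centroid. Dwell time between consecutive fixes
is attributed to the earlier fix's cluster, and the day's final fix carries
forward to local midnight — under displacement-triggered sampling, no new fix
means no movement. Hours before the day's first fix have no carried position
and are `no_data`, excluded from the day's `hours_observed`.

Per hour, the number of distinct clusters occupied for at least 2 minutes
(intervals clipped at hour boundaries) classifies the hour: 1 location is
*stationary*, 2–9 *moving*, 10 or more *transportation*. The boundary count
of exactly 10 is assigned to *transportation* so the classes partition the
counts contiguously. Daily summaries are: hours stationary, hours moving
(moving + transportation), kilometers traveled (Haversine over retained
fixes), and the normalized location entropy

$$H = -\sum_{i=1}^{N} p_i \log p_i \,/\, \log N,$$

where \(p_i\) is cluster \(i\)'s share of the day's dwell time. The log base
cancels in the ratio (asserted by test); \(H\) is 0 when one cluster holds
all dwell, exactly 1 for a uniform spread over any \(N \ge 2\), and depends
only on the shape of \(p\). Entropy is computed per day and then averaged
across days, consistent with aggregating all features into daily summaries.

**Calls.** A call is *connected* when its direction is incoming or outgoing
and its duration is positive; missed calls are counted separately and never
contribute to the incoming count or to daily call minutes. This makes
`n_connected = n_incoming + n_outgoing` an identity, which is why the
connected count stays out of the linear models (it would be exactly
collinear) while remaining in the correlation analysis.

**Screen.** On/off events become use sessions: consecutive same-state events
are deduplicated keeping the first, an off before any on is dropped, a
trailing unmatched on is closed at the next local midnight, and sessions
straddling midnight are split at the boundary (the unlock is counted once, on
the day the session began). All repairs are counted and reported. Screen
time is the summed session duration — a difference of event *counts* cannot
yield minutes, so the summed-interval reading is the only dimensionally
consistent one.

**Night light (sleep proxy).** The light stream logs changes, so each sample
holds its value until the next (zero-order hold). Over the 11 PM–7 AM window
— attributed to the date containing 11 PM — the pipeline reports the
time-weighted mean lux and the minutes below 10 lux (darkness) and above
1,000 lux (bright light). The source protocol never defines its "lowest and
highest intensity ranges", so these two thresholds are explicit, documented
parameters. A sample preceding the window is carried into the window head,
but a night with no in-window sample at all is reported missing rather than
extrapolated. The upstream study's printed light statistic has unstated
units (its magnitude, ~3×10⁵, suggests a lux·time sum); this package reports
the interpretable time-weighted nightly mean instead and makes no attempt to
reproduce that aggregate.

## Instrument scoring

SCARED (33 items, 0–2) and ASRS (18 items, 0–4) are plain sums; CES-DC
(20 items, 0–3) reverse-scores the positively worded items 4, 8, 12, 16 as
`3 − raw` per the published key (the key is an argument, so alternative item
orderings can be supplied). Which 33 of SCARED's 41 items were administered
is the caller's responsibility; items are summed as given. Totals are
missing when fewer than 80% of items are answered; otherwise missing items
are imputed at the participant's mean over answered items. ASRS responses
are treated dimensionally (0–4 frequency sum), matching their correlational
use as a comparator.

## Statistical analysis

Daily features are averaged per participant over non-missing days (unweighted),
giving one row per retained participant. Retention applies three filters in
fixed order — withdrawal, then fewer than 14 days of data, then missing
required sensors — and a participant failing several counts once, under the
first. This unique attribution is what makes the exclusion ledger sum to the
enrolled count.

Participants whose feature values fall outside Tukey's far-out fences
(\(Q_1 - 3\,\mathrm{IQR}\), \(Q_3 + 3\,\mathrm{IQR}\)) are excluded from that
sensor domain's analyses only — an extreme GPS outlier still contributes to
call analyses. The fences are affine-equivariant, so flagging does not
depend on units.

**Adjusted Spearman correlation.** "Adjusted" rank correlation is
operationalized as the standard partial-Spearman construction: rank-transform
both variables (average ranks for ties), residualize each rank vector on the
covariate design (categorical covariates expanded to indicators; the
"missing" maternal-education category is kept as its own level), and take the
Pearson correlation of the residuals. The p-value uses the t reference with
`df = n − 2 − (covariate columns)`. With no covariates this reduces exactly
to plain Spearman, and it inherits rank invariance under strictly monotone
transforms. Covariates are age, sex, maternal education, operating system
and assessment month; by default each outcome is additionally adjusted for
the other two instruments' totals, so anxiety associations are net of
comorbid depression and vice versa — the comparison that makes
symptom-specific claims possible. Unadjusted coefficients are reported
alongside, and Benjamini–Hochberg q-values accompany the raw p-values.

**Nested model comparison.** Base OLS (covariates only) against base plus
the sensor features on listwise-complete cases, compared with
\(F = ((\mathrm{RSS}_0 - \mathrm{RSS}_1)/d_1) / (\mathrm{RSS}_1/d_2)\).
The implementation fits by QR; the tests verify it against an explicit
normal-equations computation and against `stats::anova`. The feature set in
the model excludes the connected-call count (see above), so 10 features
enter. The exact predictor count of the upstream analysis is not
recoverable from its printed degrees of freedom, so the package exposes
`df1`/`df2` as outputs rather than forcing any particular value.

**Discriminant validity.** Each outcome's full-model fitted values
("sensor-predicted scores") are Spearman-correlated with the *other*
observed instruments: a predicted internalizing score should track the other
internalizing instrument but not the ADHD comparator.

## The synthetic cohort generator

The generator defines the study conditions the package is validated under:
161 enrolled participants, 14 days, retention drawn as a single categorical
event per participant with probabilities 11/161 (withdrew), 25/161 (short
data), 3/161 (missing sensors) — disjoint by construction, matching the
arithmetic of the emulated study's participant flow (161 − 11 − 25 − 3 =
122). Demographics follow the printed cohort: age from a clipped normal
(base location 18.23 so the clipped mean lands on 18.0, SD 2.76, range
10–21), 78.6% female, 78.6% iOS, the five maternal-education proportions,
assessment months February–July 2020.

Latent anxiety and depression are bivariate standard normal with correlation
0.5; latent ADHD is independent. Planted couplings are standardized
log-rate shifts of magnitude 0.3 — the scale of the weak-to-moderate rank
correlations such studies report — with directions: depression increases
stationary time and nighttime light and decreases trips/distance and
outgoing calls; anxiety does the reverse for mobility and increases screen
time. Each behavioral process:

- **GPS**: home plus five personal anchors 0.4–2 km away; a Poisson number
  of round trips per day with log-rate `0.3·anx − 0.3·dep`; trip waypoints
  at 90 s intervals at 8 m/s; dwell fixes with sub-threshold jitter; the raw
  trace passes through the 20 m displacement filter, and coordinates carry
  6-decimal (≈0.1 m) resolution, like real GPS logs. Two constructions keep
  location entropy *uncoupled* from the planted mobility effects, emulating
  the upstream null finding: the total time away from home follows a
  per-participant budget independent of the trip count, and one primary
  anchor dominates destination choice (weight 0.75), so the dwell
  distribution's shape varies with the independent budget rather than with
  how often the participant goes out. The day's first fix arrives at a
  variable overnight time, so daily coverage varies as in real streams.
- **Calls**: Poisson counts (incoming 1.8/day, outgoing 2.1/day with the
  depression coupling, missed 0.5/day); log-normal durations with a
  direction-specific median (incoming 180 s, outgoing 60 s) and an
  independent per-participant duration trait (sdlog 0.9). The trait and the
  direction asymmetry keep total call minutes — driven mostly by the longer,
  uncoupled incoming calls — effectively null despite the outgoing-count
  coupling.
- **Screen**: ~54 sessions/day with log-normal durations scaled by
  `exp(0.3·anx)`; the session *count* carries no coupling, so unlock counts
  act as a null feature while screen time carries the planted one.
- **Night light**: a dark personal baseline (0.5–5 lux) with Poisson light
  episodes (rate `1·exp(0.3·dep)` per night, 300 lux median, 10–30 min).
- **Surveys**: item responses are binomial ordinal draws whose logistic
  propensity loads on the latent score (loading 0.7). The logistic constants
  (SCARED slope 1.06; CES-DC intercept 0.23, slope 1.30) were calibrated
  once, numerically, so total means and SDs match the emulated cohort's
  printed 33.0 (14.8) and 32.6 (15.2); reverse-keyed CES-DC items are stored
  inverted so scoring restores them.

Randomness is split per participant-day by an integer mixing function of
(seed, participant, day), so enlarging the cohort or extending the window
never perturbs existing participants' data, and the whole study is
byte-reproducible from one seed.

What the generator does **not** emulate: street networks or realistic
routing, weekday/weekend structure, pandemic-era behavior shifts,
demographic confounding (latents are independent of age, sex and the other
covariates, so covariate adjustment is exercised as a no-op on average), and
within-person symptom dynamics (latents are static, matching the
between-person design). Passing recovery tests therefore show the *analysis
stack* is correct and calibrated under known truth — not that real youths
behave like the generator.

## Numerical choices and degenerate inputs

- Entropy: `0·log 0 ≡ 0`; a single cluster returns 0; dwell fractions must
  sum to 1 within 1e-9; output clamped to [0, 1] against rounding.
- A stray parenthetical in the printed entropy formula could be read as a
  log base; base invariance of the normalized ratio makes the choice moot,
  and natural logs are used.
- Empty streams yield empty (not missing) feature tables; a day with no GPS
  fix is a missing mobility row excluded from the participant's averages; a
  day with an active but event-free call or screen stream is a true zero.
- Sessions ending exactly at midnight belong wholly to the earlier day
  (half-open days, exact modulo arithmetic rather than an epsilon).
- Zero-variance association inputs and rank-deficient designs are errors
  naming the offending columns, not silent results.
- Clustering ties (a fix within 150 m of several centroids) go to the oldest
  cluster, by creation order.
- Whether the printed "time moving" includes transportation hours is
  ambiguous upstream; moving ⊇ transportation is adopted (the complement
  structure of the printed daily hours supports it) and documented here.

## Problem sizes in the validation suite

The test suite validates the full stack at sizes chosen to balance Monte
Carlo resolution against desk-scale runtimes: oracle-equivalence checks on
instances of up to ~120 observations; type-I calibration with 2,000
replicates (nested F at n = 80 with 17 noise predictors; partial Spearman at
n = 100); end-to-end recovery on 100 seeded cohorts of 300 enrolled
participants (≈229 retained each after the retention filters); and
conservation bounds over ≈1,000 simulated participant-days. Survey
calibration uses 5,000 simulated participants.

## Known limitations

- The greedy clustering is order-dependent; a different fix order can yield
  different clusters. This mirrors the simple online rule the feature
  definitions are built on, not a clustering optimum.
- The partial-Spearman p-value is a t approximation; it is near-nominal in
  the calibration suite (≈5% at n = 100) but is not exact at small n.
- Entropy and call-duration nulls in the generator are *structural*
  approximations: residual leakage through trip counts and call counts is
  kept below |r| ≈ 0.1 on average by design, not exactly zero.
- The pipeline analyzes between-person differences only; no within-person
  (day-level) modeling is attempted.
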