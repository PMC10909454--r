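---
title: "Methods: from acceleration bursts to survival estimates in a partially migratory stork population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from acceleration bursts to survival estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciconia)
```

`ciconia` analyses biologging data from a white stork population in
which four movement strategies coexist: local residency (year-round
within 50 km of the nest), regional residency (ranging farther across
Southwest Europe), short-distance migration to Northwest Africa, and
long-distance migration across the Sahara into the Sahel. This vignette
documents the models, the conventions chosen where the procedures were
genuinely open, and what the synthetic tests do and do not demonstrate.

## Energetics and behaviour from acceleration bursts

Loggers record a 9-s tri-axial burst every 20 min. ODBA is computed by
removing the static (gravitational) component of each axis with a
centred running mean and averaging the 3-axis absolute dynamic sum over
samples:

$$\mathrm{ODBA} = \frac{1}{n}\sum_{t=1}^{n}\sum_{k \in \{x,y,z\}}
  \left| a_k(t) - \bar a_k^{(w)}(t) \right|$$

Conventions, each of which matters numerically:

* **Window width** is `round(window_s * rate_hz)` samples (4 s by
  default), centred, with the extra sample trailing for even widths,
  and truncated at the burst edges rather than padded — no data are
  invented at the boundaries. A constant series is returned exactly
  unchanged, so constant bursts have ODBA exactly 0.
* **Averaging over samples** (rather than summing) makes values
  comparable across tag schedules with different rates and durations.
* ODBA is invariant to per-axis constant offsets (calibration shifts)
  and to axis permutation; these invariances are tested as properties.

Behaviour classification uses a random forest (via `ranger`) over a
15-dimensional burst summary: per-axis mean, SD and range, ODBA,
pairwise axis correlations (0 by convention for constant axes), the
dominant heave frequency, and the share of non-DC heave spectral power
above a quarter of the sampling rate (high for noise-like signals, low
for smooth drift). The feature set is an implementer choice: the field
workflow this mirrors trained random forests on manually labelled
bursts without publishing a feature list. Accuracy is reported on a
seeded stratified held-out split (25% by default). Two tag families can
be served by training two classifier instances on their respective
subsets; tag type is otherwise carried through outputs as metadata, and
no cross-tag calibration is applied.

Behavioural budgets are proportions of bursts (bursts are equally
spaced, so burst shares are time shares), computed per day first and
then averaged across days, so unevenly sampled days weigh equally.

## Trajectory segmentation

* **Roosts.** "Roost" is operationalised as the median position of
  fixes in the nocturnal window, 22:00–04:00 local solar time (derived
  from longitude alone), assigned to the evening's date. The median
  resists outlying fixes; solar rather than clock time keeps the window
  aligned with darkness across the 30° of longitude a migrant spans.
* **Migration windows.** A migration day displaces the roost by more
  than 60 km relative to the previous calendar date; a qualifying run is
  at least 3 consecutive such days, and a missing roost date breaks a
  run (the strictest reading of "consecutively"; a gap-tolerant variant
  was considered and rejected because it blurs the window edges the
  tests pin to the day). Qualifying runs are merged by direction: the
  southbound group forms the autumn window, the northbound group the
  spring window. This directional reading resolves an ambiguity in how
  the "after departing the range" clause attaches to multi-leg
  passages, and reproduces the intended phenology on any
  single-passage track.
* **Strategy rules.** A bird is a migrant as soon as any roost lies
  south of the Gibraltar line (35.9° N by default): at this spatial
  scale a latitude line is equivalent to a strait-crossing polygon and
  far simpler. Among migrants, the wintering-period roost centroid
  south of 20° N (the Sahel) makes a `sub_saharan` bird, else
  `nw_africa`. Among residents, all roosts within 50 km of the nest
  make a `local` bird, else `regional`; roost (not fix) distances are
  used so that daytime foraging trips cannot tip the label. All lines
  and radii are configurable.
* **Seasons.** Residents use the population's fixed dates (autumn
  Aug 4 – Sep 5, wintering Sep 6 – Dec 12, spring Dec 13 – Jan 22,
  breeding Jan 23 – Aug 3). Migrants use their own detected windows,
  with breeding as the remainder of a 365-day cycle anchored at the
  autumn departure; anchoring migrants at Aug 4 instead would split
  breeding into two intervals and break the four-interval contract.
  Intervals are closed on both ends and are validated to tile the cycle
  contiguously.
* **Nest occupation** is the first day of the first run of 3
  consecutive days with a fix within 75 m of the nest (the radius is
  unpublished in the field protocol; 75 m separates nest attendance
  from neighbouring perches at typical GPS error). Because the annual
  cycle opens at the nest in August, the search starts by default on
  Dec 1 of the cycle so the date measures the post-winter return.

`total_displacement` sums great-circle legs between consecutive fixes
(haversine, Earth radius 6371.0088 km), so it includes fine-scale
foraging movement, not just net travel; this is the "sum of all
distances moved" convention and is what makes season-level values
recombine exactly to annual ones (minus the three boundary links, which
belong to no season).

## The multievent survival model

Encounter histories code, per annual occasion: 0 = not observed, 1 =
detected with active GPS, 2 = resighted alive without a working tag,
3 = recovered dead. Hidden states are Aa, Ai (alive with
active/inactive tag), Ra (recently dead, tag active), LD (long dead).
Three design constants reflect the study system and are never
estimated: every bird is released alive with a working tag
(τ_Aa = 1), active tags are always detected (p_Aa = 1), and dead birds
with active tags are always recovered (r = 1).

Transitions compose survival first, then tag fate:

|      | Aa         | Ai   | Ra    | LD    |
|------|------------|------|-------|-------|
| Aa   | φ(1−λ)     | φλ   | 1−φ   | 0     |
| Ai   | 0          | φ    | 0     | 1−φ   |
| Ra   | 0          | 0    | 0     | 1     |
| LD   | 0          | 0    | 0     | 1     |

so Ra is reachable exactly when death occurs while the tag is active —
consistent with all recoveries coming from birds with working loggers.
A bird whose tag fails in the interval it dies resolves to Ra (death
takes precedence); this is a convention, flagged here because the
source material specifies the matrices only in an appendix. Ra persists
one occasion and then absorbs into LD ("recently dead" semantics:
recovery can happen once). λ is constant across groups and occasions by
default.

The likelihood of a history is the forward-algorithm sum over hidden
state paths; impossible histories yield −∞ rather than an error. The
implementation is vectorised over pooled identical histories and is
verified in the tests against exhaustive path enumeration over all
4^4 event histories. Fitting maximises the joint log-likelihood on the
logit scale with seeded multi-start BFGS (10 starts by default; ties
broken by lowest deviance, then start index). Confidence intervals are
Wald on the logit scale, back-transformed — adequate away from the
boundary; profile intervals were considered and left out as the Wald
intervals cover the recovery tests' needs.

Model comparison uses QAICc with the overdispersion coefficient ĉ taken
as an input (goodness-of-fit testing is out of scope; the motivating
analysis used ĉ = 2.52 from external GOF software) and effective sample
size equal to the number of individuals, the standard capture–recapture
convention. Both are arguments, not constants.

## The synthetic-data generator

The generator exists so that every stage has ground truth; its defaults
are the study conditions, chosen once:

* **Geography**: nest at (−8.0, 38.8) in southern Portugal; Gibraltar
  line 35.9° N; Sahara line 20° N. Coastlines, habitat and weather are
  deliberately absent — only roost-scale geometry feeds the rules.
* **Movement**: one roost per day, drawn per phase. Migrant travel legs
  are ~100–300 km/day (always ≥ 3 consecutive days over 60 km);
  NW-Africa winter centroids fall at 31–34° N, Sahel centroids at
  13–16° N. Regional residents reach their non-breeding area 80–400 km
  away in at most 2-day hops, so they can never satisfy the 3-day
  migration rule. Local birds rotate among sites within 25 km. Fixes
  every 20 min interpolate between consecutive roosts (en route
  08:00–20:00 local) with ~1 km daytime and ~10 m nocturnal jitter.
* **Strategy mix** defaults to 9 local : 42 regional : 6 NW-Africa :
  10 sub-Saharan (the 67 birds with a fixed annual strategy in the
  motivating population).
* **Bursts**: static gravity vector plus behaviour-specific dynamics —
  near-zero noise (resting), mid-amplitude white noise (foraging),
  sinusoidal heave of 0.8 g (flapping), slow smooth drift (soaring).
  The default schedule is the field one, 9 s at 1 Hz; since 1-Hz
  sampling has a 0.5-Hz Nyquist limit, the default flapping frequency
  is set to 0.3 Hz so that the periodic heave is representable at the
  default rate (real wing-beats are faster; tests also exercise 10 Hz
  with 3.5-Hz flapping). The configuration validates
  `flap_hz < rate/2`.
* **Phenotypes**: wing length ~ N(580, 20) mm; migration probability is
  logistic with slope −0.05 per mm and intercept logit(16/75), matching
  the population's migrant fraction at the mean wing length.
* **Encounter histories** are simulated from the exact state/event
  matrices above. The signal-loss rate used in recovery tests is 0.3.

What passing tests show — and what they do not. The generator's classes
are cleanly separable by construction (behaviour classes by their
dynamics, strategies by their geometry), so 100% strategy recovery and
near-perfect classifier accuracy on synthetic corpora validate the
*rules and the plumbing*, not field-data performance: real bursts mix
behaviours within 9 s, real tracks have gaps, duty-cycle changes and
outliers, and real labels are noisy. The published field accuracies
(~96%) are not reproducible without the field data. Conversely, the
likelihood arithmetic, the window/partition algebra, the ODBA formula
and the estimator's bias at the study's parameter regime are exactly
the kinds of properties synthetic data can establish.

## Problem sizes and numerical choices

The test suite and the acceptance script run at: 40 annual tracks
(10 per strategy, ~26,000 fixes each) for segmentation recovery; 1000
bursts (250 per class) for the classifier; 500 histories × 6 occasions
for parameter recovery, 2000 for the bias check (|bias(φ̂)| < 0.02); 50
replicates of 150 histories for the null-model preference check. These
sizes give stable Monte-Carlo behaviour at interactive runtimes.
Optimisation starts are drawn uniformly on the logit scale in
[logit(0.15), logit(0.95)]; degenerate inputs (single-class training
sets, out-of-range probabilities, empty series, histories not starting
with event 1) raise classed input errors, while impossible histories
return −∞ likelihood by design.

## Known limitations

* Geography is two latitude lines and a point; no coastline, stopover,
  or habitat structure, and no between-year strategy switching within
  one simulated cycle (labels are per annual cycle by design).
* The ODBA–energy relationship is uncalibrated (the motivating study
  could not calibrate it either); ODBA is a within-study activity
  proxy, and cross-strategy energetic contrasts in synthetic data
  reflect the generator's behaviour schedule, not field energetics.
* λ is constant over time and groups; occasion-varying signal loss
  would need only a small extension of the parameter packing but is not
  implemented.
* Wald intervals can misbehave for parameters near 0 or 1 with few
  informative histories (e.g. p_Ai when λ is tiny); estimates remain
  valid, intervals may be degenerate.
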