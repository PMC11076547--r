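---
title: "Rhythm, tempo, rubato and ornamentation: a combinatorial analysis of sperm whale codas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm, tempo, rubato and ornamentation: a combinatorial analysis of sperm whale codas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codacomb)
```

## The model

Sperm whales vocalise in *codas*: stereotyped bursts of 3–40 broadband
clicks, generally under two seconds long, exchanged between whales in
choruses. A coda's temporal structure is fully described by its vector of
inter-click intervals (ICIs). This package decomposes that structure into
four features:

* **rhythm** — the standardised ICI vector (each ICI divided by the coda's
  duration, a unit-sum vector), discretised by nearest-centroid assignment
  within each click-count group;
* **tempo** — the total duration, discretised into the modes of a Gaussian
  kernel density estimate over all durations;
* **rubato** — smooth, sustained modulation of duration across a whale's
  consecutive codas, while rhythm is preserved;
* **ornamentation** — an extra final click appended to a coda whose
  remaining clicks match its neighbours.

Rhythm and tempo are context-independent; rubato and ornamentation are
contextual, and the package's bespoke statistics test exactly that: whether
interacting whales control and respond to them.

## Conversational structure

Ordered datasets (onset times and speaker identities) support a small
grammar of interaction, all driven by two constants:

* a **call sequence** is a maximal run of one whale's codas with
  consecutive gaps of at most 8 s (twice the average ~4 s response time);
  the gap is measured onset-to-onset by default because the constant is a
  response-period multiple, with a termination-to-onset option;
* a following coda is **adjacent** (turn-taking) if its onset falls within
  2 s after the previous coda's termination (closed interval, so a gap of
  exactly 2 s or 0 s counts), and **overlapping** if its onset falls inside
  the previous coda's span;
* a **chorus** is a connected component of the cross-whale link graph;
  within a linked pair the earlier onset leads, a whale's chorus role is
  its modal pairwise role, and onsets coinciding within 1 ms are excluded
  rather than broken arbitrarily.

## The bespoke statistics

All permutation tests use 10,000 resamplings by default and the add-one
convention `p = (extreme + 1)/(N + 1)`, so the smallest reportable p value
is 1/10,001.

**Adjacent-pair drift.** The tempo drift between two codas is the signed
difference of their durations. The observed statistic is the mean absolute
drift over consecutive same-whale pairs of the same discrete (rhythm,
tempo) type inside call sequences. The null — drift depends only on the
discrete type — is built by permuting durations within each (whale, type)
group and re-measuring the same adjacency pattern, which is exactly a draw
of random same-type pairs without replacement. One-sided: smooth rubato
makes adjacent drift *small*.

**Triple correlation.** For consecutive same-type triples, the Spearman
correlation between the first and second pairwise drifts. One subtlety is
worth stating because it changes the reference point: for independent
durations the two drifts share the middle duration with opposite signs, so
the null correlation is −1/2, *not* zero (the simulator's null worlds
reproduce −0.5 closely). A strongly positive observed correlation is
therefore even stronger evidence of sustained drift than a naive
zero-reference reading suggests.

**Chorus duration matching.** Mean absolute duration difference over
overlapping cross-whale pairs, against random non-overlapping same-type
cross-whale pairs (one drawn per observed pair, distinct within a
resample). One-sided: imitation makes overlapping pairs match *closely*.

**Ornament statistics.** An ornament is the final click of a coda with
exactly one more click than the nearest preceding or nearest following
coda within a 10 s window. The window is measured between coda spans
(onset minus previous termination), which makes the rule exactly symmetric
under time reversal; the default scope is the same whale's codas, since an
ornament is defined against the caller's own pattern. Four analyses treat
detected ornaments as a candidate feature:

1. *centroid MSE*: per ornamented coda, the squared distance of the
   standardised vector to its own assigned rhythm centroid (ornament
   retained) versus the distance, after dropping the final ICI and
   re-standardising, to the rhythm centroid of its adjacent same-whale
   codas; the paired one-sided p value comes from a sign-flip permutation
   of the per-coda differences;
2. *final-ICI distribution*: `(last ICI − penultimate ICI)/penultimate
   ICI` — scale-invariant, so rubato cancels — compared between ornamented
   and plain codas of shared click counts by a two-sample KS test;
3. *position*: Fisher tests of ornamented status against sequence-initial
   and sequence-final position (singleton sequences excluded — a coda that
   is both first and last carries no positional information);
4. *chorusing changes*: Fisher test of whether a leader's ornamented codas
   are disproportionately followed by the follower beginning to chorus,
   pausing (next follower coda more than 8 s after the leader coda's
   termination, vocalising resuming later), or ceasing for the rest of
   the recording. A leader coda enters this test when the follower was
   active within 8 s around it; anchoring on exchange context rather than
   strict link membership matters, because the very coda that triggers a
   pause is unanswered and would otherwise drop out of its chorus.

**Ornaments and the drift pools.** The rubato analyses exclude detected
ornamented codas from both the adjacent pairs and the permutation pools.
The appended click inflates a coda's duration by a full ICI — an
ornamentation effect, not tempo modulation — and, because the inflated
duration lands in a different tempo class, such codas would contaminate
other types' null pools and bias the drift tests anticonservative (we
measured ~10% rejection at nominal 5% without the exclusion, 5.0% with
it).

## Discretisation choices

The tempo KDE uses a Gaussian kernel on a 2048-point grid spanning
`[0, max duration + 3 bandwidths]`. Silverman's rule is the default
bandwidth but deliberately over-smooths multimodal duration data, so the
analysis scripts use 0.05 s — the within-mode duration sd scale — and
report a multiplicative bandwidth sweep so the robustness of any mode
count can be read off directly. Local maxima below 5% of the global
density peak are not counted as modes (a handful of long ornamented codas
would otherwise register as spurious bumps). Boundaries are the deepest
valleys between consecutive modes; a duration exactly on a boundary takes
the lower class, and durations outside the outer modes map to the nearest
terminal class.

Rhythm centroids are fitted by k-means per click-count group (vectors of
different lengths cannot share a centroid) under a fixed seed, on
standardised absolute ICIs by default — the same space as the ornament
centroid statistic — with standardised cumulative ICIs as an option.
Assignment minimises mean squared distance among centroids of the coda's
click count; codas whose click count has no centroid are flagged
unassignable rather than forced. The package ships an 18-centroid
*synthetic* reference inventory (`synthetic_reference_centroids()`,
mirrored at `inst/extdata/rhythm_centroids_synthetic_reference.csv`) with
the reference cardinality and click-count coverage, built from three
canonical shape families; it is a stand-in with the correct structure, not
a fit to field data, and externally supplied centroid tables drop in via
`read_rhythm_model()`.

## The synthetic exchange generator

Every analysis stage is validated by parameter recovery on generated
exchanges, so the generator is first-class, tested code. Its defaults are
the study conditions: five duration modes between 0.35 s and 1.8 s with
0.05 s within-mode sd; a ~4 s response period with 0.4 s jitter;
call sequences of mean length 9 separated by 15–30 s; a 4% ornament rate,
tripled at sequence boundaries, with the ornament ICI 1.5× the final
template ICI; follower duration imitation with 0.01 s noise and 45%
overlap probability; and ornamented leader codas raising the follower's
pause probability from 0.1 to 0.5.

Rubato is simulated as a bounded walk on duration whose *velocity* is an
AR(1) process (momentum 0.7, step scale 0.02 s, reflected at ±2.5 sd of
the tempo class). A plain random walk would have independent increments
and thus zero lag-1 drift correlation; the AR(1) velocity is the simplest
process that produces the smooth, sustained drift the triple-correlation
statistic is designed to detect. When rubato is disabled, durations are
drawn i.i.d. within the tempo class — which is also the null world used
for calibration, together with disabled imitation and uniform ornament
placement.

What the generator does *not* emulate: more than two whales per chorus,
within-sequence rhythm switching, behavioural-state structure (dives,
socialising bouts), click-level amplitude or spectral properties, and
annotation error in the ICIs. Passing recovery tests therefore shows the
pipeline is correct and calibrated under these idealised conditions; it
does not certify performance on field data with annotation noise or richer
social structure.

## Problem sizes and calibration

The recovery harness analyses a two-hour two-whale exchange (~1900 codas,
~1000 in-context leader codas), the scale at which the Fisher contingency
tests have adequate power at the configured effect sizes; the permutation
tests there use 999–4999 resamples. Type-I calibration runs the two
duration permutation tests on 200 independent 10-minute null worlds at 199
resamples each (p resolution 0.005, ample at the 5% level); both tests
reject at 3–7% and the positional odds ratios centre on 1. These sizes are
the package's validation conditions; the analysis scripts under
`analysis/` run the same pipeline on a single 30-minute exchange with the
full 10,000 resamples.

## Capacity summaries

A repertoire of *n* distinguishable types carries at most `log2(n)` bits
per coda (`capacity_bits()` also reports the whole-bit ceiling: 21 types →
4.39, at most 5 bits). Treating the features as freely combinable — 18
rhythms × 5 tempos × optional ornament × 3 rubato classes = 540
combinations — gives `log2(540) ≈ 9.08` bits (`feature_capacity()`), about
twice the type-repertoire figure. These are upper bounds on a per-coda
information rate under independence and uniform use, not estimates of
realised entropy; `count_realized()` and its threshold sweep quantify how
much of the combinatorial space is actually attested at a given occurrence
threshold.

## Known limitations

* The field dataset the printed statistics come from is deposited
  externally and not bundled; `load_deposited_codas()` takes a converted
  table, and `as_coda_set()` adapts arbitrary wide layouts onto the
  canonical schema (`coda_id, recording_id, whale_id, onset_time_s,
  ici_1..ici_9`).
* The chorus-change operationalisation ("pauses chorusing") is a free
  design parameter; the 8 s constant is reused deliberately so the test
  has no tunable knob of its own.
* Ornament detection only models final-click additions, and its
  comparison-window convention (span-to-span) is one of several defensible
  readings; both scope variants (same-whale, any-whale) are implemented.
* Rubato classification reduces a contour to its net duration change
  against a 0.05 s threshold (the adjacent-drift scale); it does not model
  contour shape.
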