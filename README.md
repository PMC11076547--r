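# codacomb

Feature analysis of sperm whale codas: rhythm, tempo, rubato and
ornamentation.

Sperm whales vocalise in *codas* — stereotyped bursts of 3–40 broadband
clicks, generally under two seconds — exchanged in multi-whale choruses.
Historically codas have been described as a fixed inventory of discrete
types defined by their inter-click-interval (ICI) vectors. `codacomb`
implements the analysis pipeline behind a finer, combinatorial picture:
every coda is decomposed into

* **rhythm** — the standardised (unit-sum) ICI vector, discretised by
  nearest-centroid assignment per click count;
* **tempo** — total duration, discretised into the modes of a kernel
  density estimate (class = the interval between KDE valleys);
* **rubato** — smooth, sustained drift of duration across one whale's
  consecutive codas, measured as the tempo drift
  `d = duration(c2) − duration(c1)`;
* **ornamentation** — an extra final click appended to a coda whose other
  clicks match the nearest preceding or following coda within 10 s.

The bespoke statistics establish that the two contextual features are
controlled and perceived, not noise: adjacent same-type codas drift less
than random same-type pairs (one-sided permutation test over 10,000
resamplings, null built by permuting durations within (whale, type)
groups); drift correlates across coda triples (Spearman; note the
i.i.d. reference value is −1/2, not 0, because consecutive drifts share
the middle duration); overlapping codas from different whales match
durations more closely than random same-type cross-whale pairs; and
ornaments — codas that sit closer to their neighbours' rhythm centroid
once the extra click is dropped — concentrate at call-sequence boundaries
and predict changes in the interlocutor's chorusing (Fisher's exact
tests). A rhythm × tempo matrix annotated with rubato and ornament
prevalence (the "phonetic alphabet") summarises the combinatorial
repertoire; with 18 rhythms, 5 tempos, optional ornamentation and 3
rubato classes the system could carry up to `log2(540) ≈ 9.08` bits per
coda, about twice the `log2(21) ≈ 4.39` bits of a 21-type inventory.

Because the annotated field tables are deposited externally (see
`?load_deposited_codas` for how to supply them), every stage is validated
against a synthetic multi-whale exchange generator with a full
ground-truth channel: rhythm templates, clustered duration modes, an
AR(1)-velocity rubato walk, ~4 s response periodicity, duration imitation
by the chorusing follower, and boundary-enriched ornaments that raise the
follower's pause probability.

## Worked example

```r
library(codacomb)

sim   <- generate_exchange(generator_config(duration_s = 1800, seed = 7))
codas <- filter_clicks(sim$codas, max_clicks = 10)

tempo  <- fit_tempo_model(coda_duration(codas), bandwidth = 0.05)
rhythm <- fit_rhythm_model(codas, c("4" = 1, "5" = 2, "6" = 1, "8" = 1))
types  <- assign_types(codas, tempo, rhythm)
orn    <- detect_ornaments(codas)

tempo
#> <tempo_model> 5 mode(s) at 0.40, 0.73, 1.01, 1.37, 1.81 s (bw = 0.05 s, n = 454)

adjacent_drift_test(codas, types, n_resamples = 10000, seed = 71,
                    ornaments = orn)
#> <adjacent_drift> statistic = 0.01694, null = 0.06215, p = 9.999e-05 (less),
#>   n = 326, resamples = 10000

triple_correlation(codas, types, ornaments = orn)
#> <triple_drift_correlation> statistic = 0.4808, p = 1.407e-15 (two.sided), n = 245

chorus_matching_test(codas, types, n_resamples = 10000, seed = 72,
                     ornaments = orn)
#> <chorus_duration_matching> statistic = 0.01013, null = 0.05911,
#>   p = 9.999e-05 (less), n = 88, resamples = 10000
```

Read: the five simulated duration modes are recovered at their configured
locations; adjacent same-type codas drift by 17 ms on average where random
same-type pairs would drift by 62 ms (p at the permutation floor), the
drift persists across triples (r = 0.48 against an i.i.d. reference of
−0.5), and overlapping codas from the two whales match durations to 10 ms
against a 59 ms same-type null — the generator's rubato and imitation,
recovered end to end.

The numbered scripts under `analysis/` run the same pipeline as a
narrative workflow (simulate → segment → type → rubato → ornamentation →
alphabet → calibration) and write their tables under `results/`.

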