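---
title: "Models and methods behind silacswap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind silacswap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the tunable parameters, and
the design and numerical choices behind `silacswap`, in the spirit of the
methods sections of mature omics packages. It states no empirical result
that the package's tests do not themselves compute.

## 1. The measurement model

A triplex SILAC experiment with two reciprocal label swaps yields, per
quantified protein group, six log2 ratios: four *treated* ratios comparing
exposed to sham cultures (two per labeling experiment) and two *control*
ratios comparing equally treated channels. All treated ratios are stored
oriented as log2(exposed/sham) regardless of which channel carried the
exposed culture; the file reader applies the reciprocal flip declared in
its column map, so downstream code sees one sign convention.

The generative model the package assumes (and that `simulate_exposure()`
implements) is, per protein *i*:

```
treated_r1_HL = D + b_HL + e        treated_r2_LH = D − b_HL + e
treated_r1_HM = D + b_HM + e        treated_r2_MH = D − b_HM + e
control_r1 = control_r2 = kappa (b_HM − b_HL) + e
```

where

* `D` is the true log2 regulation effect, 0 for unregulated proteins;
* `b_HL ~ N(0, s_HL^2)`, `b_HM ~ N(0, s_HM^2)` are *per-protein*
  label-incorporation biases of the two labeling pairs, with
  `s_HL > s_HM` (the heavy–light pair is the noisier one);
* `e ~ N(0, sigma(I)^2)` is measurement noise shrinking with log10
  intensity: `sigma(I) = sigma0 * exp(-slope * (logI − median logI))`.

Three structural facts drive everything downstream:

1. the treatment effect is swap-invariant while the label bias flips
   sign, so the mean of the four treated ratios estimates `D` free of
   label bias;
2. with oriented ratios on both axes, the correlation between a pair's
   replicate-1 and replicate-2 treated ratios is positive when treatment
   dominates and negative when labeling dominates
   (`cor(D + b + e, D − b + e)` has the sign of `var(D) − var(b)`);
3. the control ratios co-move with the label biases (coupling `kappa`),
   so "treated ratios dominate control ratios" is evidence that a
   consistent shift is treatment, not labeling.

Label bias is modeled as a zero-mean *per-protein random effect*, not a
global shift: a global shift is removed by median normalization, whereas
the reciprocal-correlation signature and the composite filter's
discrimination both require protein-specific bias. `kappa = 1` (controls
share the label effects) is the default because it gives the composite
filter genuine discriminating power; `kappa = 0` provides a harder null
in which controls are pure noise.

## 2. Generator parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `n_proteins` | 3000 | count | scale of one quantified cell-line × exposure dataset |
| `frac_regulated` | 0.01 | proportion | "less than 1% of the quantitated proteome" regime |
| `effect_log2fc_range` | log2(1.2)–log2(2.8) | log2 | modest fold changes spanning the 1.2 threshold up to the largest MS-reported change (~2.8-fold) |
| `noise_sd_base` | 0.1 | log2 | typical SILAC ratio repeatability |
| `noise_intensity_slope` | 0.3 | per log10 unit | mild precision gain with intensity; keeps marginal SDs within 5% of sqrt(s^2 + sigma0^2) |
| `s_HL`, `s_HM` | 0.3, 0.15 | log2 | not quantified in the source study; chosen once to reproduce its qualitative ordering (strong negative H–L correlation, weaker H–M) |
| `kappa` | 1 | – | see above |
| `missing_rate` | 0.08 | per slot | complete-case fraction (1−m)^6 ≈ 0.61, inside the published 54–79% completeness range |
| `n_decoys`, `n_contaminants` | 2%, 2.5% of n | count | published decoy/contaminant scale |
| intensity | log10-normal(9, 0.8) | arbitrary | MaxQuant-like summed peak intensities (1e7–1e11) |

Decoys and contaminants receive ratios from the *null* model, so the
quality filters — not the statistics — must remove them. Effects get
random signs; `|D|` is uniform on its range. Under a fixed `seed` the
generator is byte-identical (one R RNG stream, restored on exit).

What the generator does **not** emulate: peptide-level evidence and
roll-up, ratio compression, correlated missingness (censoring at low
intensity), isoform grouping, retention-time structure, and any
between-cell-line biology. A green test therefore certifies the
statistical machinery under the stated model, not performance on any
particular real dataset.

## 3. Filters and signal-to-noise

* `filter_quality()` removes decoys, contaminants, and groups with fewer
  than 2 razor/unique peptides (configurable), reporting counts per
  reason.
* `normalize_ratios()` median-centers each of the six log2 ratio columns
  (loading correction); idempotent; columns with <3 values are skipped
  with a warning. Whether an upstream pipeline already normalized is
  irrelevant to idempotence.
* `consistency_filter()`: all four treated ratios share one *strict*
  sign. Exact zeros fail both signs — they are measure-zero under noise
  and deterministic fixtures document the convention.
* `composite_filter()`: complete six-ratio records that pass consistency
  **and** whose treated magnitudes dominate the controls. The published
  description ("greater treated than control") does not fix the
  dominance rule, so both are implemented:
  `min |treated| > max |control|` (default, strict) and
  `mean |treated| > mean |control|` (permissive). The strict rule is the
  default because it is the only reading under which every treated ratio
  individually out-weighs every control ratio, which is what "consistent
  change larger than technical variation" means protein by protein.
* `signal_to_noise()` pools all treated slots across proteins into one
  vector and all control slots into another and reports
  `MAD_treated / MAD_control`. Pooling (rather than per-protein MADs) is
  the only reading that yields one MAD per dataset per ratio class, as
  the source figures report. The 1.4826 consistency constant cancels in
  the ratio.

The expected cascade `snr(composite) > snr(consistent) > snr(unfiltered)`
is a *selection* effect and is verified as a property over 100 generator
seeds, not asserted for any single dataset.

## 4. The six detectors

All statistical detectors report raw two-tailed p-values and
Benjamini–Hochberg adjusted values (step-up, hand-implemented, capped at
1, NA-preserving).

**FC** — `2^mean(four treated log2 ratios)`; magnitude
`max(fc, 1/fc)` is compared to the tier (1.2 or 1.5). Non-statistical.

**Z and M** — standardize the per-protein mean treated ratio by
mean/SD (Z) or median/MAD (M, scaled by 0.6745 = 1/1.4826); two-tailed
normal p. The per-protein summary requires *all four* treated slots
(configurable): the label bias only cancels in the mean over both swaps,
so a two-slot mean from a single replicate would leak bias into the
statistic.

**Significance B** — proteins sorted by intensity are cut into
consecutive bins of ≥ `min_bin` (default 300; last bin absorbs the
remainder, single bin if n < 2·min_bin); each bin's 15.87/50/84.13
percentiles calibrate an asymmetric z-score; tail p from the normal.
The reported `p_raw` is the doubled (two-sided) tail probability, with
the one-sided value kept in `p_tail` — the doubling convention matters
only when the two-tailed tier is applied. Degenerate bin percentiles
(`r1 = r0`) raise an informative error rather than silently producing
infinite scores.

**Rank product** — per treated column, descending ranks (average ties);
`RP = (prod rank/n)^(1/4)`. The null is built by independently permuting
each column's ranks `n_perm` times (seeded) and pooling permuted RP
values across proteins; `p_up` is the pooled fraction ≤ observed.
`exact = TRUE` replaces permutation by exhaustive enumeration of all
`n^k` rank tuples (the marginal null of independent column permutation),
used by the test oracle at small n. The two-sided value
`min(1, 2 min(p_up, p_down))` is a Bonferroni-style combination: because
`p_up` and `p_down` are only partially antithetic for k > 1 (they come
from different rank reversals), the combination is *conservative in the
bulk* and deliberately so; calibration statements (uniformity under the
null) therefore attach to the one-sided permutation p, which is exact.

**FCROS-style statistic** — ascending rank fractions `rank/(n+1)` per
column, averaged to `rbar`; a normal null centered at 0.5 with SD
estimated from the central 80% interquantile range of the observed
`rbar` (mean fixed at 0.5; `sigma = (q90 − q10) / (2 qnorm(0.9))`).
This diverges from the reference implementation by fixing the null
center and fitting only the scale — a deliberate simplification that
keeps the statistic self-calibrating. n < 20 warns (unstable scale fit).

**Moderated TREAT** — per protein, the four treated slots share mean
`theta` and the two controls share `gamma` (residual df 4), so
`theta − gamma` is the design-encoded contrast: a pure label artifact
moves controls along with treated ratios and cancels, while a true
effect does not. Residual variances are shrunk toward a prior fitted by
moment matching on `log s^2` (digamma/trigamma relations; the trigamma
inverse solved by Newton iteration). A degenerate moment fit (no excess
variance heterogeneity, as in homoscedastic data) falls back to the
pooled variance, `d0 = Inf`, with a warning. The threshold null
`|theta − gamma| <= log2(tau)` (default tau 1.2, the lowest tier) uses
the two-one-sided construction
`p = P(T > (|c|−delta)/se) + P(T > (|c|+delta)/se)` with `d0 + 4` df;
`tau = 1` reduces exactly to the ordinary moderated t-test. Agreement
with an independent implementation of the same moderated-threshold test
is enforced in the test suite.

### Ensemble

`ensemble_union()` declares a protein a member if **any** detector calls
it at the configured tier: the FC detector needs the fold-change tier;
statistical detectors need the p tier (raw by default, BH-adjusted with
`use_adjusted = TRUE`), optionally also the FC tier. Direction comes per
method from the sign of its effect estimate; members whose supporting
methods disagree are flagged `conflicted`. Membership is monotone: no
tier relaxation can remove a member.

`run_detectors()` implements the standard policy of this design: the
outlier/rank detectors operate on the composite-filtered proteins while
the moderated threshold test, whose contrast already encodes the design,
operates on all complete six-ratio records; `filter_mode = "none"` runs
everything unfiltered for comparison. Both modes are first-class because
the published description does not fix the order per method.

## 5. Calibration and the recovery benchmark

Two choices in the test battery deserve explicit statement.

**The calibration null.** Detector p-value uniformity is asserted on the
generator with no regulation, no label bias, and homoscedastic noise.
Each relaxation breaks an assumption some detector does not make for
itself: intensity-dependent variance turns the marginal ratio
distribution into a scale mixture, so the global Z/M standardization is
miscalibrated *by construction* — repairing exactly that is why
significance B bins by intensity — and label bias correlates the
replicate columns, which the design stages (filters and the TREAT
contrast), not the detectors' nulls, are responsible for absorbing.
Calibration under the exchangeable null plus explicit design handling of
the structured components is the package's contract.

**The recovery benchmark.** Sensitivity/FDR of the ensemble at tier
(FC > 1.2, BH-adjusted p < 0.05) is measured with the battery in
`filter_mode = "none"` and with sensitivity taken over regulated
proteins that have *complete six-ratio records* — the analyzed universe,
matching the restriction of the differential analysis to fully
quantitated protein groups. Two honest caveats, quantified during
development and reproducible from the generator: (i) proteins lacking a
complete record are invisible to complete-case detectors (at the default
missing rate that is ~39% of proteins); (ii) in the default
composite-first mode, regulated proteins whose label bias rivals their
effect are excluded *by the filter* — the label-robustness/sensitivity
trade that motivates the design. The benchmark isolates detector power;
the filter's operating characteristics are tested separately (S/N
cascade, monotone power in |D|).

## 6. Model-based term-set analysis

The model: each term is active with prior probability p; an item's
hidden state is the OR of its active annotating terms; observation flips
hidden-off items into the study set with false-positive rate `alpha` and
drops hidden-on items with false-negative rate `beta`. `alpha`, `beta`
and `p` are marginalized over discrete grids with uniform grid priors —
defaults: 10 points each on [0.01, 0.3] for the error rates and
[1/n_terms, 0.3] for p. The grids are explicit and configurable rather
than inherited from any reference implementation.

`mgsa_enumerate()` sums the joint over all `2^n_terms` activation
vectors (guard: 15 terms); the grid sums factorize into alpha-, beta-
and p-parts computed in log space. It is the exact oracle against which
the sampler is validated.

`mgsa_mcmc()` is a Metropolis sampler over (state vector, grid indices):
proposals toggle a uniformly chosen term (prob 0.75) or resample one
grid parameter; per-item active-term counts make a toggle O(term size).
Posteriors are activation frequencies after a 20% burn-in (no thinning —
means of indicator draws do not benefit from it), averaged over
independent runs; the across-run SD is reported as the Monte Carlo error
estimate, and any term with run SD > 0.2 triggers a non-mixing warning.
Defaults (20 runs × 1e6 steps) follow the published protocol; tests use
smaller, validated settings.

A monotonicity worth recording: a term none of whose items reaches the
study set is penalized by the factor `(beta/(1−alpha))^size`, so its
posterior is *non-decreasing* in beta — a larger false-negative rate
makes total misses cheaper. The property suite asserts this direction
(and that such a term never overtakes a fully observed one).

## 7. Set comparisons and report rounding

Set algebra is exact over accession identifiers; splice isoforms count
as distinct accessions unless `collapse_isoforms = TRUE` strips the
`-N` suffix. The overlap score is the intersection relative to the
*largest* set (in percent); the Jaccard index is intersection over
union. Report output rounds half-up to 2 decimals (matching printed
tables; R's `round()` uses round-half-even, hence the explicit
`floor(x·100 + 0.5)/100`), with full precision retained internally.
Coverage means average the rounded per-dataset percentages, as printed
tables do.

## 8. Known limitations

* Complete-case detectors: no imputation is attempted; missingness is
  treated as ignorable, which real intensity-censored data violate.
* The per-protein label-bias effects `b_HL`, `b_HM` are drawn
  independently, so the simulated control-ratio spread
  (`s_HL^2 + s_HM^2` at `kappa = 1`) is an upper bound on what shared
  per-channel effects would produce; the S/N cascade ordering is robust
  to this, but absolute S/N levels are not comparable to any particular
  instrument.
* Quadrant numerals in `classify_quadrants()` are presentation-only (the
  published caption's numeral convention is internally ambiguous); the
  semantic classes (consistent-up/-down, inconsistent) are canonical and
  ties at exactly zero are classed inconsistent.
* The FCROS-style and rank-product implementations follow the stated
  algorithms, not the reference packages' internals; numerical equality
  with those packages is out of scope.
* GSA annotations are taken as given (pre-propagated); ontology DAG
  propagation and live database retrieval are out of scope. Pooled
  versus intersected universes for combined study sets are both
  supported (`items` argument) since the published protocol does not
  say which was used.
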