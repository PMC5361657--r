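---
title: "Comparing paired strains on phenotype microarrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing paired strains on phenotype microarrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmcompare)
```

`pmcompare` analyses two-channel kinetic Biolog FF assays comparing a
fungal strain that naturally hosts an endohyphal bacterium (EHB+) with its
cured clone (EHB−). This vignette is the package's account of the models
and statistics it implements, the tunable parameters and their defaults,
the design decisions taken where several choices were defensible, and what
the synthetic-data tests do and do not demonstrate about real data.

## The measurement model

Each 96-well FF plate carries 95 carbon sources and a water control. Two
absorbance channels are read every 12 h for 7 days:

* **A750** (turbidity): hyphal density, the package's definition of
  *growth*. It is the channel used for all inference, because turbidity is
  comparable across indicator-dye chemistries and hyphal morphologies.
* **A490**: formazan produced by irreversible reduction of
  iodonitrotetrazolium violet during respiration. Hyaline mycelium absorbs
  evenly from 490 to 750 nm, so the corrected redox signal is
  `Ac490 = A490 − A750` (`corrected_absorbance()`). Negative corrected
  values are blank-level noise and are *preserved*, not clamped — they are
  only clamped to zero (with a logged count) where a downstream method
  requires nonnegativity, namely Bray–Curtis input.

The two channels are strongly rank-correlated; `channel_correlation()`
reports Kendall's tau-b across strain × substrate means. Because tau is a
rank statistic, the log transform sometimes applied before plotting the
two channels cannot change it — the package exposes `log = TRUE` for
parity but treats the transform as cosmetic, and the test suite asserts
the invariance on random positive data.

## Measurable growth and the five outcomes

Measurable growth on a substrate is defined on the day-7 replicate-mean
turbidity: `0.3 < Ā750 ≤ 3.0` (`growth_thresholds()`, `is_measurable()`).
The lower bound separates lag-phase noise from log-phase growth and is
strict; the upper bound (99.9 % light absorbance) is inclusive.
Measurability is assessed on the replicate mean — not per plate — because
the endpoint comparison table is defined at the level of strain means.

Each substrate is classified (`classify_outcome()`) as:

1. negligible growth by both strains (both means ≤ 0.3);
2. measurable growth by both, no significant difference;
3. measurable growth by EHB+ only;
4. measurable growth by both, EHB− denser;
5. measurable growth by both, EHB+ denser.

Two edge cases are handled explicitly. The mirror of outcome 3 (EHB−
measurable, EHB+ negligible) is not one of the five named outcomes; it is
returned as code 4 with a `mirror` attribute so it can never be silently
conflated. A significant difference with *exactly* equal means has no
direction and raises an error rather than applying a tie-break: it cannot
arise from real data at instrument precision, so silence would only ever
mask a bug. An endpoint mean above 3.0 is outside the measurable range and
is likewise an error rather than a guess.

## Per-substrate inference

`welch_test()` implements the unequal-variance *t*-test from summary
statistics (mean, SD, n per strain), with Welch–Satterthwaite degrees of
freedom and a two-sided p-value. Two-sidedness is the package's choice
where the direction of the effect is not known in advance — it is also
what permits detecting substrates on which the *cured* strain grows
denser. The df satisfy `df ≤ n₁ + n₂ − 2`, with equality exactly when the
two standard errors coincide; the test suite asserts this bound as a
property.

`bh_adjust()` applies Benjamini–Hochberg step-up FDR control via
`stats::p.adjust`. The testing family is exactly the set of substrates on
which at least one strain shows measurable growth; substrates negligible
for both strains are *not tested* and keep an absent (`NA`) adjusted p.
Modelling "not tested" as absent rather than as 1.0 lets the census
distinguish "no significant difference" from "never entered the family",
and `NA` entries are excluded before adjustment so they cannot inflate the
family size. Significance is `p_adj < α` with α = 0.05 by default; no
observable decision in the packaged reference table depends on strict
versus non-strict comparison (no adjusted p equals 0.05 exactly), so the
strict form was chosen and documented.

### Census rules

`census()` recomputes all panel-level counts from rule primitives — means,
thresholds, adjusted p, direction — and never from stored outcome labels.
This makes the census reproducible from a printed endpoint table alone,
and robust to label typos in such tables (the packaged table contains one
row whose printed label contradicts the stated threshold rules; the
rule-based census sides with the rules). Two conventions matter:

* "EHB+ denser" includes the significant substrates on which only EHB+
  grew measurably; under that convention the count decomposition
  `n_significant = n_plus_higher + n_minus_higher` holds.
* Percentages are of the 95-substrate panel, rounded to whole percent.

On the packaged table the rule-based buckets partition the panel:
64 significant + 15 no-difference + 16 negligible-both = 95.

### Printed-precision consistency

A t statistic recomputed from rounded means and SDs need not match a
printed t. `welch_interval()` computes the exact attainable interval of
(t, df) when every mean and SD may sit anywhere within ± half a printed
unit, exploiting monotonicity: t grows with the mean gap and shrinks with
either SD, while df depends only on the variance ratio
`u = (s₁/s₂)²` through `(n−1)(1+u)²/(1+u²)`, peaking at `2(n−1)` when the
standard errors are equal and tending to `n−1` as the ratio degenerates.
`table1_consistency()` applies this row-wise; every row of the packaged
table passes, including rows where naive point recomputation is off by
more than 10 %.

## Distance-based global comparisons

At each time point the per-plate turbidity profiles across all 95
substrates (control excluded by default — dissimilarity considers growth
across the substrates, not the blank) are compared with Bray–Curtis
dissimilarity and three permutation tests, all implemented from first
principles in this package (an independent ecology library is used only to
cross-check them in the tests):

* **PERMANOVA**: `SS_total = Σ_{i<j} d²_{ij}/N`, within-group sums scaled
  by group size, `F = (SS_B/(a−1))/(SS_W/(N−a))`, `R² = SS_B/SS_total`.
  A perfectly separated design has `SS_W = 0` and reports `F = ∞`.
* **ANOSIM**: mid-ranks of all N(N−1)/2 distances;
  `R = (r̄_between − r̄_within)/(M/2) ∈ [−1, 1]`, with R = 1 exactly when
  every between-group distance exceeds every within-group distance.
* **MRPP**: observed weighted mean within-group distance
  `δ = Σ_g w_g δ_g` with the community-ecology default weights
  `w_g = n_g/N` (weights `n_g − 1` and `n_g(n_g−1)/2` are exposed as
  options), expected δ taken as the mean over permuted labelings, and
  `A = 1 − δ_obs/δ_exp`.

### Permutation conventions

Monte-Carlo p-values use `(1 + #extreme)/(1 + n_perm)`: the observed
labeling counts as one permutation, so p is never 0 and never below
`1/(n_perm + 1)`. With `exact_enumeration = TRUE` the tests enumerate all
distinct labelings (multiset permutations of the group vector, the
observed labeling included) and report the exact tail fraction.

One consequence of enumeration deserves a note. Relabeling the groups —
swapping which group is called which — produces the *same partition* of
samples and therefore the same statistic. With two balanced groups of two,
the 1-D instance {0, 1} vs {3, 4} gives SS_total = 10, F = 18, R² = 0.9,
and the maximal F appears **twice** among the six labelings (the observed
one and its label swap), so the smallest attainable exact p is 2/6 = 1/3,
not 1/6. The test suite pins this value against a brute-force enumeration
written independently of the package's recursive enumerator.

Statistic ties are compared with a small absolute tolerance (1e−12) so
that exact duplicates produced by the label-swap symmetry are always
counted as extreme regardless of floating-point noise.

`global_scan()` runs all three tests at every time point under shared
settings; when a seed is supplied, each time point uses a deterministic
offset so the scan is reproducible end to end. `upgma_dendrogram()` writes
average-linkage (UPGMA) trees as Newick — linkage is not dictated by the
method, so the conventional choice for Bray–Curtis community profiles is
the default, with single and complete linkage exposed; ties break
deterministically by input order, and leaf heights are half the merge
distance (ultrametric).

## The synthetic-data generator

`simulation_config()` + `generate_dataset()` emulate the study design: two
strains × 5 replicate plates × 96 wells × 14 half-day time points × two
wavelengths. Per substrate, turbidity follows a logistic curve
`b + K/(1 + e^{−r(t − t_mid)})` with baseline `b = 0.1`, rate
`r ∈ [1.5, 3] d⁻¹` and midpoint `t_mid ∈ [2, 3.5] d`, so planted strain
effects (capacity gaps) express in log/stationary phase, as observed for
the real strain pair. Noise is Gaussian (SD 0.03 per reading) truncated at
zero, because plate readers report nonnegative optical density. The
490 nm channel is turbidity plus `redox_gain` times noiseless cumulative
growth plus its own noise; the noiseless corrected channel is therefore
nondecreasing, emulating irreversible formazan accumulation. No dye
kinetics are claimed beyond that monotone coupling.

Planted outcomes default to the composition of the packaged endpoint
table's rule-based census — 17 negligible, 15 equal, 2 plus-only, 5
minus-higher, 56 plus-higher — with an effect size (capacity gap) of 0.3,
the typical significant day-7 endpoint gap in that table. Outcome-1
(negligible) archetypes draw each strain's weak capacity *independently*
(≤ 0.15, keeping endpoints safely below the 0.3 bound), mirroring the
small but real differences seen between strains on no-growth substrates.

That last point matters for null simulations: a dataset made of outcome-1
and outcome-2 substrates is **not** a null, because independent weak
capacities are genuine (if tiny) strain effects, and a global scan
correctly detects them. The null condition used for type-I checks plants
identical parameters for both strains on every substrate
(`proportions = c("2" = 95)`), which makes the replicate plates
exchangeable; under it the pooled per-time-point PERMANOVA rejection rate
sits at the nominal level (about 0.03–0.05 in the packaged checks, against
a 0.1 ceiling). Note that a 14-time-point scan performs 14 correlated-but-
not-identical tests per run, so "at least one p < 0.05 somewhere on the
scan" occurs in roughly half of null runs — the scan is a description of a
trajectory, not a single corrected test, and the per-test rate is the
meaningful error measure.

What passing synthetic tests shows — and what it does not: the generator
has no spatial plate effects, no edge evaporation, no between-plate batch
effects, no heteroscedasticity (real plates show larger SDs on
high-variance substrates such as adenosine), and logistic curves cannot
express diauxie or decline phases. Recovery and type-I results therefore
validate the *pipeline's logic*, not instrument behaviour.

## Numerical and interface choices

* The endpoint table fixture stores printed precision only (two
  decimals); `load_table1()` checks an md5 checksum and keeps printed
  `<x` p-value bounds verbatim alongside their numeric parse.
* Well-to-substrate assignment is in endpoint-table order A1→H12 with
  water last; only substrate identity, never physical position, enters
  any computation, so this is a convention and flagged as such.
* CSV/TSV writers emit decimal representations that round-trip exactly.
* Time points are matched with a 1e−9 tolerance; requesting an off-grid
  time is an error, never a nearest-neighbour guess.
* All randomness is seeded and scoped: the archetype draw, the noise
  stream and the permutation streams use distinct deterministic offsets
  of the user seed, and RNG state is restored after every seeded
  operation, so library calls never perturb a caller's stream.
* The checks shipped with the package run at the study's own scale
  (10 plates × 95 substrates), with 199–999 permutations for Monte-Carlo
  tests and 10–20 seeds for replicated properties — sizes chosen so the
  whole suite completes in well under a minute while keeping Monte-Carlo
  granularity (1/200) far below the decision thresholds involved.

## Known limitations

* No parametric growth-curve *fitting* on observed data: curves are only
  generated. Changepoint detection (lag/log/stationary boundaries) is out
  of scope; the 0.3 bound itself is the lag/log discriminator.
* No ordination (PCoA/NMDS) and no dispersion test (PERMDISP); the global
  toolkit is deliberately the trio actually used for this design.
* The printed values of the published per-time-point comparison table
  cannot be recomputed from printed data (they require the authors' raw
  plate reads), so the package validates its permutation machinery by
  exact-enumeration oracles, saturation and null properties, and
  trajectory shape instead.
* Vendor plate-reader exports (e.g. Gen5) are not parsed; the interchange
  format is the documented long CSV.
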