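---
title: "Rank-based chunk detection in response-time sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based chunk detection in response-time sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chunkrank)
```

## The problem and the model

When people learn a sequence of responses, they spontaneously group
consecutive items into *chunks* retrieved from memory as units. Chunking
leaves a reliable footprint in reaction times (RTs): the first item of a
chunk (its *head*) is slow, because the whole chunk is retrieved before
execution, while the following items (the *body*) are fast. RT series are
however noisy, and chunk boundaries drift across practice, so detecting
chunks from raw RTs is unreliable.

`chunkrank` implements a non-parametric detector that works at the level
of a *block*: `k` repetitions of the same `N`-item sequence. Within each
repetition the RTs are replaced by ranks, 1 for the fastest item up to
`N` for the slowest, which removes the overall RT scale and tames
outliers (one aberrant RT can distort one repetition's ranks by at most
`N - 1`). Missing responses are imputed first with the item's mean RT
over the other repetitions of the same block. Ranks are summed per item
over the `k` repetitions, giving `S[1..N]`, and consecutive sums are
differenced:

    d[i] = S[i+1] - S[i],   i = 1..N-1

A strongly negative `d[i]` means item `i` is consistently slower than
item `i + 1` across the whole block -- the head-to-body transition.

**Head criterion.** `d[i] <= theta`, where `theta` is the critical value,
at per-comparison rate `alpha` (default 0.05), of the *exact* null
distribution of `d`: under the null each item's rank is uniform on
`{1..N}` independently per repetition, so each rank sum is a `k`-fold
convolution of that uniform, and the difference of two such sums is the
self-convolution of the sum distribution, centered on zero. All
convolutions are done by direct summation on exact integer supports (no
FFT), so the pmf is reproducible to ~1e-12 and is validated in the test
suite against brute-force enumeration of all `N^(2k)` rank assignments
for every geometry with `N^(2k) <= 1e6`.

**Body extension.** From a head `h`, successive items `j = h+1, h+2, ...`
join the chunk while both hold: (1) `S[j] - S[h] <= theta` (the whole
body stays "fast relative to the head" by the same critical margin --
at `j = h + 1` this restates the head criterion, so every chunk has at
least two items); and (2) for `j >= h + 2`,
`|S[j] - S[j-1]| <= median(|d|)` over the block's `N - 1` differences,
ensuring all body items have comparable ranks. Chunks are resolved left
to right, never overlap, and never wrap past position `N`.

**Consistency index.** Per block, the Pearson statistic
`sum((S - E)^2 / E)` with `E = k (N + 1) / 2` measures how far the rank
sums depart from the uniform expectation. Consistent chunking
concentrates high ranks on heads and low ranks on bodies repetition
after repetition, inflating the statistic; the raw value (no p-value) is
used as a graded chunking-consistency score. It is comparable only
across blocks with equal `N` and `k`.

```{r example}
set.seed(42)
sim <- generate_block(N = 16, k = 5, condition = "few_short",
                      noise = noise_spec(slope = 0.1, intercept = 5))
fit <- detect_chunks(sim$block, alpha = 0.05)
fit
sim$truth
```

## Tunable parameters

* `alpha` (default 0.05): per-comparison type-I rate of the head
  criterion. Lower it for fewer, more certain chunks. The exact
  threshold construction guarantees the achieved null tail mass never
  exceeds `alpha` (the test suite confirms this on 1e5 simulated null
  blocks).
* `theta_mode`: `"exact"` (default) or `"rule_of_thumb"`, the printed
  closed form `-0.5 - 0.70647 sqrt(N) k`, kept for compatibility. See
  "The rule-of-thumb formula" below for why the exact mode is preferred.
* `k`, the repetitions per block, is the main reliability lever: with
  `k < 4` the discrete null is so coarse that detection is unreliable
  (and at tiny `N * k` no critical value with tail mass `<= alpha`
  exists at all -- the package then warns and disables detection rather
  than inflating the error rate).

## The convolution convention

The source description of the null is ambiguous about how many
convolutions produce the rank-sum distribution: its prose says the
uniform pmf is convolved `k` times (one term per repetition), but its
printed recursion starts from a convolution of *two* uniforms
(`F1 = U * U`, `Fk = Fk-1 * U`), which makes the "k-fold" sum a sum of
`k + 1` uniforms and the null correspondingly wider. The package
exposes both as `convention = "k"` / `"k_plus_1"`.

Two defaults coexist deliberately:

* `sum_rank_pmf()`, `diff_distribution()`, `exact_threshold()` default
  to `"k"`, their mathematically stated contract (the distribution of a
  difference of two `k`-fold sums).
* `detect_chunks()` and the Monte Carlo harness default to
  `"k_plus_1"` -- the printed recursion. Empirically this wider null
  (`theta = -27` instead of `-25` at `N = 16`, `k = 5`) is the
  convention that reproduces the published recovery behaviour of the
  detector on simulated data: under `"k"` the few/short condition at
  experimentally realistic noise shows a systematic +0.3 excess in
  detected chunk count (false heads among the 12 exchangeable non-chunk
  items), while under `"k_plus_1"` the count is unbiased to within
  0.2. The refit of the rule-of-thumb formula, which was meant to
  disambiguate the conventions, turned out not to discriminate between
  them (see below).

Note a genuine approximation shared by both conventions: real ranks
within a repetition form a permutation, so adjacent rank sums are
negatively correlated, and non-chunk items' ranks are squeezed into a
sub-range by the chunk items. The independence null is therefore not an
exact description of any observed block; `alpha` is a nominal
per-comparison rate, not an exact one.

## The rule-of-thumb formula

Refitting `theta ~ a + b sqrt(N) k` by OLS over the stated grid
(`k` 2-20, `N` 2-64, `alpha = 0.05`) does **not** recover the printed
constants (-0.5, -0.70647) under either convention: both give
`b ~ -1.05` with residual sd ~23 ranks. The exact critical values are
almost perfectly linear in `N sqrt(k)` instead (R^2 = 0.99995,
`b = -0.672 ~ qnorm(0.05)/sqrt(6)`, the normal-approximation scaling of
a difference of two rank sums), which strongly suggests the printed
formula misplaces the square root; but even that fit does not land on
the printed coefficients. The refit is kept in
[fit_rule_of_thumb()] with per-cell residuals (both predictors
available) so the discrepancy is inspectable; the corresponding
acceptance test is expected to fail and documents the mismatch. The
closed form is therefore offered only as the compatibility mode
`theta_mode = "rule_of_thumb"`; note it is *less* conservative than the
exact threshold at the published geometry (-14.63 vs -25).

## The synthetic-data generator

`generate_block()` emulates the published simulation: baseline RTs of
810 ms for heads, 495 ms for bodies and 760 ms for non-chunk items
(values estimated from empirical data), with independent Gaussian noise
per cell whose standard deviation is `rt0 * slope + intercept`,
mirroring the strong SD-mean correlation of real RT blocks. Chunk
placements are drawn uniformly over all legal placements (non-
overlapping, no overhang past position `N`) via a stars-and-bars
bijection, and are shared by all `k` repetitions of a block. Observed
parameter ranges in real data are slope -0.1 to 0.8 and intercept -12
to 12 ms; `run_noise_grid()` spans them by default with 9 x 24 bins.
(The source text attaches the bin counts to the parameters
inconsistently with its own matrix shape; the matrix shape -- 9 slope
bins, 24 intercept bins -- is followed here.) "In-range" noise, used by
the acceptance experiments, is slope 0.1, intercept 5 (non-chunk cell
SD 81 ms); "moderate" noise for the k-sweep is slope 0.35, intercept 0,
the midpoints of the printed ranges, since the empirical mean noise of
the reference dataset is not published.

What the generator does *not* emulate: learning dynamics (RT decline,
chunk drift across blocks), within-block correlation of noise,
non-Gaussian RT tails, and the negative rank correlations of real
permutation ranks. A green recovery test therefore establishes that the
detector recovers *this* stated world, not that it is unbiased on any
empirical dataset. At extreme noise the linear SD model can produce
non-positive RTs; they are kept (ranking uses order only) with a
warning, and grid cells whose implied SD is negative are marked
infeasible rather than simulated.

## Numerical and design choices

* **Ties.** Tied RTs are ranked by order of appearance, the earlier item
  receiving the higher rank. Ties are irrelevant for real millisecond
  RTs but dominate degenerate noiseless input (see below).
* **Head criterion boundary.** Heads are flagged at `d <= theta`
  (non-strict); since `theta` is the largest value with tail mass
  `<= alpha`, including the boundary preserves the type-I guarantee.
* **Which pair member is the head.** The slower, first item of a flagged
  pair: a negative `d` means the first item is slower, and heads carry
  the retrieval cost.
* **Body condition 2 is non-strict** (`<=` the median absolute
  difference). With strict `<`, any noiseless long chunk is truncated to
  two items, because tied body ranks make every within-body difference
  exactly equal to the block median; equality is read as "comparable
  ranks". With continuous noise the choice is almost immaterial.
* **Body extension is contiguous**: it stops at the first failing item;
  skipping over a failing item is not allowed. A position absorbed into
  a body is removed from the head list; adjacent candidate heads
  therefore resolve in favour of the left one.
* **No pre-head rise is required** (`d[h-1] > 0` is not checked): the
  head criterion is applied per pair, as stated in the source method.
* **Error rate normalisation** (unstated in the source): per block,
  (false-positive + missed heads) / number of planted chunks, and
  / `(N - 1)` for the control condition. Chunk matching requires exact
  head equality; an off-by-one-tolerant rate is reported as a separate
  diagnostic column, not used in the headline error rate.
* **Confidence intervals** are 2.5/97.5 percentiles over Monte Carlo
  iterations (the source's CI construction is unstated). One master
  seed spawns per-cell child seeds, so grids are reproducible cell-wise.

## Known limitations

* **Noiseless degenerate input is not fully recovered.** With zero
  noise, the appearance-order tie rule creates systematic rank
  gradients: in the many/long condition the four tied heads receive
  ranks 16..13, so the first chunk's head-to-body difference is only
  `-4k = -20`, above the exact threshold (-25/-27), and that chunk is
  missed; in the many/short condition a low-ranked non-chunk item
  following a chunk can satisfy both body conditions and over-extend
  it. Few-chunk conditions and the constant block are recovered
  exactly. Any positive noise removes the ties and with it the
  artefact. The corresponding acceptance test asserts exact recovery
  for all four conditions and is left failing, with this analysis.
* **Chunk-length recovery biases low for long chunks.** At in-range
  noise the mean detected length in the few/long condition is ~3.67
  (planted 4): in ~25% of chunks one within-body difference exceeds the
  block median and truncates the body by one item. The corresponding
  published claim is CI-inclusion over 1000 iterations, which holds;
  the stricter mean-within-0.25 test is left failing for this
  condition.
* The chi-square index has no p-value and no cross-geometry
  normalisation; compare it only at fixed `N`, `k`.
* The detector treats each block independently: no chunk tracking
  across blocks, no within-repetition detection.

## Monte Carlo validation

The shipped experiments (also run by `scripts/acceptance.R` and the
acceptance test file) check, at `N = 16`, `k = 5`:

1. the empirical null head rate over 1e5 uniform-rank blocks is at most
   `alpha`;
2. mean detected chunk count at in-range noise is within 0.25 of the
   planted 2 / 4 for all four structured conditions;
3. mean detected chunk length is within 0.25 of the planted value
   (fails for few/long, see above);
4. the 95% percentile bands of the chi-square index for every
   structured condition separate from the control band;
5. the sequence-wise error rate decreases monotonically in
   `k = 2, 4, 5, 6, 8, 10` at moderate noise, with `k >= 4` markedly
   better than `k = 2` -- the basis for recommending at least four
   repetitions per block.
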