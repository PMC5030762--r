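# chunkrank

Non-parametric detection of **chunks** in reaction-time (RT) sequences
from sequence-learning experiments.

When people practise a fixed sequence of responses, they group
consecutive items into chunks retrieved from memory as units. The
retrieval cost makes the first item of a chunk (the *head*) slow and the
following items (the *body*) fast. `chunkrank` turns that RT signature
into explicit chunk positions, per block of `k` repetitions of an
`N`-item sequence, plus a graded per-block index of chunking
consistency. It is aimed at researchers analysing serial reaction time
tasks and explicit sequence-learning data.

## The method

Within one block:

1. each repetition's RTs are ranked (1 = fastest .. `N` = slowest;
   missing responses are first imputed with the item's mean over the
   other repetitions);
2. ranks are summed per item over the `k` repetitions: `S[1..N]`;
3. consecutive sums are differenced: `d[i] = S[i+1] - S[i]`;
4. item `i` is a **chunk head** when `d[i] <= theta`, the critical value
   at rate `alpha` of the exact null distribution of `d` -- obtained by
   convolving the uniform rank pmf into the rank-sum distribution and
   convolving that with itself (all by direct summation on integer
   supports, no approximation);
5. following items join the **chunk body** while they stay fast relative
   to the head (`S[j] - S[h] <= theta`) and mutually comparable
   (`|S[j] - S[j-1]|` at most the block's median absolute difference).

A Pearson statistic on the rank sums, `sum((S - E)^2 / E)` with
`E = k(N+1)/2`, serves as the block's chunking-consistency index.

The package also ships the published validation apparatus: a synthetic
RT generator with planted chunks (baselines 810/495/760 ms for
head/body/non-chunk items, cell noise SD = `rt0 * slope + intercept`)
and a Monte Carlo harness measuring chunk-count/length recovery, error
rates, chi-square separation from structureless controls, and the
effect of `k`.

## Worked example

```r
library(chunkrank)
set.seed(42)

sim <- generate_block(N = 16, k = 5, condition = "few_short",
                      noise = noise_spec(slope = 0.1, intercept = 5))
fit <- detect_chunks(sim$block, alpha = 0.05)
fit
#> Chunk detection: N = 16 items, k = 5 repetitions
#>   theta = -27 (exact, k_plus_1), alpha = 0.05
#>   2 chunk(s):
#>     head 1, length 2 (items 1-2)
#>     head 6, length 2 (items 6-7)
#>   chi^2 index: 82.824
sim$truth
#>   head length
#> 1    1      2
#> 2    6      2
```

Both planted chunks are found at their true positions: items 1 and 6
are heads (rank-sum drops of at least 27 to their successors under 5
repetitions of 16 items) and each owns a one-item body. The chi-square
index of 82.8 is far above the structureless-control band (roughly
18-66 at this geometry and noise), flagging a consistent chunking
pattern. `plot(fit)` draws the rank sums and the thresholded
differences.

Monte Carlo recovery for a whole condition:

```r
evaluate_cell("few_short", noise_spec(0.1, 5), iterations = 200, seed = 7)[,
  c("mean_n_chunks", "mean_chunk_len", "error_rate", "chi2_mean")]
#>   mean_n_chunks mean_chunk_len error_rate chi2_mean
#> 1         2.165          2.019      0.128    96.664
```

On 200 simulated blocks with 2 planted 2-item chunks at realistic
noise, the detector finds on average 2.17 chunks of mean length 2.02.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/chunkrank.R detect --input rts.csv --output chunks.json
Rscript inst/cli/chunkrank.R threshold --N 16 --k 5 --alpha 0.05
```

Input is long-format CSV/TSV (`subject, block, sequence, item, rt`;
blank `rt` = missing response); output is nested JSON or tidy CSV, with
1-based item positions throughout.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the empirical
false-positive rate of the head criterion under its own null
(100,000 simulated uniform-rank blocks at `N = 16`, `k = 5`), and the
mean detected chunk count (few/short and many/short conditions) and
mean detected chunk length (few/long condition) over 500 Monte Carlo
blocks each at in-range noise (slope 0.1, intercept 5 ms). Results are
written as JSON to `--out`.

## Further reading

The vignette (`vignettes/chunk-detection.Rmd`) documents the model and
its assumptions, the convolution-convention ambiguity and how it was
resolved, why the printed closed-form threshold is kept only as a
compatibility mode, what the simulator does and does not emulate, and
the detector's known limitations on degenerate noiseless input.
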