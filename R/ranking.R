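#' Rank the RTs of one sequence repetition
#'
#' Ascending ranks: 1 for the fastest item, `N` for the slowest. Ties are
#' broken by order of appearance, the *earlier* item receiving the
#' *higher* rank (in practice ties are vanishingly rare with millisecond
#' RTs; the rule mainly matters for degenerate, noiseless input).
#'
#' @param rts numeric vector of length `N >= 2`, no missing values
#'   (impute first, see [impute_missing()]).
#' @return integer vector: a permutation of `1:N`.
#' @examples
#' rank_sequence(c(100, 200, 300))  # 1 2 3
#' rank_sequence(c(500, 500, 400))  # 3 2 1 -- first of the tied pair ranks higher
#' @export
rank_sequence <- function(rts) {
  if (length(rts) < 2L) stop("a sequence needs at least 2 items")
  if (any(!is.finite(rts)))
    stop("missing or non-finite RTs: run impute_missing() before ranking")
  # ascending by RT; among ties, descending by position => earlier item higher rank
  o <- order(rts, -seq_along(rts))
  r <- integer(length(rts))
  r[o] <- seq_along(rts)
  r
}

#' Rank sums and pairwise differences of a block
#'
#' Applies [rank_sequence()] to every repetition, sums ranks per item over
#' the `k` repetitions, and differences consecutive items' rank sums.
#' A negative difference `d[i] = S[i+1] - S[i]` means item `i` is overall
#' *slower* than item `i + 1` -- the signature of a chunk head followed by
#' its body.
#'
#' @param block an [rt_block()] or numeric matrix with no missing values.
#' @return An object of class `rank_summary`:
#' \describe{
#'   \item{ranks}{`k x N` integer matrix, each row a permutation of `1:N`.}
#'   \item{summed_ranks}{length-`N` vector `S`; always sums to
#'     `k N (N + 1) / 2`.}
#'   \item{diffs}{length-`(N-1)` vector `d`, `d[i] = S[i+1] - S[i]`.}
#'   \item{median_abs_diff}{median of `|d|`, the block's yardstick for the
#'     body-extension rule of [detect_chunks()].}
#' }
#' @export
summarize_ranks <- function(block) {
  block <- as_rt_block(block)
  if (any(is.na(block)))
    stop("block has missing values: run impute_missing() first")
  k <- nrow(block)
  N <- ncol(block)
  ranks <- t(apply(unclass(block), 1L, rank_sequence))
  S <- colSums(ranks)
  d <- diff(S)
  structure(list(ranks = ranks,
                 summed_ranks = S,
                 diffs = d,
                 median_abs_diff = stats::median(abs(d)),
                 N = N, k = k),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat(sprintf("Rank summary: N = %d, k = %d\n", x$N, x$k))
  cat("  summed ranks S:", x$summed_ranks, "\n")
  cat("  differences  d:", x$diffs, "\n")
  cat("  median |d|:", x$median_abs_diff, "\n")
  invisible(x)
}
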