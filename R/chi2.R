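#' Chi-square index of chunking consistency
#'
#' Pearson goodness-of-fit statistic measuring how far a block's summed
#' ranks depart from the uniform expectation `E = k (N + 1) / 2` that
#' holds when no item is systematically slow or fast:
#' `sum_i (S_i - E)^2 / E`.
#'
#' The raw statistic -- not a p-value -- is the index: a consistent
#' chunking pattern concentrates high ranks on heads and low ranks on
#' bodies repetition after repetition, inflating the statistic, so larger
#' values mean more consistent chunking. The index is comparable only
#' across blocks of equal `N` and `k` (no degrees-of-freedom
#' normalisation is applied).
#'
#' @param x a `rank_summary` (see [summarize_ranks()]), an [rt_block()]
#'   (imputed and summarised on the fly), or a numeric vector of summed
#'   ranks (then `k` is required).
#' @param k number of repetitions; only used when `x` is a bare vector.
#' @return object of class `chi2_result`: list with `chi2_index`,
#'   `expected_sum` and `per_item_contributions` (length `N`;
#'   `chi2_index` is their sum and is 0 iff every rank sum equals the
#'   expectation).
#' @examples
#' chi2_index(c(3, 6, 3), k = 2)$chi2_index  # 1.5
#' @export
chi2_index <- function(x, k = NULL) {
  if (inherits(x, "rt_block") || is.matrix(x))
    x <- summarize_ranks(impute_missing(x))
  if (inherits(x, "rank_summary")) {
    S <- x$summed_ranks
    k <- x$k
  } else {
    S <- as.numeric(x)
    if (is.null(k)) stop("'k' is required when 'x' is a plain vector of rank sums")
  }
  N <- length(S)
  E <- k * (N + 1) / 2
  contrib <- (S - E)^2 / E
  structure(list(chi2_index = sum(contrib),
                 expected_sum = E,
                 per_item_contributions = contrib),
            class = "chi2_result")
}

#' @export
print.chi2_result <- function(x, ...) {
  cat(sprintf("chi^2 index: %.4f (expected rank sum %.1f per item)\n",
              x$chi2_index, x$expected_sum))
  invisible(x)
}
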