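# Exact null distribution of rank-sum differences, by iterated discrete
# convolution, and the closed-form rule-of-thumb critical value.

# Direct-summation convolution of two pmfs on consecutive integer supports.
# No FFT: results are exact to accumulation error (~1e-15), reproducible.
convolve_pmf <- function(a, b) {
  if (length(a) > length(b)) { tmp <- a; a <- b; b <- tmp }
  out <- numeric(length(a) + length(b) - 1L)
  m <- length(b)
  for (i in seq_along(a)) {
    idx <- i:(i + m - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

match_convention <- function(convention) {
  match.arg(convention, c("k", "k_plus_1"))
}

#' Distribution of the sum of k independent uniform ranks
#'
#' Under the null model each item's rank in one repetition is uniform on
#' `{1, .., N}`, independently across repetitions; the rank sum over `k`
#' repetitions is then the `k`-fold convolution of that uniform.
#'
#' @param N sequence length (integer >= 2).
#' @param k number of repetitions (integer >= 1).
#' @return list with `support` (`k:(k*N)`) and `pmf` (sums to 1, symmetric
#'   about `k (N + 1) / 2`).
#' @examples
#' sum_rank_pmf(2, 2)$pmf  # 1/4 1/2 1/4
#' @export
sum_rank_pmf <- function(N, k) {
  stopifnot(N >= 2L, k >= 1L)
  u <- rep(1 / N, N)
  f <- u
  if (k > 1L) for (i in seq_len(k - 1L)) f <- convolve_pmf(f, u)
  list(support = seq.int(k, k * N), pmf = f)
}

#' Exact null distribution of the difference of two rank sums
#'
#' The null for the pairwise difference `d[i] = S[i+1] - S[i]` treats the
#' two rank sums as independent `k`-fold sums of uniform ranks; their
#' difference is obtained by convolving the sum distribution with itself
#' and centering on zero (valid because the sum pmf is symmetric).
#'
#' @section Convolution convention:
#' `convention = "k"` (default) takes each rank sum as a sum of `k`
#' uniforms -- one per repetition, matching the data flow. The source
#' recursion for the sum distribution can also be read as starting from a
#' convolution of two uniforms, making each "k-fold" sum a sum of `k + 1`
#' uniforms; `convention = "k_plus_1"` reproduces that (wider, more
#' conservative) null. [detect_chunks()] defaults to `"k_plus_1"`; see the
#' package vignette for the evidence behind the two defaults.
#'
#' @param N sequence length.
#' @param k repetitions per block.
#' @param convention `"k"` or `"k_plus_1"` (see Details).
#' @return object of class `diff_distribution`: list with `support`
#'   (consecutive integers, symmetric about 0), `pmf`, `N`, `k`,
#'   `convention`.
#' @examples
#' d <- diff_distribution(2, 2)
#' rbind(d$support, d$pmf)  # 1/16 1/4 3/8 1/4 1/16 on -2..2
#' @export
diff_distribution <- function(N, k, convention = "k") {
  convention <- match_convention(convention)
  kk <- if (convention == "k") k else k + 1L
  f <- sum_rank_pmf(N, kk)$pmf
  g <- convolve_pmf(f, f)            # support 2*kk .. 2*kk*N
  # E[G] = kk*(N+1); centering gives symmetric support -kk(N-1) .. kk(N-1)
  structure(list(support = seq.int(-kk * (N - 1L), kk * (N - 1L)),
                 pmf = g, N = N, k = k, convention = convention),
            class = "diff_distribution")
}

#' @export
print.diff_distribution <- function(x, ...) {
  cat(sprintf("Null distribution of rank-sum differences (N = %d, k = %d, convention = %s)\n",
              x$N, x$k, x$convention))
  cat(sprintf("  support %d .. %d, sd = %.4f\n",
              min(x$support), max(x$support),
              sqrt(sum(x$pmf * x$support^2))))
  invisible(x)
}

#' Exact critical value for a rank-sum difference
#'
#' The largest support value `x` of the null difference distribution whose
#' lower-tail cumulative mass is at most `alpha`. Differences at or below
#' this value mark chunk heads in [detect_chunks()].
#'
#' If even the most extreme support point carries more than `alpha` mass
#' (extreme discreteness at tiny `N * k`), no critical value is attainable:
#' the function warns and returns `min(support) - 1`, which makes detection
#' impossible -- a signal that the block geometry is underpowered (at least
#' 4 repetitions per block are recommended).
#'
#' @inheritParams diff_distribution
#' @param alpha per-comparison type-I rate, in (0, 1].
#' @return integer critical value (negative for any `alpha <= 0.5`).
#' @examples
#' exact_threshold(16, 5, 0.05)   # -25
#' exact_threshold(2, 3, 0.05)    # -3
#' @export
exact_threshold <- function(N, k, alpha = 0.05, convention = "k") {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must be a single probability in (0, 1]")
  d <- diff_distribution(N, k, convention)
  cdf <- cumsum(d$pmf)
  ok <- which(cdf <= alpha + 1e-12)  # tolerance against accumulation error
  if (!length(ok)) {
    warning(sprintf(
      "no attainable critical value for N = %d, k = %d at alpha = %g: detection impossible; at least k = 4 repetitions per block are recommended",
      N, k, alpha))
    return(min(d$support) - 1L)
  }
  d$support[max(ok)]
}

#' Closed-form rule-of-thumb critical value
#'
#' Convenience approximation to [exact_threshold()] at `alpha = 0.05`,
#' as printed in the source method:
#' `theta = -0.5 - 0.70647 * sqrt(N) * k`.
#'
#' Note that this closed form does not track the exact critical values
#' well over a wide `(N, k)` range (they scale as `N * sqrt(k)`, not
#' `sqrt(N) * k`); see [fit_rule_of_thumb()] and the package vignette.
#' The exact threshold is the default everywhere in this package.
#'
#' @inheritParams diff_distribution
#' @return numeric critical value.
#' @examples
#' rule_of_thumb_threshold(16, 5)  # -14.6294
#' @export
rule_of_thumb_threshold <- function(N, k) {
  -0.5 - 0.70647 * sqrt(N) * k
}

#' Refit the rule-of-thumb threshold formula
#'
#' Recomputes [exact_threshold()] over a grid of `(N, k)` geometries and
#' fits the closed form `theta ~ a + b * sqrt(N) * k` by ordinary least
#' squares -- the procedure that produced the printed constants
#' `a = -0.5`, `b = -0.70647`. Residuals are kept per grid cell so the
#' adequacy of the `sqrt(N) * k` predictor can be inspected; an
#' alternative predictor `N * sqrt(k)` (the standard-deviation scaling of
#' a difference of rank sums) can be requested for comparison.
#'
#' @param k_range integer vector of repetition counts (default 2:20).
#' @param N_range integer vector of sequence lengths (default 2:64).
#' @param alpha type-I rate at which thresholds are computed.
#' @param convention convolution convention, see [diff_distribution()].
#' @param predictor `"sqrtN_k"` for `sqrt(N) * k` (the printed form) or
#'   `"N_sqrtk"` for `N * sqrt(k)`.
#' @return object of class `threshold_fit`: list with `intercept`,
#'   `coefficient`, `grid` (data frame of N, k, theta, fitted, residual),
#'   `alpha`, `convention`, `predictor`, `r_squared`.
#' @examples
#' # tiny grid; the full default grid takes a few seconds
#' fit_rule_of_thumb(k_range = 2:4, N_range = c(4, 8, 16))
#' @export
fit_rule_of_thumb <- function(k_range = 2:20, N_range = 2:64, alpha = 0.05,
                              convention = "k",
                              predictor = c("sqrtN_k", "N_sqrtk")) {
  predictor <- match.arg(predictor)
  convention <- match_convention(convention)
  if (!length(k_range) || !length(N_range))
    stop("empty grid")
  grid <- expand.grid(N = as.integer(N_range), k = as.integer(k_range))
  if (nrow(grid) < 2L)
    stop("degenerate grid: need at least two (N, k) points to fit")
  grid$theta <- mapply(function(N, k) exact_threshold(N, k, alpha, convention),
                       grid$N, grid$k)
  grid$x <- if (predictor == "sqrtN_k") sqrt(grid$N) * grid$k
            else grid$N * sqrt(grid$k)
  fit <- stats::lm(theta ~ x, data = grid)
  grid$fitted <- stats::fitted(fit)
  grid$residual <- stats::resid(fit)
  grid$x <- NULL
  structure(list(intercept = unname(stats::coef(fit)[1L]),
                 coefficient = unname(stats::coef(fit)[2L]),
                 grid = grid, alpha = alpha, convention = convention,
                 predictor = predictor,
                 r_squared = summary(fit)$r.squared),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  form <- if (x$predictor == "sqrtN_k") "sqrt(N) * k" else "N * sqrt(k)"
  cat(sprintf("Threshold refit: theta ~ %.5f + %.5f * %s\n",
              x$intercept, x$coefficient, form))
  cat(sprintf("  grid: k in [%d, %d], N in [%d, %d] (%d cells), alpha = %g, convention = %s\n",
              min(x$grid$k), max(x$grid$k), min(x$grid$N), max(x$grid$N),
              nrow(x$grid), x$alpha, x$convention))
  cat(sprintf("  R^2 = %.5f, residual sd = %.3f\n",
              x$r_squared, stats::sd(x$grid$residual)))
  invisible(x)
}

#' @export
coef.threshold_fit <- function(object, ...) {
  c(intercept = object$intercept, coefficient = object$coefficient)
}

#' @export
residuals.threshold_fit <- function(object, ...) object$grid$residual

#' @importFrom stats fitted resid sd
NULL
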