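#' Detect chunks in a block of RT sequences
#'
#' The core detector. Within one block (`k` repetitions of an `N`-item
#' sequence) the algorithm proceeds in five steps:
#' \enumerate{
#'   \item rank each repetition's RTs (1 = fastest; missing values are
#'     imputed first with the item's mean over the other repetitions);
#'   \item sum ranks per item over the `k` repetitions, giving `S`;
#'   \item difference consecutive items' rank sums, `d[i] = S[i+1] - S[i]`;
#'   \item flag positions with `d[i] <= theta` as chunk *heads*, where
#'     `theta` is the critical value of the exact null distribution of
#'     rank-sum differences at rate `alpha`;
#'   \item extend each head's *body* rightward: item `j` joins the chunk
#'     while (1) `S[j] - S[head] <= theta` and (2) for `j >= head + 2`,
#'     `|S[j] - S[j-1]|` does not exceed the block's median absolute
#'     rank-sum difference (the head--first-body pair is exempt from
#'     condition 2, which it satisfies by construction of the head).
#' }
#' Every head therefore owns at least its immediate successor: chunks have
#' length >= 2, never wrap past position `N`, and are disjoint -- scanning
#' left to right, a position absorbed into a body is not reconsidered as a
#' head.
#'
#' @param block an [rt_block()] or numeric `k x N` matrix (rows =
#'   repetitions). Missing values allowed; imputation runs first.
#' @param alpha per-comparison type-I rate for head detection, in (0, 1).
#'   Default 0.05; lower it for fewer, more reliable chunks.
#' @param theta_mode `"exact"` (default) uses [exact_threshold()];
#'   `"rule_of_thumb"` uses the closed form [rule_of_thumb_threshold()]
#'   (alpha is then fixed at the 0.05 the formula was built for).
#' @param convention convolution convention for the exact null; the
#'   detector's default is `"k_plus_1"`, the convention written in the
#'   source recursion, whose wider null reproduces the published recovery
#'   behaviour on simulated data (see the vignette). The distribution
#'   functions themselves default to `"k"`.
#' @param theta optional precomputed critical value, overriding
#'   `theta_mode` (used by the Monte Carlo harness to avoid recomputing
#'   the null per block).
#'
#' @return An object of class `chunk_fit`:
#' \describe{
#'   \item{chunks}{data frame with one row per detected chunk: `head`
#'     (1-based item position), `length` (head plus body).}
#'   \item{bodies}{list of integer vectors, the body positions of each
#'     chunk.}
#'   \item{theta, alpha, theta_mode, convention}{detection parameters.}
#'   \item{ranks}{the block's `rank_summary`.}
#'   \item{chi2}{the block's [chi2_index()] result.}
#' }
#'
#' @examples
#' sim <- generate_block(condition = "few_short", noise = noise_spec(0.1, 5))
#' fit <- detect_chunks(sim$block)
#' fit
#' sim$truth
#' @export
detect_chunks <- function(block, alpha = 0.05,
                          theta_mode = c("exact", "rule_of_thumb"),
                          convention = "k_plus_1",
                          theta = NULL) {
  theta_mode <- match.arg(theta_mode)
  convention <- match_convention(convention)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single probability in (0, 1)")
  block <- impute_missing(as_rt_block(block))
  k <- nrow(block)
  N <- ncol(block)

  rs <- summarize_ranks(block)
  S <- rs$summed_ranks
  d <- rs$diffs
  mad <- rs$median_abs_diff

  if (is.null(theta))
    theta <- switch(theta_mode,
                    exact = exact_threshold(N, k, alpha, convention),
                    rule_of_thumb = rule_of_thumb_threshold(N, k))

  candidates <- which(d <= theta)
  used <- logical(N)
  heads <- integer(0)
  lens <- integer(0)
  bodies <- list()
  for (h in candidates) {
    if (used[h]) next                      # absorbed into an earlier body
    last <- h + 1L                         # first body item: restates the head criterion
    j <- h + 2L
    while (j <= N &&
           S[j] - S[h] <= theta &&
           abs(S[j] - S[j - 1L]) <= mad) { # non-strict: items with equal spread are comparable
      last <- j
      j <- j + 1L
    }
    used[h:last] <- TRUE
    heads <- c(heads, h)
    lens <- c(lens, last - h + 1L)
    bodies <- c(bodies, list(seq.int(h + 1L, last)))
  }

  structure(list(chunks = data.frame(head = heads, length = lens),
                 bodies = bodies,
                 n_chunks = length(heads),
                 theta = theta, alpha = alpha, theta_mode = theta_mode,
                 convention = convention,
                 ranks = rs,
                 chi2 = chi2_index(rs),
                 N = N, k = k,
                 block_id = attr(block, "block_id"),
                 subject = attr(block, "subject")),
            class = "chunk_fit")
}

#' @export
print.chunk_fit <- function(x, ...) {
  id <- if (!is.null(x$block_id)) paste0(" '", x$block_id, "'") else ""
  cat(sprintf("Chunk detection%s: N = %d items, k = %d repetitions\n", id, x$N, x$k))
  cat(sprintf("  theta = %s (%s%s), alpha = %g\n",
              format(x$theta), x$theta_mode,
              if (x$theta_mode == "exact") paste0(", ", x$convention) else "",
              x$alpha))
  if (x$n_chunks == 0L) {
    cat("  no chunks detected\n")
  } else {
    cat(sprintf("  %d chunk(s):\n", x$n_chunks))
    for (i in seq_len(x$n_chunks))
      cat(sprintf("    head %d, length %d (items %d-%d)\n",
                  x$chunks$head[i], x$chunks$length[i],
                  x$chunks$head[i], x$chunks$head[i] + x$chunks$length[i] - 1L))
  }
  cat(sprintf("  chi^2 index: %.3f\n", x$chi2$chi2_index))
  invisible(x)
}

#' @export
summary.chunk_fit <- function(object, ...) {
  print(object)
  cat("\n  summed ranks S:", object$ranks$summed_ranks, "\n")
  cat("  differences  d:", object$ranks$diffs, "\n")
  cat("  median |d|:", object$ranks$median_abs_diff, "\n")
  invisible(object)
}

#' Plot a chunk detection result
#'
#' Two panels: the per-item summed ranks with detected heads (red) and
#' bodies (green), and the pairwise rank-sum differences with the critical
#' value `theta` marked.
#'
#' @param x a `chunk_fit`.
#' @param ... passed to [graphics::barplot()] for the top panel.
#' @return `x`, invisibly.
#' @export
plot.chunk_fit <- function(x, ...) {
  role <- rep("none", x$N)
  role[x$chunks$head] <- "head"
  role[unlist(x$bodies)] <- "body"
  cols <- c(none = "grey70", head = "firebrick", body = "forestgreen")[role]
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$ranks$summed_ranks, names.arg = seq_len(x$N),
                    col = cols, xlab = "item position", ylab = "summed rank",
                    main = "rank sums (head = red, body = green)", ...)
  plot(seq_len(x$N - 1L) + 0.5, x$ranks$diffs, type = "h",
       xlab = "item pair", ylab = "d = S[i+1] - S[i]",
       main = sprintf("pairwise differences, theta = %s", format(x$theta)))
  graphics::abline(h = x$theta, lty = 2, col = "firebrick")
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}
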