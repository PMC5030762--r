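# Synthetic RT blocks with planted chunk structure: the test bed for the
# detector. The stated world: N = 16 items, k = 5 repetitions, baseline RTs
# 760 ms (non-chunk items), 810 ms (chunk heads), 495 ms (chunk bodies),
# and cell noise sd = rt0 * slope + intercept (Gaussian, independent).

#' Planted-chunk conditions
#'
#' The five simulated conditions: `few` = 2 chunks, `many` = 4 chunks,
#' `short` = 2 items per chunk, `long` = 4 items per chunk, and a
#' structureless `control`.
#'
#' @param name one of `"few_short"`, `"few_long"`, `"many_short"`,
#'   `"many_long"`, `"control"`, or `"custom"` (then supply `n_chunks`
#'   and `chunk_len`).
#' @param n_chunks,chunk_len used only with `name = "custom"`.
#' @return list with `name`, `n_chunks`, `chunk_len`.
#' @examples
#' chunk_condition("many_short")
#' @export
chunk_condition <- function(name = c("few_short", "few_long", "many_short",
                                     "many_long", "control", "custom"),
                            n_chunks = NULL, chunk_len = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    few_short  = list(n_chunks = 2L, chunk_len = 2L),
    few_long   = list(n_chunks = 2L, chunk_len = 4L),
    many_short = list(n_chunks = 4L, chunk_len = 2L),
    many_long  = list(n_chunks = 4L, chunk_len = 4L),
    control    = list(n_chunks = 0L, chunk_len = 0L),
    custom     = {
      if (is.null(n_chunks) || is.null(chunk_len))
        stop("custom condition needs 'n_chunks' and 'chunk_len'")
      list(n_chunks = as.integer(n_chunks), chunk_len = as.integer(chunk_len))
    })
  c(list(name = name), cfg)
}

as_condition <- function(condition) {
  if (is.character(condition)) chunk_condition(condition) else condition
}

#' Noise specification for simulated RTs
#'
#' Each simulated cell is `rt0 + (rt0 * slope + intercept) * z` with
#' `z ~ N(0, 1)` drawn independently per cell: the noise standard
#' deviation grows linearly with the baseline RT, mirroring the strong
#' SD--mean correlation of empirical RT blocks. Observed parameter ranges
#' in real data: slope -0.1 to 0.8, intercept -12 to 12 ms.
#'
#' @param slope dimensionless SD-vs-mean slope.
#' @param intercept SD offset in milliseconds.
#' @param rt0 named baseline RTs (ms) for the three item roles.
#' @return list of class `noise_spec`.
#' @examples
#' noise_spec(0.1, 5)  # sd 81 ms on a 760 ms non-chunk item
#' @export
noise_spec <- function(slope, intercept,
                       rt0 = c(nonchunk = 760, head = 810, body = 495)) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            is.numeric(rt0), all(c("nonchunk", "head", "body") %in% names(rt0)))
  structure(list(slope = slope, intercept = intercept, rt0 = rt0),
            class = "noise_spec")
}

#' Randomly place non-overlapping chunks in a sequence
#'
#' Samples uniformly from all placements of `n_chunks` runs of
#' `chunk_len` consecutive positions that neither overlap nor hang over
#' the end of the sequence, via the stars-and-bars bijection between
#' placements and `n_chunks`-subsets of `1:(N - n_chunks*(chunk_len-1))`.
#'
#' @param N sequence length.
#' @param n_chunks number of chunks (0 gives an empty placement).
#' @param chunk_len items per chunk (>= 2 unless `n_chunks` is 0).
#' @return sorted integer vector of head positions. Uses the current RNG.
#' @examples
#' set.seed(1)
#' place_chunks(16, 2, 2)
#' place_chunks(16, 4, 4)  # only one legal tiling: 1, 5, 9, 13
#' @export
place_chunks <- function(N, n_chunks, chunk_len) {
  n_chunks <- as.integer(n_chunks)
  chunk_len <- as.integer(chunk_len)
  if (n_chunks == 0L) return(integer(0))
  if (chunk_len < 2L) stop("chunks have at least 2 items (head + body)")
  if (n_chunks * chunk_len > N)
    stop(sprintf("infeasible placement: %d chunks of %d items do not fit in %d positions",
                 n_chunks, chunk_len, N))
  m <- N - n_chunks * (chunk_len - 1L)
  u <- sort(sample.int(m, n_chunks))
  u + (seq_len(n_chunks) - 1L) * (chunk_len - 1L)
}

#' Generate one synthetic RT block with planted chunks
#'
#' Chunk positions are drawn once per block and shared by all `k`
#' repetitions; every cell gets an independent Gaussian noise draw with
#' standard deviation `rt0 * slope + intercept` for its role's baseline
#' `rt0` (810 head / 495 body / 760 otherwise).
#'
#' @param N sequence length (default 16, the published geometry).
#' @param k repetitions per block (default 5).
#' @param condition a name accepted by [chunk_condition()] or the list it
#'   returns.
#' @param noise a [noise_spec()]; the default is noiseless.
#' @param heads optional fixed head positions (skips random placement).
#' @return list of class `sim_block`:
#'   `block` (an [rt_block()]), `truth` (data frame of planted `head` and
#'   `length`), `roles` (character vector per item), `condition`, `noise`.
#'   At extreme noise, simulated RTs can be non-positive; they are kept
#'   (the detector only uses rank order) with a warning from [rt_block()].
#' @examples
#' set.seed(42)
#' sim <- generate_block(condition = "few_short", noise = noise_spec(0.1, 5))
#' sim$truth
#' @export
generate_block <- function(N = 16, k = 5, condition = "few_short",
                           noise = noise_spec(0, 0), heads = NULL) {
  condition <- as_condition(condition)
  stopifnot(inherits(noise, "noise_spec"))
  if (is.null(heads)) {
    heads <- place_chunks(N, condition$n_chunks, condition$chunk_len)
  } else {
    heads <- sort(as.integer(heads))
  }
  L <- condition$chunk_len
  roles <- rep("nonchunk", N)
  for (h in heads) {
    roles[h] <- "head"
    roles[(h + 1L):(h + L - 1L)] <- "body"
  }
  rt0 <- noise$rt0[roles]
  sd <- rt0 * noise$slope + noise$intercept
  if (any(sd < 0))
    stop(sprintf("configuration error: noise sd = rt0 * slope + intercept is negative (%.1f) for rt0 = %g",
                 min(sd), rt0[which.min(sd)]))
  rts <- matrix(rep(rt0, each = k) + rep(sd, each = k) * stats::rnorm(k * N),
                nrow = k)
  truth <- data.frame(head = heads,
                      length = rep(L, length(heads)))
  structure(list(block = rt_block(rts),
                 truth = truth, roles = roles,
                 condition = condition, noise = noise),
            class = "sim_block")
}

#' @export
print.sim_block <- function(x, ...) {
  cat(sprintf("Simulated block: condition '%s' (N = %d, k = %d), slope %g, intercept %g\n",
              x$condition$name, ncol(x$block), nrow(x$block),
              x$noise$slope, x$noise$intercept))
  if (nrow(x$truth)) {
    cat("  planted heads:", x$truth$head, "(length", x$truth$length[1], "each)\n")
  } else cat("  no planted structure (control)\n")
  invisible(x)
}
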