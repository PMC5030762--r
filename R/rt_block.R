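#' Construct an RT block
#'
#' A block is the unit of analysis: `k` repetitions (rows) of an `N`-item
#' sequence (columns) of reaction times in milliseconds. Missing responses
#' (time-outs, lapses) are held as `NA` and must be imputed with
#' [impute_missing()] before ranking; [detect_chunks()] does this
#' automatically.
#'
#' @param rts numeric matrix or data frame, `k` rows (repetitions) by `N`
#'   columns (item positions). `NA` marks a missing response.
#' @param block_id optional label for the block.
#' @param subject optional subject label (carried through to output files).
#'
#' @return An object of class `rt_block`: the RT matrix with `block_id`
#'   and `subject` attributes.
#'
#' @details Non-missing RTs must be finite. RTs are expected to be
#'   positive; non-positive values (possible in simulation at extreme
#'   noise) are kept -- ranking only uses order -- but raise a warning.
#'   An item missing in *all* repetitions is an error, since its imputation
#'   donor mean would be undefined.
#'
#' @examples
#' b <- rt_block(rbind(c(510, 300, 290), c(480, NA, 305)), block_id = "b1")
#' impute_missing(b)
#' @export
rt_block <- function(rts, block_id = NULL, subject = NULL) {
  rts <- as.matrix(rts)
  if (!is.numeric(rts)) stop("'rts' must be numeric")
  k <- nrow(rts)
  N <- ncol(rts)
  if (N < 2L || k < 2L)
    stop("unsupported geometry: a block needs at least 2 items (N) and 2 repetitions (k), got N = ",
         N, ", k = ", k)
  if (any(is.nan(rts))) rts[is.nan(rts)] <- NA_real_
  if (any(!is.na(rts) & !is.finite(rts)))
    stop("non-finite RT values (Inf) are not allowed")
  all_missing <- colSums(!is.na(rts)) == 0L
  if (any(all_missing))
    stop("unimputable item(s) ", paste(which(all_missing), collapse = ", "),
         if (!is.null(block_id)) paste0(" in block '", block_id, "'") else "",
         ": missing in every repetition")
  if (any(rts <= 0, na.rm = TRUE))
    warning("block contains non-positive RTs; they are kept (ranking uses order only)")
  dimnames(rts) <- list(NULL, NULL)
  structure(rts, class = "rt_block",
            block_id = block_id, subject = subject)
}

#' @export
print.rt_block <- function(x, ...) {
  cat(sprintf("RT block%s: N = %d items x k = %d repetitions, %d missing\n",
              if (!is.null(attr(x, "block_id"))) paste0(" '", attr(x, "block_id"), "'") else "",
              ncol(x), nrow(x), sum(is.na(x))))
  print(unclass(x)[,, drop = FALSE], ...)
  invisible(x)
}

as_rt_block <- function(x) {
  if (inherits(x, "rt_block")) x else rt_block(x)
}

#' Impute missing RTs within a block
#'
#' Replaces each missing value by the arithmetic mean of the non-missing
#' RTs of the *same item* in the remaining repetitions of the block.
#' Imputation always precedes ranking.
#'
#' @param block an [rt_block()] (a plain matrix is coerced).
#' @return The block with no missing entries; non-missing cells unchanged.
#' @export
impute_missing <- function(block) {
  block <- as_rt_block(block)
  miss <- is.na(block)
  if (!any(miss)) return(block)
  for (i in which(colSums(miss) > 0L)) {
    donors <- block[!miss[, i], i]
    # all-missing columns are rejected at construction, so donors is non-empty
    block[miss[, i], i] <- mean(donors)
  }
  block
}
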