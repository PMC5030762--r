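# Readers and writers: long-format CSV/TSV of RTs in, JSON/CSV of detected
# chunks out. All item positions are 1-based in files and messages.

sniff_sep <- function(path, sep) {
  if (!is.null(sep)) return(sep)
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a long-format RT table into blocks
#'
#' Expects a header and five columns: `subject`, `block`, `sequence`
#' (repetition index, 1..k), `item` (position, 1..N), `rt` (milliseconds;
#' empty field, `NA` or `NaN` marks a missing response). Each
#' (subject, block) group must form a complete `k x N` grid apart from
#' missing `rt` values.
#'
#' @param path CSV or TSV file (separator sniffed from the first line
#'   unless `sep` is given).
#' @param sep optional field separator.
#' @param quiet suppress the per-block summary messages.
#' @return named list of [rt_block()]s (names `"subject.block"`), each
#'   carrying its `subject` and `block_id` attributes.
#' @seealso [read_rt_matrix()] for a wide single-block matrix.
#' @export
read_rt_table <- function(path, sep = NULL, quiet = FALSE) {
  sep <- sniff_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          na.strings = c("", "NA", "NaN"),
                          stringsAsFactors = FALSE)
  needed <- c("subject", "block", "sequence", "item", "rt")
  if (!all(needed %in% names(df)))
    stop("parse error: missing column(s) ",
         paste(setdiff(needed, names(df)), collapse = ", "))
  df$rt <- as.numeric(df$rt)
  key <- paste(df$subject, df$block, df$sequence, df$item, sep = "\r")
  if (anyDuplicated(key)) {
    row <- which(duplicated(key))[1L]
    stop(sprintf("parse error: duplicated (subject, block, sequence, item) key at data row %d", row))
  }
  groups <- split(df, list(df$subject, df$block), drop = TRUE, sep = "\r")
  out <- list()
  for (g in groups) {
    subj <- as.character(g$subject[1L])
    blk <- as.character(g$block[1L])
    seqs <- sort(unique(g$sequence))
    items <- sort(unique(g$item))
    k <- length(seqs); N <- length(items)
    if (!identical(as.integer(items), seq_len(N)) ||
        !identical(as.integer(seqs), seq_len(k)) ||
        nrow(g) != k * N)
      stop(sprintf("parse error: subject '%s' block '%s' is not a complete k x N grid (sequences 1..k, items 1..N)",
                   subj, blk))
    m <- matrix(NA_real_, k, N)
    m[cbind(g$sequence, g$item)] <- g$rt
    b <- rt_block(m, block_id = blk, subject = subj)
    if (!quiet)
      message(sprintf("block %s/%s: N = %d, k = %d, %d missing",
                      subj, blk, N, k, sum(is.na(m))))
    out[[paste(subj, blk, sep = ".")]] <- b
  }
  out
}

#' Read a wide single-block RT matrix
#'
#' Convenience reader for a `k x N` matrix CSV/TSV (one row per
#' repetition, one column per item, no header), as an alternative to the
#' long format of [read_rt_table()].
#'
#' @inheritParams read_rt_table
#' @param block_id,subject labels attached to the block.
#' @return an [rt_block()].
#' @export
read_rt_matrix <- function(path, sep = NULL, block_id = NULL, subject = NULL) {
  sep <- sniff_sep(path, sep)
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep,
                                   na.strings = c("", "NA", "NaN")))
  rt_block(m, block_id = block_id, subject = subject)
}

fit_to_record <- function(fit) {
  chunks <- lapply(seq_len(fit$n_chunks), function(i)
    list(head = fit$chunks$head[i],
         length = fit$chunks$length[i],
         body = as.list(fit$bodies[[i]])))
  list(theta = fit$theta, alpha = fit$alpha,
       chunks = chunks,
       chi2_index = fit$chi2$chi2_index)
}

results_to_nested <- function(results) {
  if (inherits(results, "chunk_fit")) results <- list(results)
  nested <- list()
  for (i in seq_along(results)) {
    fit <- results[[i]]
    subj <- if (!is.null(fit$subject)) as.character(fit$subject) else "1"
    blk <- if (!is.null(fit$block_id)) as.character(fit$block_id) else as.character(i)
    nested[[subj]][[blk]] <- fit_to_record(fit)
  }
  nested
}

#' Write detection results to JSON or CSV
#'
#' JSON: nested subject -> block -> record with `theta`, `alpha`, the
#' chunk list (`head`, `length`, `body` positions) and `chi2_index`;
#' writing, reading back with [read_results()] and writing again is
#' byte-identical. CSV: one row per detected chunk plus one summary row
#' per block. Positions are 1-based.
#'
#' @param results a `chunk_fit`, a list of them, or a nested list as
#'   returned by [read_results()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  nested <- if (inherits(results, "chunk_results")) unclass(results)
            else results_to_nested(results)
  if (format == "json") {
    json <- jsonlite::toJSON(nested, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null")
    writeLines(json, path)
  } else {
    rows <- list()
    for (subj in names(nested)) for (blk in names(nested[[subj]])) {
      rec <- nested[[subj]][[blk]]
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, block = blk, record = "block_summary",
        head = NA_integer_, length = NA_integer_, body = "",
        theta = rec$theta, alpha = rec$alpha,
        n_chunks = length(rec$chunks), chi2_index = rec$chi2_index)
      for (ch in rec$chunks)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj, block = blk, record = "chunk",
          head = ch$head, length = ch$length,
          body = paste(unlist(ch$body), collapse = ";"),
          theta = rec$theta, alpha = rec$alpha,
          n_chunks = NA_integer_, chi2_index = NA_real_)
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON results file
#'
#' @param path a file written by [write_results()] with `format = "json"`.
#' @return the nested subject -> block -> record list (class
#'   `chunk_results`), acceptable to [write_results()] for a stable
#'   round trip.
#' @export
read_results <- function(path) {
  structure(jsonlite::fromJSON(path, simplifyVector = FALSE),
            class = "chunk_results")
}
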