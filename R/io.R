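#' Write a pipeline table to CSV with a seed header comment
#'
#' All generator outputs round-trip losslessly through these writers and
#' readers. The RNG seed (attribute `"seed"` on generated tables, or the
#' `seed` argument) is recorded as a `# seed: <n>` comment line so every
#' file documents its own provenance.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param seed Seed to record; defaults to `attr(x, "seed")`.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(x, path, seed = attr(x, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pipeline table written by [write_pipeline_csv()]
#'
#' @param path CSV path; `#`-prefixed header comments are skipped and the
#'   recorded seed, if any, is re-attached as attribute `"seed"`.
#' @return A data frame.
#' @export
read_pipeline_csv <- function(path) {
  first <- readLines(path, n = 1L)
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "# seed:"))
    attr(x, "seed") <- as.integer(sub("# seed:", "", first))
  x
}

#' Split a timelines table into per-cell passage-time vectors
#'
#' @param timelines Data frame as produced by [gen_timelines()] (column
#'   `passage_times_min`, semicolon separated).
#' @return A list of numeric vectors, one per row (possibly empty).
#' @export
parse_passage_times <- function(timelines) {
  lapply(as.character(timelines$passage_times_min), function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ";")[[1L]])
  })
}
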