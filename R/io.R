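#' Write and read a BOLD series as delimited text
#'
#' Two tab-separated columns (`volume_index`, `value`) preceded by a comment
#' header carrying the repetition time and origin, so a series round-trips
#' losslessly through text.
#'
#' @param ts A [bold_time_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bold_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "bold_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_seconds=%.17g origin_time_s=%.17g",
                     ts$tr_seconds, ts$origin_time_s), con)
  utils::write.table(
    data.frame(volume_index = seq_along(ts$values) - 1L, value = ts$values),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bold_tsv
#' @return `read_bold_tsv`: a [bold_time_series()].
#' @export
read_bold_tsv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "tr_seconds=([-0-9.eE+]+) origin_time_s=([-0-9.eE+]+)", hdr))[[1]]
  if (length(m) != 3L) stop("missing tr_seconds header in ", path,
                            call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  bold_time_series(d$value, as.numeric(m[2]), as.numeric(m[3]))
}

#' Write and read trial tables as delimited text
#'
#' Plain tab-separated tables with a header row; used for trial records,
#' trigger events, and offer lists alike.
#'
#' @param df A data.frame.
#' @param path File path.
#' @return `path` invisibly; `read_trials_tsv` returns the data.frame.
#' @export
write_trials_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_tsv
#' @export
read_trials_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
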