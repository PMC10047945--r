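# Delimited-text IO for multichannel matrices: channels as rows, first
# column the channel label, comma- or tab-delimited, '#' comment lines
# allowed, decimal point '.', no thousands separators.

#' Read a multichannel matrix from delimited text
#'
#' Expects channels as rows with the channel label in the first column and
#' a header line (`channel,s1,s2,...`). The delimiter (comma or tab) is
#' detected from the header; `#`-prefixed lines are ignored.
#'
#' @param path file path.
#' @return channels-by-samples numeric matrix with labelled rows.
#' @export
read_mc_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no data rows in ", path)
  sepchar <- if (grepl("\t", lines[1L])) "\t" else ","
  con <- textConnection(lines)
  on.exit(close(con))
  d <- read.csv(con, sep = sepchar, check.names = FALSE,
                stringsAsFactors = FALSE)
  labels <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  colnames(m) <- NULL
  if (!all(is.finite(m))) stop("non-finite values in ", path)
  m
}

#' Write a multichannel matrix as delimited text
#'
#' Channels as rows, channel label in the first column, header line
#' `channel,s1,...`.
#'
#' @param series channels-by-samples matrix (row names used as labels;
#'   `ch1..chp` when absent).
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_mc_matrix <- function(series, path, sep = ",") {
  x <- as_channel_matrix(series)
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  d <- data.frame(channel = labels, x, check.names = FALSE)
  names(d) <- c("channel", paste0("s", seq_len(ncol(x))))
  write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
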