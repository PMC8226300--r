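#' Read a BED3+ file
#'
#' BED is already 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. Records are returned sorted by
#' (seq_id, start); overlapping records are merged only on request.
#'
#' @param path BED file (optionally gzipped).
#' @param merge merge overlapping records after reading.
#' @return interval data.frame with extra columns `name` and `score` when the
#'   file carries them (BED4+/BED5+), and `strand` from column 6 when present.
#' @export
read_bed <- function(path, merge = FALSE) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(intervals())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  if (ncol < 3) stop("BED record with fewer than 3 fields")
  start <- as.numeric(vapply(fields, `[`, "", 2))
  end <- as.numeric(vapply(fields, `[`, "", 3))
  bad <- which(start >= end)
  if (length(bad)) {
    stop("degenerate BED interval (start >= end) at line ", bad[1])
  }
  df <- data.frame(
    seq_id = vapply(fields, `[`, "", 1),
    start = start, end = end,
    strand = if (ncol >= 6) vapply(fields, `[`, "", 6) else ".",
    stringsAsFactors = FALSE
  )
  if (ncol >= 4) df$name <- vapply(fields, `[`, "", 4)
  if (ncol >= 5) df$score <- suppressWarnings(
    as.numeric(vapply(fields, `[`, "", 5)))
  df <- df[order(df$seq_id, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  if (merge) df <- merge_intervals(df)
  df
}

#' Write intervals as BED
#'
#' @param df interval data.frame (optionally with `name`, `score`).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- list(df$seq_id, format(df$start, scientific = FALSE, trim = TRUE),
               format(df$end, scientific = FALSE, trim = TRUE))
  if (!is.null(df$name) || !is.null(df$score) ||
      any(df$strand %in% c("+", "-"))) {
    cols <- c(cols, list(df$name %||% rep(".", nrow(df)),
                         df$score %||% rep(0, nrow(df)),
                         df$strand %||% rep(".", nrow(df))))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}
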