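#' Construct an interval table
#'
#' Intervals are the package's common currency for genomic extents. All
#' internal coordinates are 0-based half-open (`start` inclusive, `end`
#' exclusive); conversion to and from 1-based formats (GFF3, VCF) happens only
#' in the readers and writers.
#'
#' @param seq_id character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand strand characters in `+`, `-`, `.` (recycled).
#' @return A `data.frame` with columns `seq_id`, `start`, `end`, `strand`.
#' @export
intervals <- function(seq_id = character(), start = integer(),
                      end = integer(), strand = ".") {
  df <- data.frame(
    seq_id = as.character(seq_id),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(seq_id)),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(df)))
  if (nrow(df) && any(df$start < 0)) stop("interval start < 0")
  if (nrow(df) && any(df$start >= df$end)) {
    stop("degenerate interval (start >= end)")
  }
  invisible(df)
}

#' Convert intervals to an IRanges list keyed by sequence
#'
#' @param df interval data.frame (0-based half-open).
#' @return named list of [IRanges::IRanges] (1-based closed), one per seq_id.
#' @keywords internal
iv_to_iranges <- function(df) {
  sp <- split(df, df$seq_id)
  lapply(sp, function(d) IRanges::IRanges(start = d$start + 1, end = d$end))
}

#' Merge overlapping or adjacent intervals
#'
#' @param df interval data.frame.
#' @return merged, sorted interval data.frame (strand dropped to `.`).
#' @export
merge_intervals <- function(df) {
  if (!nrow(df)) return(intervals())
  sp <- split(df, df$seq_id)
  out <- lapply(names(sp), function(s) {
    r <- IRanges::reduce(IRanges::IRanges(sp[[s]]$start + 1, sp[[s]]$end))
    data.frame(seq_id = s, start = IRanges::start(r) - 1,
               end = IRanges::end(r), strand = ".",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  sort_intervals(out)
}

sort_intervals <- function(df) {
  df[order(df$seq_id, df$start, df$end), , drop = FALSE]
}

#' Total number of bases covered by a set of intervals (after merging)
#' @param df interval data.frame.
#' @return numeric scalar.
#' @export
interval_coverage <- function(df) {
  m <- merge_intervals(df)
  if (!nrow(m)) return(0)
  sum(m$end - m$start)
}

#' Bases shared between two interval sets
#'
#' @param a,b interval data.frames.
#' @return numeric: total overlap in bases (both sets merged first).
#' @export
interval_overlap_bases <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  seqs <- intersect(unique(a$seq_id), unique(b$seq_id))
  tot <- 0
  for (s in seqs) {
    ra <- IRanges::IRanges(a$start[a$seq_id == s] + 1, a$end[a$seq_id == s])
    rb <- IRanges::IRanges(b$start[b$seq_id == s] + 1, b$end[b$seq_id == s])
    ov <- IRanges::intersect(ra, rb)
    tot <- tot + sum(IRanges::width(ov))
  }
  tot
}

#' Intersect two interval sets, returning the shared extents
#' @param a,b interval data.frames.
#' @return interval data.frame of the intersection.
#' @export
interval_intersect <- function(a, b) {
  a <- merge_intervals(a); b <- merge_intervals(b)
  seqs <- intersect(unique(a$seq_id), unique(b$seq_id))
  out <- list()
  for (s in seqs) {
    ra <- IRanges::IRanges(a$start[a$seq_id == s] + 1, a$end[a$seq_id == s])
    rb <- IRanges::IRanges(b$start[b$seq_id == s] + 1, b$end[b$seq_id == s])
    ov <- IRanges::intersect(ra, rb)
    if (length(ov)) {
      out[[s]] <- data.frame(seq_id = s, start = IRanges::start(ov) - 1,
                             end = IRanges::end(ov), strand = ".",
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(intervals())
  sort_intervals(do.call(rbind, out))
}

#' Expand intervals into individual 0-based positions
#' @param df interval data.frame.
#' @return data.frame with columns seq_id, pos.
#' @keywords internal
iv_positions <- function(df) {
  if (!nrow(df)) return(data.frame(seq_id = character(), pos = numeric()))
  n <- df$end - df$start
  data.frame(seq_id = rep(df$seq_id, n),
             pos = unlist(mapply(function(s, e) s:(e - 1), df$start, df$end,
                                 SIMPLIFY = FALSE), use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Collapse sorted positions into maximal-run intervals
#' @param seq_id single sequence name.
#' @param pos sorted unique 0-based positions.
#' @return interval data.frame.
#' @keywords internal
positions_to_intervals <- function(seq_id, pos) {
  if (!length(pos)) return(intervals())
  pos <- sort(unique(pos))
  brk <- which(diff(pos) != 1)
  starts <- pos[c(1, brk + 1)]
  ends <- pos[c(brk, length(pos))] + 1
  data.frame(seq_id = seq_id, start = starts, end = ends, strand = ".",
             stringsAsFactors = FALSE)
}
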