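BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#' @param x character vector of sequences (IUPAC; case preserved).
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split a sequence string into a character vector of single bases
#' @keywords internal
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' GC fraction of a sequence, computed over non-N bases
#' @param x character scalar or vector of sequences.
#' @return numeric GC fraction in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  x <- toupper(paste(x, collapse = ""))
  n <- nchar(x)
  counts <- vapply(c("G", "C", "A", "T"), function(b) {
    lengths(regmatches(x, gregexpr(b, x, fixed = TRUE)))
  }, numeric(1))
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  unname((counts["G"] + counts["C"]) / tot)
}

#' Extract a subsequence with 0-based half-open coordinates
#' @keywords internal
subseq0 <- function(seq, start, end) substr(seq, start + 1, end)

#' Overwrite part of a sequence at a 0-based offset
#' @keywords internal
write_at0 <- function(seq, start, replacement) {
  substr(seq, start + 1, start + nchar(replacement)) <- replacement
  seq
}

#' All rotations of a short motif
#' @keywords internal
motif_rotations <- function(motif) {
  k <- nchar(motif)
  vapply(seq_len(k), function(i) {
    paste0(substr(motif, i, k), substr(motif, 1, i - 1))
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
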