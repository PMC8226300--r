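#' Read a FASTA file
#'
#' Sequences are returned verbatim: case is preserved (lower-case marks
#' soft-masked repeat sequence) and ambiguity codes are legal. The sequence id
#' is the first whitespace-delimited token of the header; the remainder is
#' kept in the `descriptions` attribute.
#'
#' @param path FASTA file (optionally gzipped).
#' @return named character vector of sequences, with a `descriptions`
#'   attribute (named character vector, possibly empty strings).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (any(Biostrings::width(set) == 0)) stop("empty FASTA record in ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- as.character(set)
  names(out) <- ids
  attr(out, "descriptions") <- setNames(desc, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    n <- nchar(s)
    starts <- seq(1, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, n)), con)
  }
  invisible(path)
}
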