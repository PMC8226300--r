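#' Construct a gene model
#'
#' A gene model is one transcript: ordered exons, the strand- and phase-aware
#' spliced CDS, and UTR intervals, all on a named sequence and in 0-based
#' half-open coordinates. Exons must be non-overlapping and sorted by start;
#' CDS segments must fall within the exons.
#'
#' @param gene_id,transcript_id identifiers.
#' @param seq_id sequence name.
#' @param strand "+" or "-".
#' @param exons data.frame with `start`, `end`.
#' @param cds data.frame with `start`, `end`, `phase` (0/1/2).
#' @param utr5,utr3 optional interval data.frames.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, seq_id, strand, exons, cds,
                       utr5 = NULL, utr3 = NULL) {
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in ", transcript_id)
  }
  for (i in seq_len(nrow(cds))) {
    ok <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    if (!ok) stop("CDS segment outside exon span in transcript ",
                  transcript_id)
  }
  empty <- data.frame(start = numeric(), end = numeric())
  structure(list(
    gene_id = gene_id, transcript_id = transcript_id, seq_id = seq_id,
    strand = strand, exons = exons, cds = cds,
    utr5 = utr5 %||% empty, utr3 = utr3 %||% empty
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s/%s %s:%d-%d (%s) %d exon(s), CDS %d bp>\n",
              x$gene_id, x$transcript_id, x$seq_id,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), sum(x$cds$end - x$cds$start)))
  invisible(x)
}

#' Spliced CDS length of a model
#' @param gene a `gene_model`.
#' @return numeric length in bp (before phase trimming).
#' @export
cds_length <- function(gene) sum(gene$cds$end - gene$cds$start)

#' Genomic positions of the spliced CDS in transcription order
#'
#' Applies the declared phase of the first CDS segment (in transcription
#' order), so the first returned position is the first base of codon 1.
#'
#' @param gene a `gene_model`.
#' @return numeric vector of 0-based genomic positions.
#' @export
cds_genomic_positions <- function(gene) {
  cds <- gene$cds
  if (!nrow(cds)) return(numeric())
  if (gene$strand == "+") {
    ord <- order(cds$start)
    pos <- unlist(lapply(ord, function(i) cds$start[i]:(cds$end[i] - 1)))
    phase <- cds$phase[ord[1]]
  } else {
    ord <- order(cds$start, decreasing = TRUE)
    pos <- unlist(lapply(ord, function(i) (cds$end[i] - 1):cds$start[i]))
    phase <- cds$phase[ord[1]]
  }
  if (is.na(phase)) phase <- 0
  if (phase > 0) pos <- pos[-seq_len(phase)]
  pos
}

#' Spliced CDS sequence on the coding strand
#'
#' @param gene a `gene_model`.
#' @param genome named character vector of sequences.
#' @return character scalar: the CDS read 5'->3' on the coding strand, after
#'   phase trimming; upper-cased.
#' @export
spliced_cds <- function(gene, genome) {
  seq <- genome[[gene$seq_id]]
  cds <- gene$cds[order(gene$cds$start), , drop = FALSE]
  parts <- substring(seq, cds$start + 1, cds$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  phase <- if (gene$strand == "+") cds$phase[1] else cds$phase[nrow(cds)]
  if (is.na(phase)) phase <- 0
  if (phase > 0) s <- substr(s, phase + 1, nchar(s))
  toupper(s)
}

#' Intron intervals of a model, in transcription order
#' @param gene a `gene_model`.
#' @return interval data.frame with `ordinal` (1 = first intron transcribed).
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons
  if (nrow(ex) < 2) {
    return(data.frame(seq_id = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      ordinal = integer()))
  }
  df <- data.frame(seq_id = gene$seq_id,
                   start = ex$end[-nrow(ex)], end = ex$start[-1],
                   strand = gene$strand, stringsAsFactors = FALSE)
  df$ordinal <- if (gene$strand == "+") seq_len(nrow(df)) else rev(seq_len(nrow(df)))
  df
}

#' Genomic span of a model (exon extremes)
#' @param gene a `gene_model`.
#' @return interval data.frame of one row.
#' @export
gene_span <- function(gene) {
  data.frame(seq_id = gene$seq_id, start = min(gene$exons$start),
             end = max(gene$exons$end), strand = gene$strand,
             stringsAsFactors = FALSE)
}
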