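STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Codon degeneracy of one codon position
#'
#' Fold is the conventional degeneracy label: a position is 0-fold (0D) when
#' no substitution is synonymous, 2-fold/3-fold when one/two of the three
#' possible substitutions are synonymous, and 4-fold (4D) when all three are.
#' Stop codons are classified by stop preservation: a substitution counts as
#' synonymous only when it yields another stop codon.
#'
#' @param codon 3-mer over ACGT (case-insensitive); vectorised.
#' @param offset within-codon position, 1-3; vectorised (recycled).
#' @return integer fold in `{0, 2, 3, 4}`; `NA` for codons containing
#'   ambiguous bases (uncallable, not an error).
#' @export
classify_codon_degeneracy <- function(codon, offset) {
  codon <- toupper(codon)
  n <- max(length(codon), length(offset))
  codon <- rep_len(codon, n); offset <- rep_len(offset, n)
  key <- paste0(codon, offset)
  out <- degeneracy_lookup()[key]
  unname(out)
}

degeneracy_cache <- new.env(parent = emptyenv())

degeneracy_lookup <- function() {
  if (!is.null(degeneracy_cache$tab)) return(degeneracy_cache$tab)
  tt <- codon_table()
  codons <- names(tt)
  tab <- rep(NA_integer_, 64 * 3)
  names(tab) <- paste0(rep(codons, each = 3), rep(1:3, 64))
  for (cod in codons) {
    aa <- tt[[cod]]
    is_stop <- cod %in% STOP_CODONS
    for (off in 1:3) {
      alts <- setdiff(BASES, substr(cod, off, off))
      syn <- 0L
      for (b in alts) {
        mut <- cod
        substr(mut, off, off) <- b
        same <- if (is_stop) mut %in% STOP_CODONS else
          (!(mut %in% STOP_CODONS) && tt[[mut]] == aa)
        if (same) syn <- syn + 1L
      }
      fold <- c(0L, 2L, 3L, 4L)[syn + 1L]
      tab[paste0(cod, off)] <- fold
    }
  }
  degeneracy_cache$tab <- tab
  tab
}

#' Per-base degeneracy map of a gene's CDS
#'
#' The CDS is spliced in transcription order (reverse-complemented for minus
#' strand), translated codon by codon, and every genomic CDS base is labelled
#' with its codon, within-codon offset and fold. Genes with internal stop
#' codons are flagged but still mapped, so downstream audits can score them;
#' a CDS length not divisible by three flags the gene incomplete and leaves
#' the trailing partial codon unclassified.
#'
#' @param gene a [gene_model()].
#' @param genome named character vector of sequences.
#' @return data.frame with columns `seq_id`, `pos` (0-based genomic), `codon`
#'   (coding-strand), `offset` (1-3), `fold` (NA when the codon contains a
#'   non-ACGT base); attributes `internal_stop` and `incomplete`.
#' @export
map_gene_degeneracy <- function(gene, genome) {
  cds <- spliced_cds(gene, genome)
  pos <- cds_genomic_positions(gene)
  n <- nchar(cds)
  incomplete <- (n %% 3) != 0
  n_use <- n - (n %% 3)
  if (n_use == 0) {
    out <- data.frame(seq_id = character(), pos = numeric(),
                      codon = character(), offset = integer(),
                      fold = integer())
    attr(out, "internal_stop") <- FALSE
    attr(out, "incomplete") <- incomplete
    return(out)
  }
  codons <- substring(cds, seq(1, n_use, 3), seq(3, n_use, 3))
  internal <- codons[-length(codons)] %in% STOP_CODONS
  offs <- rep(1:3, n_use / 3)
  cod_per_base <- rep(codons, each = 3)
  fold <- classify_codon_degeneracy(cod_per_base, offs)
  out <- data.frame(seq_id = gene$seq_id, pos = pos[seq_len(n_use)],
                    codon = cod_per_base, offset = offs, fold = fold,
                    stringsAsFactors = FALSE)
  attr(out, "internal_stop") <- any(internal)
  attr(out, "incomplete") <- incomplete
  out
}

#' High-impact positions of a gene
#'
#' The union of: the three start-codon positions; stop-codon positions at
#' which no substitution yields another stop (TAA -> position 1, TGA ->
#' positions 1 and 3, TAG -> positions 1 and 2); and the 2+2 terminal
#' dinucleotides (donor/acceptor) of each intron.
#'
#' @param gene a [gene_model()].
#' @param genome named character vector of sequences.
#' @return data.frame `seq_id`, `pos` of high-impact genomic positions, with
#'   attribute `flags` listing omitted components (missing start/stop).
#' @export
high_impact_sites <- function(gene, genome) {
  cds <- spliced_cds(gene, genome)
  pos <- cds_genomic_positions(gene)
  flags <- character()
  keep <- numeric()
  if (nchar(cds) >= 3 && substr(cds, 1, 3) == "ATG") {
    keep <- c(keep, pos[1:3])
  } else {
    flags <- c(flags, "missing_start")
  }
  n <- nchar(cds)
  stop_cod <- if (n >= 3 && n %% 3 == 0) substr(cds, n - 2, n) else ""
  if (stop_cod %in% STOP_CODONS) {
    zero_off <- which(classify_codon_degeneracy(stop_cod, 1:3) == 0L)
    keep <- c(keep, pos[n - 3 + zero_off])
  } else {
    flags <- c(flags, "missing_stop")
  }
  intr <- gene_introns(gene)
  for (i in seq_len(nrow(intr))) {
    keep <- c(keep, intr$start[i], intr$start[i] + 1,
              intr$end[i] - 2, intr$end[i] - 1)
  }
  out <- data.frame(seq_id = gene$seq_id, pos = sort(unique(keep)),
                    stringsAsFactors = FALSE)
  attr(out, "flags") <- flags
  out
}
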