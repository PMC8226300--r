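KOZAK_SITES <- c(-5:-1, 4:8)  # relative to the A of ATG at +1

#' Extract the 10-base start-codon context of a gene
#'
#' Five bases upstream and five downstream of the start codon (the ATG
#' itself is excluded), read on the coding strand from genomic (pre-mRNA)
#' sequence. Genes whose window crosses an intron are flagged; windows
#' truncated by contig edges return `NA`.
#'
#' @param gene a [gene_model()].
#' @param genome named character vector of sequences.
#' @return character scalar 10-mer (or `NA`), with attribute
#'   `crosses_intron`.
#' @export
kozak_context <- function(gene, genome) {
  seq <- genome[[gene$seq_id]]
  cds <- gene$cds[order(gene$cds$start), , drop = FALSE]
  first_seg_len <- if (gene$strand == "+") {
    cds$end[1] - cds$start[1]
  } else {
    cds$end[nrow(cds)] - cds$start[nrow(cds)]
  }
  crosses <- first_seg_len < 8  # +4..+8 extends past the first CDS segment
  if (gene$strand == "+") {
    a <- cds$start[1]                 # position of A of ATG
    up_s <- a - 5; dn_e <- a + 8
    if (up_s < 0 || dn_e > nchar(seq)) {
      return(structure(NA_character_, crosses_intron = crosses))
    }
    ctx <- paste0(subseq0(seq, up_s, a), subseq0(seq, a + 3, dn_e))
  } else {
    a_end <- cds$end[nrow(cds)]       # A of ATG is base a_end-1 on + strand
    up_e <- a_end + 5; dn_s <- a_end - 8
    if (dn_s < 0 || up_e > nchar(seq)) {
      return(structure(NA_character_, crosses_intron = crosses))
    }
    ctx <- revcomp(paste0(subseq0(seq, dn_s, a_end - 3),
                          subseq0(seq, a_end, up_e)))
  }
  structure(toupper(ctx), crosses_intron = crosses)
}

#' Build a Kozak consensus model from start-codon contexts
#'
#' Per-site base frequencies over the 10 context sites (-5..-1, +4..+8),
#' per-site information content R_s = 2 - H_s bits (H_s the Shannon entropy
#' of the site), and the consensus base per site (frequency argmax; ties go
#' to the lexicographically first base and are flagged). No small-sample
#' entropy correction is applied; training sets are expected to be large,
#' and fewer than 50 contexts triggers an instability warning.
#'
#' @param contexts character vector of 10-mers (contexts with non-ACGT
#'   bases contribute only their ACGT sites).
#' @return object of class `kozak_model`: `freq` (4 x 10), `R` (10),
#'   `consensus` (10), `n`, `tied_sites`.
#' @export
build_kozak_model <- function(contexts) {
  contexts <- toupper(contexts[!is.na(contexts)])
  if (any(nchar(contexts) != 10)) stop("Kozak contexts must be 10-mers")
  if (length(contexts) < 50) {
    warning("fewer than 50 contexts; Kozak model may be unstable")
  }
  mat <- do.call(rbind, strsplit(contexts, ""))
  freq <- vapply(seq_len(10), function(s) {
    col <- mat[, s]
    col <- col[col %in% BASES]
    tab <- table(factor(col, levels = BASES))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  rownames(freq) <- BASES
  colnames(freq) <- as.character(KOZAK_SITES)
  H <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  R <- 2 - H
  cons_idx <- apply(freq, 2, which.max)
  tied <- vapply(seq_len(10), function(s) {
    sum(freq[, s] == max(freq[, s])) > 1
  }, logical(1))
  structure(list(freq = freq, R = R, consensus = BASES[cons_idx],
                 n = length(contexts), tied_sites = which(tied)),
            class = "kozak_model")
}

#' @export
print.kozak_model <- function(x, ...) {
  cat(sprintf("<kozak_model: n = %d, consensus %s|%s, max score %.3f bits>\n",
              x$n, paste(x$consensus[1:5], collapse = ""),
              paste(x$consensus[6:10], collapse = ""),
              kozak_max_score(x)))
  invisible(x)
}

#' Maximum attainable Kozak score (the consensus sequence's score)
#' @param model a `kozak_model`.
#' @return numeric bits.
#' @export
kozak_max_score <- function(model) {
  sum(model$freq[cbind(match(model$consensus, BASES), 1:10)] * model$R)
}

#' Score a query context against a Kozak model
#'
#' The score sums, over the 10 sites, the consensus base's bit contribution
#' f_consensus * R_s for every site where the query base matches the
#' consensus; mismatching sites (and N) contribute 0. With
#' `match_only = FALSE` the alternative reading is used: every site credits
#' the query base's own height f_query * R_s regardless of match.
#'
#' @param model a `kozak_model`.
#' @param context character 10-mer(s); vectorised.
#' @param match_only credit only consensus matches (the default reading).
#' @return numeric score(s) in bits.
#' @export
kozak_score <- function(model, context, match_only = TRUE) {
  context <- toupper(context)
  if (any(nchar(context) != 10)) stop("query context must be a 10-mer")
  mat <- do.call(rbind, strsplit(context, ""))
  cons <- model$consensus
  R <- unname(model$R)
  scores <- numeric(nrow(mat))
  for (s in 1:10) {
    if (match_only) {
      hit <- mat[, s] == cons[s]
      scores <- scores + ifelse(hit, model$freq[cons[s], s] * R[s], 0)
    } else {
      b <- match(mat[, s], BASES)
      f <- ifelse(is.na(b), 0, model$freq[cbind(b, s)])
      scores <- scores + f * R[s]
    }
  }
  unname(scores)
}

#' Random start-codon contexts at a given GC content
#'
#' I.i.d. 10-mers with P(G) = P(C) = gc/2 and P(A) = P(T) = (1 - gc)/2,
#' the null model used to compare observed Kozak scores against random
#' sequence of matched composition.
#'
#' @param n number of contexts.
#' @param gc_fraction GC content in (0, 1).
#' @param seed optional integer seed for reproducibility.
#' @return character vector of 10-mers.
#' @export
random_contexts <- function(n, gc_fraction, seed = NULL) {
  stopifnot(gc_fraction > 0, gc_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  draws <- sample(BASES, n * 10, replace = TRUE, prob = p)
  apply(matrix(draws, nrow = n), 1, paste, collapse = "")
}

#' Draw contexts from a Kozak model's own frequency profile
#' @param model a `kozak_model`.
#' @param n number of contexts.
#' @return character vector of 10-mers.
#' @export
sample_kozak_contexts <- function(model, n) {
  cols <- lapply(1:10, function(s) {
    sample(BASES, n, replace = TRUE, prob = model$freq[, s])
  })
  do.call(paste0, cols)
}
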