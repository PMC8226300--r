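#' Synonymous codon sub-family table
#'
#' The 59 sense codons with a synonymous choice (Met, Trp and the stops are
#' excluded). With `split = TRUE` the six-fold families are broken into
#' sub-families sharing their first two codon positions (Leu -> TTR + CTN,
#' Ser -> TCN + AGY, Arg -> CGN + AGR), the convention used by codon
#' adaptation indices that treat those halves as separate choices.
#'
#' @param split split six-fold families in two.
#' @return data.frame `codon`, `aa`, `subfamily`.
#' @export
codon_subfamilies <- function(split = TRUE) {
  tt <- codon_table()
  codons <- names(tt)[!(names(tt) %in% c(STOP_CODONS, "ATG", "TGG"))]
  aa <- unname(tt[codons])
  subfam <- if (split) paste0(aa, "_", substr(codons, 1, 2)) else aa
  if (split) {
    # only six-fold families actually split; collapse spurious two-splits of
    # four-fold families (all NNx share the first two positions anyway)
    six <- names(table(aa))[table(aa) == 6]
    subfam[!(aa %in% six)] <- aa[!(aa %in% six)]
  }
  data.frame(codon = codons, aa = aa, subfamily = subfam,
             stringsAsFactors = FALSE)
}

#' Codon usage matrix over gene models
#'
#' Counts of the 59 synonymous sense codons per gene, over the spliced CDS.
#' The start codon is included (it counts toward Met and therefore never
#' enters the matrix); the stop codon is excluded. Genes with an incomplete
#' CDS (length not divisible by three) are skipped with a warning; genes
#' whose CDS uses only Met/Trp codons yield an all-zero row and are flagged.
#'
#' @param genes list of [gene_model()] objects.
#' @param genome named character vector of sequences.
#' @return integer matrix genes x 59 codons, with attribute `flagged` naming
#'   all-zero rows.
#' @export
codon_usage <- function(genes, genome) {
  fam <- codon_subfamilies()
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  mat <- matrix(0L, nrow = length(genes), ncol = nrow(fam),
                dimnames = list(ids, fam$codon))
  skipped <- character()
  for (i in seq_along(genes)) {
    cds <- spliced_cds(genes[[i]], genome)
    n <- nchar(cds)
    if (n %% 3 != 0 || n < 3) {
      skipped <- c(skipped, ids[i])
      next
    }
    codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
    if (codons[length(codons)] %in% STOP_CODONS) {
      codons <- codons[-length(codons)]
    }
    tab <- table(codons)
    keep <- intersect(names(tab), fam$codon)
    mat[i, keep] <- as.integer(tab[keep])
  }
  if (length(skipped)) {
    warning("skipped gene(s) with incomplete CDS: ",
            paste(head(skipped, 5), collapse = ", "))
  }
  attr(mat, "flagged") <- ids[rowSums(mat) == 0]
  mat
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count over its
#' (sub-)family, computed per gene.
#'
#' @param usage counts matrix from [codon_usage()].
#' @param split use split sub-families.
#' @return numeric matrix of the same shape (NaN where a family is unused).
#' @export
rscu <- function(usage, split = TRUE) {
  fam <- codon_subfamilies(split)
  out <- usage * NA_real_
  for (sf in unique(fam$subfamily)) {
    cods <- fam$codon[fam$subfamily == sf]
    sub <- usage[, cods, drop = FALSE]
    out[, cods] <- sub / rowMeans(sub)
  }
  out
}

#' Correspondence analysis of a codon usage matrix
#'
#' Standard CA: the count matrix is scaled to a probability table, the
#' standardized residuals (observed - expected) / sqrt(expected) under row x
#' column independence are decomposed by SVD, and genes' principal
#' coordinates on axis 1 are returned together with its inertia share.
#' Zero-margin rows and columns are dropped with a warning.
#'
#' @param usage counts matrix (genes x codons).
#' @return data.frame `gene_id`, `axis1`; attributes `inertia_share` (axis 1
#'   share of total inertia) and `dropped` (row/col names removed).
#' @export
correspondence_analysis <- function(usage) {
  dropped <- c(rownames(usage)[rowSums(usage) == 0],
               colnames(usage)[colSums(usage) == 0])
  if (length(dropped)) {
    warning("dropped zero-margin rows/columns: ",
            paste(head(dropped, 5), collapse = ", "))
    usage <- usage[rowSums(usage) > 0, colSums(usage) > 0, drop = FALSE]
  }
  if (nrow(usage) < 2 || ncol(usage) < 2) {
    stop("correspondence analysis needs >= 2 genes and >= 2 codons")
  }
  P <- usage / sum(usage)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  dec <- svd(S)
  # first singular triplet is the trivial one only if margins are exact;
  # standardized residuals already remove it, so axis 1 is dec 1
  coord <- (dec$u[, 1] * dec$d[1]) / sqrt(r)
  out <- data.frame(gene_id = rownames(usage), axis1 = coord,
                    stringsAsFactors = FALSE)
  attr(out, "inertia_share") <- dec$d[1]^2 / sum(dec$d^2)
  attr(out, "dropped") <- dropped
  out
}

#' Select the highly-expressed reference gene set from CA axis 1
#'
#' Takes the given fraction of genes from one extreme of axis 1. The extreme
#' is the pole showing greater enrichment of marker genes expected to be
#' highly expressed (one-sided hypergeometric comparison); without markers
#' the caller must name the pole explicitly.
#'
#' @param ca output of [correspondence_analysis()].
#' @param fraction fraction of genes to take (set size = ceiling).
#' @param marker_genes character vector of marker gene ids.
#' @param pole "positive" or "negative"; overrides marker-based choice.
#' @return character vector of selected gene ids, with attribute `pole`.
#' @export
select_reference_set <- function(ca, fraction = 0.05, marker_genes = NULL,
                                 pole = NULL) {
  k <- ceiling(fraction * nrow(ca))
  pos_set <- ca$gene_id[order(ca$axis1, decreasing = TRUE)][seq_len(k)]
  neg_set <- ca$gene_id[order(ca$axis1)][seq_len(k)]
  if (is.null(pole)) {
    if (is.null(marker_genes)) {
      stop("no marker genes supplied: name the pole explicitly")
    }
    m <- sum(ca$gene_id %in% marker_genes)
    n_tot <- nrow(ca)
    p_enrich <- function(set) {
      x <- sum(set %in% marker_genes)
      phyper(x - 1, m, n_tot - m, k, lower.tail = FALSE)
    }
    p_pos <- p_enrich(pos_set); p_neg <- p_enrich(neg_set)
    if (p_pos == p_neg) {
      stop("marker enrichment tied between poles: name the pole explicitly")
    }
    pole <- if (p_pos < p_neg) "positive" else "negative"
  }
  out <- if (pole == "positive") pos_set else neg_set
  attr(out, "pole") <- pole
  out
}
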