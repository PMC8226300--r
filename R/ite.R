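#' Codon adaptation weights adjusted for background mutation bias
#'
#' For codon c in sub-family F the weight is w_c = r_c / max(r within F),
#' where r_c = F_hi(c) / F_bg(c): the codon's frequency within its
#' sub-family in the highly-expressed reference set divided by the same
#' frequency in the background set (a proxy for mutation bias). A
#' pseudocount of 1/2 is added to every count so small sub-families never
#' yield zero or undefined ratios. Sub-families entirely unused in the
#' reference set get uniform weights 1 and are flagged (and later excluded
#' from scoring). Weights are scale-invariant in the reference counts and
#' interpretable like CAI weights: the sub-family optimum scores 1.
#'
#' @param usage_ref codon usage counts of the reference set: a matrix from
#'   [codon_usage()] (rows summed) or a named count vector.
#' @param usage_bg background counts, same form (conventionally all genes
#'   minus the reference set).
#' @param split_families split six-fold families into two (default on).
#' @return data.frame `codon`, `subfamily`, `weight`, `unused`.
#' @export
ite_weights <- function(usage_ref, usage_bg, split_families = TRUE) {
  fam <- codon_subfamilies(split_families)
  as_counts <- function(u) {
    if (is.matrix(u)) u <- colSums(u)
    u[fam$codon]
  }
  hi <- as_counts(usage_ref); bg <- as_counts(usage_bg)
  out <- data.frame(codon = fam$codon, subfamily = fam$subfamily,
                    weight = NA_real_, unused = FALSE,
                    stringsAsFactors = FALSE)
  for (sf in unique(fam$subfamily)) {
    ix <- which(fam$subfamily == sf)
    raw_hi <- hi[ix]
    if (sum(raw_hi) == 0) {
      out$weight[ix] <- 1
      out$unused[ix] <- TRUE
      warning("sub-family ", sf, " unused in reference set; weights set to 1")
      next
    }
    fh <- (raw_hi + 0.5) / sum(raw_hi + 0.5)
    fb <- (bg[ix] + 0.5) / sum(bg[ix] + 0.5)
    r <- fh / fb
    out$weight[ix] <- r / max(r)
  }
  out
}

#' Codon adaptation score of genes (I_TE-like)
#'
#' The geometric mean of the sub-family weights over a gene's codons,
#' excluding Met, Trp, stop codons and codons from sub-families flagged
#' unused. A gene consisting entirely of sub-family-optimal codons scores
#' exactly 1.
#'
#' @param usage codon usage counts: matrix (one row per gene) or named
#'   vector for a single gene.
#' @param weights table from [ite_weights()].
#' @return data.frame `gene_id`, `ite`, `n_codons`; `ite` is `NA` when a
#'   gene has no scorable codons.
#' @export
ite_score <- function(usage, weights) {
  if (!is.matrix(usage)) usage <- matrix(usage, nrow = 1,
                                         dimnames = list("gene",
                                                         names(usage)))
  w <- weights[!weights$unused, , drop = FALSE]
  cods <- intersect(colnames(usage), w$codon)
  lw <- log(setNames(w$weight, w$codon)[cods])
  sub <- usage[, cods, drop = FALSE]
  n <- rowSums(sub)
  score <- ifelse(n > 0, exp(as.vector(sub %*% lw) / n), NA_real_)
  data.frame(gene_id = rownames(usage), ite = score, n_codons = n,
             stringsAsFactors = FALSE, row.names = NULL)
}
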