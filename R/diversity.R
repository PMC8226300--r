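#' Per-site nucleotide diversity for haploid samples
#'
#' The unbiased per-site estimator pi = (n / (n - 1)) * (1 - sum(p_i^2)) with
#' n the number of called haploid alleles and p_i the allele frequencies
#' among them. The full multiallelic form is used (it reduces to 2pq for two
#' alleles).
#'
#' @param allele_counts named or unnamed numeric vector of per-allele called
#'   counts at one site.
#' @return numeric pi; `NA` when fewer than 2 alleles were called
#'   (pairwise difference undefined).
#' @export
site_pi <- function(allele_counts) {
  n <- sum(allele_counts)
  if (n < 2) return(NA_real_)
  p <- allele_counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

positions_in_intervals <- function(seq_id, pos, iv) {
  out <- logical(length(pos))
  for (s in unique(seq_id)) {
    sel <- seq_id == s
    sub <- iv[iv$seq_id == s, , drop = FALSE]
    if (!nrow(sub)) next
    r <- IRanges::IRanges(sub$start + 1, sub$end)
    q <- IRanges::IRanges(pos[sel] + 1, pos[sel] + 1)
    out[sel] <- IRanges::overlapsAny(q, r)
  }
  out
}

count_non_acgt <- function(genome, iv) {
  tot <- 0
  for (i in seq_len(nrow(iv))) {
    s <- toupper(subseq0(genome[[iv$seq_id[i]]], iv$start[i], iv$end[i]))
    tot <- tot + nchar(gsub("[ACGT]", "", s))
  }
  tot
}

#' Nucleotide diversity over a genomic region
#'
#' pi is the sum of per-site pi over callable sites divided by L, where L
#' counts callable monomorphic sites too. When the variant table carries no
#' callable mask, all non-N reference positions in the region are assumed
#' callable (pass `genome` to discount Ns; without it every position counts).
#' Variant sites with fewer than 2 called alleles are excluded from both
#' numerator and denominator.
#'
#' @param sites interval data.frame delimiting the region.
#' @param variants a [variant_table()].
#' @param genome optional named character vector, used to exclude non-ACGT
#'   reference positions from L when no callable mask is present.
#' @param label region label carried into the output.
#' @return one-row data.frame: `region`, `pi`, `L`, `S` (segregating sites);
#'   `pi` is `NA` with a `reason` when L = 0.
#' @export
region_pi <- function(sites, variants, genome = NULL, label = "region") {
  sites <- merge_intervals(sites)
  if (!is.null(variants$callable)) {
    sites <- interval_intersect(sites, variants$callable)
  }
  L <- sum(sites$end - sites$start)
  if (!is.null(genome) && L > 0) L <- L - count_non_acgt(genome, sites)
  inside <- positions_in_intervals(variants$seq_id, variants$pos, sites)
  pis <- numeric(0)
  if (any(inside)) {
    sub <- variants$alleles[inside, , drop = FALSE]
    n <- rowSums(!is.na(sub))
    lev <- unique(sub[!is.na(sub)])
    sumsq <- rep(0, nrow(sub))
    for (a in lev) sumsq <- sumsq + rowSums(sub == a, na.rm = TRUE)^2
    pis <- ifelse(n < 2, NA_real_, (n / (n - 1)) * (1 - sumsq / n^2))
    low_n <- is.na(pis)
    L <- L - sum(low_n)
    pis <- pis[!low_n]
  }
  if (L <= 0) {
    out <- data.frame(region = label, pi = NA_real_, L = 0, S = 0)
    attr(out, "reason") <- "no callable sites"
    return(out)
  }
  data.frame(region = label, pi = sum(pis) / L, L = L,
             S = sum(pis > 0), stringsAsFactors = FALSE)
}

#' Per-gene pi0D/pi4D diversity ratio
#'
#' Diversity at the gene's zero-fold degenerate sites divided by diversity
#' at its four-fold degenerate sites. Under purifying selection on the
#' protein the ratio is well below 1; spurious gene models, whose "0D" sites
#' evolve like neutral sequence, have ratios near 1. The ratio is undefined
#' when pi4D = 0 or either site set is empty; the undefined marker is
#' propagated (downstream classification treats it as threshold-exceeding).
#'
#' @param gene a [gene_model()].
#' @param degeneracy its [map_gene_degeneracy()] output.
#' @param variants a [variant_table()].
#' @param genome optional genome for N discounting.
#' @return one-row data.frame: `gene_id`, `pi0`, `pi4`, `ratio`, `L0`, `L4`,
#'   `defined`, `reason`.
#' @export
gene_pi_ratio <- function(gene, degeneracy, variants, genome = NULL) {
  iv_for <- function(fold) {
    p <- degeneracy$pos[!is.na(degeneracy$fold) & degeneracy$fold == fold]
    positions_to_intervals(gene$seq_id, p)
  }
  iv0 <- iv_for(0L); iv4 <- iv_for(4L)
  r0 <- if (nrow(iv0)) region_pi(iv0, variants, genome, "0D") else NULL
  r4 <- if (nrow(iv4)) region_pi(iv4, variants, genome, "4D") else NULL
  pi0 <- if (!is.null(r0)) r0$pi else NA_real_
  pi4 <- if (!is.null(r4)) r4$pi else NA_real_
  L0 <- if (!is.null(r0)) r0$L else 0
  L4 <- if (!is.null(r4)) r4$L else 0
  defined <- !is.na(pi0) && !is.na(pi4) && pi4 > 0 && L0 > 0 && L4 > 0
  reason <- if (defined) NA_character_
    else if (L0 == 0 || L4 == 0) "no callable sites"
    else "pi4D = 0"
  data.frame(gene_id = gene$gene_id, pi0 = pi0, pi4 = pi4,
             ratio = if (defined) pi0 / pi4 else NA_real_,
             L0 = L0, L4 = L4, defined = defined, reason = reason,
             stringsAsFactors = FALSE)
}

#' Diversity over high-impact sites of a gene set
#'
#' [region_pi()] over the union of start-codon, stop-preserving stop-codon
#' and splice-junction positions of the input genes.
#'
#' @param genes list of [gene_model()] objects.
#' @param variants a [variant_table()].
#' @param genome named character vector of sequences.
#' @return one-row data.frame as [region_pi()].
#' @export
high_impact_pi <- function(genes, variants, genome) {
  hits <- lapply(genes, high_impact_sites, genome = genome)
  hits <- do.call(rbind, hits)
  if (is.null(hits) || !nrow(hits)) {
    out <- data.frame(region = "high_impact", pi = NA_real_, L = 0, S = 0)
    attr(out, "reason") <- "no high-impact sites"
    return(out)
  }
  ivs <- lapply(unique(hits$seq_id), function(s) {
    positions_to_intervals(s, hits$pos[hits$seq_id == s])
  })
  region_pi(do.call(rbind, ivs), variants, genome, "high_impact")
}
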