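#' Per-species, per-site-class alignability
#'
#' A reference base counts as aligned to species S when the pileup pairs it
#' with a non-gap base of S. Fractions are reported per site class, the
#' standard way to show that coding sequence stays alignable to distant
#' species long after intergenic sequence has diverged beyond recognition.
#'
#' @param pileup a [maf_pileup()].
#' @param class_map a [call_site_classes()] map over the same sequences.
#' @return data.frame `species` x `class`: `aligned`, `class_size`,
#'   `fraction`.
#' @export
alignability <- function(pileup, class_map) {
  out <- list()
  for (sp in pileup$species) {
    aligned <- rep(0, 5)
    size <- rep(0, 5)
    for (s in names(pileup$bases)) {
      cls <- class_map$codes[[s]]
      stopifnot(length(cls) == ncol(pileup$bases[[s]]))
      mask <- pileup$bases[[s]][sp, ] > 0L
      aligned <- aligned + tabulate(cls[mask], 5)
      size <- size + tabulate(cls, 5)
    }
    out[[sp]] <- data.frame(species = sp, class = class_map$levels,
                            aligned = aligned, class_size = size,
                            fraction = ifelse(size > 0, aligned / size, NA),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract four-fold degenerate alignment columns
#'
#' Walks each gene's spliced CDS codon by codon. A reference third-position
#' 4D site is retained when, in every species, the three reference columns
#' of that codon carry gap-free unambiguous bases whose triplet (read on
#' the gene's coding strand) is itself 4D at the third position. Codons
#' whose three positions come from different alignment blocks are dropped
#' and counted, as are codons failing the gap or degeneracy rules.
#'
#' @param pileup a [maf_pileup()] (duplicate-filtered blocks).
#' @param genes list of [gene_model()] objects (longest isoforms).
#' @param genome named character vector of sequences.
#' @return list: `sites` (data.frame `seq_id`, `pos`, `gene_id`),
#'   `alignment` (matrix species x sites of third-position bases on the
#'   coding strand, reference row included), `dropped` (named counts).
#' @export
extract_4d_columns <- function(pileup, genes, genome) {
  species <- pileup$species
  comp <- c(`1` = 4L, `2` = 3L, `3` = 2L, `4` = 1L)
  site_rows <- list()
  aln_cols <- list()
  dropped <- c(split_block = 0L, gap = 0L, not_4d = 0L)
  for (g in genes) {
    cds <- spliced_cds(g, genome)
    pos <- cds_genomic_positions(g)
    n_use <- nchar(cds) - (nchar(cds) %% 3)
    if (n_use < 3) next
    codons <- substring(cds, seq(1, n_use, 3), seq(3, n_use, 3))
    fold3 <- classify_codon_degeneracy(codons, 3L)
    bid <- pileup$block_id[[g$seq_id]]
    base_mat <- pileup$bases[[g$seq_id]]
    for (k in which(!is.na(fold3) & fold3 == 4L)) {
      p <- pos[(3 * k - 2):(3 * k)]  # transcription order, 0-based
      ids <- bid[p + 1]
      if (any(ids == 0L)) { dropped["gap"] <- dropped["gap"] + 1L; next }
      if (length(unique(ids)) != 1L) {
        dropped["split_block"] <- dropped["split_block"] + 1L
        next
      }
      trip <- base_mat[, p + 1, drop = FALSE]
      if (any(trip == 0L | trip == 5L)) {
        dropped["gap"] <- dropped["gap"] + 1L
        next
      }
      if (g$strand == "-") trip[] <- comp[as.character(trip)]
      cod_str <- apply(trip, 1, function(r) paste(BASES[r], collapse = ""))
      sp_fold <- classify_codon_degeneracy(cod_str, 3L)
      if (any(is.na(sp_fold) | sp_fold != 4L)) {
        dropped["not_4d"] <- dropped["not_4d"] + 1L
        next
      }
      site_rows[[length(site_rows) + 1L]] <-
        data.frame(seq_id = g$seq_id, pos = p[3], gene_id = g$gene_id,
                   stringsAsFactors = FALSE)
      aln_cols[[length(aln_cols) + 1L]] <- BASES[trip[, 3]]
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(seq_id = character(), pos = numeric(), gene_id = character())
  aln <- if (length(aln_cols)) {
    m <- do.call(cbind, aln_cols)
    rownames(m) <- species
    m
  } else matrix(character(), nrow = length(species),
                dimnames = list(species, NULL))
  list(sites = sites, alignment = aln, dropped = dropped)
}

#' Scan for ultraconserved elements
#'
#' Maximal runs of reference positions at which every species of the strict
#' set is aligned, gap-free and base-identical to the reference
#' (case-insensitive; an ambiguous reference base never conforms). Runs of
#' at least `min_len` are reported. Because conformance is evaluated per
#' reference position on the pileup, runs split across alignment blocks are
#' merged automatically whenever the intervening columns conform.
#'
#' @param pileup a [maf_pileup()].
#' @param genome named character vector of reference sequences.
#' @param strict_species species that must be identical (the reference
#'   itself is implied and may be included or not).
#' @param min_len minimum element length in bp.
#' @return interval data.frame with `length` and `source = "UCE"`.
#' @export
scan_uces <- function(pileup, genome, strict_species, min_len = 50) {
  strict <- setdiff(strict_species, pileup$reference_species)
  out <- list()
  for (s in names(pileup$bases)) {
    refcode <- encode_bases(seq_chars(genome[[s]]))
    conform <- refcode >= 1L & refcode <= 4L
    for (sp in strict) {
      conform <- conform & pileup$bases[[s]][sp, ] == refcode
    }
    r <- rle(conform)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- r$values & r$lengths >= min_len
    if (any(sel)) {
      out[[s]] <- data.frame(seq_id = s, start = starts[sel],
                             end = ends[sel], strand = ".",
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    res <- intervals()
    res$length <- numeric()
    res$source <- character()
    return(res)
  }
  res <- sort_intervals(do.call(rbind, out))
  res$length <- res$end - res$start
  res$source <- "UCE"
  rownames(res) <- NULL
  res
}

#' Filter UCEs for broad conservation across all species
#'
#' Keeps elements for which at least `min_identity` of reference positions
#' have every species aligned, gap-free and identical to the reference --
#' the column-wise reading of "at least 95% sequence conservation".
#'
#' @param uces output of [scan_uces()].
#' @param pileup a [maf_pileup()].
#' @param genome named character vector of reference sequences.
#' @param all_species species that must all conform.
#' @param min_identity column-identity fraction required.
#' @return subset of `uces` with an added `identity` column.
#' @export
broad_conservation_filter <- function(uces, pileup, genome, all_species,
                                      min_identity = 0.95) {
  if (!nrow(uces)) return(cbind(uces, identity = numeric()))
  allsp <- setdiff(all_species, pileup$reference_species)
  ident <- numeric(nrow(uces))
  for (i in seq_len(nrow(uces))) {
    s <- uces$seq_id[i]
    idx <- (uces$start[i] + 1):uces$end[i]
    refcode <- encode_bases(seq_chars(subseq0(genome[[s]], uces$start[i],
                                              uces$end[i])))
    conform <- refcode >= 1L & refcode <= 4L
    for (sp in allsp) {
      conform <- conform & pileup$bases[[s]][sp, idx] == refcode
    }
    ident[i] <- mean(conform)
  }
  out <- uces[ident >= min_identity, , drop = FALSE]
  out$identity <- ident[ident >= min_identity]
  rownames(out) <- NULL
  out
}

interval_setdiff <- function(a, b) {
  a <- merge_intervals(a)
  if (!nrow(a)) return(a)
  b <- merge_intervals(b)
  out <- list()
  for (s in unique(a$seq_id)) {
    ra <- IRanges::IRanges(a$start[a$seq_id == s] + 1, a$end[a$seq_id == s])
    rb <- IRanges::IRanges(b$start[b$seq_id == s] + 1, b$end[b$seq_id == s])
    d <- IRanges::setdiff(ra, rb)
    if (length(d)) {
      out[[s]] <- data.frame(seq_id = s, start = IRanges::start(d) - 1,
                             end = IRanges::end(d), strand = ".",
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(intervals())
  sort_intervals(do.call(rbind, out))
}

#' Overlap between conserved elements and genomic site classes
#'
#' Per class (with intergenic split into short and long tracts at 250 bp):
#' bases overlapped by CEs, the percentage of all CE bases falling in the
#' class, the percentage of the class covered, and -- when a variant table
#' is supplied -- nucleotide diversity over all, CE and non-CE sites of the
#' class.
#'
#' @param ces interval data.frame of conserved elements.
#' @param class_map a [call_site_classes()] map.
#' @param variants optional [variant_table()].
#' @param genome optional genome (N discounting for pi).
#' @return data.frame, one row per class.
#' @export
ce_overlap_table <- function(ces, class_map, variants = NULL,
                             genome = NULL) {
  seqlen <- vapply(class_map$codes, length, numeric(1))
  bad <- ces$end > seqlen[ces$seq_id] | ces$start < 0 |
    !(ces$seq_id %in% names(seqlen))
  if (any(is.na(bad) | bad)) stop("CE outside genome bounds")
  ces <- merge_intervals(ces)
  total_ce <- sum(ces$end - ces$start)
  tracts <- extract_intergenic_tracts(class_map)
  class_iv <- list(
    CDS = class_intervals(class_map, "CDS"),
    UTR5 = class_intervals(class_map, "UTR5"),
    UTR3 = class_intervals(class_map, "UTR3"),
    intron = class_intervals(class_map, "intron"),
    intergenic_short = tracts[tracts$class == "short",
                              c("seq_id", "start", "end", "strand")],
    intergenic_long = tracts[tracts$class == "long",
                             c("seq_id", "start", "end", "strand")]
  )
  rows <- lapply(names(class_iv), function(cl) {
    iv <- class_iv[[cl]]
    size <- if (nrow(iv)) sum(iv$end - iv$start) else 0
    ov_iv <- interval_intersect(iv, ces)
    ov <- if (nrow(ov_iv)) sum(ov_iv$end - ov_iv$start) else 0
    row <- data.frame(
      class = cl, class_size = size, ce_overlap = ov,
      pct_of_ce = if (total_ce > 0) 100 * ov / total_ce else NA_real_,
      pct_of_class = if (size > 0) 100 * ov / size else NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(variants) && size > 0) {
      row$pi_all <- region_pi(iv, variants, genome, cl)$pi
      row$pi_ce <- if (nrow(ov_iv))
        region_pi(ov_iv, variants, genome, cl)$pi else NA_real_
      non <- interval_setdiff(iv, ces)
      row$pi_nonce <- if (nrow(non))
        region_pi(non, variants, genome, cl)$pi else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "total_ce_bases") <- total_ce
  out
}

per_interval_overlap <- function(df, ces) {
  ces <- merge_intervals(ces)
  ov <- numeric(nrow(df))
  for (s in unique(df$seq_id)) {
    sel <- which(df$seq_id == s)
    sub <- ces[ces$seq_id == s, , drop = FALSE]
    if (!nrow(sub)) next
    rq <- IRanges::IRanges(df$start[sel] + 1, df$end[sel])
    rs <- IRanges::IRanges(sub$start + 1, sub$end)
    hits <- IRanges::findOverlaps(rq, rs)
    if (!length(hits)) next
    w <- IRanges::width(IRanges::pintersect(
      rq[S4Vectors::queryHits(hits)], rs[S4Vectors::subjectHits(hits)]))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    ov[sel[as.integer(names(agg))]] <- agg
  }
  ov
}

#' Intron length versus conservation, in equal-count bins
#'
#' Introns are ordered by length (ties by genomic position) and divided
#' into `n_bins` contiguous groups whose sizes differ by at most one. Per
#' bin, the mean intron length and the fraction of intronic bases
#' overlapped by CEs are computed and the two per-bin vectors are tested
#' for Pearson correlation (two-sided). Also reported: the CE-overlap
#' contrast between introns shorter than `short_bp` and the rest, and an
#' independent-samples t-test of the relative transcript position of short
#' versus long introns.
#'
#' @param introns [intron_table()] output.
#' @param ces conserved-element intervals.
#' @param n_bins number of bins.
#' @param short_bp boundary defining short introns.
#' @return list: `bins` (data.frame), `pearson` (htest), `short_ce_frac`,
#'   `long_ce_frac`, `rel_pos_test` (htest or NULL).
#' @export
intron_ce_bins <- function(introns, ces, n_bins = 50, short_bp = 100) {
  n <- nrow(introns)
  if (n < n_bins) stop("fewer introns (", n, ") than bins (", n_bins, ")")
  ord <- order(introns$length, introns$seq_id, introns$start)
  introns <- introns[ord, , drop = FALSE]
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  bin <- rep(seq_len(n_bins), times = sizes)
  ov <- per_interval_overlap(introns, ces)
  bins <- data.frame(
    bin = seq_len(n_bins),
    n = sizes,
    mean_length = as.numeric(tapply(introns$length, bin, mean)),
    ce_fraction = as.numeric(tapply(ov, bin, sum) /
                               tapply(introns$length, bin, sum))
  )
  if (sd(bins$ce_fraction) == 0 || sd(bins$mean_length) == 0) {
    pear <- NULL
    warning("zero variance across bins; correlation undefined")
  } else {
    pear <- cor.test(bins$mean_length, bins$ce_fraction,
                     method = "pearson", alternative = "two.sided")
  }
  short <- introns$length < short_bp
  short_frac <- if (any(short)) sum(ov[short]) / sum(introns$length[short])
    else NA_real_
  long_frac <- if (any(!short)) sum(ov[!short]) / sum(introns$length[!short])
    else NA_real_
  rp <- NULL
  if ("rel_pos" %in% names(introns) && any(short) && any(!short)) {
    rp <- t.test(introns$rel_pos[short], introns$rel_pos[!short],
                 var.equal = FALSE)
  }
  list(bins = bins, pearson = pear, short_ce_frac = short_frac,
       long_ce_frac = long_frac, rel_pos_test = rp)
}
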