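#' Detect telomere-like tandem motifs at contig termini
#'
#' Scans both ends of each contig for tandem repeats of the motif. At the
#' contig end the motif is matched in any rotation (telomeric arrays rarely
#' start in phase); at the contig start the reverse complement's rotations
#' are matched, so a call set is strand-consistent: reverse-complementing a
#' contig swaps start and end calls exactly. A call requires at least
#' `min_copies` consecutive copies inside the terminal `window`, with the
#' array reaching within `max_gap` bases of the contig end.
#'
#' @param genome named character vector of contig sequences.
#' @param motif telomeric repeat unit (e.g. "TTTTAGGG").
#' @param window terminal window scanned, bp.
#' @param min_copies minimum tandem copies.
#' @param max_gap maximum distance between array and contig end.
#' @return data.frame `contig`, `end` ("start"/"end"), `kind = "motif"`,
#'   `family` (the motif), `copies`, `dist_to_end`.
#' @export
detect_terminal_motif <- function(genome, motif, window = 1000,
                                  min_copies = 2, max_gap = 100) {
  stopifnot(nchar(motif) >= 4)
  k <- nchar(motif)
  pat_end <- paste0("(?:", paste(motif_rotations(motif), collapse = "|"),
                    "){", min_copies, ",}")
  pat_start <- paste0("(?:",
                      paste(motif_rotations(revcomp(motif)), collapse = "|"),
                      "){", min_copies, ",}")
  rows <- list()
  for (ctg in names(genome)) {
    seq <- toupper(genome[[ctg]])
    L <- nchar(seq)
    w <- min(window, L)
    tail_seq <- substr(seq, L - w + 1, L)
    m <- gregexpr(pat_end, tail_seq, perl = TRUE)[[1]]
    if (m[1] != -1) {
      lens <- attr(m, "match.length")
      match_end <- m + lens - 1
      dist <- w - max(match_end)
      best <- which.max(match_end)
      if (dist <= max_gap) {
        rows[[length(rows) + 1]] <- data.frame(
          contig = ctg, end = "end", kind = "motif", family = motif,
          copies = lens[best] %/% k, dist_to_end = dist,
          stringsAsFactors = FALSE)
      }
    }
    head_seq <- substr(seq, 1, w)
    m <- gregexpr(pat_start, head_seq, perl = TRUE)[[1]]
    if (m[1] != -1) {
      lens <- attr(m, "match.length")
      dist <- min(m) - 1
      best <- which.min(m)
      if (dist <= max_gap) {
        rows[[length(rows) + 1]] <- data.frame(
          contig = ctg, end = "start", kind = "motif", family = motif,
          copies = lens[best] %/% k, dist_to_end = dist,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(), end = character(),
                      kind = character(), family = character(),
                      copies = integer(), dist_to_end = numeric()))
  }
  do.call(rbind, rows)
}

#' Detect annotated elements at contig termini
#'
#' Calls a contig end when an element of the given family overlaps its
#' first or last `terminal_window` bases (the rule used to associate
#' centromeric Zepp-like LINE clusters with syntenic contig breaks).
#'
#' @param annotations interval data.frame with a `family` column.
#' @param seq_lengths named numeric vector of contig lengths.
#' @param family element family to look for.
#' @param terminal_window bp from each end considered terminal.
#' @return data.frame `contig`, `end`, `kind = "annotated-element"`,
#'   `family`, `dist_to_end` (element edge to contig end).
#' @export
detect_terminal_feature <- function(annotations, seq_lengths, family,
                                    terminal_window = 20000) {
  ann <- annotations[annotations$family == family, , drop = FALSE]
  rows <- list()
  for (ctg in names(seq_lengths)) {
    L <- seq_lengths[[ctg]]
    sub <- ann[ann$seq_id == ctg, , drop = FALSE]
    if (!nrow(sub)) next
    at_start <- sub$start < terminal_window
    if (any(at_start)) {
      rows[[length(rows) + 1]] <- data.frame(
        contig = ctg, end = "start", kind = "annotated-element",
        family = family, dist_to_end = min(sub$start[at_start]),
        stringsAsFactors = FALSE)
    }
    at_end <- sub$end > L - terminal_window
    if (any(at_end)) {
      rows[[length(rows) + 1]] <- data.frame(
        contig = ctg, end = "end", kind = "annotated-element",
        family = family, dist_to_end = L - max(sub$end[at_end]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(contig = character(), end = character(),
                      kind = character(), family = character(),
                      dist_to_end = numeric()))
  }
  do.call(rbind, rows)
}

#' Windowed annotation density track
#'
#' Percentage of bases covered by the (merged) annotation in fixed windows
#' along each sequence; the last window may be short and its fraction uses
#' its true length.
#'
#' @param annotations interval data.frame.
#' @param seq_lengths named numeric vector of sequence lengths.
#' @param window window size in bp.
#' @return data.frame `seq_id`, `start`, `end`, `density` (0-100).
#' @export
window_density <- function(annotations, seq_lengths, window = 50000) {
  ann <- merge_intervals(annotations)
  rows <- list()
  for (s in names(seq_lengths)) {
    L <- seq_lengths[[s]]
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    wins <- data.frame(seq_id = s, start = starts, end = ends, strand = ".",
                       stringsAsFactors = FALSE)
    ov <- per_interval_overlap(wins, ann)
    rows[[s]] <- data.frame(seq_id = s, start = starts, end = ends,
                            density = 100 * ov / (ends - starts),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeat-overlap and integrity filters for gene models
#'
#' Per gene: the fraction of the spliced CDS covered by each repeat class,
#' and the filter flags used to purge repeat-derived gene models from an
#' annotation: `te_filter` when TEs/satellites cover at least 30% of the
#' CDS, `simple_filter` when low-complexity/simple repeats cover at least
#' 70%, `internal_stop`, and `short_protein` for proteins under 30 amino
#' acids.
#'
#' @param genes list of [gene_model()] objects.
#' @param repeats interval data.frame with a `class` column containing
#'   "TE" (TEs/satellites) or "simple" (low-complexity/simple).
#' @param genome named character vector of sequences.
#' @return data.frame of per-gene fractions and flags; `filtered` is the
#'   union of all flags.
#' @export
gene_repeat_filter <- function(genes, repeats, genome) {
  te <- repeats[repeats$class == "TE", , drop = FALSE]
  simple <- repeats[repeats$class == "simple", , drop = FALSE]
  rows <- lapply(genes, function(g) {
    cds_iv <- data.frame(seq_id = g$seq_id, start = g$cds$start,
                         end = g$cds$end, strand = ".",
                         stringsAsFactors = FALSE)
    len <- sum(cds_iv$end - cds_iv$start)
    te_f <- if (nrow(te)) sum(per_interval_overlap(cds_iv, te)) / len else 0
    si_f <- if (nrow(simple))
      sum(per_interval_overlap(cds_iv, simple)) / len else 0
    cds <- spliced_cds(g, genome)
    n <- nchar(cds)
    n_use <- n - n %% 3
    codons <- substring(cds, seq(1, n_use, 3), seq(3, n_use, 3))
    has_stop <- length(codons) > 1 &&
      any(codons[-length(codons)] %in% STOP_CODONS)
    aa_len <- n_use / 3 -
      (codons[length(codons)] %in% STOP_CODONS)
    data.frame(gene_id = g$gene_id, te_fraction = te_f,
               simple_fraction = si_f,
               te_filter = te_f >= 0.30, simple_filter = si_f >= 0.70,
               internal_stop = has_stop, short_protein = aa_len < 30,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$filtered <- out$te_filter | out$simple_filter | out$internal_stop |
    out$short_protein
  rownames(out) <- NULL
  out
}

#' Gene-family expansion/contraction calls from orthogroup counts
#'
#' For each orthogroup, the log2 ratio of the focal species' gene count to
#' the mean count over the other species. Ratios above 1 are expansions,
#' below -1 contractions. A zero mean with a positive focal count gives
#' +Inf (expansion); a zero focal count with a positive mean gives -Inf
#' (contraction); both zero gives `neither` and is flagged.
#'
#' @param counts data.frame or matrix: orthogroups x species gene counts
#'   (orthogroup ids as rownames or a `orthogroup` column).
#' @param focal_species focal species column name.
#' @return data.frame `orthogroup`, `focal`, `mean_others`, `log2_ratio`,
#'   `call`, `flagged`.
#' @export
family_log2_ratio <- function(counts, focal_species) {
  if (is.data.frame(counts) && "orthogroup" %in% names(counts)) {
    og <- counts$orthogroup
    counts <- as.matrix(counts[, setdiff(names(counts), "orthogroup"),
                               drop = FALSE])
    rownames(counts) <- og
  }
  others <- setdiff(colnames(counts), focal_species)
  if (length(others) < 2) stop("need at least 2 non-focal species")
  focal <- counts[, focal_species]
  mo <- rowMeans(counts[, others, drop = FALSE])
  ratio <- ifelse(focal > 0 & mo > 0, log2(focal / mo),
                  ifelse(focal > 0, Inf, ifelse(mo > 0, -Inf, NA)))
  call <- ifelse(is.na(ratio), "neither",
                 ifelse(ratio > 1, "expansion",
                        ifelse(ratio < -1, "contraction", "neither")))
  data.frame(orthogroup = rownames(counts), focal = focal,
             mean_others = mo, log2_ratio = ratio, call = call,
             flagged = focal == 0 & mo == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign functional domains to orthogroups
#'
#' A domain id is kept for an orthogroup when it is assigned to at least
#' `min_gene_frac` of the orthogroup's genes and occurs in at least
#' `min_species_frac` of the species represented in it.
#'
#' @param gene_domains data.frame `gene_id`, `domain`.
#' @param orthogroups data.frame `gene_id`, `orthogroup`, `species`.
#' @param min_gene_frac,min_species_frac the two fractions.
#' @return data.frame `orthogroup`, `domain`, `gene_frac`, `species_frac`.
#' @export
assign_domains_to_orthogroups <- function(gene_domains, orthogroups,
                                          min_gene_frac = 0.20,
                                          min_species_frac = 0.50) {
  merged <- merge(orthogroups, gene_domains, by = "gene_id")
  rows <- list()
  for (og in unique(orthogroups$orthogroup)) {
    og_genes <- orthogroups[orthogroups$orthogroup == og, , drop = FALSE]
    n_genes <- nrow(og_genes)
    n_species <- length(unique(og_genes$species))
    sub <- merged[merged$orthogroup == og, , drop = FALSE]
    if (!nrow(sub)) next
    for (dom in unique(sub$domain)) {
      hit <- sub[sub$domain == dom, , drop = FALSE]
      gf <- length(unique(hit$gene_id)) / n_genes
      sf <- length(unique(hit$species)) / n_species
      if (gf >= min_gene_frac && sf >= min_species_frac) {
        rows[[length(rows) + 1]] <- data.frame(
          orthogroup = og, domain = dom, gene_frac = gf, species_frac = sf,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(orthogroup = character(), domain = character(),
                      gene_frac = numeric(), species_frac = numeric()))
  }
  do.call(rbind, rows)
}
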