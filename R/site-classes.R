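SITE_CLASSES <- c("CDS", "UTR5", "UTR3", "intron", "intergenic")

#' Hierarchical site-class partition of a genome
#'
#' Every base receives exactly one class. When annotations overlap, the
#' highest-ranking class wins, with the fixed precedence CDS > 5'UTR > 3'UTR
#' > intron > intergenic; unannotated bases are intergenic. There is no
#' precedence between genes, only between classes.
#'
#' @param genes list of [gene_model()] objects.
#' @param genome named character vector of sequences (defines lengths).
#' @return object of class `site_class_map`: per-sequence integer vectors
#'   coding classes 1-5 in the order CDS, UTR5, UTR3, intron, intergenic.
#' @export
call_site_classes <- function(genes, genome) {
  codes <- lapply(genome, function(s) rep(5L, nchar(s)))
  paint <- function(codes, df, seq_id, code) {
    v <- codes[[seq_id]]
    for (i in seq_len(nrow(df))) {
      idx <- (df$start[i] + 1):df$end[i]
      v[idx] <- ifelse(code < v[idx], code, v[idx])
    }
    codes[[seq_id]] <- v
    codes
  }
  for (g in genes) {
    if (!g$seq_id %in% names(codes)) {
      stop("gene ", g$gene_id, " on unknown sequence ", g$seq_id)
    }
    intr <- gene_introns(g)
    if (nrow(intr)) codes <- paint(codes, intr, g$seq_id, 4L)
    if (nrow(g$utr3)) codes <- paint(codes, g$utr3, g$seq_id, 3L)
    if (nrow(g$utr5)) codes <- paint(codes, g$utr5, g$seq_id, 2L)
    codes <- paint(codes, g$cds, g$seq_id, 1L)
  }
  structure(list(codes = codes, levels = SITE_CLASSES),
            class = "site_class_map")
}

#' @export
print.site_class_map <- function(x, ...) {
  cat("<site_class_map>\n")
  print(class_lengths(x))
  invisible(x)
}

#' Total bases per site class
#' @param map a `site_class_map`.
#' @return named numeric vector over the five classes.
#' @export
class_lengths <- function(map) {
  counts <- rep(0, 5)
  for (v in map$codes) counts <- counts + tabulate(v, 5)
  setNames(counts, map$levels)
}

#' Intervals occupied by one site class
#' @param map a `site_class_map`.
#' @param class one of CDS, UTR5, UTR3, intron, intergenic.
#' @return interval data.frame of maximal runs.
#' @export
class_intervals <- function(map, class) {
  code <- match(class, map$levels)
  out <- list()
  for (s in names(map$codes)) {
    r <- rle(map$codes[[s]] == code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- r$values
    if (any(sel)) {
      out[[s]] <- data.frame(seq_id = s, start = starts[sel],
                             end = ends[sel], strand = ".",
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(intervals())
  sort_intervals(do.call(rbind, out))
}

#' Intergenic tracts with the short/long split
#'
#' Maximal intergenic runs per sequence, labelled `short` (< 250 bp) or
#' `long` (>= 250 bp). Contig-terminal runs bound only one gene and are
#' flagged. Flanking gene ids are reported when a gene span abuts the tract.
#'
#' @param map a `site_class_map`.
#' @param genes optional gene list used to name flanking genes.
#' @param short_threshold boundary in bp (short is strictly below it).
#' @return data.frame of tracts with `length`, `class`, `terminal`,
#'   `left_gene`, `right_gene`.
#' @export
extract_intergenic_tracts <- function(map, genes = NULL,
                                      short_threshold = 250) {
  tr <- class_intervals(map, "intergenic")
  if (!nrow(tr)) return(tr)
  tr$length <- tr$end - tr$start
  tr$class <- ifelse(tr$length < short_threshold, "short", "long")
  seqlen <- vapply(map$codes, length, numeric(1))
  tr$terminal <- tr$start == 0 | tr$end == seqlen[tr$seq_id]
  tr$left_gene <- NA_character_
  tr$right_gene <- NA_character_
  if (!is.null(genes)) {
    spans <- do.call(rbind, lapply(genes, function(g) {
      cbind(gene_span(g), gene_id = g$gene_id)
    }))
    for (i in seq_len(nrow(tr))) {
      l <- spans$gene_id[spans$seq_id == tr$seq_id[i] &
                           spans$end == tr$start[i]]
      r <- spans$gene_id[spans$seq_id == tr$seq_id[i] &
                           spans$start == tr$end[i]]
      if (length(l)) tr$left_gene[i] <- l[1]
      if (length(r)) tr$right_gene[i] <- r[1]
    }
  }
  rownames(tr) <- NULL
  tr
}

#' Table of introns across gene models
#'
#' One record per intron of the supplied (longest-isoform) models. By
#' default only CDS-internal introns are reported (the convention used for
#' annotation metrics, avoiding artefacts of UTR annotation quality);
#' `cds_only = FALSE` reports all introns. The relative position is the
#' intron's start offset from the transcript 5' end divided by transcript
#' length, in percent; the first intron is the one nearest the transcript 5'
#' end in transcription order.
#'
#' @param genes list of [gene_model()] objects.
#' @param cds_only restrict to introns between CDS segments.
#' @return data.frame: `gene_id`, `seq_id`, `start`, `end`, `length`,
#'   `ordinal`, `first_intron`, `rel_pos`.
#' @export
intron_table <- function(genes, cds_only = TRUE) {
  rows <- lapply(genes, function(g) {
    intr <- gene_introns(g)
    if (!nrow(intr)) return(NULL)
    if (cds_only) {
      lo <- min(g$cds$start); hi <- max(g$cds$end)
      intr <- intr[intr$start >= lo & intr$end <= hi, , drop = FALSE]
      if (!nrow(intr)) return(NULL)
    }
    sp <- gene_span(g)
    tx_len <- sp$end - sp$start
    off <- if (g$strand == "+") intr$start - sp$start else sp$end - intr$end
    data.frame(gene_id = g$gene_id, seq_id = g$seq_id,
               start = intr$start, end = intr$end,
               length = intr$end - intr$start,
               ordinal = intr$ordinal,
               first_intron = intr$ordinal == 1L,
               rel_pos = 100 * off / tx_len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), seq_id = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      ordinal = integer(), first_intron = logical(),
                      rel_pos = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Annotation summary metrics
#'
#' Genome-level metrics of the kind used to compare annotations across
#' species: gene and UTR coverage (Mb and % of genome), mean intron number
#' per CDS, median CDS-internal intron length, median intergenic tract
#' length, and GC content over non-N bases.
#'
#' @param genes list of [gene_model()] objects.
#' @param genome named character vector of sequences.
#' @return one-row data.frame of metrics.
#' @export
summarize_annotation <- function(genes, genome) {
  genome_len <- sum(nchar(genome))
  spans <- do.call(rbind, lapply(genes, gene_span))
  gene_cov <- if (is.null(spans)) 0 else interval_coverage(spans)
  utrs <- do.call(rbind, lapply(genes, function(g) {
    u <- rbind(g$utr5, g$utr3)
    if (!nrow(u)) return(NULL)
    data.frame(seq_id = g$seq_id, start = u$start, end = u$end, strand = ".",
               stringsAsFactors = FALSE)
  }))
  utr_cov <- if (is.null(utrs)) 0 else interval_coverage(utrs)
  intr <- intron_table(genes, cds_only = TRUE)
  n_genes <- length(genes)
  map <- call_site_classes(genes, genome)
  tracts <- extract_intergenic_tracts(map)
  data.frame(
    n_genes = n_genes,
    gene_coverage_mb = gene_cov / 1e6,
    gene_coverage_pct = 100 * gene_cov / genome_len,
    utr_coverage_mb = utr_cov / 1e6,
    utr_coverage_pct = 100 * utr_cov / genome_len,
    mean_intron_number = nrow(intr) / n_genes,
    median_intron_length = if (nrow(intr)) median(intr$length) else NA_real_,
    median_intergenic_distance = if (nrow(tracts)) median(tracts$length)
      else NA_real_,
    gc_pct = 100 * gc_fraction(paste(genome, collapse = ""))
  )
}
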