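#' Read gene models from GFF3
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention at this boundary. When `longest_isoform_only` is set,
#' exactly one transcript is retained per gene: the one with the longest
#' spliced CDS, ties broken by the lexicographically smallest transcript id.
#' UTR intervals are taken from `five_prime_UTR`/`three_prime_UTR` features
#' when present and otherwise inferred as exon minus CDS span, oriented by
#' strand. A missing CDS phase is computed from the running CDS length with a
#' warning.
#'
#' @param path GFF3 file (optionally gzipped).
#' @param longest_isoform_only keep one transcript per gene.
#' @return list of [gene_model()] objects.
#' @export
read_gff3_models <- function(path, longest_isoform_only = FALSE) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  id <- as.character(md$ID)
  parent <- vapply(as.list(md$Parent), function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  is_tx <- typ %in% c("mRNA", "transcript")
  tx_ids <- id[is_tx]
  tx_gene <- parent[is_tx]
  tx_gene[is.na(tx_gene)] <- tx_ids[is.na(tx_gene)]
  names(tx_gene) <- tx_ids
  models <- vector("list", length(tx_ids))
  names(models) <- tx_ids
  starts <- GenomicRanges::start(gr) - 1   # to 0-based half-open
  ends <- GenomicRanges::end(gr)
  seqs <- as.character(GenomicRanges::seqnames(gr))
  strands <- as.character(GenomicRanges::strand(gr))
  phase <- if ("phase" %in% names(md)) as.integer(md$phase) else
    rep(NA_integer_, length(gr))
  for (tid in tx_ids) {
    sel <- which(parent == tid)
    sub_typ <- typ[sel]
    ex <- sel[sub_typ == "exon"]
    cd <- sel[sub_typ == "CDS"]
    if (!length(cd)) next
    if (!length(ex)) ex <- cd  # CDS-only annotations
    strand <- strands[cd[1]]
    exons <- data.frame(start = starts[ex], end = ends[ex])
    exons <- exons[order(exons$start), , drop = FALSE]
    cds <- data.frame(start = starts[cd], end = ends[cd], phase = phase[cd])
    cds <- cds[order(cds$start), , drop = FALSE]
    if (anyNA(cds$phase)) {
      warning("missing CDS phase for ", tid, "; computed from running length")
      cds$phase <- running_phase(cds, strand)
    }
    u5 <- sel[sub_typ == "five_prime_UTR"]
    u3 <- sel[sub_typ == "three_prime_UTR"]
    if (length(u5) || length(u3)) {
      utr5 <- data.frame(start = starts[u5], end = ends[u5])
      utr3 <- data.frame(start = starts[u3], end = ends[u3])
    } else {
      inf <- infer_utrs(exons, cds, strand)
      utr5 <- inf$utr5; utr3 <- inf$utr3
    }
    models[[tid]] <- gene_model(
      gene_id = tx_gene[[tid]], transcript_id = tid, seq_id = seqs[cd[1]],
      strand = strand, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3
    )
  }
  models <- Filter(Negate(is.null), models)
  if (longest_isoform_only) {
    genes <- vapply(models, function(m) m$gene_id, character(1))
    lens <- vapply(models, cds_length, numeric(1))
    tids <- vapply(models, function(m) m$transcript_id, character(1))
    keep <- unlist(lapply(split(seq_along(models), genes), function(ix) {
      best <- ix[lens[ix] == max(lens[ix])]
      best[order(tids[best])][1]
    }))
    models <- models[sort(keep)]
  }
  unname(models)
}

running_phase <- function(cds, strand) {
  ord <- if (strand == "+") order(cds$start) else
    order(cds$start, decreasing = TRUE)
  lens <- (cds$end - cds$start)[ord]
  ph <- integer(length(lens))
  acc <- 0
  for (i in seq_along(lens)) {
    ph[i] <- (3 - acc %% 3) %% 3
    acc <- acc + lens[i]
  }
  out <- integer(length(lens))
  out[ord] <- ph
  out
}

infer_utrs <- function(exons, cds, strand) {
  cds_lo <- min(cds$start); cds_hi <- max(cds$end)
  left <- list(); right <- list()
  for (i in seq_len(nrow(exons))) {
    s <- exons$start[i]; e <- exons$end[i]
    if (s < cds_lo) left[[length(left) + 1]] <-
        data.frame(start = s, end = min(e, cds_lo))
    if (e > cds_hi) right[[length(right) + 1]] <-
        data.frame(start = max(s, cds_hi), end = e)
  }
  left <- if (length(left)) do.call(rbind, left) else
    data.frame(start = numeric(), end = numeric())
  right <- if (length(right)) do.call(rbind, right) else
    data.frame(start = numeric(), end = numeric())
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

#' Write gene models as GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' inclusive GFF3 convention, so a read/write round trip preserves
#' coordinates bit-exactly.
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @export
write_gff3_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(seq, type, s0, e0, strand, phase, attrs) {
    sprintf("%s\tchlamycomp\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            seq, type, as.integer(s0 + 1), as.integer(e0), strand,
            phase, attrs)
  }
  for (m in models) {
    sp <- gene_span(m)
    writeLines(fmt(m$seq_id, "gene", sp$start, sp$end, m$strand, ".",
                   paste0("ID=", m$gene_id)), con)
    writeLines(fmt(m$seq_id, "mRNA", sp$start, sp$end, m$strand, ".",
                   paste0("ID=", m$transcript_id, ";Parent=", m$gene_id)),
               con)
    for (i in seq_len(nrow(m$exons))) {
      writeLines(fmt(m$seq_id, "exon", m$exons$start[i], m$exons$end[i],
                     m$strand, ".", paste0("Parent=", m$transcript_id)), con)
    }
    for (i in seq_len(nrow(m$cds))) {
      writeLines(fmt(m$seq_id, "CDS", m$cds$start[i], m$cds$end[i],
                     m$strand, m$cds$phase[i],
                     paste0("Parent=", m$transcript_id)), con)
    }
    for (i in seq_len(nrow(m$utr5))) {
      writeLines(fmt(m$seq_id, "five_prime_UTR", m$utr5$start[i],
                     m$utr5$end[i], m$strand, ".",
                     paste0("Parent=", m$transcript_id)), con)
    }
    for (i in seq_len(nrow(m$utr3))) {
      writeLines(fmt(m$seq_id, "three_prime_UTR", m$utr3$start[i],
                     m$utr3$end[i], m$strand, ".",
                     paste0("Parent=", m$transcript_id)), con)
    }
  }
  invisible(path)
}
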