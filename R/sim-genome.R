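#' Specification of a synthetic genome
#'
#' Defaults emulate the architecture of a compact, GC-rich unicellular
#' green-algal genome: high intron numbers per gene (mean ~8 exons), an
#' atypical intron-length distribution with a small short (<100 bp)
#' component and a lognormal body with median ~230 bp, short intergenic
#' tracts (median near 134 bp, split short/long at 250 bp),
#' Chlamydomonas-type telomeric repeats at contig termini, and a clustered
#' Zepp-like LINE family marking a centromere-like locus per contig. A
#' fraction of genes is planted as spurious models whose evidence profile
#' the audit pipeline should flag.
#'
#' @param ... overrides for the default fields (see source for the full
#'   list).
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(...) {
  spec <- list(
    n_seqs = 2, seq_length = 1e6, gc = 0.64,
    n_genes = 300, spurious_fraction = 0.25,
    mean_introns = 7, spurious_mean_introns = 1.2,
    mean_codons = 420, spurious_mean_codons = 130,
    min_codons = 60, spurious_min_codons = 40,
    intron_short_weight = 0.05, intron_short_range = c(30, 99),
    intron_long_meanlog = log(230), intron_long_sdlog = 0.45,
    first_intron_short_bias = 0.6,
    utr5_meanlog = log(120), utr5_sdlog = 0.4,
    utr3_meanlog = log(300), utr3_sdlog = 0.4,
    intergenic_short_weight = 0.6, intergenic_short_range = c(30, 249),
    intergenic_long_meanlog = log(700), intergenic_long_sdlog = 0.6,
    minus_strand_prob = 0.5,
    telomere_motif = "TTTTAGGG", telomere_copies = 25,
    te_family = "ZeppL_like", te_cluster_n = 25,
    te_cluster_halfwidth = 30000, te_len_range = c(500, 3000),
    te_scatter_n = 40, simple_scatter_n = 30,
    scatter_len_range = c(100, 800),
    ortholog_prob = 0.85, domain_prob = 0.5, n_markers = 10
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown)) stop("unknown genome_spec field(s): ",
                            paste(unknown, collapse = ", "))
  spec[names(over)] <- over
  structure(spec, class = "genome_spec")
}

random_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# random composition of L into k parts, each >= min_len
split_len <- function(L, k, min_len) {
  stopifnot(L >= k * min_len)
  extra <- L - k * min_len
  w <- as.vector(stats::rmultinom(1, extra, rep(1, k)))
  min_len + w
}

draw_intron_lengths <- function(k, spec) {
  if (k == 0) return(numeric())
  short <- runif(k) < spec$intron_short_weight
  out <- numeric(k)
  out[short] <- sample(seq(spec$intron_short_range[1],
                           spec$intron_short_range[2]),
                       sum(short), replace = TRUE)
  out[!short] <- pmax(100, round(rlnorm(sum(!short),
                                        spec$intron_long_meanlog,
                                        spec$intron_long_sdlog)))
  # plant the first-intron enrichment: a short intron preferentially takes
  # ordinal 1
  out <- out[sample.int(k)]
  if (any(out < 100) && runif(1) < spec$first_intron_short_bias) {
    j <- which(out < 100)[1]
    out[c(1, j)] <- out[c(j, 1)]
  }
  out
}

draw_gap <- function(spec) {
  if (runif(1) < spec$intergenic_short_weight) {
    sample(seq(spec$intergenic_short_range[1],
               spec$intergenic_short_range[2]), 1)
  } else {
    max(250, round(rlnorm(1, spec$intergenic_long_meanlog,
                          spec$intergenic_long_sdlog)))
  }
}

# lay out one gene's structure in genomic coordinates
build_gene_structure <- function(gene_id, seq_id, start, strand, utr5_len,
                                 chunks, intron_lens, utr3_len) {
  segs_tx <- list(list(type = "utr5", len = utr5_len, idx = 0L))
  for (i in seq_along(chunks)) {
    segs_tx[[length(segs_tx) + 1]] <- list(type = "cds", len = chunks[i],
                                           idx = i)
    if (i <= length(intron_lens)) {
      segs_tx[[length(segs_tx) + 1]] <- list(type = "intron",
                                             len = intron_lens[i], idx = i)
    }
  }
  segs_tx[[length(segs_tx) + 1]] <- list(type = "utr3", len = utr3_len,
                                         idx = 0L)
  segs <- if (strand == "+") segs_tx else rev(segs_tx)
  cur <- start
  for (i in seq_along(segs)) {
    segs[[i]]$start <- cur
    segs[[i]]$end <- cur + segs[[i]]$len
    cur <- cur + segs[[i]]$len
  }
  cds <- Filter(function(s) s$type == "cds", segs)
  intr <- Filter(function(s) s$type == "intron", segs)
  # phases from running CDS length in transcription order
  cum <- c(0, cumsum(chunks))[seq_along(chunks)]
  phase_tx <- (3 - cum %% 3) %% 3
  cds_df <- data.frame(
    start = vapply(cds, `[[`, numeric(1), "start"),
    end = vapply(cds, `[[`, numeric(1), "end"),
    phase = phase_tx[vapply(cds, `[[`, integer(1), "idx")]
  )
  # exons: merge consecutive non-intron segments
  exon_rows <- list()
  cur_s <- NA
  for (s in segs) {
    if (s$type == "intron") {
      exon_rows[[length(exon_rows) + 1]] <- c(cur_s, s$start)
      cur_s <- s$end
    } else if (is.na(cur_s)) {
      cur_s <- s$start
    }
  }
  exon_rows[[length(exon_rows) + 1]] <- c(cur_s, cur)
  exons <- data.frame(start = vapply(exon_rows, `[`, numeric(1), 1),
                      end = vapply(exon_rows, `[`, numeric(1), 2))
  u5 <- Filter(function(s) s$type == "utr5", segs)[[1]]
  u3 <- Filter(function(s) s$type == "utr3", segs)[[1]]
  model <- gene_model(
    gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
    seq_id = seq_id, strand = strand, exons = exons, cds = cds_df,
    utr5 = data.frame(start = u5$start, end = u5$end),
    utr3 = data.frame(start = u3$start, end = u3$end)
  )
  list(model = model, span = c(start, cur),
       chunks = chunks,
       introns = data.frame(
         start = vapply(intr, `[[`, numeric(1), "start"),
         end = vapply(intr, `[[`, numeric(1), "end"),
         tx_idx = vapply(intr, `[[`, integer(1), "idx")))
}

#' Simulate a genome backbone with gene coordinates, repeats and telomeres
#'
#' Generates random GC-biased contig sequences, places gene structures
#' (drawn from the spec's exon/intron/UTR distributions) without overlap,
#' writes telomeric tandem arrays at contig termini, and places a clustered
#' TE family at a centromere-like midpoint plus scattered TE and
#' low-complexity repeats in intergenic gaps. Gene CDS content is written
#' later by [simulate_gene_sequences()]. The RNG is used as-is: seed once
#' in the caller for full determinism.
#'
#' @param spec a [genome_spec()].
#' @return list: `genome`, `models`, `structures`, `labels`, `repeats`
#'   (interval df with `family`, `class`), `telomeres`, `truth` fragments.
#' @export
simulate_genome <- function(spec = genome_spec()) {
  seq_ids <- paste0("chr", seq_len(spec$n_seqs))
  genome <- setNames(
    vapply(seq_ids, function(s) random_seq(spec$seq_length, spec$gc), ""),
    seq_ids)
  n_spur <- round(spec$n_genes * spec$spurious_fraction)
  labels <- rep("genuine", spec$n_genes)
  labels[sample.int(spec$n_genes, n_spur)] <- "spurious"
  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))

  # structural draws per gene
  draws <- lapply(seq_len(spec$n_genes), function(i) {
    spurious <- labels[i] == "spurious"
    n_intr <- rpois(1, if (spurious) spec$spurious_mean_introns else
      spec$mean_introns)
    n_cod <- max(if (spurious) spec$spurious_min_codons else
      spec$min_codons,
      round(rlnorm(1, log(if (spurious) spec$spurious_mean_codons else
        spec$mean_codons), 0.3)))
    cds_len <- 3 * n_cod
    # first/last chunks >= 12 bp so the Kozak window stays in one exon
    min_chunk <- 12
    if (cds_len < (n_intr + 1) * min_chunk) {
      n_intr <- max(0, cds_len %/% min_chunk - 1)
    }
    chunks <- split_len(cds_len, n_intr + 1, min_chunk)
    list(
      n_codons = n_cod,
      chunks = chunks,
      introns = draw_intron_lengths(n_intr, spec),
      utr5 = max(10, round(rlnorm(1, spec$utr5_meanlog, spec$utr5_sdlog))),
      utr3 = max(10, round(rlnorm(1, spec$utr3_meanlog, spec$utr3_sdlog))),
      strand = if (runif(1) < spec$minus_strand_prob) "-" else "+"
    )
  })

  tel_len <- spec$telomere_copies * nchar(spec$telomere_motif)
  margin <- tel_len + 200
  cen_lo <- spec$seq_length / 2 - spec$te_cluster_halfwidth
  cen_hi <- spec$seq_length / 2 + spec$te_cluster_halfwidth

  structures <- vector("list", spec$n_genes)
  gaps <- list()
  per_seq <- split(seq_len(spec$n_genes),
                   rep(seq_ids, length.out = spec$n_genes))
  for (s in seq_ids) {
    cursor <- margin
    prev_end <- margin
    for (gi in per_seq[[s]]) {
      gap <- draw_gap(spec)
      start <- cursor + gap
      if (start < cen_hi && start + 50000 > cen_lo) {
        gaps[[length(gaps) + 1]] <- data.frame(seq_id = s, start = prev_end,
                                               end = cen_lo)
        start <- cen_hi + gap
      }
      d <- draws[[gi]]
      st <- build_gene_structure(gene_ids[gi], s, start, d$strand,
                                 d$utr5, d$chunks, d$introns, d$utr3)
      if (st$span[2] > spec$seq_length - margin) {
        stop("gene packing infeasible: genes exceed sequence length")
      }
      structures[[gi]] <- st
      gaps[[length(gaps) + 1]] <- data.frame(seq_id = s, start = prev_end,
                                             end = start)
      prev_end <- st$span[2]
      cursor <- st$span[2]
    }
    gaps[[length(gaps) + 1]] <- data.frame(seq_id = s, start = prev_end,
                                           end = spec$seq_length - margin)
  }
  gaps <- do.call(rbind, gaps)
  gaps <- gaps[gaps$end - gaps$start > 0, , drop = FALSE]

  # telomeric arrays at contig termini
  telomeres <- list()
  for (s in seq_ids) {
    arr <- strrep(spec$telomere_motif, spec$telomere_copies)
    genome[[s]] <- write_at0(genome[[s]], nchar(genome[[s]]) - tel_len, arr)
    genome[[s]] <- write_at0(genome[[s]], 0, revcomp(arr))
    telomeres[[length(telomeres) + 1]] <-
      data.frame(contig = s, end = c("start", "end"),
                 stringsAsFactors = FALSE)
  }
  telomeres <- do.call(rbind, telomeres)

  # clustered TE family at centromere-like midpoint
  reps <- list()
  for (s in seq_ids) {
    starts <- sort(round(runif(spec$te_cluster_n, cen_lo, cen_hi - 3000)))
    lens <- round(runif(spec$te_cluster_n, spec$te_len_range[1],
                        spec$te_len_range[2]))
    reps[[length(reps) + 1]] <- data.frame(
      seq_id = s, start = starts, end = pmin(starts + lens, cen_hi),
      strand = ".", family = spec$te_family, class = "TE",
      stringsAsFactors = FALSE)
  }
  # scattered repeats in intergenic gaps
  big_gaps <- gaps[gaps$end - gaps$start >= 400, , drop = FALSE]
  scatter <- function(n, fam, cls) {
    if (!nrow(big_gaps) || n == 0) return(NULL)
    rows <- big_gaps[sample.int(nrow(big_gaps), n, replace = TRUE), ]
    lens <- round(runif(n, spec$scatter_len_range[1],
                        spec$scatter_len_range[2]))
    starts <- floor(rows$start + runif(n) *
                      pmax(1, (rows$end - rows$start - lens)))
    data.frame(seq_id = rows$seq_id, start = starts,
               end = pmin(starts + lens, rows$end), strand = ".",
               family = fam, class = cls, stringsAsFactors = FALSE)
  }
  reps[[length(reps) + 1]] <- scatter(spec$te_scatter_n, "TE_misc", "TE")
  reps[[length(reps) + 1]] <- scatter(spec$simple_scatter_n, "simple_rep",
                                      "simple")
  repeats <- do.call(rbind, Filter(Negate(is.null), reps))
  repeats <- repeats[repeats$end > repeats$start, , drop = FALSE]
  repeats <- repeats[order(repeats$seq_id, repeats$start), , drop = FALSE]
  rownames(repeats) <- NULL

  list(spec = spec, genome = genome,
       models = lapply(structures, `[[`, "model"),
       structures = structures,
       labels = setNames(labels, gene_ids), gene_ids = gene_ids,
       repeats = repeats, telomeres = telomeres, gaps = gaps,
       centromere = data.frame(seq_id = seq_ids, start = cen_lo,
                               end = cen_hi))
}
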