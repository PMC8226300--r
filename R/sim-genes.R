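#' Optimal codon set used by the biased synthetic regime
#'
#' One optimal codon per synonymous sub-family: the C-ending codon when the
#' sub-family has one, otherwise the G-ending one (GC-rich genomes prefer
#' G/C-ending codons), otherwise the lexicographically last codon.
#'
#' @param split use split six-fold sub-families.
#' @return data.frame `subfamily`, `codon`.
#' @export
optimal_codon_set <- function(split = TRUE) {
  fam <- codon_subfamilies(split)
  rows <- lapply(split(fam, fam$subfamily), function(d) {
    third <- substr(d$codon, 3, 3)
    pick <- if (any(third == "C")) d$codon[third == "C"][1] else
      if (any(third == "G")) d$codon[third == "G"][1] else
        sort(d$codon, decreasing = TRUE)[1]
    data.frame(subfamily = d$subfamily[1], codon = pick,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

draw_biased_cds <- function(n_codons, q_hi, optimal) {
  fam <- codon_subfamilies()
  aas <- unique(c(fam$aa, "M", "W"))
  aa_draw <- sample(aas, n_codons - 2, replace = TRUE)
  opt_by_sf <- setNames(optimal$codon, optimal$subfamily)
  cods <- vapply(aa_draw, function(a) {
    if (a == "M") return("ATG")
    if (a == "W") return("TGG")
    sub <- fam[fam$aa == a, , drop = FALSE]
    sf <- sample(unique(sub$subfamily), 1)
    cands <- sub$codon[sub$subfamily == sf]
    opt <- opt_by_sf[[sf]]
    if (runif(1) < q_hi) opt else sample(rep(setdiff(cands, opt), 2), 1)
  }, character(1))
  paste0("ATG", paste(cods, collapse = ""), sample(STOP_CODONS, 1))
}

draw_random_cds <- function(n_codons, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draw <- function(k) {
    m <- matrix(sample(BASES, 3 * k, replace = TRUE, prob = p), ncol = 3)
    paste0(m[, 1], m[, 2], m[, 3])
  }
  cods <- draw(n_codons - 2)
  while (any(cods %in% STOP_CODONS)) {
    ix <- cods %in% STOP_CODONS
    cods[ix] <- draw(sum(ix))
  }
  paste0("ATG", paste(cods, collapse = ""), sample(STOP_CODONS, 1))
}

#' Planted Kozak position model
#'
#' Per-site base frequencies with the consensus base at probability
#' `consensus_prob` and the rest uniform.
#'
#' @param consensus 10-base consensus (5 upstream + 5 downstream sites).
#' @param consensus_prob probability of the consensus base per site.
#' @return 4 x 10 frequency matrix (rows ACGT).
#' @export
planted_kozak_pwm <- function(consensus = c("C", "A", "A", "A", "C",
                                            "G", "C", "C", "G", "C"),
                              consensus_prob = 0.7) {
  freq <- matrix((1 - consensus_prob) / 3, nrow = 4, ncol = 10,
                 dimnames = list(BASES, as.character(KOZAK_SITES)))
  for (s in 1:10) freq[consensus[s], s] <- consensus_prob
  freq
}

draw_pwm_context <- function(freq) {
  paste(vapply(seq_len(ncol(freq)), function(s) {
    sample(BASES, 1, prob = freq[, s])
  }, character(1)), collapse = "")
}

write_cds_sequence <- function(seq, st, cds_str) {
  chunks <- st$chunks
  model <- st$model
  offs <- c(0, cumsum(chunks))
  cds_rows <- model$cds[order(model$cds$start), , drop = FALSE]
  tx_order <- if (model$strand == "+") seq_len(nrow(cds_rows)) else
    rev(seq_len(nrow(cds_rows)))
  for (k in seq_along(tx_order)) {
    row <- tx_order[k]
    part <- substr(cds_str, offs[k] + 1, offs[k + 1])
    if (model$strand == "-") part <- revcomp(part)
    seq <- write_at0(seq, cds_rows$start[row], part)
  }
  # canonical splice dinucleotides
  for (i in seq_len(nrow(st$introns))) {
    s0 <- st$introns$start[i]; e0 <- st$introns$end[i]
    if (model$strand == "+") {
      seq <- write_at0(seq, s0, "GT")
      seq <- write_at0(seq, e0 - 2, "AG")
    } else {
      seq <- write_at0(seq, s0, "CT")
      seq <- write_at0(seq, e0 - 2, "AC")
    }
  }
  seq
}

write_kozak_context <- function(seq, model, ctx) {
  cds <- model$cds[order(model$cds$start), , drop = FALSE]
  up <- substr(ctx, 1, 5); dn <- substr(ctx, 6, 10)
  if (model$strand == "+") {
    a <- cds$start[1]
    seq <- write_at0(seq, a - 5, up)
    seq <- write_at0(seq, a + 3, dn)
  } else {
    a_end <- cds$end[nrow(cds)]
    seq <- write_at0(seq, a_end, revcomp(up))
    seq <- write_at0(seq, a_end - 8, revcomp(dn))
  }
  seq
}

#' Write planted gene content into a simulated genome
#'
#' Genuine genes receive a CDS drawn from the biased codon regime
#' (sub-family-optimal codon probability `q_hi`), a start-codon context
#' drawn from the planted Kozak position model, positive per-exon
#' coding-potential score entries, and ortholog/domain table rows with the
#' spec's probabilities. Spurious genes receive GC-matched random ORFs,
#' random GC-matched contexts, zero-or-negative score entries, and no
#' ortholog/domain rows. Canonical splice dinucleotides are written at all
#' intron boundaries. The Kozak context overwrites two downstream codons;
#' contexts are redrawn if that would introduce a premature stop.
#'
#' @param sim output of [simulate_genome()].
#' @param q_hi optimal-codon probability of the biased regime.
#' @param kozak_pwm planted Kozak frequency matrix.
#' @return `sim` with updated `genome` plus `scores` (per-exon),
#'   `cds_scores`, `orthogroups`, `domains`, `markers`, `kozak_pwm`,
#'   `optimal_codons`.
#' @export
simulate_gene_sequences <- function(sim, q_hi = 0.8,
                                    kozak_pwm = planted_kozak_pwm()) {
  spec <- sim$spec
  optimal <- optimal_codon_set()
  genome <- sim$genome
  score_rows <- list()
  cds_rows <- list()
  ortho_rows <- list()
  dom_rows <- list()
  opt_frac <- setNames(rep(NA_real_, length(sim$gene_ids)), sim$gene_ids)
  for (gi in seq_along(sim$structures)) {
    st <- sim$structures[[gi]]
    gid <- sim$gene_ids[gi]
    label <- sim$labels[[gid]]
    n_cod <- sum(st$chunks) / 3
    cds_str <- if (label == "genuine") {
      draw_biased_cds(n_cod, q_hi, optimal)
    } else {
      draw_random_cds(n_cod, spec$gc)
    }
    cods <- substring(cds_str, seq(1, nchar(cds_str), 3),
                      seq(3, nchar(cds_str), 3))
    opt_frac[gid] <- mean(cods %in% optimal$codon)
    seq <- genome[[st$model$seq_id]]
    seq <- write_cds_sequence(seq, st, cds_str)
    # start-codon context; redraw if it creates a premature stop in the
    # overwritten downstream codons
    repeat {
      ctx <- if (label == "genuine") draw_pwm_context(kozak_pwm) else
        random_contexts(1, spec$gc)
      cod2 <- substr(ctx, 6, 8)
      cod3 <- paste0(substr(ctx, 9, 10), substr(cds_str, 9, 9))
      if (!(cod2 %in% STOP_CODONS) && !(cod3 %in% STOP_CODONS)) break
    }
    seq <- write_kozak_context(seq, st$model, ctx)
    genome[[st$model$seq_id]] <- seq
    # external coding-potential score entries
    k <- length(st$chunks)
    sc <- if (label == "genuine") rnorm(k, 15, 5) else
      ifelse(runif(k) < 0.5, 0, rnorm(k, -8, 3))
    score_rows[[gi]] <- data.frame(gene_id = gid, exon_index = seq_len(k),
                                   bp = st$chunks, score = round(sc, 3),
                                   stringsAsFactors = FALSE)
    cds_rows[[gi]] <- data.frame(
      gene_id = gid,
      score = round(if (label == "genuine") rnorm(1, 18, 6) else
        rnorm(1, -9, 4), 3),
      stringsAsFactors = FALSE)
    if (label == "genuine") {
      if (runif(1) < spec$ortholog_prob) {
        og <- paste0("OG", sprintf("%04d", gi))
        ortho_rows[[gi]] <- data.frame(
          gene_id = c(gid, paste0("cin_", gid)),
          orthogroup = og, species = c("cre", "cin"),
          stringsAsFactors = FALSE)
      }
      if (runif(1) < spec$domain_prob) {
        dom_rows[[gi]] <- data.frame(
          gene_id = gid, domain = paste0("IPR", sprintf("%05d",
                                                        sample.int(300, 1))),
          stringsAsFactors = FALSE)
      }
    }
  }
  genuine_ids <- sim$gene_ids[sim$labels == "genuine"]
  sim$genome <- genome
  sim$scores <- do.call(rbind, score_rows)
  sim$cds_scores <- do.call(rbind, cds_rows)
  sim$orthogroups <- do.call(rbind, Filter(Negate(is.null), ortho_rows))
  sim$domains <- do.call(rbind, Filter(Negate(is.null), dom_rows))
  # markers stand in for genes known to be highly expressed (ribosomal
  # proteins and the like), which in codon-usage terms are the most
  # strongly biased; pick the genuine genes with the highest realized
  # optimal-codon fraction so they sit at the adapted pole of CA axis 1
  ranked <- genuine_ids[order(opt_frac[genuine_ids], decreasing = TRUE)]
  sim$markers <- head(ranked, min(spec$n_markers, length(ranked)))
  sim$kozak_pwm <- kozak_pwm
  sim$optimal_codons <- optimal
  sim$q_hi <- q_hi
  sim
}
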