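#' Expected per-site pi of a segregating site under the neutral SFS
#'
#' With n haploid samples and derived-allele count i drawn with probability
#' proportional to 1/i (i = 1..n-1), the expected unbiased per-site
#' heterozygosity of a segregating site. Used to convert a per-site pi
#' target into a segregation probability.
#'
#' @param n number of haploid samples.
#' @return numeric expectation.
#' @export
expected_pi_segregating <- function(n) {
  i <- seq_len(n - 1)
  w <- (1 / i) / sum(1 / i)
  v <- (n / (n - 1)) * 2 * i * (n - i) / n^2
  sum(w * v)
}

#' Build the per-position pi target vector for a simulated genome
#'
#' Non-coding classes get the per-class targets directly (with conserved
#' elements at `ce_pi_mult` of the class level before rescaling, so CE
#' sites are less diverse than non-CE sites within every class). Within
#' CDS, per-site relative levels follow degeneracy: 4D = 1, 0D = 0.2 for
#' genuine genes but 1 for spurious genes (their "0D" sites are not under
#' purifying selection), 2D/3D intermediate; high-impact sites are nearly
#' invariant in genuine genes and neutral in spurious ones. Each class is
#' then rescaled so its mean equals the class target exactly; the CDS
#' rescale preserves the planted 0.2 and 1.0 pi0D/pi4D ratios.
#'
#' @param sim simulated dataset (after [plant_conserved_elements()]).
#' @param class_targets named per-class pi targets.
#' @param ce_pi_mult CE diversity multiplier within non-CDS classes.
#' @return list: `targets` (per-seq numeric vectors), `class_targets`,
#'   `class_map`.
#' @export
build_pi_targets <- function(sim,
                             class_targets = c(CDS = 0.0144, UTR5 = 0.0189,
                                               UTR3 = 0.0205,
                                               intron = 0.0248,
                                               intergenic_short = 0.0229,
                                               intergenic_long = 0.0137),
                             ce_pi_mult = 0.6) {
  map <- call_site_classes(sim$models, sim$genome)
  tracts <- extract_intergenic_tracts(map)
  targets <- lapply(sim$genome, function(s) numeric(nchar(s)))
  fill <- function(targets, iv, value) {
    for (i in seq_len(nrow(iv))) {
      targets[[iv$seq_id[i]]][(iv$start[i] + 1):iv$end[i]] <- value
    }
    targets
  }
  targets <- fill(targets, class_intervals(map, "UTR5"),
                  class_targets[["UTR5"]])
  targets <- fill(targets, class_intervals(map, "UTR3"),
                  class_targets[["UTR3"]])
  targets <- fill(targets, class_intervals(map, "intron"),
                  class_targets[["intron"]])
  targets <- fill(targets, tracts[tracts$class == "short", , drop = FALSE],
                  class_targets[["intergenic_short"]])
  targets <- fill(targets, tracts[tracts$class == "long", , drop = FALSE],
                  class_targets[["intergenic_long"]])
  # damp CE sites within non-CDS classes, then rescale each non-CDS class
  # back to its exact target mean (CE < non-CE contrast preserved)
  for (i in seq_len(nrow(sim$ces))) {
    if (sim$ces$class[i] == "CDS") next
    s <- sim$ces$seq_id[i]
    idx <- (sim$ces$start[i] + 1):sim$ces$end[i]
    targets[[s]][idx] <- targets[[s]][idx] * ce_pi_mult
  }
  subtype <- lapply(names(targets), function(s) {
    sub <- map$levels[map$codes[[s]]]
    tr <- tracts[tracts$seq_id == s, , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      sub[(tr$start[i] + 1):tr$end[i]] <-
        paste0("intergenic_", tr$class[i])
    }
    sub
  })
  names(subtype) <- names(targets)
  for (cl in setdiff(names(class_targets), "CDS")) {
    num <- 0; tot <- 0
    for (s in names(targets)) {
      sel <- subtype[[s]] == cl
      num <- num + sum(targets[[s]][sel])
      tot <- tot + sum(sel)
    }
    if (tot == 0 || num == 0) next
    scale <- class_targets[[cl]] / (num / tot)
    for (s in names(targets)) {
      sel <- subtype[[s]] == cl
      targets[[s]][sel] <- targets[[s]][sel] * scale
    }
  }
  # CDS: relative levels by degeneracy and gene label, then one scale so
  # the CDS mean hits its target exactly (the scale preserves the planted
  # 0.2 and 1.0 pi0D/pi4D ratios); the scale is the absolute pi4D level
  rel <- c(`0` = NA, `2` = 0.5, `3` = 0.75, `4` = 1)
  deg_maps <- vector("list", length(sim$models))
  for (gi in seq_along(sim$models)) {
    g <- sim$models[[gi]]
    genuine <- sim$labels[[g$gene_id]] == "genuine"
    dm <- map_gene_degeneracy(g, sim$genome)
    deg_maps[[gi]] <- dm
    lv <- unname(rel[as.character(dm$fold)])
    lv[is.na(dm$fold)] <- 0.5
    lv[which(dm$fold == 0)] <- if (genuine) 0.2 else 1
    targets[[g$seq_id]][dm$pos + 1] <- lv
  }
  num <- 0; tot <- 0
  for (s in names(targets)) {
    sel <- subtype[[s]] == "CDS"
    num <- num + sum(targets[[s]][sel])
    tot <- tot + sum(sel)
  }
  pi4_abs <- class_targets[["CDS"]] / (num / tot)
  for (s in names(targets)) {
    sel <- subtype[[s]] == "CDS"
    targets[[s]][sel] <- targets[[s]][sel] * pi4_abs
  }
  # high-impact overrides in absolute units: nearly invariant in genuine
  # genes, neutral (4D-level) in spurious ones
  hi_genuine <- 0.001
  for (gi in seq_along(sim$models)) {
    g <- sim$models[[gi]]
    genuine <- sim$labels[[g$gene_id]] == "genuine"
    hi <- high_impact_sites(g, sim$genome)
    targets[[g$seq_id]][hi$pos + 1] <- if (genuine) hi_genuine else pi4_abs
  }
  list(targets = targets, class_targets = class_targets, class_map = map,
       tracts = tracts, pi4_abs = pi4_abs, hi_genuine = hi_genuine,
       deg_maps = deg_maps)
}

#' Simulate haploid population variants to per-site pi targets
#'
#' Every site segregates independently with probability target /
#' E[pi | segregating]; derived-allele counts follow the neutral frequency
#' spectrum (probability proportional to 1/i) and carriers are drawn
#' uniformly. The realized expectation of pi at each site is therefore its
#' target.
#'
#' @param genome named character vector of sequences.
#' @param targets per-seq numeric vectors of per-site pi targets.
#' @param n number of haploid samples.
#' @return list: `variants` (a [variant_table()]), `ref`, `alt` (per-site
#'   allele strings for VCF writing).
#' @export
simulate_variants <- function(genome, targets, n = 17) {
  epi <- expected_pi_segregating(n)
  max_t <- max(unlist(lapply(targets, max)))
  if (max_t / epi > 1) stop("unreachable pi target: ", max_t)
  samples <- sprintf("iso%02d", seq_len(n))
  i_prob <- (1 / seq_len(n - 1))
  seq_v <- character(0); pos_v <- numeric(0)
  ref_v <- character(0); alt_v <- character(0)
  gmat <- list()
  for (s in names(targets)) {
    t <- targets[[s]]
    p <- pmin(1, t / epi)
    seg <- which(runif(length(p)) < p)
    if (!length(seg)) next
    refb <- toupper(substring(genome[[s]], seg, seg))
    ok <- refb %in% BASES
    seg <- seg[ok]; refb <- refb[ok]
    k <- length(seg)
    altb <- vapply(refb, function(b) sample(setdiff(BASES, b), 1), "")
    counts <- sample.int(n - 1, k, replace = TRUE, prob = i_prob)
    g <- matrix("0", nrow = k, ncol = n)
    for (j in seq_len(k)) {
      g[j, sample.int(n, counts[j])] <- "1"
    }
    seq_v <- c(seq_v, rep(s, k))
    pos_v <- c(pos_v, seg - 1)
    ref_v <- c(ref_v, refb)
    alt_v <- c(alt_v, unname(altb))
    gmat[[s]] <- g
  }
  alleles <- if (length(gmat)) do.call(rbind, gmat) else
    matrix(character(0), ncol = n)
  colnames(alleles) <- samples
  list(variants = variant_table(seq_v, pos_v, alleles, samples),
       ref = ref_v, alt = alt_v)
}
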