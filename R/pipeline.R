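#' Run the full coding-potential audit
#'
#' Convenience orchestration of the audit pipeline over in-memory objects:
#' codon usage and correspondence analysis, reference-set selection and
#' codon adaptation scores, per-gene pi0D/pi4D ratios, per-gene aggregated
#' coding-potential scores, control/test partition, control-derived
#' thresholds, classification and the Kozak contrast (model trained on a
#' random half of the control set, scored against the held-out half, the
#' flagged genes and GC-matched random contexts).
#'
#' @param models list of [gene_model()] objects (longest isoforms).
#' @param genome named character vector of sequences.
#' @param variants a [variant_table()].
#' @param exon_scores data.frame `gene_id`, `exon_index`, `bp`, `score`.
#' @param cds_scores data.frame `gene_id`, `score` (whole-CDS fallback).
#' @param ortholog_genes,domain_genes gene id vectors for the partition.
#' @param markers marker gene ids for reference-set pole selection.
#' @param gc_random GC fraction for the random Kozak contexts.
#' @param n_random number of random contexts.
#' @return list with `evidence`, `config`, `calls`, `report`,
#'   `kozak_model`, `kozak_groups`, `weights`, `ca`, `reference_set`.
#' @export
run_coding_potential_audit <- function(models, genome, variants,
                                       exon_scores, cds_scores,
                                       ortholog_genes, domain_genes,
                                       markers = NULL, gc_random = 0.64,
                                       n_random = 10000) {
  ids <- vapply(models, function(m) m$gene_id, character(1))
  usage <- codon_usage(models, genome)
  ca <- correspondence_analysis(usage)
  ref_set <- select_reference_set(ca, 0.05, marker_genes = markers)
  bg <- setdiff(rownames(usage), ref_set)
  weights <- ite_weights(usage[ref_set, , drop = FALSE],
                         usage[bg, , drop = FALSE])
  ite <- ite_score(usage, weights)

  ratio <- do.call(rbind, lapply(models, function(m) {
    dm <- map_gene_degeneracy(m, genome)
    gene_pi_ratio(m, dm, variants, genome)
  }))

  agg <- vapply(ids, function(gid) {
    ex <- exon_scores[exon_scores$gene_id == gid, , drop = FALSE]
    cs <- cds_scores$score[cds_scores$gene_id == gid]
    aggregate_gene_score(ex, if (length(cs)) cs[1] else NA_real_)
  }, numeric(1))

  part <- partition_genes(ids, ortholog_genes, domain_genes)
  evidence <- data.frame(
    gene_id = ids, set = part$set, score = unname(agg),
    ratio = ratio$ratio[match(ids, ratio$gene_id)],
    ite = ite$ite[match(ids, ite$gene_id)],
    stringsAsFactors = FALSE)
  ctrl <- evidence[evidence$set == "control", , drop = FALSE]
  config <- derive_thresholds(ctrl$ratio, ctrl$ite)
  calls <- classify_coding_potential(evidence, config)

  # Kozak: train on a random half of the control set, score the rest
  ctx <- vapply(models, function(m) {
    as.character(kozak_context(m, genome))
  }, character(1))
  names(ctx) <- ids
  ctrl_ids <- ctrl$gene_id[!is.na(ctx[ctrl$gene_id])]
  half <- sample(ctrl_ids, floor(length(ctrl_ids) / 2))
  other_half <- setdiff(ctrl_ids, half)
  kmodel <- build_kozak_model(ctx[half])
  lcp_ids <- calls$gene_id[calls$category %in% c("lcp1", "lcp2")]
  lcp_ids <- lcp_ids[!is.na(ctx[lcp_ids])]
  kozak_groups <- list(
    lcp = if (length(lcp_ids)) kozak_score(kmodel, ctx[lcp_ids])
      else numeric(0),
    control_half = kozak_score(kmodel, ctx[other_half]),
    random = kozak_score(kmodel, random_contexts(n_random, gc_random))
  )
  evidence$kozak <- ifelse(is.na(ctx), NA,
                           kozak_score(kmodel, ifelse(is.na(ctx),
                                                      strrep("A", 10), ctx)))
  report <- audit_report(calls, evidence, kozak_groups)
  list(evidence = evidence, config = config, calls = calls,
       report = report, kozak_model = kmodel, kozak_groups = kozak_groups,
       weights = weights, ca = ca, reference_set = ref_set,
       ratios = ratio, usage = usage)
}

#' Run the conservation-landscape analysis over a MAF alignment
#'
#' Duplicate-filters the blocks, builds the reference-anchored pileup, and
#' computes per-class alignability, the 4D alignment columns, UCEs (with
#' the broad-conservation subset), the CE/site-class overlap table and the
#' intron-length conservation bins.
#'
#' @param blocks MAF blocks (from [read_maf()] or the generator).
#' @param models list of [gene_model()] objects.
#' @param genome named character vector of reference sequences.
#' @param ces conserved-element intervals (external caller's output).
#' @param reference_species reference species name.
#' @param trio_species strict species set for UCE scanning.
#' @param all_species full species set for the broad filter.
#' @param variants optional [variant_table()] for the pi columns.
#' @param n_bins intron bins.
#' @return list with `pileup`, `alignability`, `fourd`, `uces`,
#'   `deep_uces`, `ce_table`, `intron_bins`, `class_map`.
#' @export
run_conservation_analysis <- function(blocks, models, genome, ces,
                                      reference_species, trio_species,
                                      all_species = NULL, variants = NULL,
                                      n_bins = 50) {
  blocks <- lapply(blocks, filter_duplicates)
  seq_lengths <- setNames(nchar(genome), names(genome))
  pileup <- maf_pileup(blocks, reference_species, seq_lengths)
  if (is.null(all_species)) all_species <- pileup$species
  class_map <- call_site_classes(models, genome)
  alib <- alignability(pileup, class_map)
  fourd <- extract_4d_columns(pileup, models, genome)
  uces <- scan_uces(pileup, genome, trio_species)
  deep <- broad_conservation_filter(uces, pileup, genome, all_species)
  ce_table <- ce_overlap_table(ces, class_map, variants, genome)
  introns <- intron_table(models, cds_only = TRUE)
  bins <- if (nrow(introns) >= n_bins) {
    intron_ce_bins(introns, ces, n_bins = n_bins)
  } else NULL
  list(pileup = pileup, alignability = alib, fourd = fourd, uces = uces,
       deep_uces = deep, ce_table = ce_table, intron_bins = bins,
       class_map = class_map, introns = introns)
}
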