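#' Partition genes into control and test sets
#'
#' The control set contains genes with at least one ortholog in a related
#' species and/or an annotated functional domain; genes with neither form
#' the test set whose coding potential is audited.
#'
#' @param gene_ids character vector of gene ids.
#' @param ortholog_genes gene ids present in the orthogroup table.
#' @param domain_genes gene ids with at least one domain assignment.
#' @return data.frame `gene_id`, `has_ortholog`, `has_domain`, `set`.
#' @export
partition_genes <- function(gene_ids, ortholog_genes, domain_genes) {
  has_o <- gene_ids %in% ortholog_genes
  has_d <- gene_ids %in% domain_genes
  n_absent <- sum(!has_o & !has_d)
  if (n_absent) {
    message(n_absent, " gene(s) absent from both evidence tables -> test set")
  }
  data.frame(gene_id = gene_ids, has_ortholog = has_o, has_domain = has_d,
             set = ifelse(has_o | has_d, "control", "test"),
             stringsAsFactors = FALSE)
}

#' Aggregate per-exon coding-potential scores to a per-gene score
#'
#' The per-gene score is the highest-scoring exon among exons of at least
#' `min_exon_bp` (localized misalignment can sink a whole-CDS score, so the
#' best exon is more robust); if no exon qualifies, the whole-CDS score is
#' used; if there is no alignment at all, the score is 0 by convention.
#'
#' @param exon_scores data.frame with `bp` and `score` per exon (may be
#'   empty or NULL).
#' @param cds_score whole-CDS fallback score (NA when no alignment).
#' @param min_exon_bp minimum exon length considered.
#' @return numeric per-gene score.
#' @export
aggregate_gene_score <- function(exon_scores, cds_score = NA_real_,
                                 min_exon_bp = 45) {
  if (!is.null(exon_scores) && nrow(exon_scores)) {
    ok <- exon_scores$bp >= min_exon_bp & !is.na(exon_scores$score)
    if (any(ok)) return(max(exon_scores$score[ok]))
  }
  if (!is.na(cds_score)) return(cds_score)
  0
}

#' Derive classification thresholds from the control distribution
#'
#' Thresholds are empirical percentiles (linear interpolation) of the
#' control set: the 95th percentile of pi0D/pi4D and the 5th percentile of
#' I_TE. They are always derived from the control distribution of the run
#' at hand, never hard-coded. Undefined ratios are excluded from the
#' percentile computation.
#'
#' @param control_ratio numeric pi0D/pi4D values of control genes (NA =
#'   undefined, dropped).
#' @param control_ite numeric I_TE values of control genes.
#' @param ratio_percentile,ite_percentile percentile settings.
#' @param score_cutoff the coding-potential score cutoff (genes below it
#'   fail the score test).
#' @return list of class `classifier_config` with the derived thresholds.
#' @export
derive_thresholds <- function(control_ratio, control_ite,
                              ratio_percentile = 95, ite_percentile = 5,
                              score_cutoff = 1) {
  control_ratio <- control_ratio[!is.na(control_ratio)]
  control_ite <- control_ite[!is.na(control_ite)]
  if (length(control_ratio) < 20 || length(control_ite) < 20) {
    stop("control set too small (< 20 genes) to derive thresholds")
  }
  structure(list(
    score_cutoff = score_cutoff,
    ratio_percentile = ratio_percentile,
    ite_percentile = ite_percentile,
    ratio_threshold = unname(quantile(control_ratio, ratio_percentile / 100,
                                      type = 7)),
    ite_threshold = unname(quantile(control_ite, ite_percentile / 100,
                                    type = 7)),
    n_control_ratio = length(control_ratio),
    n_control_ite = length(control_ite)
  ), class = "classifier_config")
}

#' Classify genes by coding potential
#'
#' A gene fails the score test when its aggregated score is below the
#' cutoff (a score exactly at the cutoff passes); fails the diversity test
#' when pi0D/pi4D exceeds the control-derived threshold or could not be
#' calculated at all; fails the adaptation test when I_TE is below its
#' threshold (an undefined I_TE also fails, flagged). Test-set genes
#' failing all three are `lcp1` (low coding potential, strict); those
#' failing the score test plus exactly one other are `lcp2`. Control genes
#' are never labelled lcp regardless of their values.
#'
#' @param evidence data.frame with columns `gene_id`, `set`, `score`,
#'   `ratio` (NA = undefined), `ite` (NA = undefined).
#' @param config a `classifier_config` from [derive_thresholds()].
#' @return data.frame with per-test failure flags and `category` in
#'   `{lcp1, lcp2, other_fail, pass}`.
#' @export
classify_coding_potential <- function(evidence, config) {
  fail_score <- evidence$score < config$score_cutoff
  fail_ratio <- is.na(evidence$ratio) |
    evidence$ratio > config$ratio_threshold
  fail_ite <- is.na(evidence$ite) | evidence$ite < config$ite_threshold
  n_fail <- fail_score + fail_ratio + fail_ite
  is_test <- evidence$set == "test"
  category <- rep("pass", nrow(evidence))
  category[n_fail > 0] <- "other_fail"
  category[is_test & fail_score & n_fail == 3] <- "lcp1"
  category[is_test & fail_score & n_fail == 2] <- "lcp2"
  data.frame(gene_id = evidence$gene_id, set = evidence$set,
             fail_score = fail_score, fail_ratio = fail_ratio,
             fail_ite = fail_ite, category = category,
             stringsAsFactors = FALSE)
}

#' Summary report of a coding-potential audit
#'
#' Per-category counts and medians of the evidence axes, plus optional
#' Kozak-score distribution summaries contrasting the low-coding-potential
#' genes with the held-out control half and GC-matched random contexts.
#'
#' @param calls output of [classify_coding_potential()].
#' @param evidence the evidence data.frame used for classification
#'   (optionally with `orf_bp`, `n_exons`, `gc3`, `kozak`).
#' @param kozak_groups optional named list of numeric Kozak score vectors
#'   (e.g. lcp / control_half / random) summarised side by side.
#' @return list with `category_summary` (data.frame) and
#'   `kozak_summary` (data.frame or NULL).
#' @export
audit_report <- function(calls, evidence, kozak_groups = NULL) {
  df <- merge(calls, evidence, by = c("gene_id", "set"))
  med <- function(x) if (length(x)) median(x, na.rm = TRUE) else NA_real_
  cats <- c("lcp1", "lcp2", "other_fail", "pass")
  rows <- lapply(cats, function(cat) {
    sub <- df[df$category == cat, , drop = FALSE]
    data.frame(category = cat, n = nrow(sub),
               median_score = med(sub$score),
               median_ratio = med(sub$ratio),
               median_ite = med(sub$ite),
               mean_orf_bp = if ("orf_bp" %in% names(sub))
                 mean(sub$orf_bp, na.rm = TRUE) else NA_real_,
               mean_n_exons = if ("n_exons" %in% names(sub))
                 mean(sub$n_exons, na.rm = TRUE) else NA_real_,
               mean_gc3 = if ("gc3" %in% names(sub))
                 mean(sub$gc3, na.rm = TRUE) else NA_real_,
               median_kozak = if ("kozak" %in% names(sub))
                 med(sub$kozak) else NA_real_)
  })
  ks <- NULL
  if (!is.null(kozak_groups)) {
    ks <- do.call(rbind, lapply(names(kozak_groups), function(g) {
      x <- kozak_groups[[g]]
      data.frame(group = g, n = length(x), mean = mean(x),
                 median = median(x), sd = sd(x))
    }))
  }
  list(category_summary = do.call(rbind, rows), kozak_summary = ks)
}
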