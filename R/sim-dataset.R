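#' Ground-truth 4D alignment columns of a simulated dataset
#'
#' Computed directly from the generator's internal alignment matrices (not
#' from the MAF), applying the extraction rules by construction: a
#' reference third-position 4D site is in the truth set when no species
#' has a deletion in the codon's three columns, the codon does not
#' straddle a block boundary, and every species' triplet is 4D at the
#' third position on the gene's coding strand.
#'
#' @param sim simulated dataset after [simulate_alignment()].
#' @return data.frame `seq_id`, `pos`, `gene_id`.
#' @export
truth_4d_sites <- function(sim) {
  comp <- c(`1` = 4L, `2` = 3L, `3` = 2L, `4` = 1L)
  block_cols <- sim$aspec$block_cols
  rows <- list()
  for (g in sim$models) {
    cds <- spliced_cds(g, sim$genome)
    pos <- cds_genomic_positions(g)
    n_use <- nchar(cds) - (nchar(cds) %% 3)
    if (n_use < 3) next
    codons <- substring(cds, seq(1, n_use, 3), seq(3, n_use, 3))
    fold3 <- classify_codon_degeneracy(codons, 3L)
    mat <- sim$aln[[g$seq_id]]
    for (k in which(!is.na(fold3) & fold3 == 4L)) {
      p <- pos[(3 * k - 2):(3 * k)]
      if (length(unique(p %/% block_cols)) != 1L) next
      trip <- mat[, p + 1, drop = FALSE]
      if (anyNA(trip)) next
      if (g$strand == "-") trip[] <- comp[as.character(trip)]
      cod_str <- apply(trip, 1, function(r) paste(BASES[r], collapse = ""))
      if (any(classify_codon_degeneracy(cod_str, 3L) != 4L)) next
      rows[[length(rows) + 1L]] <- data.frame(
        seq_id = g$seq_id, pos = p[3], gene_id = g$gene_id,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(seq_id = character(), pos = numeric(),
                      gene_id = character()))
  }
  do.call(rbind, rows)
}

#' Per-species gene counts for the simulated orthogroups
#'
#' Expands the focal orthogroup table into a six-species count matrix for
#' the gene-family screen: the focal species contributes its one gene per
#' orthogroup; each other species carries 1 gene usually, occasionally 0
#' (loss) or 2 (duplication).
#'
#' @param sim simulated dataset carrying `orthogroups`.
#' @param species non-focal species names.
#' @param probs probabilities of 0, 1 and 2 copies per other species.
#' @return data.frame `orthogroup` plus one count column per species.
#' @export
simulate_orthogroup_counts <- function(sim,
                                       species = c("cin", "csc", "ede",
                                                   "gpe", "vca"),
                                       probs = c(0.05, 0.85, 0.10)) {
  ogs <- sort(unique(sim$orthogroups$orthogroup))
  out <- data.frame(orthogroup = ogs, cre = 1L)
  for (sp in species) {
    out[[sp]] <- sample(0:2, length(ogs), replace = TRUE, prob = probs)
  }
  out
}

#' Simulate a complete analysis-ready dataset
#'
#' Seeds the RNG once and runs the full generator chain: genome backbone,
#' gene content, conserved-element planting, multi-species alignment and
#' population variants. With `dir` set, every input file the analysis
#' pipeline consumes is written (FASTA, GFF3, BEDs, MAF, VCF, score and
#' evidence TSVs) together with a ground-truth manifest; outputs are
#' byte-identical across runs with the same spec and seed.
#'
#' @param seed integer seed controlling all randomness.
#' @param spec a [genome_spec()].
#' @param aspec an [alignment_spec()].
#' @param n_samples haploid sample count for the variant simulation.
#' @param q_hi optimal-codon probability of the biased regime.
#' @param dir optional output directory (created if needed).
#' @return the simulated dataset list (invisibly when `dir` is given),
#'   with `truth` summarising everything planted.
#' @export
simulate_dataset <- function(seed = 1, spec = genome_spec(),
                             aspec = alignment_spec(), n_samples = 17,
                             q_hi = 0.8, dir = NULL) {
  set.seed(seed)
  sim <- simulate_genome(spec)
  sim <- simulate_gene_sequences(sim, q_hi = q_hi)
  sim <- plant_conserved_elements(sim, aspec)
  sim <- simulate_alignment(sim, aspec)
  tg <- build_pi_targets(sim)
  sim$class_map <- tg$class_map
  sim$tracts <- tg$tracts
  sim$pi_targets <- tg$targets
  sim$class_pi_targets <- tg$class_targets
  vres <- simulate_variants(sim$genome, tg$targets, n = n_samples)
  sim$variants <- vres$variants
  sim$variant_ref <- vres$ref
  sim$variant_alt <- vres$alt
  sim$n_samples <- n_samples
  sim$og_counts <- simulate_orthogroup_counts(sim)
  sim$seed <- seed
  sim$truth <- list(
    seed = seed,
    labels = sim$labels,
    markers = sim$markers,
    class_pi_targets = as.list(tg$class_targets),
    ces = sim$ces, uces = sim$uces,
    optimal_codons = sim$optimal_codons,
    kozak_consensus = BASES[apply(sim$kozak_pwm, 2, which.max)],
    q_hi = q_hi,
    telomeres = sim$telomeres,
    te_family = spec$te_family,
    centromere = sim$centromere
  )
  if (!is.null(dir)) {
    write_dataset(sim, dir)
    return(invisible(sim))
  }
  sim
}

#' Write a simulated dataset to disk
#' @param sim output of [simulate_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$genome, p("genome.fa"))
  write_gff3_models(sim$models, p("genes.gff3"))
  reps <- sim$repeats
  reps$name <- reps$family
  reps$score <- 0
  write_bed(reps, p("repeats.bed"))
  ces <- sim$ces
  ces$name <- ces$class
  ces$score <- 0
  write_bed(ces, p("ces.bed"))
  write_maf(sim$blocks, p("alignment.maf"))
  write_vcf_haploid(sim$variants, sim$variant_ref, sim$variant_alt,
                    p("variants.vcf"))
  wt <- function(df, f) {
    write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(sim$scores, "scores.tsv")
  wt(sim$cds_scores, "cds_scores.tsv")
  wt(sim$orthogroups, "orthogroups.tsv")
  wt(sim$og_counts, "orthogroup_counts.tsv")
  wt(sim$domains, "domains.tsv")
  writeLines(sim$markers, p("markers.txt"))
  truth <- sim$truth
  truth$labels <- as.list(truth$labels)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}
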