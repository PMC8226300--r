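test_that("generated files are valid and round-trip through the readers", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  expect_equal(as.character(genome), as.character(sim$genome),
               ignore_attr = TRUE)
  models <- read_gff3_models(file.path(dir, "genes.gff3"),
                             longest_isoform_only = TRUE)
  expect_length(models, length(sim$models))
  m0 <- sim$models[[1]]
  mb <- models[[which(vapply(models, function(m) m$gene_id, "") ==
                        m0$gene_id)]]
  expect_equal(mb$cds$start, m0$cds$start)
  expect_equal(mb$exons$end, m0$exons$end)
  bed <- read_bed(file.path(dir, "repeats.bed"))
  expect_equal(nrow(bed), nrow(sim$repeats))
  blocks <- read_maf(file.path(dir, "alignment.maf"), "cre")
  expect_length(blocks, length(sim$blocks))
  expect_equal(blocks[[5]]$text, sim$blocks[[5]]$text)
  vt <- read_vcf_haploid(file.path(dir, "variants.vcf"))
  expect_equal(length(vt$pos), length(sim$variants$pos))
  expect_equal(vt$alleles[10, ], sim$variants$alleles[10, ])
})

test_that("generation is deterministic: same spec and seed, same bytes", {
  spec <- genome_spec(n_seqs = 1, seq_length = 2e5, n_genes = 15,
                      te_cluster_halfwidth = 5000, te_cluster_n = 5)
  aspec <- alignment_spec(n_uce = 3, n_deep_uce = 1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(seed = 123, spec = spec, aspec = aspec, dir = d1)
  simulate_dataset(seed = 123, spec = spec, aspec = aspec, dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
  # a different seed changes the genome
  d3 <- withr::local_tempdir()
  simulate_dataset(seed = 124, spec = spec, aspec = aspec, dir = d3)
  expect_false(unname(tools::md5sum(file.path(d1, "genome.fa"))) ==
                 unname(tools::md5sum(file.path(d3, "genome.fa"))))
})

test_that("planted gene labels are recovered from the evidence tables", {
  sim <- small_sim()
  p <- suppressMessages(partition_genes(
    sim$gene_ids, unique(sim$orthogroups$gene_id),
    unique(sim$domains$gene_id)))
  # every control gene is genuine by construction
  expect_true(all(sim$labels[p$gene_id[p$set == "control"]] == "genuine"))
  # every spurious gene lands in the test set
  expect_true(all(p$set[p$gene_id %in%
                          names(sim$labels)[sim$labels == "spurious"]] ==
                    "test"))
})

test_that("generated sequence composition matches the spec", {
  sim <- small_sim()
  gc <- gc_fraction(paste(sim$genome, collapse = ""))
  # CDS planting shifts composition slightly; stay within a percent or two
  expect_lt(abs(gc - sim$spec$gc), 0.02)
  expect_equal(sum(nchar(sim$genome)),
               sim$spec$n_seqs * sim$spec$seq_length)
  # telomere arrays present at contig termini
  tel <- detect_terminal_motif(sim$genome, sim$spec$telomere_motif)
  expect_equal(nrow(tel), 2 * sim$spec$n_seqs)
  # clustered TE family sits at the centromere-like midpoint
  fam <- sim$repeats[sim$repeats$family == sim$spec$te_family, ]
  expect_true(all(fam$start >= sim$centromere$start[1] &
                    fam$end <= sim$centromere$end[1] + 1))
})

test_that("planted structural distributions are expressed in the annotation", {
  sim <- default_sim()
  it <- intron_table(sim$models, cds_only = TRUE)
  # short introns are enriched at ordinal 1 (planted first-intron bias)
  short <- it$length < 100
  frac_first_short <- mean(it$first_intron[short])
  frac_first_long <- mean(it$first_intron[!short])
  expect_gt(frac_first_short, 2 * frac_first_long)
  # and sit closer to the transcript start
  expect_lt(mean(it$rel_pos[short]), mean(it$rel_pos[!short]))
  s <- summarize_annotation(sim$models, sim$genome)
  expect_gt(s$median_intron_length, 150)
  expect_lt(s$median_intron_length, 320)
  expect_gt(s$mean_intron_number, 4)
})

test_that("degenerate generator inputs are handled", {
  set.seed(9)
  sim0 <- simulate_genome(genome_spec(n_seqs = 1, seq_length = 1e5,
                                      n_genes = 0,
                                      te_cluster_halfwidth = 2000,
                                      te_cluster_n = 2))
  expect_length(sim0$models, 0)
  expect_equal(nchar(sim0$genome[[1]]), 1e5)
  # infeasible packing errors before writing
  expect_error(simulate_genome(genome_spec(n_seqs = 1, seq_length = 3e4,
                                           n_genes = 50)),
               "infeasible")
  # zero pi target gives an empty variant set
  v0 <- simulate_variants(c(chr = strrep("ACGT", 100)),
                          list(chr = rep(0, 400)), n = 4)
  expect_equal(length(v0$variants$pos), 0)
  # unreachable target errors
  expect_error(simulate_variants(c(chr = strrep("ACGT", 100)),
                                 list(chr = rep(0.9, 400)), n = 4),
               "unreachable")
})

test_that("zero-length branches give species identical to the reference", {
  set.seed(13)
  spec <- genome_spec(n_seqs = 1, seq_length = 2e5, n_genes = 15,
                      te_cluster_halfwidth = 5000, te_cluster_n = 5)
  tree0 <- paste0("(((cre:0,cin:0):0,csc:0):0,",
                  "(ede:0,(gpe:0,(yun:0,(eud:0,vca:0):0):0):0):0);")
  aspec <- alignment_spec(tree = tree0, n_uce = 3, n_deep_uce = 1,
                          deletion_rate = 0)
  sim <- simulate_genome(spec)
  sim <- simulate_gene_sequences(sim)
  sim <- plant_conserved_elements(sim, aspec)
  sim <- simulate_alignment(sim, aspec)
  mat <- sim$aln[[1]]
  refcodes <- mat["cre", ]
  # breaker columns flank the planted UCEs; everything else is identical
  breakers <- sort(c(sim$uces$start - 1, sim$uces$end)) + 1
  for (sp in rownames(mat)) {
    diff <- which(mat[sp, ] != refcodes)
    expect_true(all(diff %in% breakers), info = sp)
  }
  # every planted UCE is recovered inside a conforming run
  p <- maf_pileup(sim$blocks, "cre",
                  setNames(nchar(sim$genome), names(sim$genome)))
  u <- scan_uces(p, sim$genome, c("cre", "cin", "csc"))
  for (i in seq_len(nrow(sim$uces))) {
    expect_true(any(u$start <= sim$uces$start[i] &
                      u$end >= sim$uces$end[i]), info = paste("uce", i))
  }
})

test_that("neutral divergence to the nearest species matches HKY expectation", {
  sim <- small_sim()
  # 4D third positions of genuine genes evolve at rate 1; compare the
  # observed mismatch fraction to the HKY transition expectation
  mat <- sim$aln[[1]]
  tru <- truth_4d_sites(sim)
  # restrict to sites outside planted CEs/UCEs, which evolve at reduced rate
  constrained <- rbind(sim$ces[, c("seq_id", "start", "end", "strand")],
                       sim$uces[, c("seq_id", "start", "end", "strand")])
  in_ce <- chlamycomp:::positions_in_intervals(tru$seq_id, tru$pos,
                                               constrained)
  idx <- tru$pos[!in_ce] + 1
  obs <- mean(mat["cin", idx] != mat["cre", idx])
  P <- chlamycomp:::hky_pmat(0.34, sim$aspec$kappa, sim$aspec$gc)
  freqs <- c((1 - 0.64) / 2, 0.64 / 2, 0.64 / 2, (1 - 0.64) / 2)
  expected <- sum(freqs * (1 - diag(P)))
  se <- sqrt(expected * (1 - expected) / length(idx))
  expect_lt(abs(obs - expected), 4 * se + 0.02)
})

test_that("a maximally biased regime yields perfect adaptation scores", {
  set.seed(17)
  spec <- genome_spec(n_seqs = 1, seq_length = 3e5, n_genes = 25,
                      te_cluster_halfwidth = 5000, te_cluster_n = 5,
                      spurious_fraction = 0.3)
  sim <- simulate_genome(spec)
  sim <- simulate_gene_sequences(sim, q_hi = 1)
  usage <- codon_usage(sim$models, sim$genome)
  genuine <- names(sim$labels)[sim$labels == "genuine"]
  w <- suppressWarnings(ite_weights(
    usage[genuine, , drop = FALSE],
    usage[setdiff(rownames(usage), genuine), , drop = FALSE]))
  s <- ite_score(usage, w)
  got <- s$ite[s$gene_id %in% genuine]
  # the Kozak context overwrites two downstream codons, so allow a
  # near-one score driven by those few bases
  expect_true(all(got > 0.97))
  expect_gt(mean(got == 1), 0.5)
})
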