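# fixtures are built in code and cached for the test run

.fixture_cache <- new.env(parent = emptyenv())

# small dataset for unit-level recovery checks (one 0.4 Mb contig, 40 genes)
small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- simulate_dataset(
      seed = 7,
      spec = genome_spec(n_seqs = 1, seq_length = 4e5, n_genes = 40,
                         te_cluster_halfwidth = 8000, te_cluster_n = 10),
      aspec = alignment_spec(n_uce = 6, n_deep_uce = 2))
  }
  .fixture_cache$small
}

# the generator's default study conditions (2 x 1 Mb, 300 genes, 8 species)
default_sim <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- simulate_dataset(seed = 1)
  }
  .fixture_cache$default
}

default_audit <- function() {
  if (is.null(.fixture_cache$audit)) {
    sim <- default_sim()
    .fixture_cache$audit <- run_coding_potential_audit(
      sim$models, sim$genome, sim$variants, sim$scores, sim$cds_scores,
      unique(sim$orthogroups$gene_id), unique(sim$domains$gene_id),
      markers = sim$markers)
  }
  .fixture_cache$audit
}

default_conservation <- function() {
  if (is.null(.fixture_cache$cons)) {
    sim <- default_sim()
    .fixture_cache$cons <- run_conservation_analysis(
      sim$blocks, sim$models, sim$genome, sim$ces, "cre",
      c("cre", "cin", "csc"))
  }
  .fixture_cache$cons
}

# a simple two-exon plus-strand gene on a toy genome
toy_gene <- function(strand = "+") {
  # CDS: ATG GGC | TGC TAA split across two exons (junction inside codon 3)
  # layout (+): utr5 [0,5) exon1 CDS [5,12), intron [12,112), CDS [112,117),
  # utr3 [117,127)
  cds_str <- "ATGGGCTGCTAA"
  if (strand == "+") {
    genome <- c(chr = paste0("AACCA", substr(cds_str, 1, 7),
                             paste(rep("T", 25), collapse = ""), "GT",
                             paste(rep("C", 46), collapse = ""), "AG",
                             paste(rep("T", 25), collapse = ""),
                             substr(cds_str, 8, 12), "GGGGGGGGGG"))
    gene <- gene_model("gA", "gA.t1", "chr", "+",
                       exons = data.frame(start = c(0, 112),
                                          end = c(12, 127)),
                       cds = data.frame(start = c(5, 112),
                                        end = c(12, 117),
                                        phase = c(0, 2)),
                       utr5 = data.frame(start = 0, end = 5),
                       utr3 = data.frame(start = 117, end = 127))
  } else {
    plus <- paste0("AACCA", substr(cds_str, 1, 7),
                   paste(rep("T", 25), collapse = ""), "GT",
                   paste(rep("C", 46), collapse = ""), "AG",
                   paste(rep("T", 25), collapse = ""),
                   substr(cds_str, 8, 12), "GGGGGGGGGG")
    genome <- c(chr = revcomp(plus))
    L <- nchar(plus)
    flip <- function(s, e) c(L - e, L - s)
    ex1 <- flip(0, 12); ex2 <- flip(112, 127)
    cd1 <- flip(5, 12); cd2 <- flip(112, 117)
    gene <- gene_model("gA", "gA.t1", "chr", "-",
                       exons = data.frame(start = c(ex2[1], ex1[1]),
                                          end = c(ex2[2], ex1[2])),
                       cds = data.frame(start = c(cd2[1], cd1[1]),
                                        end = c(cd2[2], cd1[2]),
                                        phase = c(2, 0)),
                       utr5 = data.frame(start = L - 5, end = L),
                       utr3 = data.frame(start = L - 127, end = L - 117))
  }
  list(genome = genome, gene = gene)
}

# build a maf_pileup directly from a base matrix (species x positions,
# characters with "-" for unaligned), reference row named by ref
pileup_from_matrix <- function(mat, ref = "ref", seq_id = "chr",
                               block_id = NULL) {
  codes <- matrix(0L, nrow = nrow(mat), ncol = ncol(mat),
                  dimnames = list(rownames(mat), NULL))
  for (i in seq_len(nrow(mat))) {
    codes[i, ] <- chlamycomp:::encode_bases(mat[i, ])
  }
  structure(list(
    bases = setNames(list(codes), seq_id),
    block_id = setNames(list(block_id %||% rep(1L, ncol(mat))), seq_id),
    species = rownames(mat), reference_species = ref,
    n_multi_covered = 0L), class = "maf_pileup")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

make_variant_table <- function(seq_id, pos, alleles_list, samples) {
  m <- if (length(alleles_list)) do.call(rbind, alleles_list) else
    matrix(character(0), ncol = length(samples))
  colnames(m) <- samples
  variant_table(rep_len(seq_id, length(pos)), pos, m, samples)
}
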