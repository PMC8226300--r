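#!/usr/bin/env Rscript
# Conservation landscape over the whole-genome alignment: duplicate-filter
# MAF blocks, per-class alignability, 4D-site extraction, UCE scanning
# with the broad-conservation subset, CE/site-class overlap (Table-3
# style) and the intron-length conservation bins.

suppressMessages(library(chlamycomp))

d <- "results/dataset"
stopifnot(dir.exists(d))

genome <- read_fasta(file.path(d, "genome.fa"))
models <- read_gff3_models(file.path(d, "genes.gff3"),
                           longest_isoform_only = TRUE)
variants <- read_vcf_haploid(file.path(d, "variants.vcf"))
ces <- read_bed(file.path(d, "ces.bed"))
blocks <- read_maf(file.path(d, "alignment.maf"), "cre")

cons <- run_conservation_analysis(blocks, models, genome, ces,
                                  reference_species = "cre",
                                  trio_species = c("cre", "cin", "csc"),
                                  variants = variants)

wt <- function(df, f) write.table(df, file.path("results", f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)
wt(cons$alignability, "alignability.tsv")
wt(cons$ce_table, "ce_overlap_table.tsv")
wt(cons$uces, "uces.tsv")
wt(cons$deep_uces, "uces_deep.tsv")
wt(cons$fourd$sites, "fourd_sites.tsv")
wt(cons$intron_bins$bins, "intron_bins.tsv")
# the 4D alignment as a FASTA matrix for downstream model fitting
fourd_fa <- apply(cons$fourd$alignment, 1, paste, collapse = "")
write_fasta(fourd_fa, "results/fourd_alignment.fa")

cat("UCEs:", nrow(cons$uces), "(deeply conserved:",
    nrow(cons$deep_uces), ")\n")
cat("4D sites extracted:", nrow(cons$fourd$sites),
    "| dropped:", paste(names(cons$fourd$dropped),
                        cons$fourd$dropped, collapse = ", "), "\n")
cat("CE overlap by class (% of CE bases):\n")
print(cons$ce_table[, c("class", "ce_overlap", "pct_of_ce",
                        "pct_of_class", "pi_ce", "pi_nonce")],
      row.names = FALSE)
cat("intron bins: Pearson r =", round(cons$intron_bins$pearson$estimate, 3),
    ", p =", format(cons$intron_bins$pearson$p.value, digits = 3), "\n")
cat("CE fraction, introns <100 bp vs longer:",
    round(cons$intron_bins$short_ce_frac, 3), "vs",
    round(cons$intron_bins$long_ce_frac, 3), "\n")
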