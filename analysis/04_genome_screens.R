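#!/usr/bin/env Rscript
# Genome screens: telomeric repeat arrays at contig termini, terminal
# Zepp-like elements on centromere-split contigs, 50 kb TE density
# windows, repeat-overlap gene filtering and orthogroup domain/family
# summaries.

suppressMessages(library(chlamycomp))

d <- "results/dataset"
stopifnot(dir.exists(d))

genome <- read_fasta(file.path(d, "genome.fa"))
models <- read_gff3_models(file.path(d, "genes.gff3"),
                           longest_isoform_only = TRUE)
reps <- read_bed(file.path(d, "repeats.bed"))
reps$family <- reps$name
reps$class <- ifelse(reps$family == "simple_rep", "simple", "TE")
orthogroups <- read.delim(file.path(d, "orthogroups.tsv"))
domains <- read.delim(file.path(d, "domains.tsv"))
seq_lengths <- setNames(nchar(genome), names(genome))

tel <- detect_terminal_motif(genome, "TTTTAGGG")
cat("telomere calls:\n"); print(tel, row.names = FALSE)

# contigs of real assemblies break at centromeres; emulate by splitting
# each chromosome at its midpoint before the terminal-feature screen
split_reps <- list(); split_lens <- numeric()
for (s in names(genome)) {
  L <- seq_lengths[[s]]; mid <- floor(L / 2)
  r <- reps[reps$seq_id == s, , drop = FALSE]
  left <- r[r$end <= mid, , drop = FALSE]
  left$seq_id <- paste0(s, "_L")
  right <- r[r$start >= mid, , drop = FALSE]
  right$start <- right$start - mid
  right$end <- right$end - mid
  right$seq_id <- paste0(s, "_R")
  split_reps[[s]] <- rbind(left, right)
  split_lens[paste0(s, "_L")] <- mid
  split_lens[paste0(s, "_R")] <- L - mid
}
zeppl <- detect_terminal_feature(do.call(rbind, split_reps), split_lens,
                                 "ZeppL_like")
cat("\nZepp-like elements within 20 kb of split-contig ends:\n")
print(zeppl, row.names = FALSE)

wd <- window_density(reps[reps$family == "ZeppL_like", ], seq_lengths)
write.table(wd, "results/zeppl_density_50kb.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
peak <- wd[which.max(wd$density), ]
cat("\npeak Zepp-like 50 kb window density:", round(peak$density, 1),
    "% at", peak$seq_id, peak$start, "-", peak$end, "\n")

filt <- gene_repeat_filter(models, reps, genome)
write.table(filt, "results/gene_repeat_filter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ngenes flagged by repeat/integrity filters:", sum(filt$filtered),
    "of", nrow(filt), "\n")

dom_og <- assign_domains_to_orthogroups(
  domains, orthogroups[, c("gene_id", "orthogroup", "species")])
write.table(dom_og, "results/orthogroup_domains.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
counts <- read.delim(file.path(d, "orthogroup_counts.tsv"))
fam <- family_log2_ratio(counts, "cre")
write.table(fam, "results/family_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("orthogroup families:", nrow(fam),
    "| expansions:", sum(fam$call == "expansion"),
    "| contractions:", sum(fam$call == "contraction"), "\n")
cat("orthogroups with assigned domains:", nrow(dom_og), "\n")
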