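# independent brute-force degeneracy oracle built on seqinr's codon table
oracle_degeneracy <- function(codon, offset) {
  stops <- c("TAA", "TAG", "TGA")
  translate1 <- function(cod) {
    seqinr::translate(strsplit(cod, "")[[1]])
  }
  syn <- 0
  for (b in setdiff(c("A", "C", "G", "T"), substr(codon, offset, offset))) {
    mut <- codon
    substr(mut, offset, offset) <- b
    same <- if (codon %in% stops) mut %in% stops else
      (!(mut %in% stops)) && translate1(mut) == translate1(codon)
    if (same) syn <- syn + 1
  }
  c(0L, 2L, 3L, 4L)[syn + 1L]
}

test_that("codon degeneracy matches brute-force enumeration for all codons", {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  for (off in 1:3) {
    got <- classify_codon_degeneracy(codons, off)
    want <- vapply(codons, oracle_degeneracy, integer(1), offset = off)
    expect_equal(got, unname(want), info = paste("offset", off))
  }
  # exactly 32 sense codons are 4D at the third position
  sense <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  expect_equal(sum(classify_codon_degeneracy(sense, 3) == 4L), 32L)
})

test_that("degeneracy handles worked examples and ambiguity codes", {
  expect_equal(classify_codon_degeneracy("GGA", 3), 4L)
  expect_equal(classify_codon_degeneracy("ATG", 1), 0L)
  expect_equal(classify_codon_degeneracy("ATA", 3), 3L)  # ATT/ATC syn, ATG not
  expect_equal(classify_codon_degeneracy("TGA", 3), 0L)  # no stop preserved
  expect_true(is.na(classify_codon_degeneracy("ANA", 3)))
})

test_that("gene degeneracy maps are strand-aware and splice-aware", {
  genome <- c(chr = "ATGGGCTAAGGGGGGG")
  g <- gene_model("g", "g.t", "chr", "+",
                  exons = data.frame(start = 0, end = 9),
                  cds = data.frame(start = 0, end = 9, phase = 0))
  dm <- map_gene_degeneracy(g, genome)
  expect_equal(nrow(dm), 9)
  expect_equal(dm$fold[dm$pos == 5], 4L)  # GGC offset 3
  expect_equal(dm$codon[dm$pos == 5], "GGC")
  expect_false(attr(dm, "internal_stop"))

  # same CDS on the minus strand of the mirrored genome
  gm <- c(chr = revcomp(genome[["chr"]]))
  L <- nchar(genome[["chr"]])
  g2 <- gene_model("g", "g.t", "chr", "-",
                   exons = data.frame(start = L - 9, end = L),
                   cds = data.frame(start = L - 9, end = L, phase = 0))
  dm2 <- map_gene_degeneracy(g2, gm)
  expect_equal(spliced_cds(g2, gm), "ATGGGCTAA")
  # positions mirror: genomic position of the 4D site is L - 1 - 5
  expect_equal(dm2$fold[dm2$pos == L - 1 - 5], 4L)
  expect_equal(sort(dm$fold), sort(dm2$fold))

  # codon spanning an exon junction is classified from the spliced codon
  tg <- toy_gene("+")
  dmj <- map_gene_degeneracy(tg$gene, tg$genome)
  expect_equal(unique(dmj$codon[dmj$pos %in% c(11, 112, 113)]), "TGC")
  tgm <- toy_gene("-")
  expect_equal(spliced_cds(tgm$gene, tgm$genome),
               spliced_cds(tg$gene, tg$genome))
})

test_that("internal stops and incomplete CDS are flagged but still mapped", {
  genome <- c(chr = "ATGTAAGGCTAAGG")
  g <- gene_model("g", "g.t", "chr", "+",
                  exons = data.frame(start = 0, end = 12),
                  cds = data.frame(start = 0, end = 12, phase = 0))
  dm <- map_gene_degeneracy(g, genome)
  expect_true(attr(dm, "internal_stop"))
  expect_equal(nrow(dm), 12)
  g2 <- gene_model("g2", "g2.t", "chr", "+",
                   exons = data.frame(start = 0, end = 14),
                   cds = data.frame(start = 0, end = 14, phase = 0))
  dm2 <- map_gene_degeneracy(g2, genome)
  expect_true(attr(dm2, "incomplete"))
  expect_equal(nrow(dm2), 12)  # trailing partial codon unclassified
})

test_that("site classes follow the fixed hierarchy and partition the genome", {
  genome <- c(chr = strrep("A", 200))
  # gene A: CDS [50,80); gene B: exons [40,60)+[90,110) with intron [60,90)
  gA <- gene_model("gA", "gA.t", "chr", "+",
                   exons = data.frame(start = 50, end = 80),
                   cds = data.frame(start = 50, end = 80, phase = 0))
  gB <- gene_model("gB", "gB.t", "chr", "+",
                   exons = data.frame(start = c(40, 90), end = c(60, 110)),
                   cds = data.frame(start = c(40, 90), end = c(60, 110),
                                    phase = c(0, 0)))
  map <- call_site_classes(list(gA, gB), genome)
  # base 70: CDS of gA, intron of gB -> CDS wins
  expect_equal(map$levels[map$codes$chr[71]], "CDS")
  expect_equal(map$levels[map$codes$chr[85]], "intron")
  expect_equal(sum(class_lengths(map)), 200)

  # UTR5 of one gene beats UTR3 of another
  gC <- gene_model("gC", "gC.t", "chr", "+",
                   exons = data.frame(start = 120, end = 160),
                   cds = data.frame(start = 120, end = 150, phase = 0),
                   utr3 = data.frame(start = 150, end = 160))
  gD <- gene_model("gD", "gD.t", "chr", "+",
                   exons = data.frame(start = 155, end = 190),
                   cds = data.frame(start = 170, end = 185, phase = 0),
                   utr5 = data.frame(start = 155, end = 170))
  map2 <- call_site_classes(list(gC, gD), genome)
  expect_equal(map2$levels[map2$codes$chr[157]], "UTR5")

  # empty annotation: everything intergenic
  map3 <- call_site_classes(list(), genome)
  expect_equal(unname(class_lengths(map3)["intergenic"]), 200)
})

test_that("intergenic tracts tile the class and split at 250 bp", {
  genome <- c(chr = strrep("A", 1000))
  gA <- gene_model("gA", "gA.t", "chr", "+",
                   exons = data.frame(start = 100, end = 220),
                   cds = data.frame(start = 100, end = 220, phase = 0))
  gB <- gene_model("gB", "gB.t", "chr", "+",
                   exons = data.frame(start = 340, end = 400),
                   cds = data.frame(start = 340, end = 400, phase = 0))
  gC <- gene_model("gC", "gC.t", "chr", "+",
                   exons = data.frame(start = 650, end = 700),
                   cds = data.frame(start = 650, end = 700, phase = 0))
  map <- call_site_classes(list(gA, gB, gC), genome)
  tr <- extract_intergenic_tracts(map, genes = list(gA, gB, gC))
  expect_equal(sum(tr$length),
               unname(class_lengths(map)["intergenic"]))
  mid <- tr[tr$start == 220, ]
  expect_equal(mid$length, 120)
  expect_equal(mid$class, "short")
  expect_false(mid$terminal)
  expect_equal(mid$left_gene, "gA")
  expect_equal(mid$right_gene, "gB")
  # a 250 bp tract is long (threshold is < 250 for short)
  tr250 <- tr[tr$start == 400, ]
  expect_equal(tr250$length, 250)
  expect_equal(tr250$class, "long")
  expect_true(all(tr$terminal[tr$start == 0 | tr$end == 1000]))
})

test_that("intron table orders introns in transcription order", {
  genome <- c(chr = strrep("A", 300))
  g <- gene_model("g", "g.t", "chr", "-",
                  exons = data.frame(start = c(0, 150), end = c(50, 200)),
                  cds = data.frame(start = c(0, 150), end = c(50, 200),
                                   phase = c(1, 0)))
  it <- intron_table(list(g), cds_only = TRUE)
  expect_equal(nrow(it), 1)
  expect_equal(it$length, 100)
  # minus strand: the first intron is nearest the 3' genomic end
  expect_equal(it$ordinal, 1L)
  expect_true(it$first_intron)
  expect_equal(it$rel_pos, 100 * (200 - 150) / 200)

  gp <- gene_model("g2", "g2.t", "chr", "+",
                   exons = data.frame(start = c(0, 150), end = c(50, 200)),
                   cds = data.frame(start = c(0, 150), end = c(50, 200),
                                    phase = c(0, 1)))
  itp <- intron_table(list(gp))
  expect_equal(itp$length, 100)
  expect_equal(itp$rel_pos, 100 * 50 / 200)
})

test_that("high-impact sites follow stop-preservation and splice rules", {
  # intronless gene with stop TGA: 3 start + 2 stop positions
  genome <- c(chr = "ATGGGCTGAGGG")
  g <- gene_model("g", "g.t", "chr", "+",
                  exons = data.frame(start = 0, end = 9),
                  cds = data.frame(start = 0, end = 9, phase = 0))
  hi <- high_impact_sites(g, genome)
  expect_equal(nrow(hi), 5)
  expect_equal(hi$pos, c(0, 1, 2, 6, 8))  # TGA: positions 1 and 3

  # two-exon gene with stop TAA: 3 + 1 + 4 positions
  tg <- toy_gene("+")
  hi2 <- high_impact_sites(tg$gene, tg$genome)
  expect_equal(nrow(hi2), 3 + 1 + 4)
  expect_true(all(c(12, 13, 110, 111) %in% hi2$pos))  # intron termini

  # TAG stop: positions 1 and 2 are zero-fold
  genome3 <- c(chr = "ATGGGCTAGGGG")
  g3 <- gene_model("g3", "g3.t", "chr", "+",
                   exons = data.frame(start = 0, end = 9),
                   cds = data.frame(start = 0, end = 9, phase = 0))
  expect_equal(high_impact_sites(g3, genome3)$pos, c(0, 1, 2, 6, 7))
})

test_that("annotation summary computes coverage and GC correctly", {
  genome <- c(chr = paste0(strrep("G", 500), strrep("A", 9500)))
  g <- gene_model("g", "g.t", "chr", "+",
                  exons = data.frame(start = 1000, end = 2000),
                  cds = data.frame(start = 1000, end = 2000, phase = 0))
  s <- summarize_annotation(list(g), genome)
  expect_equal(s$gene_coverage_pct, 10)
  expect_equal(s$gc_pct, 5)
  expect_equal(s$mean_intron_number, 0)
})
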