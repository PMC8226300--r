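mk_cds_gene <- function(id, cds_str, offset = 0) {
  n <- nchar(cds_str)
  list(genome = cds_str,
       gene = gene_model(id, paste0(id, ".t"), "chr", "+",
                         exons = data.frame(start = offset, end = offset + n),
                         cds = data.frame(start = offset, end = offset + n,
                                          phase = 0)))
}

test_that("codon usage counts spliced CDS, excluding the stop codon", {
  genome <- c(chr = "ATGGGCGGCTAA")
  g <- mk_cds_gene("g1", "ATGGGCGGCTAA")$gene
  u <- codon_usage(list(g), genome)
  expect_equal(unname(u["g1", "GGC"]), 2L)
  expect_equal(sum(u["g1", ]), 2L)  # ATG and TAA never counted
  expect_false("TAA" %in% colnames(u))
  expect_equal(ncol(u), 59L)

  # Met/Trp-only gene: all-zero row, flagged
  genome2 <- c(chr = "ATGTGGTGA")
  g2 <- gene_model("g2", "g2.t", "chr", "+",
                   exons = data.frame(start = 0, end = 9),
                   cds = data.frame(start = 0, end = 9, phase = 0))
  u2 <- codon_usage(list(g2), genome2)
  expect_equal(sum(u2), 0L)
  expect_equal(attr(u2, "flagged"), "g2")

  # incomplete CDS skipped with warning
  g3 <- gene_model("g3", "g3.t", "chr", "+",
                   exons = data.frame(start = 0, end = 10),
                   cds = data.frame(start = 0, end = 10, phase = 0))
  expect_warning(codon_usage(list(g3), c(chr = "ATGGGCGGCT")), "incomplete")
})

test_that("RSCU divides by the sub-family mean after splitting", {
  u <- matrix(0L, 1, 59,
              dimnames = list("g", codon_subfamilies()$codon))
  u[1, "GCC"] <- 6  # Ala family GCN: counts (6,0,0,0), mean 1.5
  r <- rscu(u)
  expect_equal(unname(r[1, "GCC"]), 4)
  # sole used codon of a 2-codon sub-family: count / (count/2) = 2
  u2 <- u * 0L
  u2[1, "TGC"] <- 7  # Cys TGT/TGC
  expect_equal(unname(rscu(u2)[1, "TGC"]), 2)
})

test_that("correspondence analysis separates regimes and matches an oracle", {
  set.seed(11)
  # two codon-preference regimes over two Cys/Asp columns
  mk_row <- function(bias) {
    c(GCC = rbinom(1, 100, bias), GCT = rbinom(1, 100, 1 - bias),
      GAC = rbinom(1, 80, bias), GAT = rbinom(1, 80, 1 - bias))
  }
  m <- rbind(t(sapply(1:10, function(i) mk_row(0.9))),
             t(sapply(1:10, function(i) mk_row(0.2))))
  rownames(m) <- paste0("g", 1:20)
  ca <- correspondence_analysis(m)
  grp1 <- ca$axis1[1:10]; grp2 <- ca$axis1[11:20]
  expect_true(max(grp1) < min(grp2) || max(grp2) < min(grp1))

  # identical rows carry no inertia
  m2 <- matrix(rep(c(5L, 10L, 2L), each = 4), nrow = 4,
               dimnames = list(paste0("g", 1:4), c("GCC", "GCT", "GCA")))
  ca2 <- correspondence_analysis(m2)
  expect_true(all(abs(ca2$axis1) < 1e-8))

  # permutation equivariance
  perm <- sample(nrow(m))
  ca_p <- correspondence_analysis(m[perm, ])
  expect_equal(ca_p$axis1[match(ca$gene_id, ca_p$gene_id)], ca$axis1,
               tolerance = 1e-9)

  # axis-1 agrees with the MASS::corresp oracle up to sign and scale
  m3 <- matrix(c(20L, 5L, 3L, 4L, 18L, 2L, 1L, 6L, 30L), nrow = 3,
               dimnames = list(paste0("g", 1:3), c("c1", "c2", "c3")))
  ca3 <- correspondence_analysis(m3)
  or <- MASS::corresp(m3, nf = 1)
  expect_equal(abs(cor(ca3$axis1, or$rscore)), 1, tolerance = 1e-6)

  expect_warning(correspondence_analysis(rbind(m3, g4 = c(0L, 0L, 0L))),
                 "zero-margin")
})

test_that("reference-set selection sizes the set and resolves the pole", {
  ca <- data.frame(gene_id = paste0("g", 1:100), axis1 = seq(-1, 1,
                                                             length.out = 100))
  set <- select_reference_set(ca, 0.05, marker_genes = c("g1", "g2", "g3"))
  expect_length(set, 5)
  expect_equal(attr(set, "pole"), "negative")
  expect_true(all(c("g1", "g2", "g3") %in% set))
  set2 <- select_reference_set(ca, 0.05, pole = "positive")
  expect_true("g100" %in% set2)
  expect_error(select_reference_set(ca, 0.05), "pole")
  expect_error(select_reference_set(ca, 0.05, marker_genes = "absent"),
               "pole")
})

test_that("adaptation weights are ratio-of-ratios, max-normalised per family", {
  fam <- codon_subfamilies()
  cys <- fam$codon[fam$aa == "C"]  # TGT, TGC
  mk <- function(tgc, tgt) {
    v <- setNames(rep(0, nrow(fam)), fam$codon)
    v["TGC"] <- tgc; v["TGT"] <- tgt
    v
  }
  # F_hi = (0.9, 0.1), F_bg = (0.5, 0.5) at large counts -> w ~ (1, 1/9)
  w <- suppressWarnings(ite_weights(mk(9000, 1000), mk(5000, 5000)))
  expect_equal(w$weight[w$codon == "TGC"], 1)
  expect_equal(w$weight[w$codon == "TGT"], 1 / 9, tolerance = 2e-3)
  # F_hi = F_bg -> no adaptation signal, w = 1
  w2 <- suppressWarnings(ite_weights(mk(700, 300), mk(7000, 3000)))
  expect_equal(w2$weight[w2$codon %in% cys], c(1, 1), tolerance = 1e-3)
  # scale invariance in the reference counts
  w3 <- suppressWarnings(ite_weights(mk(90000, 10000), mk(5000, 5000)))
  expect_equal(w3$weight[w3$codon == "TGT"],
               w$weight[w$codon == "TGT"], tolerance = 2e-3)
  # unused sub-family flagged with uniform weights
  expect_warning(w4 <- ite_weights(mk(10, 10), mk(10, 10)), "unused")
  expect_true(all(w4$unused[w4$subfamily != "C"]))
  expect_true(all(w4$weight[w4$unused] == 1))
})

test_that("six-fold families split into sub-families sharing two positions", {
  fam <- codon_subfamilies(split = TRUE)
  ser <- fam[fam$aa == "S", ]
  expect_setequal(unique(ser$subfamily), c("S_TC", "S_AG"))
  expect_setequal(ser$codon[ser$subfamily == "S_AG"], c("AGT", "AGC"))
  leu <- fam[fam$aa == "L", ]
  expect_setequal(unique(leu$subfamily), c("L_TT", "L_CT"))
  arg <- fam[fam$aa == "R", ]
  expect_setequal(arg$codon[arg$subfamily == "R_AG"], c("AGA", "AGG"))
  # splitting off: one six-codon family, max-normalisation over all six
  fam_off <- codon_subfamilies(split = FALSE)
  expect_equal(sum(fam_off$subfamily == "S"), 6)
  # four-fold families never split
  expect_length(unique(fam$subfamily[fam$aa == "A"]), 1)
})

test_that("adaptation scores are geometric means bounded in (0, 1]", {
  fam <- codon_subfamilies()
  w <- data.frame(codon = fam$codon, subfamily = fam$subfamily,
                  weight = 1, unused = FALSE)
  w$weight[w$codon == "TGT"] <- 0.25
  u <- matrix(0L, 2, nrow(fam), dimnames = list(c("opt", "mix"), fam$codon))
  u["opt", "TGC"] <- 10L
  u["mix", "TGC"] <- 1L
  u["mix", "TGT"] <- 1L
  s <- ite_score(u, w)
  expect_equal(s$ite[s$gene_id == "opt"], 1)
  expect_equal(s$ite[s$gene_id == "mix"], 0.5)  # sqrt(1 * 0.25)
  expect_true(all(s$ite > 0 & s$ite <= 1))
  # no scorable codons -> undefined
  u0 <- u * 0L
  expect_true(all(is.na(ite_score(u0, w)$ite)))
})
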