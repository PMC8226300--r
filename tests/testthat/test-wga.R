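mk_block <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(species = r[[1]], src = paste0(r[[1]], ".chr"),
               start = as.numeric(r[[2]]),
               size = nchar(gsub("-", "", r[[3]], fixed = TRUE)),
               strand = "+", src_size = 1000, text = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

# exhaustive best-row-per-species oracle mirroring the stated rule
oracle_filter <- function(block) {
  mat <- do.call(rbind, strsplit(toupper(block$text), ""))
  cons <- apply(mat, 2, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    if (!length(col)) return("")
    tab <- table(col)
    sort(names(tab)[tab == max(tab)])[1]
  })
  score <- apply(mat, 1, function(r) sum(r == cons))
  keep <- vapply(unique(block$species), function(sp) {
    ix <- which(block$species == sp)
    ix[which.max(score[ix])]
  }, integer(1))
  block[sort(keep), , drop = FALSE]
}

test_that("duplicate filtering keeps the consensus-closest row per species", {
  b <- mk_block(list("ref", 0, "ACGTACGT"),
                list("spA", 0, "ACGTACGT"),
                list("spA", 100, "TTTTACGT"))
  out <- filter_duplicates(b)
  expect_equal(nrow(out), 2)
  expect_equal(out$start[out$species == "spA"], 0)
  # idempotence and no-op on single-copy blocks
  expect_identical(filter_duplicates(out)[, 1:7], out[, 1:7])
  b2 <- mk_block(list("ref", 0, "ACGT"), list("spA", 0, "AC-T"))
  expect_identical(filter_duplicates(b2), b2)
})

test_that("duplicate filtering equals the brute-force oracle on random blocks", {
  set.seed(21)
  for (i in 1:60) {
    n_rows <- sample(3:6, 1)
    width <- sample(10:30, 1)
    species <- c("ref", sample(c("spA", "spA", "spB", "spB", "spC"),
                               n_rows - 1, replace = TRUE))
    txt <- vapply(seq_len(n_rows), function(j) {
      chars <- sample(c("A", "C", "G", "T", "-"), width, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
      paste(chars, collapse = "")
    }, character(1))
    rows <- lapply(seq_len(n_rows), function(j) {
      list(species[j], (j - 1) * 100, txt[j])
    })
    b <- do.call(mk_block, rows)
    got <- filter_duplicates(b)
    want <- oracle_filter(b)
    expect_equal(got$text, want$text, info = paste("case", i))
    expect_equal(got$start, want$start, info = paste("case", i))
  }
})

test_that("the pileup is reference-anchored with first-block-wins semantics", {
  b1 <- mk_block(list("ref", 0, "AC-GT"), list("spA", 0, "ACAGT"))
  b2 <- mk_block(list("ref", 2, "GTAA"), list("spB", 5, "GTCC"))
  p <- maf_pileup(list(b1, b2), "ref", c(chr = 10))
  expect_equal(unname(p$bases$chr["ref", 1:4]), c(1L, 2L, 3L, 4L))
  # ref positions 2-3 covered by both blocks: first wins, spB unaligned there
  expect_equal(unname(p$bases$chr["spB", 3:4]), c(0L, 0L))
  expect_equal(unname(p$bases$chr["spB", 5:6]), c(2L, 2L))
  expect_equal(p$n_multi_covered, 2L)
  expect_equal(unname(p$block_id$chr[1:6]), c(1L, 1L, 1L, 1L, 2L, 2L))
})

test_that("alignability counts aligned reference bases per class", {
  mat <- rbind(ref = c("A", "C", "G", "T", "A", "C"),
               spA = c("A", "-", "G", "-", "-", "-"),
               spB = c("C", "C", "G", "T", "A", "C"))
  p <- pileup_from_matrix(mat)
  genome <- c(chr = "ACGTAC")
  g <- gene_model("g", "g.t", "chr", "+",
                  exons = data.frame(start = 0, end = 3),
                  cds = data.frame(start = 0, end = 3, phase = 0))
  map <- call_site_classes(list(g), genome)
  a <- alignability(p, map)
  expect_equal(a$fraction[a$species == "ref"], c(1, NaN, NaN, NaN, 1),
               tolerance = 1e-12)
  expect_equal(a$aligned[a$species == "spA" & a$class == "CDS"], 2)
  expect_equal(a$aligned[a$species == "spB" & a$class == "intergenic"], 3)
  # column ref=A, spA=-, spB=C: aligned to spB only
  expect_equal(unname(p$bases$chr["spA", 2]), 0L)
  expect_gt(unname(p$bases$chr["spB", 2]), 0L)
})

test_that("UCE scanning matches a brute-force column scanner", {
  brute_scan <- function(mat, min_len = 50) {
    ref <- mat["ref", ]
    ok <- ref %in% c("A", "C", "G", "T")
    for (sp in setdiff(rownames(mat), "ref")) {
      ok <- ok & mat[sp, ] == ref
    }
    runs <- rle(ok)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths
    keep <- runs$values & runs$lengths >= min_len
    data.frame(start = starts[keep], end = ends[keep])
  }
  set.seed(31)
  for (i in 1:200) {
    L <- sample(80:200, 1)
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    mat <- rbind(ref = ref,
                 spA = ifelse(runif(L) < 0.85, ref,
                              sample(c("A", "C", "G", "T", "-"), L, TRUE)),
                 spB = ifelse(runif(L) < 0.85, ref,
                              sample(c("A", "C", "G", "T", "-"), L, TRUE)))
    # occasionally plant a long conforming run to cross the threshold
    if (i %% 4 == 0) {
      st <- sample(1:(L - 60), 1)
      mat["spA", st:(st + 59)] <- ref[st:(st + 59)]
      mat["spB", st:(st + 59)] <- ref[st:(st + 59)]
    }
    p <- pileup_from_matrix(mat)
    got <- scan_uces(p, c(chr = paste(ref, collapse = "")),
                     c("spA", "spB"), min_len = 20)
    want <- brute_scan(mat, min_len = 20)
    expect_equal(got$start, want$start, info = paste("case", i))
    expect_equal(got$end, want$end, info = paste("case", i))
  }
})

test_that("UCE boundaries sit exactly at the 50 bp threshold", {
  mk <- function(run) {
    L <- run + 2
    ref <- rep("A", L)
    spA <- ref; spB <- ref
    spA[1] <- "C"; spA[L] <- "C"
    mat <- rbind(ref = ref, spA = spA, spB = spB)
    scan_uces(pileup_from_matrix(mat),
              c(chr = paste(ref, collapse = "")), c("spA", "spB"))
  }
  expect_equal(nrow(mk(49)), 0)
  u <- mk(50)
  expect_equal(nrow(u), 1)
  expect_equal(u$length, 50)
  expect_equal(c(u$start, u$end), c(1, 51))
})

test_that("UCE output is invariant to block splitting at conforming columns", {
  set.seed(41)
  ref <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  txt <- paste(ref, collapse = "")
  one <- mk_block(list("ref", 0, txt), list("spA", 0, txt),
                  list("spB", 0, txt))
  split_at <- 60
  two <- list(
    mk_block(list("ref", 0, substr(txt, 1, split_at)),
             list("spA", 0, substr(txt, 1, split_at)),
             list("spB", 0, substr(txt, 1, split_at))),
    mk_block(list("ref", split_at, substr(txt, split_at + 1, 120)),
             list("spA", split_at, substr(txt, split_at + 1, 120)),
             list("spB", split_at, substr(txt, split_at + 1, 120))))
  g <- c(chr = txt)
  p1 <- maf_pileup(list(one), "ref", c(chr = 120))
  p2 <- maf_pileup(two, "ref", c(chr = 120))
  u1 <- scan_uces(p1, g, c("spA", "spB"))
  u2 <- scan_uces(p2, g, c("spA", "spB"))
  expect_equal(u1[c("start", "end")], u2[c("start", "end")])
  expect_equal(u1$length, 120)
})

test_that("broad conservation filtering applies the 95% column rule", {
  L <- 100
  ref <- rep("A", L)
  mk_sp <- function(n_bad) {
    x <- ref
    if (n_bad > 0) x[seq_len(n_bad)] <- "G"
    x
  }
  mat_keep <- rbind(ref = ref, spA = ref, spB = ref, spC = mk_sp(5))
  mat_drop <- rbind(ref = ref, spA = ref, spB = ref, spC = mk_sp(6))
  uce <- data.frame(seq_id = "chr", start = 0, end = L, strand = ".",
                    length = L, source = "UCE")
  g <- c(chr = paste(ref, collapse = ""))
  keep <- broad_conservation_filter(uce, pileup_from_matrix(mat_keep), g,
                                    c("spA", "spB", "spC"))
  drop <- broad_conservation_filter(uce, pileup_from_matrix(mat_drop), g,
                                    c("spA", "spB", "spC"))
  expect_equal(nrow(keep), 1)
  expect_equal(keep$identity, 0.95)
  expect_equal(nrow(drop), 0)  # 94% falls below the threshold
})

test_that("4D column extraction enforces gap, offset and block rules", {
  # ref CDS ATG GGA TAA on a 9-bp gene; GGA third position is 4D
  genome <- c(chr = "ATGGGATAAGGG")
  g <- gene_model("g", "g.t", "chr", "+",
                  exons = data.frame(start = 0, end = 9),
                  cds = data.frame(start = 0, end = 9, phase = 0))
  base <- rbind(ref = seq_chars("ATGGGATAAGGG"))
  ok <- rbind(base, spA = seq_chars("ATGGGTTAAGGG"))  # GGT: still 4D
  p <- pileup_from_matrix(ok, ref = "ref")
  res <- extract_4d_columns(p, list(g), genome)
  expect_equal(res$sites$pos, 5)
  expect_equal(unname(res$alignment[, 1]), c("A", "T"))

  gap <- rbind(base, spA = seq_chars("ATGG-TTAAGGG"))  # gap mid-codon
  res2 <- extract_4d_columns(pileup_from_matrix(gap, ref = "ref"),
                             list(g), genome)
  expect_equal(nrow(res2$sites), 0)
  expect_equal(unname(res2$dropped["gap"]), 1L)

  not4d <- rbind(base, spA = seq_chars("ATGATGTAAGGG"))  # ATG offset-3 is 0D
  res3 <- extract_4d_columns(pileup_from_matrix(not4d, ref = "ref"),
                             list(g), genome)
  expect_equal(nrow(res3$sites), 0)
  expect_equal(unname(res3$dropped["not_4d"]), 1L)

  # codon split across blocks is dropped and counted
  split_ids <- c(rep(1L, 4), rep(2L, 8))
  res4 <- extract_4d_columns(pileup_from_matrix(ok, ref = "ref",
                                                block_id = split_ids),
                             list(g), genome)
  expect_equal(nrow(res4$sites), 0)
  expect_equal(unname(res4$dropped["split_block"]), 1L)
})

test_that("4D extraction is strand-aware", {
  plus <- "ATGGGATAAGGG"
  genome <- c(chr = revcomp(plus))
  L <- nchar(plus)
  g <- gene_model("g", "g.t", "chr", "-",
                  exons = data.frame(start = L - 9, end = L),
                  cds = data.frame(start = L - 9, end = L, phase = 0))
  mat <- rbind(ref = seq_chars(genome[["chr"]]),
               spA = seq_chars(genome[["chr"]]))
  res <- extract_4d_columns(pileup_from_matrix(mat, ref = "ref"),
                            list(g), genome)
  expect_equal(res$sites$pos, L - 1 - 5)  # mirrored genomic position
  expect_equal(unname(res$alignment[, 1]), c("A", "A"))
})

test_that("CE overlap table conserves bases and reports per-class splits", {
  genome <- c(chr = strrep("A", 1000))
  g <- gene_model("g", "g.t", "chr", "+",
                  exons = data.frame(start = c(100, 230), end = c(200, 300)),
                  cds = data.frame(start = c(100, 230), end = c(200, 300),
                                   phase = c(0, 1)))
  map <- call_site_classes(list(g), genome)
  # one CE covering 30 CDS bases and 20 intron bases
  ces <- intervals("chr", 170, 220)
  tab <- ce_overlap_table(ces, map)
  expect_equal(sum(tab$ce_overlap), attr(tab, "total_ce_bases"))
  expect_equal(tab$ce_overlap[tab$class == "CDS"], 30)
  expect_equal(tab$ce_overlap[tab$class == "intron"], 20)
  expect_error(ce_overlap_table(intervals("chr", 900, 2000), map),
               "bounds")
})

test_that("intron bins are equal-sized and detect the planted length trend", {
  set.seed(51)
  n <- 100
  lens <- sort(round(runif(n, 40, 400)))
  introns <- data.frame(gene_id = paste0("g", 1:n), seq_id = "chr",
                        start = cumsum(lens + 50) - lens,
                        end = cumsum(lens + 50),
                        length = lens, ordinal = 1L, first_intron = TRUE,
                        rel_pos = runif(n, 0, 100))
  # CE fraction proportional to 1/length
  ces <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- max(1, round(30 / lens[i] * lens[i] / 10))
    intervals("chr", introns$start[i], introns$start[i] + w)
  }))
  res <- intron_ce_bins(introns, ces, n_bins = 50)
  expect_equal(res$bins$n, rep(2, 50))
  expect_lt(res$pearson$estimate, 0)
  expect_gt(res$short_ce_frac, res$long_ce_frac)
  expect_error(intron_ce_bins(introns[1:10, ], ces, n_bins = 50), "fewer")
  # zero-variance CE fractions flag the correlation as undefined
  expect_warning(
    res0 <- intron_ce_bins(introns, intervals("chr", 0, 1), n_bins = 50),
    "zero variance")
  expect_null(res0$pearson)
})
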