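#' Specification of a synthetic multi-species alignment
#'
#' Defaults place eight species on a fixed tree whose focal-to-nearest and
#' focal-to-next divergences are ~0.34 and ~0.45 substitutions/site, with
#' the remaining species at roughly neutral saturation (0.8-1.0). Sites
#' evolve independently under HKY; planted conserved elements evolve at a
#' reduced rate, planted ultraconserved elements accept no substitutions
#' within the designated trio (a deep subset accepts none anywhere), and
#' per-species deletions in unconstrained regions grow with divergence.
#'
#' @param ... overrides for the default fields.
#' @return list of class `alignment_spec`.
#' @export
alignment_spec <- function(...) {
  spec <- list(
    tree = paste0("(((cre:0.17,cin:0.17):0.055,csc:0.225):0.175,",
                  "(ede:0.25,(gpe:0.28,(yun:0.33,(eud:0.30,vca:0.32)",
                  ":0.05):0.04):0.06):0.15);"),
    reference = "cre",
    trio = c("cre", "cin", "csc"),
    kappa = 2.5, gc = 0.64,
    ce_rate = 0.4,
    n_uce = 20, n_deep_uce = 5, uce_len_range = c(50, 120),
    ce_cds_prob = 0.6, ce_cds_cover = 0.7,
    ce_intron_scale = 45, ce_utr_prob = 0.25,
    ce_intergenic_prob = 0.12,
    deletion_rate = 0.35, deletion_mean_len = 300,
    block_cols = 800
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(spec))
  if (length(unknown)) stop("unknown alignment_spec field(s): ",
                            paste(unknown, collapse = ", "))
  spec[names(over)] <- over
  structure(spec, class = "alignment_spec")
}

#' Plant conserved and ultraconserved elements on a simulated genome
#'
#' CE coverage is class-structured: most CDS exons carry a central CE;
#' intronic CE coverage scales as `ce_intron_scale / length` so short
#' introns are proportionally more constrained than long ones; UTRs and
#' intergenic gaps carry occasional CEs. UCEs are placed inside single CDS
#' chunks of genuine genes, at least 50 bp, with a designated deep subset.
#' Every element lies strictly within one site class.
#'
#' @param sim output of [simulate_gene_sequences()].
#' @param aspec an [alignment_spec()].
#' @return `sim` with `ces` (interval df with `class`) and `uces`
#'   (interval df with `deep`).
#' @export
plant_conserved_elements <- function(sim, aspec = alignment_spec()) {
  ces <- list()
  add <- function(seq_id, start, end, cls) {
    ces[[length(ces) + 1]] <<- data.frame(
      seq_id = seq_id, start = start, end = end, strand = ".",
      class = cls, stringsAsFactors = FALSE)
  }
  uce_cands <- list()
  for (gi in seq_along(sim$structures)) {
    st <- sim$structures[[gi]]
    m <- st$model
    genuine <- sim$labels[[sim$gene_ids[gi]]] == "genuine"
    if (genuine) {
      for (i in seq_len(nrow(m$cds))) {
        len <- m$cds$end[i] - m$cds$start[i]
        if (len >= 40 && runif(1) < aspec$ce_cds_prob) {
          ce_len <- round(len * aspec$ce_cds_cover)
          off <- floor((len - ce_len) / 2)
          add(m$seq_id, m$cds$start[i] + off,
              m$cds$start[i] + off + ce_len, "CDS")
        }
        if (len >= 70) {
          uce_cands[[length(uce_cands) + 1]] <-
            data.frame(gi = gi, seq_id = m$seq_id, start = m$cds$start[i],
                       end = m$cds$end[i], stringsAsFactors = FALSE)
        }
      }
    }
    intr <- gene_introns(m)
    for (i in seq_len(nrow(intr))) {
      len <- intr$end[i] - intr$start[i]
      if (len < 20) next
      frac <- min(0.85, aspec$ce_intron_scale / len)
      ce_len <- max(8, round(frac * len))
      off <- floor(runif(1, 0, len - ce_len + 1))
      add(m$seq_id, intr$start[i] + off, intr$start[i] + off + ce_len,
          "intron")
    }
    for (u in list(list(df = m$utr5, cls = "UTR5"),
                   list(df = m$utr3, cls = "UTR3"))) {
      for (i in seq_len(nrow(u$df))) {
        len <- u$df$end[i] - u$df$start[i]
        if (len >= 20 && runif(1) < aspec$ce_utr_prob) {
          ce_len <- round(len / 2)
          off <- floor((len - ce_len) / 2)
          add(m$seq_id, u$df$start[i] + off, u$df$start[i] + off + ce_len,
              u$cls)
        }
      }
    }
  }
  for (i in seq_len(nrow(sim$gaps))) {
    len <- sim$gaps$end[i] - sim$gaps$start[i]
    if (len >= 60 && runif(1) < aspec$ce_intergenic_prob) {
      ce_len <- min(150, floor(len * 0.5))
      off <- floor(runif(1, 0, len - ce_len + 1))
      add(sim$gaps$seq_id[i], sim$gaps$start[i] + off,
          sim$gaps$start[i] + off + ce_len, "intergenic")
    }
  }
  ces <- do.call(rbind, ces)
  ces <- sort_intervals(ces)
  rownames(ces) <- NULL

  cands <- do.call(rbind, uce_cands)
  pick <- cands[sample.int(nrow(cands), min(aspec$n_uce, nrow(cands))), ,
                drop = FALSE]
  uces <- lapply(seq_len(nrow(pick)), function(i) {
    len <- pick$end[i] - pick$start[i]
    ulen <- min(len - 10, sample(seq(aspec$uce_len_range[1],
                                     aspec$uce_len_range[2]), 1))
    off <- floor(runif(1, 5, len - ulen - 4))
    data.frame(seq_id = pick$seq_id[i], start = pick$start[i] + off,
               end = pick$start[i] + off + ulen, strand = ".",
               stringsAsFactors = FALSE)
  })
  uces <- do.call(rbind, uces)
  uces$deep <- seq_len(nrow(uces)) <= aspec$n_deep_uce
  uces <- sort_intervals(uces)
  rownames(uces) <- NULL
  sim$ces <- ces
  sim$uces <- uces
  sim
}

hky_pmat <- function(t, kappa, gc) {
  freqs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  Q <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  transitions <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  for (i in BASES) for (j in BASES) {
    if (i == j) next
    rate <- freqs[j]
    if (any(transitions[, 1] == i & transitions[, 2] == j)) {
      rate <- rate * kappa
    }
    Q[i, j] <- rate
  }
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  ev <- eigen(Q)
  P <- Re(ev$vectors %*% diag(exp(ev$values * t)) %*% solve(ev$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

evolve_edge <- function(parent, t, rates, kappa, gc) {
  child <- parent
  for (r in unique(rates)) {
    if (r == 0) next
    P <- hky_pmat(t * r, kappa, gc)
    idx <- which(rates == r)
    for (b in 1:4) {
      sel <- idx[parent[idx] == b]
      if (!length(sel)) next
      child[sel] <- sample.int(4, length(sel), replace = TRUE,
                               prob = P[b, ])
    }
  }
  child
}

#' Simulate the multi-species whole-genome alignment
#'
#' Evolves the reference sequence down the species tree site by site under
#' HKY, with per-site rate multipliers 1 (neutral), `ce_rate` (CEs), 0 on
#' trio branches for UCEs (0 on all branches for the deep subset), then
#' applies per-species deletions in unconstrained non-CDS regions with
#' deleted fraction proportional to divergence from the reference, forces
#' a mismatch in the nearest species immediately flanking every planted
#' UCE (so recovered elements match the planted intervals exactly), and
#' tiles the result into reference-anchored MAF blocks. Coding columns of
#' all genes are never deleted, so reading frame is preserved.
#'
#' @param sim output of [plant_conserved_elements()].
#' @param aspec an [alignment_spec()].
#' @return `sim` with `aln` (per-seq species x position integer matrices,
#'   NA = deleted/unaligned), `blocks` (MAF block list), `aspec`.
#' @export
simulate_alignment <- function(sim, aspec = alignment_spec()) {
  tree <- ape::read.tree(text = aspec$tree)
  stopifnot(aspec$reference %in% tree$tip.label,
            all(aspec$trio %in% tree$tip.label))
  # re-root at the reference tip and transfer its terminal branch to the
  # sibling edge, so the root sequence IS the reference genome and
  # patristic distances from the reference are preserved
  tree <- ape::root(tree, outgroup = aspec$reference, resolve.root = TRUE)
  tips <- tree$tip.label
  root_node <- length(tips) + 1L
  ref_tip <- which(tips == aspec$reference)
  ref_edge <- which(tree$edge[, 1] == root_node & tree$edge[, 2] == ref_tip)
  sib_edge <- which(tree$edge[, 1] == root_node & tree$edge[, 2] != ref_tip)
  tree$edge.length[sib_edge] <- tree$edge.length[sib_edge] +
    tree$edge.length[ref_edge] / length(sib_edge)
  tree$edge.length[ref_edge] <- 0
  nnode <- max(tree$edge)
  # leaves under each node
  desc <- vector("list", nnode)
  for (i in seq_along(tips)) desc[[i]] <- tips[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  trio_edge <- vapply(seq_len(nrow(tree$edge)), function(e) {
    k <- sum(aspec$trio %in% desc[[tree$edge[e, 2]]])
    k > 0 && k < length(aspec$trio)
  }, logical(1))
  div_from_ref <- setNames(
    as.vector(ape::cophenetic.phylo(tree)[aspec$reference, tips]), tips)

  seq_ids <- names(sim$genome)
  aln <- list()
  for (s in seq_ids) {
    L <- nchar(sim$genome[[s]])
    root <- unname(BASE_CODES[seq_chars(toupper(sim$genome[[s]]))])
    # site rate classes: 3 neutral, 2 CE, 1 UCE (trio-frozen), 0 deep UCE
    cls <- rep(3L, L)
    ce_s <- sim$ces[sim$ces$seq_id == s, , drop = FALSE]
    for (i in seq_len(nrow(ce_s))) {
      cls[(ce_s$start[i] + 1):ce_s$end[i]] <- 2L
    }
    uce_s <- sim$uces[sim$uces$seq_id == s, , drop = FALSE]
    for (i in seq_len(nrow(uce_s))) {
      cls[(uce_s$start[i] + 1):uce_s$end[i]] <-
        if (uce_s$deep[i]) 0L else 1L
    }
    # preorder traversal carrying node sequences
    node_seq <- vector("list", nnode)
    root_node <- length(tips) + 1L
    node_seq[[root_node]] <- root
    mat <- matrix(NA_integer_, nrow = length(tips), ncol = L,
                  dimnames = list(tips, NULL))
    for (e in rev(ape::postorder(tree))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      rates <- c(0, if (trio_edge[e]) 0 else aspec$ce_rate,
                 aspec$ce_rate, 1)[cls + 1L]
      child <- evolve_edge(node_seq[[p]], tree$edge.length[e], rates,
                           aspec$kappa, aspec$gc)
      if (ch <= length(tips)) {
        mat[tips[ch], ] <- child
      } else {
        node_seq[[ch]] <- child
      }
    }
    mat[aspec$reference, ] <- root  # reference is the root sequence
    # breaker mismatches flanking each UCE in the nearest non-ref species
    nearest <- names(sort(div_from_ref[setdiff(tips, aspec$reference)]))[1]
    for (i in seq_len(nrow(uce_s))) {
      for (p0 in c(uce_s$start[i] - 1, uce_s$end[i])) {
        if (p0 >= 0 && p0 < L) {
          mat[nearest, p0 + 1] <- root[p0 + 1] %% 4L + 1L
        }
      }
    }
    aln[[s]] <- mat
  }

  # deletions in unconstrained non-CDS regions, growing with divergence
  cds_iv <- do.call(rbind, lapply(sim$models, function(m) {
    data.frame(seq_id = m$seq_id, start = m$cds$start, end = m$cds$end,
               strand = ".", stringsAsFactors = FALSE)
  }))
  constrained <- merge_intervals(rbind(
    cds_iv, sim$ces[, c("seq_id", "start", "end", "strand")],
    sim$uces[, c("seq_id", "start", "end", "strand")]))
  for (s in seq_ids) {
    L <- ncol(aln[[s]])
    eligible <- rep(TRUE, L)
    cst <- constrained[constrained$seq_id == s, , drop = FALSE]
    for (i in seq_len(nrow(cst))) {
      eligible[(cst$start[i] + 1):cst$end[i]] <- FALSE
    }
    E <- sum(eligible)
    for (sp in setdiff(tips, aspec$reference)) {
      f <- min(0.7, aspec$deletion_rate * div_from_ref[[sp]])
      target <- f * E
      deleted <- 0
      guard <- 0
      while (deleted < target && guard < 1e5) {
        guard <- guard + 1
        st0 <- sample.int(L, 1)
        len <- rgeom(1, 1 / aspec$deletion_mean_len) + 50
        idx <- st0:min(L, st0 + len - 1)
        idx <- idx[eligible[idx] & !is.na(aln[[s]][sp, idx])]
        if (!length(idx)) next
        aln[[s]][sp, idx] <- NA_integer_
        deleted <- deleted + length(idx)
      }
    }
  }
  sim$aln <- aln
  sim$aspec <- aspec
  sim$blocks <- alignment_to_blocks(sim, aspec$block_cols)
  sim
}

alignment_to_blocks <- function(sim, block_cols) {
  ref <- sim$aspec$reference
  blocks <- list()
  for (s in names(sim$aln)) {
    mat <- sim$aln[[s]]
    tips <- rownames(mat)
    L <- ncol(mat)
    src_size <- rowSums(!is.na(mat))
    counters <- setNames(rep(0, length(tips)), tips)
    starts <- seq(1, L, by = block_cols)
    for (bs in starts) {
      be <- min(bs + block_cols - 1, L)
      rows <- list()
      for (sp in c(ref, setdiff(tips, ref))) {
        codes <- mat[sp, bs:be]
        n_bases <- sum(!is.na(codes))
        if (n_bases == 0) next
        chars <- ifelse(is.na(codes), "-", BASES[codes])
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, src = paste0(sp, ".", s),
          start = counters[[sp]], size = n_bases, strand = "+",
          src_size = src_size[[sp]],
          text = paste(chars, collapse = ""), stringsAsFactors = FALSE)
        counters[[sp]] <- counters[[sp]] + n_bases
      }
      blocks[[length(blocks) + 1]] <- do.call(rbind, rows)
    }
  }
  blocks
}
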