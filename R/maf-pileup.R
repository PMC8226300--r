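BASE_CODES <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_bases <- function(chars) {
  code <- BASE_CODES[toupper(chars)]
  code[is.na(code) & chars != "-"] <- 5L  # N / ambiguity
  code[chars == "-"] <- 0L
  as.integer(code)
}

#' Reduce each species to one row per alignment block
#'
#' For species represented by multiple (paralogous) rows, the row with the
#' most matches to the column-wise majority-base consensus of the block is
#' retained. Consensus ties go to the lexicographically first base;
#' row-score ties keep the first row in file order and are flagged in the
#' `tied_species` attribute. Blocks without duplicated species are returned
#' unchanged, so the filter is idempotent.
#'
#' @param block one MAF block data.frame (see [read_maf()]).
#' @return filtered block with at most one row per species.
#' @export
filter_duplicates <- function(block) {
  if (!anyDuplicated(block$species)) return(block)
  mat <- do.call(rbind, strsplit(toupper(block$text), ""))
  ncol <- ncol(mat)
  consensus <- character(ncol)
  for (j in seq_len(ncol)) {
    col <- mat[, j]
    col <- col[col %in% BASES]
    if (!length(col)) { consensus[j] <- ""; next }
    tab <- table(col)
    consensus[j] <- sort(names(tab)[tab == max(tab)])[1]
  }
  scores <- vapply(seq_len(nrow(mat)), function(i) {
    sum(mat[i, ] == consensus)
  }, numeric(1))
  tied <- character()
  keep <- vapply(split(seq_len(nrow(block)), block$species), function(ix) {
    best <- ix[scores[ix] == max(scores[ix])]
    if (length(best) > 1) tied <<- c(tied, block$species[best[1]])
    best[1]
  }, integer(1))
  out <- block[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tied_species") <- tied
  out
}

#' Reference-anchored pileup of a MAF alignment
#'
#' Collapses duplicate-filtered blocks into, per reference sequence, a
#' species x position matrix of base codes (0 = unaligned/gap, 1-4 = ACGT,
#' 5 = ambiguity) plus the block index that contributed each reference
#' position. A reference position covered by more than one block is taken
#' from the first block in file order (all species jointly); re-covered
#' positions are counted in the `n_multi_covered` attribute.
#'
#' @param blocks list of MAF blocks (apply [filter_duplicates()] first).
#' @param reference_species reference species name.
#' @param seq_lengths named numeric vector: reference sequence lengths.
#' @param species optional fixed species order for the matrices.
#' @return object of class `maf_pileup`: list with `bases` (list of
#'   matrices), `block_id` (list of integer vectors), `species`.
#' @export
maf_pileup <- function(blocks, reference_species, seq_lengths,
                       species = NULL) {
  if (is.null(species)) {
    species <- unique(unlist(lapply(blocks, function(b) b$species)))
  }
  bases <- lapply(seq_lengths, function(L) {
    matrix(0L, nrow = length(species), ncol = L,
           dimnames = list(species, NULL))
  })
  block_id <- lapply(seq_lengths, function(L) integer(L))
  n_multi <- 0L
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    ri <- which(b$species == reference_species)[1]
    if (is.na(ri)) next
    if (b$strand[ri] != "+") {
      stop("minus-strand reference row in block ", bi, " unsupported")
    }
    ref_chrom <- sub(paste0("^", reference_species, "\\."), "", b$src[ri])
    if (!ref_chrom %in% names(bases)) {
      stop("reference sequence ", ref_chrom, " not in seq_lengths")
    }
    ref_chars <- strsplit(b$text[ri], "")[[1]]
    cols <- which(ref_chars != "-")
    refpos <- b$start[ri] + seq_along(cols)  # 1-based index into matrices
    new <- block_id[[ref_chrom]][refpos] == 0L
    n_multi <- n_multi + sum(!new)
    if (!any(new)) next
    use_cols <- cols[new]
    use_pos <- refpos[new]
    block_id[[ref_chrom]][use_pos] <- bi
    for (i in seq_len(nrow(b))) {
      sp <- b$species[i]
      if (!sp %in% species) next
      if (i != ri && sp == reference_species) next
      chars <- strsplit(b$text[i], "")[[1]][use_cols]
      bases[[ref_chrom]][sp, use_pos] <- encode_bases(chars)
    }
  }
  structure(list(bases = bases, block_id = block_id, species = species,
                 reference_species = reference_species,
                 n_multi_covered = n_multi),
            class = "maf_pileup")
}

#' @export
print.maf_pileup <- function(x, ...) {
  cat(sprintf("<maf_pileup: %d species x %s positions over %d sequence(s)>\n",
              length(x$species),
              format(sum(vapply(x$bases, ncol, numeric(1)))),
              length(x$bases)))
  invisible(x)
}
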