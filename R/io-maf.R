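#' Read a MAF (multiple alignment format) file
#'
#' Each alignment block is anchored to one reference species; blocks in which
#' the reference is absent are dropped with a counted warning. Species names
#' are the part of the MAF `src` field before the first dot (`species.chrom`);
#' a dotless `src` is taken as the species name itself. Minus-strand rows keep
#' MAF semantics: `start` is on the reverse strand and the source length is
#' recorded so forward coordinates remain recoverable.
#'
#' @param path MAF file (optionally gzipped).
#' @param reference_species species name that must anchor every block.
#' @return list of blocks; each block is a `data.frame` with columns
#'   `species`, `src`, `start`, `size`, `strand`, `src_size`, `text`. The
#'   number of dropped blocks is attached as attribute `n_dropped`.
#' @export
read_maf <- function(path, reference_species) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  blocks <- list()
  cur <- list()
  n_dropped <- 0L
  block_idx <- 0L
  flush <- function(cur, block_idx) {
    if (!length(cur)) return(NULL)
    df <- do.call(rbind, cur)
    if (length(unique(nchar(df$text))) != 1) {
      stop("row text length mismatch in MAF block ", block_idx)
    }
    ngap <- nchar(gsub("-", "", df$text, fixed = TRUE))
    if (any(ngap != df$size)) {
      stop("non-gap count != size in MAF block ", block_idx)
    }
    df
  }
  for (ln in lines) {
    if (grepl("^a", ln) || !nzchar(trimws(ln))) {
      block_idx <- block_idx + 1L
      df <- flush(cur, block_idx - 1L)
      cur <- list()
      if (!is.null(df)) {
        if (reference_species %in% df$species) {
          blocks[[length(blocks) + 1L]] <- df
        } else {
          n_dropped <- n_dropped + 1L
        }
      }
    } else if (grepl("^s\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      src <- f[2]
      cur[[length(cur) + 1L]] <- data.frame(
        species = sub("\\..*$", "", src), src = src,
        start = as.numeric(f[3]), size = as.numeric(f[4]),
        strand = f[5], src_size = as.numeric(f[6]), text = f[7],
        stringsAsFactors = FALSE
      )
    }
  }
  df <- flush(cur, block_idx)
  if (!is.null(df)) {
    if (reference_species %in% df$species) {
      blocks[[length(blocks) + 1L]] <- df
    } else {
      n_dropped <- n_dropped + 1L
    }
  }
  if (n_dropped > 0) {
    warning(n_dropped, " MAF block(s) without reference species dropped")
  }
  attr(blocks, "n_dropped") <- n_dropped
  attr(blocks, "reference_species") <- reference_species
  blocks
}

#' Write alignment blocks as MAF
#'
#' @param blocks list of block data.frames as returned by [read_maf()].
#' @param path output path.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a", con)
    writeLines(sprintf("s %s %d %d %s %d %s", b$src, as.integer(b$start),
                       as.integer(b$size), b$strand, as.integer(b$src_size),
                       b$text), con)
    writeLines("", con)
  }
  invisible(path)
}
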