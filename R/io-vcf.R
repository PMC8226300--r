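#' Construct a haploid variant table
#'
#' @param seq_id,pos vectors: chromosome and 0-based position per site.
#' @param alleles character matrix (sites x samples) of allele indices
#'   ("0" = ref, "1" = first alt, ...); `NA` = missing call.
#' @param samples sample names (columns of `alleles`).
#' @param callable optional interval data.frame where invariant sites are
#'   trusted; `NULL` means every non-N reference position is assumed callable.
#' @return object of class `variant_table`.
#' @export
variant_table <- function(seq_id, pos, alleles, samples,
                          callable = NULL) {
  stopifnot(length(seq_id) == length(pos), nrow(alleles) == length(pos),
            ncol(alleles) == length(samples))
  structure(list(seq_id = as.character(seq_id), pos = as.numeric(pos),
                 alleles = alleles, samples = samples, callable = callable),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table: %d sites x %d haploid samples>\n",
              length(x$pos), length(x$samples)))
  invisible(x)
}

#' Read haploid genotype calls from a VCF
#'
#' Haploid GT fields are taken as-is; homozygous diploid calls are collapsed
#' to a single allele; heterozygous diploid calls are set to missing with a
#' warning (they cannot be interpreted as a haploid genotype). Multiallelic
#' sites are retained with all alleles. VCF positions (1-based) are converted
#' to 0-based.
#'
#' @param path VCF file (optionally gzipped).
#' @param sample_ids samples to extract; default all samples in the file.
#' @param callable optional callable-sites interval data.frame to attach.
#' @return a [variant_table()].
#' @export
read_vcf_haploid <- function(path, sample_ids = NULL, callable = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  if (is.null(sample_ids)) sample_ids <- colnames(gt)
  missing_samples <- setdiff(sample_ids, colnames(gt))
  if (length(missing_samples)) {
    stop("requested sample(s) absent from VCF: ",
         paste(missing_samples, collapse = ", "))
  }
  gt <- gt[, sample_ids, drop = FALSE]
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  alleles <- collapse_gt(gt)
  variant_table(seq_id = fix[, "CHROM"],
                pos = as.numeric(fix[, "POS"]) - 1,
                alleles = alleles, samples = sample_ids,
                callable = callable)
}

collapse_gt <- function(gt) {
  flat <- as.vector(gt)
  flat[flat %in% c(".", "./.", ".|.")] <- NA_character_
  dip <- grepl("[/|]", flat)
  if (any(dip, na.rm = TRUE)) {
    parts <- strsplit(flat[which(dip)], "[/|]")
    a1 <- vapply(parts, `[`, "", 1)
    a2 <- vapply(parts, `[`, "", 2)
    hom <- a1 == a2 & a1 != "."
    het <- a1 != a2
    if (any(het)) {
      warning(sum(het), " heterozygous diploid call(s) set to missing")
    }
    res <- rep(NA_character_, length(parts))
    res[hom] <- a1[hom]
    flat[which(dip)] <- res
  }
  matrix(flat, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a haploid variant table as VCF
#'
#' Used by the synthetic-data generator; emits a minimal VCF 4.2 with haploid
#' GT fields and the reference/alternate alleles supplied.
#'
#' @param vt a [variant_table()].
#' @param ref,alt character vectors per site (alt comma-joined if multiple).
#' @param path output path.
#' @export
write_vcf_haploid <- function(vt, ref, alt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", vt$samples), collapse = "\t")), con)
  if (length(vt$pos)) {
    gt <- vt$alleles
    gt[is.na(gt)] <- "."
    body <- paste(vt$seq_id, format(vt$pos + 1, scientific = FALSE,
                                    trim = TRUE),
                  ".", ref, alt, ".", "PASS", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
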