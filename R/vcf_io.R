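## VCF input and variant-record normalization.
##
## The cascade's internal currency is a plain variant table: one row per
## biallelic record with columns chrom, pos, ref, alt, gt, qd, dp. Parsing
## is delegated to VariantAnnotation; multi-allelic records are split into
## biallelics and trimmed to minimal representation before filtering.

#' Read a single-sample VCF into a variant table
#'
#' Uses [VariantAnnotation::readVcf()], expands multi-allelic records into
#' biallelic rows (re-expressing the genotype with respect to each
#' alternate allele), and normalizes each record with
#' [normalize_variant()].
#'
#' @param path VCF path.
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`, `gt`
#'   (`"0/0"`, `"0/1"` or `"1/1"`), `qd`, `dp` (NA when the annotation is
#'   absent).
#' @export
read_sample_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gt = character(0), qd = numeric(0), dp = numeric(0)))
  }
  info <- VariantAnnotation::info(vcf)
  qd <- if ("QD" %in% names(info)) as.numeric(info$QD) else rep(NA_real_, n)
  dp <- if ("DP" %in% names(info)) as.numeric(info$DP) else rep(NA_real_, n)
  gt_raw <- as.character(VariantAnnotation::geno(vcf)$GT[, 1L])
  alts <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alts)

  idx <- rep(seq_len(n), n_alt)
  which_alt <- sequence(n_alt)
  alt_chr <- as.character(unlist(alts))
  ref_chr <- as.character(VariantAnnotation::ref(vcf))[idx]
  ## Genotype relative to each alternate allele.
  gt_split <- strsplit(gt_raw, "[/|]")
  gt_out <- mapply(function(i, j) {
    al <- suppressWarnings(as.integer(gt_split[[i]]))
    hits <- sum(al == j, na.rm = TRUE)
    c("0/0", "0/1", "1/1")[hits + 1L]
  }, idx, which_alt)

  out <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr))[idx],
    pos = GenomicRanges::start(rr)[idx],
    ref = ref_chr,
    alt = alt_chr,
    gt = gt_out,
    qd = qd[idx],
    dp = dp[idx],
    stringsAsFactors = FALSE
  )
  norm <- normalize_variant(out$pos, out$ref, out$alt)
  out$pos <- norm$pos
  out$ref <- norm$ref
  out$alt <- norm$alt
  rownames(out) <- NULL
  out
}

#' Normalize variant records to minimal left-aligned representation
#'
#' Trims shared trailing bases, then shared leading bases (advancing the
#' position), keeping at least one base in each allele - the parsimony/
#' left-trim normalization used before matching records across samples.
#' When `genome` is supplied, pure indels are additionally left-shifted
#' through repeat context.
#'
#' @param pos,ref,alt Parallel vectors.
#' @param genome Optional contig sequence (character scalar) for left
#'   shifting.
#' @return List with normalized `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt, genome = NULL) {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  last_ch <- function(x) substr(x, nchar(x), nchar(x))
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    repeat {
      if (nchar(r) >= 1L && nchar(a) >= 1L && last_ch(r) == last_ch(a)) {
        if (nchar(r) > 1L && nchar(a) > 1L) {
          r <- substr(r, 1L, nchar(r) - 1L)
          a <- substr(a, 1L, nchar(a) - 1L)
          next
        }
        if (!is.null(genome) && p > 1L) {
          ## extend left through the reference so the indel is left-aligned
          prev <- substr(genome, p - 1L, p - 1L)
          r <- paste0(prev, substr(r, 1L, nchar(r) - 1L))
          a <- paste0(prev, substr(a, 1L, nchar(a) - 1L))
          p <- p - 1L
          next
        }
      }
      break
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      p <- p + 1L
    }
    pos[i] <- p; ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}
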