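## Variant-prioritization cascade.
##
## Reproduces the study's filtering logic: per-sample hard filtering of
## homozygous-alt calls on quality-by-depth and depth (strict inequalities),
## intersection of the surviving sets across the deep affected samples,
## restriction to gene bodies (exons or introns of protein-coding genes),
## adjudication against low-coverage read support from additional affected
## and unrelated control animals, and severity-ranked candidate output.

#' Hard-filter a variant table to high-quality homozygous-alt calls
#'
#' Retains exactly the records that are homozygous for the alternate allele
#' with `QD > qd_min` and `DP > dp_min` (strict inequalities, matching the
#' published thresholds QD > 20, DP > 10). Records missing either annotation
#' are excluded and counted in the drop tally rather than raising an error.
#'
#' @param variants Variant table (see [read_sample_vcf()]).
#' @param qd_min,dp_min Exclusive lower thresholds.
#' @return The retained rows; attribute `drop_tally` holds a named count of
#'   exclusions (`not_hom_alt`, `missing_annotation`, `low_qd`, `low_dp`).
#' @export
hard_filter <- function(variants, qd_min = 20, dp_min = 10) {
  hom <- variants$gt == "1/1"
  missing_ann <- hom & (is.na(variants$qd) | is.na(variants$dp))
  low_qd <- hom & !missing_ann & variants$qd <= qd_min
  low_dp <- hom & !missing_ann & variants$qd > qd_min & variants$dp <= dp_min
  keep <- hom & !missing_ann & variants$qd > qd_min & variants$dp > dp_min
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_tally") <- c(
    not_hom_alt = sum(!hom),
    missing_annotation = sum(missing_ann),
    low_qd = sum(low_qd),
    low_dp = sum(low_dp)
  )
  out
}

variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' Intersect homozygous-alt variant sets from two samples
#'
#' Variants identical in (chrom, pos, ref, alt) and homozygous-alt in both
#' samples. Inputs are expected to be hard-filtered already; homozygosity is
#' still enforced.
#'
#' @param set_a,set_b Variant tables.
#' @return The rows of `set_a` shared with `set_b`.
#' @export
intersect_homozygous <- function(set_a, set_b) {
  a <- set_a[set_a$gt == "1/1", , drop = FALSE]
  b <- set_b[set_b$gt == "1/1", , drop = FALSE]
  out <- a[variant_key(a) %in% variant_key(b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

as_gene_ranges <- function(genes) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  if (is.list(genes) && all(vapply(genes, inherits, TRUE, "gene_model"))) {
    genes <- data.frame(
      chrom = vapply(genes, `[[`, "", "contig"),
      start = vapply(genes, `[[`, 1L, "gene_start"),
      end = vapply(genes, `[[`, 1L, "gene_end")
    )
  }
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end))
}

#' Keep variants lying within gene bodies
#'
#' A variant passes when its position falls within `[gene start, gene end]`
#' of any protein-coding gene - exons and introns alike, UTR exons included.
#'
#' @param variants Variant table.
#' @param genes A `gene_model`, a list of them, or a data frame with columns
#'   `chrom`, `start`, `end`.
#' @return The retained rows.
#' @export
genic_filter <- function(variants, genes) {
  if (nrow(variants) == 0L) return(variants)
  gr_genes <- as_gene_ranges(genes)
  gr_var <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos,
                                                    variants$pos))
  hits <- GenomicRanges::findOverlaps(gr_var, gr_genes)
  out <- variants[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Adjudicate a candidate locus against low-coverage read support
#'
#' Applies the study's support/refute logic at a locus: any alternate-allele
#' read in a control refutes the variant (`refuted_control_alt`); any
#' reference read in an additional affected animal refutes it
#' (`refuted_affected_ref`); refutation is assessed before coverage. If fewer
#' than `ceiling(min_fraction * subset size)` samples of either subset reach
#' `min_depth` total reads at the locus the verdict is
#' `insufficient_coverage`; otherwise `supported`.
#'
#' @param locus List or one-row data frame with `chrom` and `pos`.
#' @param pileups Pileup table (`sample`, `chrom`, `pos`, `ref_reads`,
#'   `alt_reads`); subset samples without a row at the locus count as zero
#'   coverage.
#' @param controls,extra_affected Character vectors of sample ids.
#' @param min_depth Minimum total reads for a sample to count as covered.
#' @param min_fraction Required covered fraction of each subset.
#' @return One-row data frame: `chrom`, `pos`, `verdict`.
#' @export
lowcov_adjudicate <- function(locus, pileups, controls, extra_affected,
                              min_depth = 1L, min_fraction = 0.75) {
  assert_that(length(controls) > 0L,
              "control subset is empty; the coverage rule is undefined")
  assert_that(length(extra_affected) > 0L,
              "extra-affected subset is empty; the coverage rule is undefined")
  at <- pileups[pileups$chrom == locus$chrom & pileups$pos == locus$pos, ,
                drop = FALSE]
  get <- function(ids, col) {
    v <- at[[col]][match(ids, at$sample)]
    v[is.na(v)] <- 0L
    v
  }
  ctrl_alt <- get(controls, "alt_reads")
  ctrl_tot <- ctrl_alt + get(controls, "ref_reads")
  aff_ref <- get(extra_affected, "ref_reads")
  aff_tot <- aff_ref + get(extra_affected, "alt_reads")

  verdict <- if (any(ctrl_alt >= 1L)) {
    "refuted_control_alt"
  } else if (any(aff_ref >= 1L)) {
    "refuted_affected_ref"
  } else if (sum(ctrl_tot >= min_depth) <
               ceiling(min_fraction * length(controls)) ||
             sum(aff_tot >= min_depth) <
               ceiling(min_fraction * length(extra_affected))) {
    "insufficient_coverage"
  } else {
    "supported"
  }
  data.frame(chrom = locus$chrom, pos = locus$pos, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' @rdname lowcov_adjudicate
#' @param variants Variant table; one verdict is produced per row.
#' @export
adjudicate_variants <- function(variants, pileups, controls, extra_affected,
                                min_depth = 1L, min_fraction = 0.75) {
  if (nrow(variants) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      verdict = character(0)))
  }
  do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    lowcov_adjudicate(variants[i, ], pileups, controls, extra_affected,
                      min_depth, min_fraction)
  }))
}

## Fixed four-class severity table standing in for a VEP-style ordering.
SEVERITY_CLASS <- c(
  splice_donor_variant = 1L,
  splice_acceptor_variant = 1L,
  stop_gained = 2L,
  frameshift_variant = 2L,
  missense_variant = 3L,
  synonymous_variant = 3L,
  intron_variant = 4L,
  utr_variant = 4L,
  intergenic_variant = 4L
)

#' Rank supported candidate variants by consequence severity
#'
#' Orders candidates by a fixed four-class severity table (splice donor or
#' acceptor > stop-gain or frameshift > other coding > other non-coding),
#' ties broken by chromosome then position. Only variants adjudicated
#' `supported` appear.
#'
#' @param variants Variant table (post-cascade).
#' @param consequences Data frame keyed by (chrom, pos, ref, alt) with a
#'   `term` column as produced by [classify_variant()].
#' @param verdicts Data frame keyed by (chrom, pos) with a `verdict` column
#'   as produced by [adjudicate_variants()].
#' @return Ranked candidate table with `term`, `severity_class`, `verdict`
#'   and `rank` columns.
#' @export
prioritize <- function(variants, consequences, verdicts) {
  out <- variants
  out$term <- consequences$term[match(variant_key(out),
                                      variant_key(consequences))]
  out$severity_class <- unname(SEVERITY_CLASS[out$term])
  vk <- paste(verdicts$chrom, verdicts$pos)
  out$verdict <- verdicts$verdict[match(paste(out$chrom, out$pos), vk)]
  out <- out[!is.na(out$verdict) & out$verdict == "supported", , drop = FALSE]
  out <- out[order(out$severity_class, out$chrom, out$pos), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
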