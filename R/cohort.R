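## Cohort simulation.
##
## Emulates the sequencing design of the study: two affected animals at deep
## (~50x) coverage with per-sample VCFs, plus additional affected animals and
## unrelated controls at low (~5x) coverage represented only as per-locus
## read-support counts. A single causal variant - the deletion of the +1 G of
## the retention-modelled intron's splice donor - is planted homozygous in
## all affected animals, heterozygous in carriers and absent in controls.
## Background variants emulate breed-vs-reference differences: biallelic SNVs
## at a configurable density whose genotypes are independent of disease
## status.

#' Configuration for the synthetic sequencing cohort
#'
#' Defaults follow the study design: 2 deep-coverage affected, 4 low-coverage
#' affected, 8 low-coverage unrelated controls, 6 carriers, ~5x mean depth
#' for the low-coverage arm. The background density default yields roughly
#' 200 background variants on the default forged contig.
#'
#' @param n_affected_hi Deep-coverage affected samples (per-sample VCFs).
#' @param n_affected_lo Additional low-coverage affected samples.
#' @param n_controls_lo Low-coverage unrelated controls.
#' @param n_carriers Low-coverage carriers (heterozygous for the causal
#'   allele); kept distinct from the control subset.
#' @param background_variant_rate Background SNVs per kb of contig.
#' @param mean_depth_hi Mean read depth of the deep samples.
#' @param mean_depth_lo Mean read depth of the low-coverage samples; per-locus
#'   depths are Poisson with this mean.
#' @param qd_mean,qd_sd Normal parameters of the simulated quality-by-depth
#'   (QD) annotation.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_affected_hi = 2L,
                          n_affected_lo = 4L,
                          n_controls_lo = 8L,
                          n_carriers = 6L,
                          background_variant_rate = 24,
                          mean_depth_hi = 50,
                          mean_depth_lo = 5,
                          qd_mean = 30,
                          qd_sd = 5,
                          seed = 1L) {
  cfg <- list(
    n_affected_hi = as.integer(n_affected_hi),
    n_affected_lo = as.integer(n_affected_lo),
    n_controls_lo = as.integer(n_controls_lo),
    n_carriers = as.integer(n_carriers),
    background_variant_rate = background_variant_rate,
    mean_depth_hi = mean_depth_hi,
    mean_depth_lo = mean_depth_lo,
    qd_mean = qd_mean,
    qd_sd = qd_sd,
    seed = as.integer(seed)
  )
  counts <- unlist(cfg[c("n_affected_hi", "n_affected_lo", "n_controls_lo",
                         "n_carriers")])
  assert_that(all(counts >= 0L), "cohort counts must be non-negative")
  assert_that(cfg$mean_depth_lo > 0, "mean_depth_lo must be positive")
  assert_that(cfg$background_variant_rate >= 0,
              "background_variant_rate must be non-negative")
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a sequencing cohort around a forged gene
#'
#' Plants the causal splice-donor deletion ([causal_variant()]) homozygous-alt
#' in every affected animal, heterozygous in carriers, absent in controls,
#' and sprinkles background SNVs whose genotypes are drawn from
#' Hardy-Weinberg proportions at a uniform random allele frequency,
#' independently of status. Deep samples get per-sample VCF records (GT, with
#' QD and DP annotations; the causal record is simulated at full quality, so
#' it always clears the hard-filter thresholds). Low-coverage samples get
#' per-locus ref/alt read counts with Poisson depths.
#'
#' @param gene A `gene_model` from [forge_gene_model()].
#' @param config A [cohort_config()].
#' @param dir Optional output directory; when given, per-sample VCFs
#'   (`<sample>.vcf`), `pileups.tsv`, `status.tsv` and `truth.json` are
#'   written there.
#' @return A list of class `cohort_sim`: `samples`, `variants`, `genotypes`
#'   (alt-allele dosage matrix), `vcf` (list of per-deep-sample variant
#'   tables), `pileups`, `truth`, and `paths` when `dir` was given.
#' @export
simulate_cohort <- function(gene, config = cohort_config(), dir = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  sim <- with_seed(config$seed, simulate_cohort_impl(gene, config))
  if (!is.null(dir)) {
    sim$paths <- write_cohort(sim, dir)
  }
  sim
}

simulate_cohort_impl <- function(gene, cfg) {
  contig_len <- nchar(gene$genome)
  causal <- causal_variant(gene)

  samples <- data.frame(
    id = c(sprintf("AF_HI_%d", seq_len(cfg$n_affected_hi)),
           sprintf("AF_LO_%d", seq_len(cfg$n_affected_lo)),
           sprintf("CTRL_%d", seq_len(cfg$n_controls_lo)),
           sprintf("CAR_%d", seq_len(cfg$n_carriers))),
    status = c(rep("affected", cfg$n_affected_hi + cfg$n_affected_lo),
               rep("control", cfg$n_controls_lo),
               rep("carrier", cfg$n_carriers)),
    platform = c(rep("deep", cfg$n_affected_hi),
                 rep("low", cfg$n_affected_lo + cfg$n_controls_lo +
                       cfg$n_carriers)),
    stringsAsFactors = FALSE
  )
  n_samp <- nrow(samples)

  ## Background SNVs, density per kb, positions unique and away from the
  ## causal anchor.
  n_bg <- rpois(1L, cfg$background_variant_rate * contig_len / 1000)
  avail <- setdiff(seq_len(contig_len), causal$pos + c(-1L, 0L, 1L))
  bg_pos <- sort(sample(avail, min(n_bg, length(avail))))
  if (length(bg_pos)) {
    bg_ref <- substring(gene$genome, bg_pos, bg_pos)
    bg_alt <- vapply(bg_ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     "")
  } else {
    bg_ref <- character(0)
    bg_alt <- character(0)
  }

  variants <- data.frame(
    chrom = gene$contig,
    pos = c(causal$pos, bg_pos),
    ref = c(causal$ref, bg_ref),
    alt = c(causal$alt, unname(bg_alt)),
    is_causal = c(TRUE, rep(FALSE, length(bg_pos))),
    stringsAsFactors = FALSE
  )
  ord <- order(variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  n_var <- nrow(variants)

  ## Alt-allele dosage matrix: causal by status, background HWE.
  geno <- matrix(0L, nrow = n_var, ncol = n_samp,
                 dimnames = list(NULL, samples$id))
  af <- numeric(n_var)
  for (i in seq_len(n_var)) {
    if (variants$is_causal[i]) {
      geno[i, ] <- c(affected = 2L, control = 0L,
                     carrier = 1L)[samples$status]
      af[i] <- NA_real_
    } else {
      f <- runif(1L, 0.1, 0.9)
      af[i] <- f
      geno[i, ] <- rbinom(n_samp, 2L, f)
    }
  }
  variants$af <- af

  ## Deep-sample VCF tables: records where the sample carries the alt.
  deep_ids <- samples$id[samples$platform == "deep"]
  vcf <- lapply(deep_ids, function(sid) {
    dose <- geno[, sid]
    keep <- which(dose > 0L)
    dp <- rpois(length(keep), cfg$mean_depth_hi)
    qd <- rnorm(length(keep), cfg$qd_mean, cfg$qd_sd)
    is_causal <- variants$is_causal[keep]
    ## The causal record is simulated at full quality: depth and QD are
    ## drawn truncated above the hard-filter thresholds.
    dp[is_causal] <- pmax(dp[is_causal], 11L)
    qd[is_causal] <- pmax(qd[is_causal], 20.5)
    data.frame(
      chrom = variants$chrom[keep],
      pos = variants$pos[keep],
      ref = variants$ref[keep],
      alt = variants$alt[keep],
      gt = ifelse(dose[keep] == 2L, "1/1", "0/1"),
      qd = round(qd, 2),
      dp = dp,
      stringsAsFactors = FALSE
    )
  })
  names(vcf) <- deep_ids

  ## Low-coverage pileups at every variant locus.
  low_ids <- samples$id[samples$platform == "low"]
  if (length(low_ids)) {
    pl <- expand.grid(sample = low_ids, idx = seq_len(n_var),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    depth <- rpois(nrow(pl), cfg$mean_depth_lo)
    dose <- geno[cbind(pl$idx, match(pl$sample, samples$id))]
    alt_reads <- rbinom(nrow(pl), depth, dose / 2)
    pileups <- data.frame(
      sample = pl$sample,
      chrom = variants$chrom[pl$idx],
      pos = variants$pos[pl$idx],
      ref_reads = depth - alt_reads,
      alt_reads = alt_reads,
      stringsAsFactors = FALSE
    )
    pileups <- pileups[order(pileups$sample, pileups$pos), , drop = FALSE]
    rownames(pileups) <- NULL
  } else {
    pileups <- data.frame(sample = character(0), chrom = character(0),
                          pos = integer(0), ref_reads = integer(0),
                          alt_reads = integer(0))
  }

  structure(list(
    samples = samples,
    variants = variants,
    genotypes = geno,
    vcf = vcf,
    pileups = pileups,
    truth = list(chrom = causal$chrom, pos = causal$pos, ref = causal$ref,
                 alt = causal$alt, intron = causal$intron),
    contig_length = contig_len,
    config = cfg
  ), class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$samples), " samples (",
      sum(x$samples$platform == "deep"), " deep), ",
      nrow(x$variants), " variant loci (1 planted causal at ",
      x$truth$chrom, ":", x$truth$pos, ")\n", sep = "")
  invisible(x)
}

## --- serialization --------------------------------------------------------

#' Write a simulated cohort to disk
#'
#' Emits one VCF 4.2 per deep sample (INFO keys `QD` and `DP`, `GT` in
#' FORMAT), a TSV pileup table, a sample status TSV and a JSON truth record
#' naming the planted locus. Byte-deterministic for a given simulation.
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory.
#' @return Named list of paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf_paths <- vapply(names(sim$vcf), function(sid) {
    path <- file.path(dir, paste0(sid, ".vcf"))
    write_sample_vcf(sim$vcf[[sid]], sid, sim$variants$chrom[1L],
                     sim$contig_length, path)
    path
  }, character(1))
  pileup_path <- file.path(dir, "pileups.tsv")
  write.table(sim$pileups, pileup_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  status_path <- file.path(dir, "status.tsv")
  write.table(sim$samples, status_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(vcf = vcf_paths, pileups = pileup_path, status = status_path,
       truth = truth_path)
}

## Minimal fixed-layout VCF 4.2 emitter for the simulator's own records;
## VariantAnnotation::readVcf round-trips this (covered by tests).
write_sample_vcf <- function(tab, sample_id, contig, contig_len, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Variant quality by depth\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id)
  )
  recs <- if (nrow(tab)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tQD=%s;DP=%d\tGT\t%s",
            tab$chrom, tab$pos, tab$ref, tab$alt,
            format(tab$qd, trim = TRUE, nsmall = 2, scientific = FALSE),
            tab$dp, tab$gt)
  } else {
    character(0)
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read and write the low-coverage pileup summary table
#'
#' Columns: `sample`, `chrom`, `pos`, `ref_reads`, `alt_reads`.
#' @param path TSV path.
#' @return Data frame.
#' @export
read_pileups <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "pos", "ref_reads", "alt_reads")
  assert_that(all(need %in% names(tab)),
              paste("pileup table must have columns:",
                    paste(need, collapse = ", ")))
  tab
}
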