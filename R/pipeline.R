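## End-to-end orchestration.
##
## run_discovery() chains simulation (or file input) -> hard filter ->
## intersection -> genic filter -> low-coverage adjudication ->
## consequence classification -> severity ranking, and summarises the top
## candidate with its mutant-protein report. run_contractility() chains
## simulation (or a fibre table) -> per-fibre Hill fits -> group
## comparison. Both log stage counts to stderr and write machine-readable
## outputs when given an output directory.

#' Configuration for a discovery run
#'
#' Exactly one input mode: either `simulate = TRUE` (a gene is forged and a
#' cohort simulated from the two config blocks) or paths to VCFs, a pileup
#' table, a status table and the gene model files.
#'
#' @param simulate Simulate inputs instead of reading files.
#' @param gene A [gene_forge_config()] (simulation mode).
#' @param cohort A [cohort_config()] (simulation mode).
#' @param vcf_paths Character vector of per-sample VCFs (file mode).
#' @param pileup_path Pileup TSV (file mode).
#' @param status_path Sample status TSV with `id`, `status`, and optionally
#'   `platform` columns (file mode).
#' @param genome_fa,gff3 Gene model files (file mode).
#' @param qd_min,dp_min Hard-filter thresholds (exclusive).
#' @param min_depth,min_fraction Low-coverage adjudication rule.
#' @param seed Master seed (overrides the block seeds in simulation mode).
#' @param outdir Optional output directory.
#' @return A list of class `discovery_config`.
#' @export
discovery_config <- function(simulate = TRUE,
                             gene = gene_forge_config(),
                             cohort = cohort_config(),
                             vcf_paths = NULL,
                             pileup_path = NULL,
                             status_path = NULL,
                             genome_fa = NULL,
                             gff3 = NULL,
                             qd_min = 20, dp_min = 10,
                             min_depth = 1L, min_fraction = 0.75,
                             seed = 1L,
                             outdir = NULL) {
  cfg <- as.list(environment())
  if (simulate) {
    assert_that(is.null(vcf_paths) && is.null(pileup_path),
                "simulation mode and input paths are mutually exclusive")
  } else {
    assert_that(!is.null(vcf_paths) && !is.null(pileup_path) &&
                  !is.null(status_path) && !is.null(genome_fa) &&
                  !is.null(gff3),
                paste("file mode needs vcf_paths, pileup_path, status_path,",
                      "genome_fa and gff3"))
  }
  class(cfg) <- "discovery_config"
  cfg
}

stage_log <- function(counts, stage, n) {
  message(sprintf("[ocpmd] %-22s %d", stage, n))
  counts[[stage]] <- n
  counts
}

#' Run the variant-discovery pipeline
#'
#' @param config A [discovery_config()].
#' @return Object of class `discovery_report`: `candidates` (ranked table),
#'   `top_consequence`, `protein_report` (for a splice-candidate top hit),
#'   `counts` (per-stage record counts), `truth` (simulation mode), `seed`.
#' @export
run_discovery <- function(config = discovery_config()) {
  counts <- list()

  if (config$simulate) {
    gene_cfg <- config$gene
    gene_cfg$seed <- derive_seed(config$seed, "gene")
    gene <- forge_gene_model(gene_cfg)
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- derive_seed(config$seed, "cohort")
    sim <- simulate_cohort(gene, cohort_cfg,
                           dir = if (!is.null(config$outdir)) {
                             file.path(config$outdir, "sim")
                           })
    vcf_tabs <- sim$vcf
    pileups <- sim$pileups
    samples <- sim$samples
    truth <- sim$truth
  } else {
    gene <- read_gene_model(config$genome_fa, config$gff3)
    vcf_tabs <- lapply(config$vcf_paths, read_sample_vcf)
    names(vcf_tabs) <- basename(config$vcf_paths)
    pileups <- read_pileups(config$pileup_path)
    samples <- read.table(config$status_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    if (!"platform" %in% names(samples)) {
      deep_ids <- character(0)
      samples$platform <- ifelse(samples$id %in% unique(pileups$sample),
                                 "low", "deep")
    }
    truth <- NULL
  }
  assert_that(length(vcf_tabs) >= 1L, "no deep-sample VCFs to analyse")

  controls <- samples$id[samples$status == "control" &
                           samples$platform == "low"]
  extra_affected <- samples$id[samples$status == "affected" &
                                 samples$platform == "low"]

  counts <- stage_log(counts, "input_records",
                      sum(vapply(vcf_tabs, nrow, 1L)))
  filtered <- lapply(vcf_tabs, hard_filter,
                     qd_min = config$qd_min, dp_min = config$dp_min)
  counts <- stage_log(counts, "hard_filtered",
                      sum(vapply(filtered, nrow, 1L)))
  shared <- Reduce(intersect_homozygous, filtered)
  counts <- stage_log(counts, "shared_homozygous", nrow(shared))
  genic <- genic_filter(shared, gene)
  counts <- stage_log(counts, "genic", nrow(genic))
  verdicts <- adjudicate_variants(genic, pileups, controls, extra_affected,
                                  min_depth = config$min_depth,
                                  min_fraction = config$min_fraction)
  counts <- stage_log(counts, "supported",
                      sum(verdicts$verdict == "supported"))
  consequences <- if (nrow(genic)) classify_variants(genic, gene) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), term = character(0))
  ranked <- prioritize(genic, consequences, verdicts)
  counts <- stage_log(counts, "ranked_candidates", nrow(ranked))

  top_consequence <- NULL
  protein <- NULL
  if (nrow(ranked)) {
    top_consequence <- classify_variant(ranked[1L, ], gene)
    if (top_consequence$term == "splice_donor_variant" &&
        !is.na(top_consequence$intron) && !is.na(gene$cds_cdna_start)) {
      protein <- tryCatch(splice_report(gene, top_consequence$intron),
                          error = function(e) NULL)
    }
  } else {
    warning("no candidate survived the cascade", call. = FALSE)
  }

  report <- structure(list(
    candidates = ranked,
    top_consequence = top_consequence,
    protein_report = protein,
    counts = counts,
    truth = truth,
    seed = config$seed,
    params = config[c("qd_min", "dp_min", "min_depth", "min_fraction")]
  ), class = "discovery_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(ranked, file.path(config$outdir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      c(list(seed = config$seed), report$params, counts),
      file.path(config$outdir, "stage_counts.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.discovery_report <- function(x, ...) {
  cat("Discovery report (seed ", x$seed, ")\n", sep = "")
  for (s in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", s, x$counts[[s]]))
  }
  if (!is.null(x$top_consequence)) {
    tc <- x$top_consequence
    cat("Top candidate: ", tc$chrom, ":", tc$pos, " ", tc$ref, ">", tc$alt,
        " [", tc$term, if (!is.na(tc$name)) paste0(", ", tc$name), "]\n",
        sep = "")
  } else {
    cat("No surviving candidate.\n")
  }
  if (!is.null(x$protein_report)) print(x$protein_report)
  invisible(x)
}

#' Run the contractility analysis
#'
#' @param data Long fibre table (`fibre_id`, `group`, `pCa`, `force`) or a
#'   TSV path; `NULL` simulates from `config`.
#' @param config A [fibre_sim_config()] used when `data` is `NULL`.
#' @param normalize Normalize each fibre's curve to its pCa 4.5 force
#'   before fitting (set for raw force input).
#' @param pooled Pool fibres per group into one fit.
#' @param welch Welch t-test instead of equal-variance.
#' @param outdir Optional output directory (`fits.tsv`,
#'   `group_comparison.tsv`).
#' @param seed Master seed used in simulation mode.
#' @return Object of class `contractility_report`: `fits` (per-fibre
#'   estimates), `comparison` (or `NULL` for a single group).
#' @export
run_contractility <- function(data = NULL, config = fibre_sim_config(),
                              normalize = FALSE, pooled = FALSE,
                              welch = FALSE, outdir = NULL, seed = NULL) {
  if (is.null(data)) {
    if (!is.null(seed)) config$seed <- derive_seed(seed, "fibres")
    data <- simulate_force_pca(config)
  } else if (is.character(data)) {
    assert_that(file.exists(data),
                paste0("fibre table not found: '", data, "'"))
    data <- read.table(data, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  }
  assert_that(nrow(data) > 0L, "empty force-pCa table")
  if (normalize) {
    data <- do.call(rbind, lapply(split(data, data$fibre_id),
                                  normalize_curve))
    rownames(data) <- NULL
  }
  fits <- fit_hill_groups(data, pooled = pooled)
  comparison <- NULL
  if (length(unique(fits$group)) >= 2L) {
    comparison <- compare_groups(fits, welch = welch)
  } else {
    warning("single group: fits only, comparison skipped", call. = FALSE)
  }
  report <- structure(list(fits = fits, comparison = comparison),
                      class = "contractility_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(fits, file.path(outdir, "fits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(comparison)) {
      write.table(comparison, file.path(outdir, "group_comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  report
}

#' @export
print.contractility_report <- function(x, ...) {
  cat("Contractility analysis: ", nrow(x$fits), " fitted curves\n", sep = "")
  for (g in unique(x$fits$group)) {
    sel <- x$fits$group == g
    cat(sprintf("  %-12s pCa50 %.3f +/- %.3f, nH %.2f +/- %.2f (n=%d)\n",
                g, mean(x$fits$pca50[sel]), sd(x$fits$pca50[sel]),
                mean(x$fits$nh[sel]), sd(x$fits$nh[sel]), sum(sel)))
  }
  if (!is.null(x$comparison)) {
    cat("Group comparison (two-tailed unpaired t-test):\n")
    cmp <- x$comparison
    for (i in seq_len(nrow(cmp))) {
      cat(sprintf("  %-8s t = %.3f, df = %.1f, p = %.3g\n",
                  cmp$metric[i], cmp$t[i], cmp$df[i], cmp$p[i]))
    }
  }
  invisible(x)
}
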