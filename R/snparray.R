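## SNP-array genotype simulation.
##
## Emulates a medium-density array (OvineSNP50-like spacing) over one
## synthetic chromosome that carries the forged gene contig at its centre.
## Affected individuals share an identical homozygous haplotype across a
## configurable autozygous window containing the causal locus; carriers
## carry one copy of that haplotype inside the window; outside the window
## (and for controls everywhere) genotypes follow Hardy-Weinberg
## proportions at per-marker allele frequencies. No meiosis/recombination
## model beyond the planted block is attempted.

#' Configuration for the SNP-array simulator
#'
#' @param n_markers Markers on the simulated chromosome.
#' @param map_length_bp Chromosome length; default 50 Mb with 1000 markers
#'   gives the ~50 kb spacing of a 50k ovine array.
#' @param window_bp Width of the autozygous window centred on the causal
#'   locus; 0 disables the window.
#' @param maf_range Range of per-marker minor-allele frequencies.
#' @param causal_freq Population frequency of the causal allele (used for
#'   the marker placed at the causal position).
#' @param include_causal_marker Place one marker exactly at the causal
#'   genomic position, genotyped from disease status.
#' @param seed Integer seed.
#' @return A list of class `snp_array_config`.
#' @export
snp_array_config <- function(n_markers = 1000L,
                             map_length_bp = 5e7,
                             window_bp = 1e7,
                             maf_range = c(0.05, 0.5),
                             causal_freq = 0.05,
                             include_causal_marker = TRUE,
                             seed = 1L) {
  cfg <- list(n_markers = as.integer(n_markers),
              map_length_bp = as.numeric(map_length_bp),
              window_bp = as.numeric(window_bp),
              maf_range = maf_range,
              causal_freq = causal_freq,
              include_causal_marker = isTRUE(include_causal_marker),
              seed = as.integer(seed))
  assert_that(cfg$n_markers >= 2L, "need at least 2 markers")
  assert_that(cfg$window_bp >= 0, "window_bp must be non-negative")
  class(cfg) <- "snp_array_config"
  cfg
}

#' Default genotyping panel statuses
#'
#' The study's array panel: 14 affected and 6 carrier sheep.
#' @param n_affected,n_carriers,n_controls Panel composition.
#' @return Data frame with `id` and `status`.
#' @export
array_statuses <- function(n_affected = 14L, n_carriers = 6L,
                           n_controls = 0L) {
  data.frame(
    id = c(sprintf("AFF_%d", seq_len(n_affected)),
           sprintf("CAR_%d", seq_len(n_carriers)),
           sprintf("CTL_%d", seq_len(n_controls))),
    status = c(rep("affected", n_affected), rep("carrier", n_carriers),
               rep("control", n_controls)),
    stringsAsFactors = FALSE
  )
}

#' Simulate SNP-array genotypes with a planted autozygous block
#'
#' @param gene A `gene_model`; its causal-variant position is embedded at
#'   the centre of the simulated chromosome. May be `NULL`, in which case
#'   the window is centred on the chromosome midpoint and no causal marker
#'   is placed.
#' @param statuses Data frame with `id` and `status`
#'   (affected/carrier/control); see [array_statuses()].
#' @param config A [snp_array_config()].
#' @return A list of class `snp_array_sim`: `map` (chrom, snp_id, cm, pos),
#'   `genotypes` (markers x individuals, minor/alt allele dosage 0/1/2),
#'   `statuses`, `window` (start/end, or NULL), `causal_row` (map row of the
#'   causal marker or NA).
#' @export
simulate_snp_array <- function(gene, statuses, config = snp_array_config()) {
  stopifnot(is.data.frame(statuses),
            all(c("id", "status") %in% names(statuses)))
  with_seed(config$seed, simulate_snp_array_impl(gene, statuses, config))
}

simulate_snp_array_impl <- function(gene, statuses, cfg) {
  chrom <- if (is.null(gene)) "chr1" else gene$contig
  causal_pos <- if (is.null(gene)) {
    round(cfg$map_length_bp / 2)
  } else {
    offset <- round((cfg$map_length_bp - nchar(gene$genome)) / 2)
    offset + causal_variant(gene)$pos
  }
  win <- NULL
  if (cfg$window_bp > 0) {
    win <- c(start = causal_pos - cfg$window_bp / 2,
             end = causal_pos + cfg$window_bp / 2)
    if (win["start"] < 1 || win["end"] > cfg$map_length_bp) {
      stop("autozygous window [", win["start"], ", ", win["end"],
           "] lies outside the map extent [1, ", cfg$map_length_bp, "]",
           call. = FALSE)
    }
  }

  pos <- sort(sample.int(cfg$map_length_bp, cfg$n_markers))
  causal_row <- NA_integer_
  if (cfg$include_causal_marker && !is.null(gene)) {
    pos <- sort(unique(c(pos, causal_pos)))
    causal_row <- match(causal_pos, pos)
  }
  n_mark <- length(pos)
  map <- data.frame(chrom = chrom,
                    snp_id = sprintf("snp%05d", seq_len(n_mark)),
                    cm = 0,
                    pos = pos,
                    stringsAsFactors = FALSE)

  n_ind <- nrow(statuses)
  freq <- runif(n_mark, cfg$maf_range[1], cfg$maf_range[2])
  in_win <- if (is.null(win)) rep(FALSE, n_mark) else {
    pos >= win["start"] & pos <= win["end"]
  }
  ## the shared (identical-by-descent) haplotype across the window
  hap <- rbinom(n_mark, 1L, freq)

  geno <- matrix(0L, nrow = n_mark, ncol = n_ind,
                 dimnames = list(map$snp_id, statuses$id))
  for (j in seq_len(n_ind)) {
    g <- rbinom(n_mark, 2L, freq)
    st <- statuses$status[j]
    if (st == "affected") {
      g[in_win] <- 2L * hap[in_win]
    } else if (st == "carrier") {
      g[in_win] <- hap[in_win] + rbinom(sum(in_win), 1L, freq[in_win])
    }
    geno[, j] <- g
  }
  if (!is.na(causal_row)) {
    geno[causal_row, ] <- c(affected = 2L, carrier = 1L,
                            control = 0L)[statuses$status]
  }

  structure(list(map = map, genotypes = geno, statuses = statuses,
                 window = win, causal_row = causal_row, config = cfg),
            class = "snp_array_sim")
}

## --- PED/MAP serialization ------------------------------------------------
## Plain-text PLINK formats; written and parsed here directly since no
## installed package handles them.

#' Write and read PED/MAP genotype files
#'
#' PED columns: family id, individual id, father, mother, sex, phenotype
#' (2 = affected, 1 = otherwise), then two allele calls (`A`/`B`) per
#' marker; `0 0` encodes a missing genotype. MAP columns: chromosome,
#' marker id, genetic position (cM), physical position (bp).
#'
#' @param sim A `snp_array_sim`.
#' @param dir Output directory.
#' @param prefix File prefix.
#' @return Named character vector of paths (`ped`, `map`).
#' @export
write_ped_map <- function(sim, dir, prefix = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  map_path <- file.path(dir, paste0(prefix, ".map"))
  write.table(sim$map, map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  allele_str <- function(g) {
    out <- c("A\tA", "A\tB", "B\tB")[g + 1L]
    out[is.na(g)] <- "0\t0"
    out
  }
  lines <- vapply(seq_len(nrow(sim$statuses)), function(j) {
    id <- sim$statuses$id[j]
    pheno <- if (sim$statuses$status[j] == "affected") 2L else 1L
    paste(c(id, id, 0L, 0L, 0L, pheno, allele_str(sim$genotypes[, j])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, ped_path)
  c(ped = ped_path, map = map_path)
}

#' @rdname write_ped_map
#' @param ped,map PED and MAP paths.
#' @return `read_ped_map()`: list with `map` (data frame) and `genotypes`
#'   (markers x individuals dosage matrix, `NA` = missing).
#' @export
read_ped_map <- function(ped, map) {
  map_tab <- read.table(map, header = FALSE, sep = "\t",
                        col.names = c("chrom", "snp_id", "cm", "pos"),
                        stringsAsFactors = FALSE)
  ped_tab <- read.table(ped, header = FALSE, sep = "\t",
                        stringsAsFactors = FALSE)
  n_mark <- nrow(map_tab)
  assert_that(ncol(ped_tab) == 6L + 2L * n_mark,
              "PED column count does not match the MAP marker count")
  ids <- ped_tab[[2]]
  a1 <- as.matrix(ped_tab[, 6L + 2L * seq_len(n_mark) - 1L, drop = FALSE])
  a2 <- as.matrix(ped_tab[, 6L + 2L * seq_len(n_mark), drop = FALSE])
  geno <- matrix(NA_integer_, nrow = n_mark, ncol = length(ids),
                 dimnames = list(map_tab$snp_id, ids))
  for (j in seq_along(ids)) {
    x1 <- a1[j, ]; x2 <- a2[j, ]
    ok <- x1 != "0" & x2 != "0"
    geno[ok, j] <- (x1[ok] == "B") + (x2[ok] == "B")
  }
  list(map = map_tab, genotypes = geno,
       phenotypes = setNames(ped_tab[[6]], ids))
}
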