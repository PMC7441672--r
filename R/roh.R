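## Runs-of-homozygosity mapping.
##
## Calls per-individual ROH segments from array genotypes and ranks regions
## shared across individuals with the study's carrier-weighting logic:
## regions homozygous in all affected and in no carrier rank first; regions
## also homozygous in a carrier are kept but down-weighted; regions
## homozygous only in carriers are excluded.

#' Call runs of homozygosity for one individual
#'
#' A run is a maximal stretch of markers that starts and ends on a
#' homozygous call and contains at most `max_het` embedded heterozygous
#' calls; missing calls never break a run and do not count towards
#' `min_snps`. Runs are found greedily left to right (each run is extended
#' as far as the het allowance permits, then scanning resumes after it), so
#' the reported segments are non-overlapping. Runs with fewer than
#' `min_snps` genotyped markers or spanning less than `min_length_bp` are
#' dropped.
#'
#' Defaults (20 SNPs, 1 Mb, 1 het) suit ~50k-marker ovine array density.
#'
#' @param genotypes Integer vector of alt-allele dosages (0/1/2, `NA` =
#'   missing), one per map row.
#' @param map Data frame with `chrom` and `pos`, sorted by chromosome then
#'   position (unsorted input is an error).
#' @param min_snps Minimum genotyped markers per run.
#' @param min_length_bp Minimum spanned length (bp, closed span).
#' @param max_het Maximum embedded heterozygous calls per run.
#' @return Data frame: `chrom`, `start`, `end` (bp, 1-based closed),
#'   `n_snps`, `n_het_exceptions`.
#' @export
call_roh <- function(genotypes, map, min_snps = 20L, min_length_bp = 1e6,
                     max_het = 1L) {
  assert_that(length(genotypes) == nrow(map),
              "genotypes and map must have the same length")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0),
                      n_het_exceptions = integer(0))
  if (all(is.na(genotypes))) return(empty)

  out <- list()
  for (chr in unique(map$chrom)) {
    sel <- which(map$chrom == chr)
    pos <- map$pos[sel]
    if (is.unsorted(pos, strictly = FALSE)) {
      stop("map positions are not sorted on ", chr, call. = FALSE)
    }
    g <- genotypes[sel]
    segs <- roh_scan(g, pos, min_snps, min_length_bp, max_het)
    if (nrow(segs)) {
      segs$chrom <- chr
      out[[length(out) + 1L]] <- segs[, c("chrom", "start", "end", "n_snps",
                                          "n_het_exceptions")]
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Greedy leftmost-maximal scan over one chromosome.
roh_scan <- function(g, pos, min_snps, min_length_bp, max_het) {
  n <- length(g)
  is_het <- !is.na(g) & g == 1L
  is_hom <- !is.na(g) & g != 1L
  segs <- list()
  hom_idx <- which(is_hom)
  ptr <- 1L
  cursor <- 1L
  while (ptr <= length(hom_idx)) {
    while (ptr <= length(hom_idx) && hom_idx[ptr] < cursor) ptr <- ptr + 1L
    if (ptr > length(hom_idx)) break
    start <- hom_idx[ptr]
    last_hom <- start
    hets <- 0L
    t <- start + 1L
    while (t <= n) {
      if (is_hom[t]) {
        last_hom <- t
      } else if (is_het[t]) {
        if (hets >= max_het) break
        hets <- hets + 1L
      }
      t <- t + 1L
    }
    idx <- start:last_hom
    n_snps <- sum(!is.na(g[idx]))
    n_het <- sum(is_het[idx])
    span <- pos[last_hom] - pos[start] + 1
    if (n_snps >= min_snps && span >= min_length_bp) {
      segs[[length(segs) + 1L]] <- data.frame(
        start = pos[start], end = pos[last_hom],
        n_snps = n_snps, n_het_exceptions = n_het)
    }
    cursor <- last_hom + 1L
  }
  if (!length(segs)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_snps = integer(0), n_het_exceptions = integer(0)))
  }
  do.call(rbind, segs)
}

#' Call ROH for every individual in a genotype matrix
#'
#' @param genotypes Markers x individuals dosage matrix.
#' @param map Marker map (see [call_roh()]).
#' @param ... Passed to [call_roh()].
#' @return Data frame of segments with an `individual` column.
#' @export
call_roh_all <- function(genotypes, map, ...) {
  res <- lapply(colnames(genotypes), function(id) {
    segs <- call_roh(genotypes[, id], map, ...)
    if (nrow(segs)) cbind(individual = id, segs) else NULL
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    return(data.frame(individual = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_snps = integer(0), n_het_exceptions = integer(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

seg_granges <- function(segs) {
  GenomicRanges::reduce(GenomicRanges::GRanges(
    segs$chrom, IRanges::IRanges(segs$start, segs$end)))
}

#' Rank candidate regions from per-individual ROH segments
#'
#' Intersects ROH across all affected individuals; each resulting region is
#' `affected_only` when no carrier's ROH fully covers it and
#' `shared_with_carriers` when at least one does. Regions homozygous only in
#' carriers (carrier ROH overlapping no affected segment) are reported as
#' `excluded`. Output is sorted `affected_only` first, then
#' `shared_with_carriers`, then `excluded`.
#'
#' @param segments Segment table from [call_roh_all()] (must include at
#'   least one affected individual's segments).
#' @param statuses Data frame with `id` and `status`.
#' @return Data frame: `chrom`, `start`, `end`, `evidence_class`,
#'   `support` (comma-separated covering individuals).
#' @export
rank_regions <- function(segments, statuses) {
  affected <- statuses$id[statuses$status == "affected"]
  carriers <- statuses$id[statuses$status == "carrier"]
  assert_that(length(affected) > 0L, "no affected individuals in statuses")
  assert_that(any(segments$individual %in% affected),
              "no ROH segments from any affected individual")

  per_ind <- split(segments, segments$individual)
  gr_of <- function(id) {
    if (!is.null(per_ind[[id]])) seg_granges(per_ind[[id]])
    else GenomicRanges::GRanges()
  }
  aff_core <- Reduce(GenomicRanges::intersect, lapply(affected, gr_of))
  carrier_grs <- lapply(carriers, gr_of)
  names(carrier_grs) <- carriers

  rows <- list()
  if (length(aff_core)) {
    for (i in seq_along(aff_core)) {
      region <- aff_core[i]
      covering <- carriers[vapply(carrier_grs, function(g) {
        length(g) > 0L &&
          any(IRanges::overlapsAny(region, g, type = "within"))
      }, TRUE)]
      cls <- if (length(covering)) "shared_with_carriers" else "affected_only"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(region)),
        start = GenomicRanges::start(region),
        end = GenomicRanges::end(region),
        evidence_class = cls,
        support = paste(c(affected, covering), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  ## carrier-only regions: carrier runs touching no affected segment at all
  if (length(carriers)) {
    carrier_union <- Reduce(GenomicRanges::union, carrier_grs,
                            GenomicRanges::GRanges())
    aff_any <- if (any(segments$individual %in% affected)) {
      seg_granges(segments[segments$individual %in% affected, ])
    } else {
      GenomicRanges::GRanges()
    }
    only_car <- carrier_union[!IRanges::overlapsAny(carrier_union, aff_any)]
    for (i in seq_along(only_car)) {
      region <- only_car[i]
      covering <- carriers[vapply(carrier_grs, function(g) {
        length(g) > 0L && any(IRanges::overlapsAny(region, g))
      }, TRUE)]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(region)),
        start = GenomicRanges::start(region),
        end = GenomicRanges::end(region),
        evidence_class = "excluded",
        support = paste(covering, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), evidence_class = character(0),
                      support = character(0)))
  }
  out <- do.call(rbind, rows)
  cls_rank <- c(affected_only = 1L, shared_with_carriers = 2L, excluded = 3L)
  out <- out[order(cls_rank[out$evidence_class], out$chrom, out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export ROH segments to BED
#'
#' One BED file (0-based half-open, as the format requires) per individual
#' or a single file when `individual` is absent.
#'
#' @param segments Segment table ([call_roh_all()] output).
#' @param path Output BED path.
#' @return The path, invisibly.
#' @export
write_roh_bed <- function(segments, path) {
  gr <- GenomicRanges::GRanges(segments$chrom,
                               IRanges::IRanges(segments$start,
                                                segments$end))
  if ("individual" %in% names(segments)) {
    S4Vectors::mcols(gr)$name <- segments$individual
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
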