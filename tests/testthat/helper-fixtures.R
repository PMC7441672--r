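## Shared fixtures and independent brute-force oracles.

## The default forged gene is deterministic; build it once per test run.
default_gene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- forge_gene_model()
    cache
  }
})

## --- ROH oracle -----------------------------------------------------------
## Enumerates every hom-bounded substring with <= max_het embedded hets
## (O(n^2)), then reproduces the leftmost-maximal selection by direct search
## over the enumeration.
oracle_roh <- function(g, pos, min_snps, min_length_bp, max_het) {
  n <- length(g)
  het <- !is.na(g) & g == 1L
  hom <- !is.na(g) & g != 1L
  sat <- list()
  for (i in seq_len(n)) {
    if (!hom[i]) next
    for (j in i:n) {
      if (!hom[j]) next
      if (sum(het[i:j]) <= max_het) {
        sat[[length(sat) + 1L]] <- c(i, j)
      }
    }
  }
  segs <- list()
  cursor <- 1L
  repeat {
    cand <- Filter(function(s) s[1] >= cursor, sat)
    if (!length(cand)) break
    i0 <- min(vapply(cand, `[`, 1L, 1L))
    jmax <- max(vapply(Filter(function(s) s[1] == i0, cand), `[`, 1L, 2L))
    idx <- i0:jmax
    if (sum(!is.na(g[idx])) >= min_snps &&
        (pos[jmax] - pos[i0] + 1) >= min_length_bp) {
      segs[[length(segs) + 1L]] <- data.frame(
        start = pos[i0], end = pos[jmax],
        n_snps = sum(!is.na(g[idx])),
        n_het_exceptions = sum(het[idx]))
    }
    cursor <- jmax + 1L
  }
  if (!length(segs)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_snps = integer(0), n_het_exceptions = integer(0)))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

## --- cascade oracle -------------------------------------------------------
## Loop-based re-implementation of the filtering cascade.
oracle_cascade <- function(vcf_tabs, gene_start, gene_end, pileups,
                           controls, extra_affected,
                           qd_min = 20, dp_min = 10,
                           min_depth = 1, min_fraction = 0.75) {
  pass <- lapply(vcf_tabs, function(tab) {
    keep <- logical(nrow(tab))
    for (i in seq_len(nrow(tab))) {
      keep[i] <- tab$gt[i] == "1/1" &&
        !is.na(tab$qd[i]) && tab$qd[i] > qd_min &&
        !is.na(tab$dp[i]) && tab$dp[i] > dp_min
    }
    tab[keep, , drop = FALSE]
  })
  keys <- lapply(pass, function(t) paste(t$chrom, t$pos, t$ref, t$alt))
  shared_keys <- Reduce(intersect, keys)
  shared <- pass[[1]][keys[[1]] %in% shared_keys, , drop = FALSE]
  genic <- shared[shared$pos >= gene_start & shared$pos <= gene_end, ,
                  drop = FALSE]
  verdicts <- character(nrow(genic))
  for (i in seq_len(nrow(genic))) {
    at <- pileups[pileups$pos == genic$pos[i], , drop = FALSE]
    reads <- function(ids, col) {
      out <- numeric(length(ids))
      for (k in seq_along(ids)) {
        row <- at[at$sample == ids[k], , drop = FALSE]
        out[k] <- if (nrow(row)) row[[col]][1] else 0
      }
      out
    }
    c_alt <- reads(controls, "alt_reads")
    c_tot <- c_alt + reads(controls, "ref_reads")
    a_ref <- reads(extra_affected, "ref_reads")
    a_tot <- a_ref + reads(extra_affected, "alt_reads")
    verdicts[i] <- if (any(c_alt >= 1)) "refuted_control_alt"
      else if (any(a_ref >= 1)) "refuted_affected_ref"
      else if (sum(c_tot >= min_depth) <
                 ceiling(min_fraction * length(controls)) ||
               sum(a_tot >= min_depth) <
                 ceiling(min_fraction * length(extra_affected)))
        "insufficient_coverage"
      else "supported"
  }
  genic$verdict <- verdicts
  rownames(genic) <- NULL
  genic
}

## --- in-silico PCR oracle -------------------------------------------------
## Naive all-substring scan.
oracle_pcr <- function(template, fwd, rev) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  scan_for <- function(pat) {
    hits <- integer(0)
    np <- nchar(pat)
    for (i in seq_len(max(0L, nchar(template) - np + 1L))) {
      if (substr(template, i, i + np - 1L) == pat) hits <- c(hits, i)
    }
    hits
  }
  f_hits <- scan_for(fwd)
  r_hits <- scan_for(revcomp(rev))
  lens <- integer(0)
  for (f in f_hits) {
    for (r in r_hits) {
      if (r >= f + nchar(fwd)) {
        lens <- c(lens, r + nchar(rev) - f)
      }
    }
  }
  sort(lens)
}

## --- Hill grid-search oracle ----------------------------------------------
oracle_hill_grid <- function(curve, pca50_grid = seq(5.0, 6.8, by = 0.01),
                             nh_grid = seq(0.5, 4, by = 0.05)) {
  best <- c(NA, NA)
  best_rss <- Inf
  for (p in pca50_grid) {
    for (h in nh_grid) {
      rss <- sum((curve$force - hill_force(curve$pCa, p, h))^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- c(p, h)
      }
    }
  }
  c(pca50 = best[1], nh = best[2])
}
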