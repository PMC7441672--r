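mk_var <- function(pos, gt = "1/1", qd = 30, dp = 20, ref = "A", alt = "T",
                   chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt,
             qd = qd, dp = dp, stringsAsFactors = FALSE)
}

test_that("hard filtering applies strict thresholds and tallies drops", {
  expect_equal(nrow(hard_filter(mk_var(1, qd = 25, dp = 15))), 1L)
  ## boundary values are exclusive
  expect_equal(nrow(hard_filter(mk_var(1, qd = 20, dp = 15))), 0L)
  expect_equal(nrow(hard_filter(mk_var(1, qd = 25, dp = 10))), 0L)

  ## hand-assigned toy set: exactly the 4 records satisfying all three
  ## predicates survive
  toy <- rbind(
    mk_var(1, "1/1", 25, 15),  # pass
    mk_var(2, "0/1", 25, 15),  # het
    mk_var(3, "1/1", 20, 15),  # QD boundary
    mk_var(4, "1/1", 19, 15),  # low QD
    mk_var(5, "1/1", 25, 10),  # DP boundary
    mk_var(6, "1/1", 40, 50),  # pass
    mk_var(7, "1/1", NA, 50),  # missing QD
    mk_var(8, "1/1", 40, NA),  # missing DP
    mk_var(9, "1/1", 21, 11),  # pass
    mk_var(10, "1/1", 99, 99)  # pass
  )
  out <- hard_filter(toy)
  expect_equal(out$pos, c(1, 6, 9, 10))
  tally <- attr(out, "drop_tally")
  expect_equal(unname(tally["not_hom_alt"]), 1L)
  expect_equal(unname(tally["missing_annotation"]), 2L)
  expect_equal(unname(tally["low_qd"]), 2L)
  expect_equal(unname(tally["low_dp"]), 1L)

  ## monotonicity: raising thresholds never enlarges the output
  set.seed(20)
  rnd <- mk_var(1:60, gt = sample(c("1/1", "0/1"), 60, TRUE),
                qd = runif(60, 10, 40), dp = sample(5:30, 60, TRUE))
  n_prev <- nrow(hard_filter(rnd, qd_min = 15, dp_min = 5))
  for (q in c(20, 25, 30)) {
    n_now <- nrow(hard_filter(rnd, qd_min = q, dp_min = q / 2))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("homozygous intersection is exact set arithmetic", {
  v <- function(pos) mk_var(pos)
  a <- rbind(v(1), v(2), v(3))
  expect_equal(intersect_homozygous(a, a), a)           # idempotent
  b <- rbind(v(2), v(3), v(4))
  expect_equal(intersect_homozygous(a, b)$pos, c(2, 3))
  expect_equal(nrow(intersect_homozygous(a, rbind(v(7), v(8)))), 0L)
  ## same position but different allele is not shared
  expect_equal(nrow(intersect_homozygous(v(5), mk_var(5, alt = "G"))), 0L)
})

test_that("genic filtering is exact interval membership", {
  gene <- data.frame(chrom = "chr1", start = 1001L, end = 2000L)
  expect_equal(nrow(genic_filter(mk_var(1500), gene)), 1L)
  expect_equal(nrow(genic_filter(mk_var(1000), gene)), 0L)  # 1 bp upstream
  expect_equal(nrow(genic_filter(mk_var(1001), gene)), 1L)
  expect_equal(nrow(genic_filter(mk_var(2001), gene)), 0L)

  ## 100 random positions on a 10-kb contig with the gene covering 10%:
  ## package output equals direct interval checks
  set.seed(7)
  pos <- sample.int(10000L, 100L)
  vars <- mk_var(pos)
  got <- genic_filter(vars, gene)
  want <- vars[vars$pos >= 1001L & vars$pos <= 2000L, ]
  rownames(want) <- NULL
  expect_equal(got, want)
  expect_equal(nrow(got), sum(pos >= 1001 & pos <= 2000))
})

test_that("low-coverage adjudication follows the support/refute rules", {
  locus <- list(chrom = "chr1", pos = 100L)
  pl <- function(ctrl_tot, aff_tot, ctrl_alt = 0L * ctrl_tot,
                 aff_ref = 0L * aff_tot) {
    data.frame(
      sample = c(sprintf("C%d", seq_along(ctrl_tot)),
                 sprintf("A%d", seq_along(aff_tot))),
      chrom = "chr1", pos = 100L,
      ref_reads = c(ctrl_tot - ctrl_alt, aff_ref),
      alt_reads = c(ctrl_alt, aff_tot - aff_ref),
      stringsAsFactors = FALSE)
  }
  ctrls <- sprintf("C%d", 1:8)
  affs <- sprintf("A%d", 1:4)

  ## 6 of 8 controls and 3 of 4 extra-affected covered, no contradicting
  ## reads -> supported
  v <- lowcov_adjudicate(locus, pl(c(1, 1, 1, 1, 1, 1, 0, 0), c(2, 1, 1, 0)),
                         ctrls, affs)
  expect_identical(v$verdict, "supported")

  ## one control with alt reads refutes regardless of coverage
  v <- lowcov_adjudicate(locus,
                         pl(c(3, 1, 1, 1, 1, 1, 0, 0), c(2, 1, 1, 0),
                            ctrl_alt = c(3L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)),
                         ctrls, affs)
  expect_identical(v$verdict, "refuted_control_alt")

  ## a reference read in an extra-affected refutes homozygosity
  v <- lowcov_adjudicate(locus,
                         pl(c(1, 1, 1, 1, 1, 1, 0, 0), c(5, 1, 1, 0),
                            aff_ref = c(1L, 0L, 0L, 0L)),
                         ctrls, affs)
  expect_identical(v$verdict, "refuted_affected_ref")

  ## 5 of 8 controls covered (< ceiling(0.75 * 8) = 6) -> insufficient
  v <- lowcov_adjudicate(locus, pl(c(1, 1, 1, 1, 1, 0, 0, 0), c(2, 1, 1, 0)),
                         ctrls, affs)
  expect_identical(v$verdict, "insufficient_coverage")

  expect_error(lowcov_adjudicate(locus, pl(1, 1), character(0), affs),
               "control subset is empty")
})

test_that("ranking orders by severity class with positional tie-break", {
  vars <- mk_var(c(50, 10, 30))
  cons <- data.frame(chrom = "chr1", pos = c(50, 10, 30),
                     ref = "A", alt = "T",
                     term = c("splice_donor_variant", "intron_variant",
                              "splice_acceptor_variant"))
  verd <- data.frame(chrom = "chr1", pos = c(50, 10, 30),
                     verdict = "supported")
  ranked <- prioritize(vars, cons, verd)
  expect_equal(ranked$pos, c(30, 50, 10))   # class 1 by position, then rest
  expect_equal(ranked$rank, 1:3)

  ## unsupported candidates never appear
  verd$verdict <- c("supported", "refuted_control_alt", "supported")
  ranked <- prioritize(vars, cons, verd)
  expect_equal(ranked$pos, c(30, 50))
})

test_that("the cascade equals a brute-force re-implementation on a cohort", {
  g <- default_gene()
  for (seed in c(5L, 17L)) {
    sim <- simulate_cohort(g, cohort_config(seed = seed))
    controls <- sim$samples$id[sim$samples$status == "control"]
    extra <- sim$samples$id[sim$samples$status == "affected" &
                              sim$samples$platform == "low"]

    filtered <- lapply(sim$vcf, hard_filter)
    shared <- Reduce(intersect_homozygous, filtered)
    genic <- genic_filter(shared, g)
    verd <- adjudicate_variants(genic, sim$pileups, controls, extra)

    want <- oracle_cascade(sim$vcf, g$gene_start, g$gene_end, sim$pileups,
                           controls, extra)
    expect_equal(genic$pos, want$pos)
    expect_identical(genic$ref, want$ref)
    expect_identical(verd$verdict, want$verdict)

    ## counts are non-increasing through the cascade
    n <- c(sum(vapply(sim$vcf, nrow, 1L)),
           sum(vapply(filtered, nrow, 1L)),
           nrow(shared), nrow(genic), sum(verd$verdict == "supported"))
    expect_true(all(diff(n) <= 0))
  }
})
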