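test_that("the default forged gene satisfies all structural invariants", {
  g <- default_gene()
  cfg <- g$config

  expect_equal(nrow(g$exons), cfg$n_exons)
  expect_equal(nchar(g$cdna), cfg$cdna_length)
  expect_identical(spliced_transcript(g), g$cdna)

  ## CDS geometry: 3 * (protein + stop), inside the configured exon span
  cds_len <- g$cds_cdna_end - g$cds_cdna_start + 1L
  expect_equal(cds_len, 3L * (cfg$target_protein_length + 1L))
  cds_g_start <- cdna_to_genomic(g, g$cds_cdna_start)
  cds_g_end <- cdna_to_genomic(g, g$cds_cdna_end)
  ex <- g$exons
  expect_true(cds_g_start >= ex$start[cfg$cds_start_exon] &&
                cds_g_start <= ex$end[cfg$cds_start_exon])
  expect_true(cds_g_end >= ex$start[cfg$cds_end_exon] &&
                cds_g_end <= ex$end[cfg$cds_end_exon])

  ## every intron starts GT and ends AG, with the configured lengths
  intr <- gene_introns(g)
  for (i in seq_len(nrow(intr))) {
    s <- intron_sequence(g, i)
    expect_equal(nchar(s), cfg$intron_lengths[i])
    expect_identical(substr(s, 1, 2), "GT")
    expect_identical(substr(s, nchar(s) - 1, nchar(s)), "AG")
  }

  ## wild-type translation reaches exactly the target length
  wt <- translate_to_stop(cds_sequence(g))
  expect_false(wt$stop_absent)
  expect_equal(nchar(wt$protein), cfg$target_protein_length)
})

test_that("the retained-intron frame encodes the configured novel tail", {
  g <- default_gene()
  cfg <- g$config
  i13 <- intron_sequence(g, cfg$retained_intron_index)
  tr <- translate_to_stop(i13)
  expect_false(tr$stop_absent)
  expect_equal(nchar(tr$protein), cfg$novel_aa_before_stop)
})

test_that("a minimal two-exon gene forges and splices correctly", {
  cfg <- gene_forge_config(
    n_exons = 2L, cdna_length = 120L, cds_start_exon = 1L,
    cds_end_exon = 2L, target_protein_length = 10L,
    retained_intron_index = 1L, novel_aa_before_stop = 3L,
    replaced_tail_aa = 4L, intron_lengths = 60L, flank = 50L, seed = 42L)
  g <- forge_gene_model(cfg)
  expect_equal(nrow(g$exons), 2L)
  expect_equal(nchar(g$cdna), 120L)
  expect_identical(spliced_transcript(g), g$cdna)
  expect_equal(nchar(translate_to_stop(cds_sequence(g))$protein), 10L)
  ## single-intron gene: retention reproduces the unspliced pre-mRNA
  pre_mrna <- substr(g$genome, g$gene_start, g$gene_end)
  expect_identical(model_intron_retention(g, 1L), pre_mrna)
})

test_that("infeasible configurations raise errors naming the constraint", {
  expect_error(forge_gene_model(gene_forge_config(
    target_protein_length = 400L)), "CDS")
  expect_error(forge_gene_model(gene_forge_config(
    intron_lengths = c(rep(300L, 12L), 30L, 330L))),
    "too short")
  expect_error(forge_gene_model(gene_forge_config(
    retained_intron_index = 14L)), "retained intron")
  expect_error(forge_gene_model(gene_forge_config(
    intron_lengths = rep(300L, 5L))), "intron_lengths")
})

test_that("forging is deterministic and FASTA/GFF3 output is byte-identical", {
  g1 <- forge_gene_model(gene_forge_config(seed = 11L))
  g2 <- forge_gene_model(gene_forge_config(seed = 11L))
  expect_identical(g1, g2)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_gene_model(g1, d1)
  p2 <- write_gene_model(g2, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  g3 <- forge_gene_model(gene_forge_config(seed = 12L))
  expect_false(identical(g1$genome, g3$genome))
})

test_that("FASTA + GFF3 round-trip reproduces coordinates and sequences", {
  for (seed in c(1L, 5L)) {
    g <- forge_gene_model(gene_forge_config(seed = seed))
    d <- withr::local_tempdir()
    p <- write_gene_model(g, d)
    g2 <- read_gene_model(p[["genome"]], p[["gff3"]])
    expect_identical(g2$exons$start, g$exons$start)
    expect_identical(g2$exons$end, g$exons$end)
    expect_identical(g2$genome, g$genome)
    expect_identical(g2$cdna, g$cdna)
    expect_identical(g2$cds_cdna_start, g$cds_cdna_start)
    expect_identical(g2$cds_cdna_end, g$cds_cdna_end)
    expect_identical(g2$gene_start, g$gene_start)
    expect_identical(g2$gene_end, g$gene_end)
  }
})

test_that("the planted donor deletion is anchored and left-aligned", {
  for (seed in 1:5) {
    g <- forge_gene_model(gene_forge_config(seed = seed))
    cv <- causal_variant(g)
    ## anchor base is not G, deleted base is the donor +1 G
    expect_identical(substr(cv$ref, 2, 2), "G")
    expect_false(substr(cv$ref, 1, 1) == "G")
    norm <- normalize_variant(cv$pos, cv$ref, cv$alt, genome = g$genome)
    expect_identical(norm$pos, cv$pos)
    expect_identical(norm$ref, cv$ref)
    expect_identical(norm$alt, cv$alt)
  }
})
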