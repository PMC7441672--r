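test_that("the planted donor deletion classifies as a named splice_donor_variant", {
  g <- default_gene()
  cv <- causal_variant(g)
  rec <- classify_variant(cv, g)
  expect_identical(rec$term, "splice_donor_variant")
  expect_equal(rec$intron, 13L)
  ## donor at CDS position 3 * (263 - 14) = 747, deletion of its +1 G
  expect_identical(rec$name, "c.747+1delG")
})

test_that("splice-region, intergenic and coding positions classify correctly", {
  g <- default_gene()
  intr <- gene_introns(g)

  ## SNV at acceptor -2 of intron 5
  pos <- intr$end[5] - 1L
  ref <- substr(g$genome, pos, pos)
  rec <- classify_variant(list(chrom = g$contig, pos = pos, ref = ref,
                               alt = setdiff(c("A", "C", "G", "T"), ref)[1]),
                          g)
  expect_identical(rec$term, "splice_acceptor_variant")
  expect_equal(rec$intron, 5L)

  ## SNV 500 bp outside the gene
  pos <- g$gene_start - 500L
  ref <- substr(g$genome, pos, pos)
  rec <- classify_variant(list(chrom = g$contig, pos = pos, ref = ref,
                               alt = setdiff(c("A", "C", "G", "T"), ref)[1]),
                          g)
  expect_identical(rec$term, "intergenic_variant")

  ## deep intronic SNV
  pos <- intr$start[2] + 100L
  ref <- substr(g$genome, pos, pos)
  rec <- classify_variant(list(chrom = g$contig, pos = pos, ref = ref,
                               alt = setdiff(c("A", "C", "G", "T"), ref)[1]),
                          g)
  expect_identical(rec$term, "intron_variant")

  ## engineered stop-gain: mutate a CDS codon to TAA
  cds <- cds_sequence(g)
  codon_i <- 50L
  codon <- substr(cds, 148, 150)
  ## find a codon where changing base 1 to T yields TAA
  hit <- regexpr("[ACG]AA", cds)
  hit <- hit + (3L - (hit - 1L) %% 3L) %% 3L  # snap to codon boundary
  repeat {
    if (substr(cds, hit, hit + 2L) %in% c("AAA", "CAA", "GAA")) break
    hit <- hit + 3L
  }
  cds_pos <- hit
  gpos <- cdna_to_genomic(g, g$cds_cdna_start + cds_pos - 1L)
  rec <- classify_variant(list(chrom = g$contig, pos = gpos,
                               ref = substr(g$genome, gpos, gpos),
                               alt = "T"), g)
  expect_identical(rec$term, "stop_gained")
  expect_identical(rec$name, sprintf("c.%d%s>T", cds_pos,
                                     substr(cds, cds_pos, cds_pos)))

  expect_error(classify_variant(list(chrom = g$contig, pos = 10^7,
                                     ref = "A", alt = "T"), g),
               "outside the contig")
})

test_that("classification is exhaustive and single-valued across the gene", {
  g <- forge_gene_model(gene_forge_config(seed = 3L))
  positions <- seq(g$gene_start - 20L, g$gene_end + 20L, by = 7L)
  for (pos in positions) {
    ref <- substr(g$genome, pos, pos)
    rec <- classify_variant(list(chrom = g$contig, pos = pos, ref = ref,
                                 alt = setdiff(c("A", "C", "G", "T"),
                                               ref)[1]),
                            g)
    expect_equal(nrow(rec), 1L)
    expect_true(rec$term %in% c(
      "splice_donor_variant", "splice_acceptor_variant", "stop_gained",
      "frameshift_variant", "missense_variant", "synonymous_variant",
      "utr_variant", "intron_variant", "intergenic_variant"))
  }
})

test_that("intron retention adds exactly the intron to the transcript", {
  g <- default_gene()
  mut <- model_intron_retention(g, 13L)
  expect_equal(nchar(mut), 1001L + 810L)   # the ~1.8 kb product
  ## length arithmetic holds for every intron of random forged genes
  for (seed in c(2L, 9L)) {
    gg <- forge_gene_model(gene_forge_config(seed = seed))
    for (k in c(1L, 7L, 14L)) {
      expect_equal(nchar(model_intron_retention(gg, k)) - nchar(gg$cdna),
                   intron_length(gg, k))
    }
  }
})

test_that("translation stops at the first stop codon", {
  expect_equal(translate_to_stop("ATGTAA"),
               list(protein = "M", stop_absent = FALSE))
  expect_equal(translate_to_stop("AT"),
               list(protein = "", stop_absent = TRUE))
  expect_true(translate_to_stop("ATGGGG")$stop_absent)
  expect_error(translate_to_stop("ATGNNNTAA"), "codon")

  ## mutant CDS of the default forged gene: 261 residues, last 12 novel
  g <- default_gene()
  junction <- 3L * (263L - 14L)
  cds <- cds_sequence(g)
  mut_cds <- paste0(substr(cds, 1, junction), intron_sequence(g, 13L))
  mut <- translate_to_stop(mut_cds)
  expect_equal(nchar(mut$protein), 261L)
  novel <- substr(mut$protein, 250L, 261L)
  expect_identical(novel, translate_to_stop(intron_sequence(g, 13L))$protein)

  ## random sequences: agree with Biostrings translation truncated at "*"
  set.seed(55)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    full <- as.character(Biostrings::translate(
      Biostrings::DNAString(s), no.init.codon = TRUE))
    want <- strsplit(full, "*", fixed = TRUE)[[1]][1]
    if (is.na(want)) want <- ""   # leading stop
    got <- translate_to_stop(s)
    expect_identical(got$protein, want)
    expect_identical(got$stop_absent, !grepl("*", full, fixed = TRUE))
  }
})

test_that("terminus comparison counts residue classes in the swapped tails", {
  rep <- compare_termini("MKKR", "MKDE")
  expect_equal(rep$shared_prefix_length, 2L)
  expect_identical(rep$wt_tail, "KR")
  expect_identical(rep$mut_tail, "DE")
  expect_equal(rep$basic_count_wt, 2L)
  expect_equal(rep$basic_count_mut, 0L)
  expect_equal(rep$acidic_count_wt, 0L)
  expect_equal(rep$acidic_count_mut, 2L)

  same <- compare_termini("MARKS", "MARKS")
  expect_equal(same$replaced_tail_length, 0L)
  expect_equal(same$novel_tail_length, 0L)

  ## report invariant: mut = wt - replaced + novel, on forged genes
  for (seed in c(1L, 4L, 8L)) {
    g <- forge_gene_model(gene_forge_config(seed = seed))
    pr <- splice_report(g)
    expect_equal(pr$mut_length,
                 pr$wt_length - pr$replaced_tail_length +
                   pr$novel_tail_length)
    expect_equal(pr$wt_length, 263L)
    expect_equal(pr$mut_length, 261L)
    expect_equal(pr$novel_tail_length, 12L)
    expect_equal(pr$replaced_tail_length, 14L)
    expect_lte(pr$basic_count_wt, pr$replaced_tail_length)
  }
})

test_that("protein masses are sums of average residue masses plus water", {
  expect_equal(protein_mass("G"), (57.0519 + 18.0153) / 1000)
  expect_equal(protein_mass("GG"), (2 * 57.0519 + 18.0153) / 1000)
  expect_error(protein_mass("GXG"), "X")
})

test_that("in-silico PCR matches the naive substring-scan oracle", {
  set.seed(77)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  fwd <- substr(tmpl, 1, 20)
  rev_rc <- substr(tmpl, 481, 500)
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rev <- revcomp(rev_rc)

  ## primers at the template ends amplify the full template
  expect_equal(as.integer(insilico_pcr(tmpl, fwd, rev)), 500L)
  ## absent primer: no product
  expect_length(insilico_pcr(tmpl, paste(rep("A", 15), collapse = ""), rev),
                0L)
  expect_error(insilico_pcr(tmpl, "ACGTACGT", rev), "at least 10 nt")

  ## same primers on wild-type vs retained transcript: size difference is
  ## exactly the intron length
  g <- default_gene()
  wt_t <- g$cdna
  mut_t <- model_intron_retention(g, 13L)
  f2 <- substr(wt_t, 30, 49)
  r2 <- revcomp(substr(wt_t, 950, 969))
  p_wt <- insilico_pcr(wt_t, f2, r2)
  p_mut <- insilico_pcr(mut_t, f2, r2)
  expect_length(p_wt, 1L)
  expect_length(p_mut, 1L)
  expect_equal(as.integer(p_mut) - as.integer(p_wt), intron_length(g, 13L))

  ## random 1-kb templates with implanted primer sites: oracle equality
  for (i in 1:10) {
    t1 <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
    f <- substr(t1, 11, 25)
    r <- revcomp(substr(t1, 900, 914))
    expect_equal(sort(as.integer(insilico_pcr(t1, f, r))),
                 oracle_pcr(t1, f, r))
  }
})

test_that("the retention report works on supplied (accession-style) sequences", {
  ## hand-built miniature: 6-codon CDS, intron encoding 2 novel aa + stop
  cds <- paste0("ATG", "AAA", "CGT", "GAT", "GAA", "TAA")  # MKRDE*
  intron <- paste0("GTT", "CAT", "TGA", "CCGCAG")          # V H *
  rep <- intron_retention_report(cds, intron, junction_cds_pos = 9L)
  expect_identical(rep$wt_protein, "MKRDE")
  expect_identical(rep$mut_protein, "MKRVH")
  expect_equal(rep$replaced_tail_length, 2L)
  expect_equal(rep$novel_tail_length, 2L)
  expect_identical(rep$wt_tail, "DE")
  expect_identical(rep$mut_tail, "VH")
  expect_equal(rep$basic_count_mut, 1L)
})
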