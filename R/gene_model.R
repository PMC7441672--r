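## Synthetic gene models.
##
## The forge builds a TNNT1-like multi-exon gene: a contig carrying one
## protein-coding gene with canonical GT..AG introns, a CDS that starts and
## ends in configurable exons, and one designated intron whose retention
## appends a fixed number of novel sense codons followed by a premature stop
## when read in the coding frame from the donor. All coordinates are 1-based
## and closed (the GRanges convention).

## The study gene's intron-13 length is reported both as the RT-PCR size
## shift (810 bp) and as a stated total (809 bp); both constants are exposed,
## neither is asserted as the true value.

#' Reported lengths of the retained TNNT1 intron
#'
#' Two published values for the length of the retained intron of ovine
#' *TNNT1*: the RT-PCR product size shift (810 nt) and the stated total
#' intron size (809 nt). Both are exposed; the forge default uses the
#' 810-nt value.
#' @format Named integer vector with elements `pcr_shift` and `stated_total`.
#' @export
TNNT1_INTRON13_LENGTHS <- c(pcr_shift = 810L, stated_total = 809L)

MIN_EXON_NT <- 8L
MIN_INTRON_NT <- 12L

#' Configuration for forging a synthetic gene model
#'
#' Defaults emulate the ovine *TNNT1* architecture: a 1001-nt cDNA over 15
#' exons, translation starting in exon 2 and terminating in exon 14, a
#' 263-residue protein, and an 810-nt intron 13 whose retention reads 12
#' novel sense codons and then a stop in the coding frame, replacing the
#' terminal 14 wild-type residues.
#'
#' @param n_exons Number of exons.
#' @param cdna_length Total spliced transcript length (nt).
#' @param cds_start_exon,cds_end_exon Exons containing the start and stop
#'   codons.
#' @param target_protein_length Wild-type protein length in residues
#'   (excluding the stop).
#' @param retained_intron_index Index of the intron whose retention is
#'   modelled (intron *k* separates exons *k* and *k + 1*).
#' @param novel_aa_before_stop Number of sense codons read from the retained
#'   intron before the in-frame stop.
#' @param replaced_tail_aa Number of wild-type C-terminal residues encoded
#'   downstream of the retained intron's donor; fixes the donor at CDS
#'   position `3 * (target_protein_length - replaced_tail_aa)`, a codon
#'   boundary.
#' @param intron_lengths Integer vector of intron lengths (nt), length
#'   `n_exons - 1`.
#' @param contig Contig name used for all emitted coordinates.
#' @param flank Flanking intergenic sequence (nt) on each side of the gene.
#' @param gene_id,transcript_id Feature identifiers used in GFF3 output.
#' @param seed Integer seed; forging is bit-reproducible given the seed.
#' @return A list of class `gene_forge_config`.
#' @export
gene_forge_config <- function(n_exons = 15L,
                              cdna_length = 1001L,
                              cds_start_exon = 2L,
                              cds_end_exon = 14L,
                              target_protein_length = 263L,
                              retained_intron_index = 13L,
                              novel_aa_before_stop = 12L,
                              replaced_tail_aa = 14L,
                              intron_lengths = c(350L, 420L, 280L, 510L, 300L,
                                                 450L, 380L, 290L, 520L, 310L,
                                                 400L, 360L, 810L, 330L),
                              contig = "chr1",
                              flank = 1000L,
                              gene_id = "TNNT1syn",
                              transcript_id = "TNNT1syn.t1",
                              seed = 1L) {
  cfg <- list(
    n_exons = as.integer(n_exons),
    cdna_length = as.integer(cdna_length),
    cds_start_exon = as.integer(cds_start_exon),
    cds_end_exon = as.integer(cds_end_exon),
    target_protein_length = as.integer(target_protein_length),
    retained_intron_index = as.integer(retained_intron_index),
    novel_aa_before_stop = as.integer(novel_aa_before_stop),
    replaced_tail_aa = as.integer(replaced_tail_aa),
    intron_lengths = as.integer(intron_lengths),
    contig = contig,
    flank = as.integer(flank),
    gene_id = gene_id,
    transcript_id = transcript_id,
    seed = as.integer(seed)
  )
  class(cfg) <- "gene_forge_config"
  cfg
}

validate_gene_forge_config <- function(cfg) {
  n <- cfg$n_exons
  s <- cfg$cds_start_exon
  e <- cfg$cds_end_exon
  k <- cfg$retained_intron_index
  p <- cfg$target_protein_length
  cds_len <- 3L * (p + 1L)
  junction <- 3L * (p - cfg$replaced_tail_aa)

  fail <- function(...) {
    stop("infeasible gene configuration: ", ..., call. = FALSE)
  }
  if (n < 2L) fail("n_exons must be at least 2 (got ", n, ")")
  if (length(cfg$intron_lengths) != n - 1L) {
    fail("intron_lengths must have n_exons - 1 = ", n - 1L, " entries (got ",
         length(cfg$intron_lengths), ")")
  }
  if (any(cfg$intron_lengths < MIN_INTRON_NT)) {
    fail("every intron must be at least ", MIN_INTRON_NT, " nt")
  }
  if (s < 1L || e > n || s >= e) {
    fail("CDS exon span [", s, ", ", e, "] must satisfy 1 <= start < end <= ",
         n)
  }
  if (k < s || k >= e) {
    fail("retained intron ", k, " must lie within the CDS exon span [",
         s, ", ", e - 1L, "]")
  }
  if (cfg$replaced_tail_aa < 1L || p - cfg$replaced_tail_aa < 2L) {
    fail("replaced_tail_aa (", cfg$replaced_tail_aa,
         ") must leave at least 2 codons upstream of the retained donor")
  }
  if (cfg$novel_aa_before_stop < 1L) {
    fail("novel_aa_before_stop must be positive")
  }
  retained_len <- cfg$intron_lengths[k]
  if (3L * (cfg$novel_aa_before_stop + 1L) > retained_len - 2L) {
    fail("retained intron (", retained_len, " nt) is too short for ",
         cfg$novel_aa_before_stop, " novel codons plus a stop (needs ",
         3L * (cfg$novel_aa_before_stop + 1L) + 2L, " nt)")
  }
  utr5_min <- (s - 1L) * MIN_EXON_NT
  utr3_min <- (n - e) * MIN_EXON_NT
  if (cds_len + utr5_min + utr3_min > cfg$cdna_length) {
    fail("CDS (", cds_len, " nt) plus minimal UTR exons exceeds the cDNA ",
         "length (", cfg$cdna_length, " nt)")
  }
  ## Coding exons sandwiched inside the CDS must each reach the minimum size.
  up_min <- 1L + max(0L, k - s) * MIN_EXON_NT
  if (junction < up_min) {
    fail("CDS upstream of the retained donor (", junction,
         " nt) cannot cover exons ", s, "..", k)
  }
  down_min <- max(0L, e - k - 1L) * MIN_EXON_NT + 1L
  if (cds_len - junction < down_min) {
    fail("CDS downstream of the retained donor (", cds_len - junction,
         " nt) cannot cover exons ", k + 1L, "..", e)
  }
  invisible(cfg)
}

## Integer composition with per-part minima.
partition_with_min <- function(total, mins) {
  total <- as.integer(total)
  mins <- as.integer(mins)
  n <- length(mins)
  if (n == 0L) {
    if (total != 0L) stop("cannot split ", total, " nt into 0 parts")
    return(integer(0))
  }
  extra <- total - sum(mins)
  if (extra < 0L) {
    stop("infeasible partition: ", total, " nt over minima ",
         paste(mins, collapse = "+"))
  }
  as.integer(rmultinom(1L, extra, rep(1 / n, n))[, 1L]) + mins
}

#' Forge a synthetic multi-exon gene model with sequences
#'
#' Builds a gene model, its genomic contig and its cDNA under the constraints
#' in [gene_forge_config()]: the spliced exons reproduce the cDNA exactly,
#' every intron starts `GT` and ends `AG`, and reading the retained intron in
#' the coding frame from its donor yields exactly `novel_aa_before_stop`
#' sense codons followed by a stop. The last exonic base before the retained
#' donor is guaranteed not to be `G`, so the single-base donor `+1 G`
#' deletion has a unique left-aligned VCF representation.
#'
#' @param config A [gene_forge_config()].
#' @return An object of class `gene_model`: contig name, strand, genomic exon
#'   table, CDS coordinates on the cDNA, the cDNA and contig sequences, and
#'   the retained-intron index.
#' @export
forge_gene_model <- function(config = gene_forge_config()) {
  validate_gene_forge_config(config)
  with_seed(config$seed, forge_gene_model_impl(config))
}

forge_gene_model_impl <- function(cfg) {
  n <- cfg$n_exons
  s <- cfg$cds_start_exon
  e <- cfg$cds_end_exon
  k <- cfg$retained_intron_index
  p <- cfg$target_protein_length
  cds_len <- 3L * (p + 1L)
  junction <- 3L * (p - cfg$replaced_tail_aa)

  ## --- exon length allocation -------------------------------------------
  rem <- cfg$cdna_length - cds_len
  utr5_min <- (s - 1L) * MIN_EXON_NT
  utr3_min <- (n - e) * MIN_EXON_NT
  utr5 <- utr5_min + sample.int(rem - utr3_min - utr5_min + 1L, 1L) - 1L
  utr3 <- rem - utr5

  ## 5' UTR across pure-UTR exons plus a prefix of the CDS-start exon.
  utr5_parts <- partition_with_min(utr5, c(rep(MIN_EXON_NT, s - 1L), 0L))
  ## CDS upstream of the retained donor across exons s..k; the donor falls
  ## exactly at the end of exon k.
  cds_up <- partition_with_min(junction, c(1L, rep(MIN_EXON_NT, k - s)))
  ## CDS downstream across exons k+1..e.
  cds_down <- partition_with_min(cds_len - junction,
                                 c(rep(MIN_EXON_NT, e - k - 1L), 1L))
  ## 3' UTR: suffix of the CDS-end exon plus pure-UTR exons.
  utr3_parts <- partition_with_min(utr3, c(0L, rep(MIN_EXON_NT, n - e)))

  exon_len <- integer(n)
  if (s > 1L) exon_len[seq_len(s - 1L)] <- utr5_parts[seq_len(s - 1L)]
  exon_len[s:k] <- cds_up
  exon_len[s] <- exon_len[s] + utr5_parts[s]
  exon_len[(k + 1L):e] <- cds_down
  exon_len[e] <- exon_len[e] + utr3_parts[1L]
  if (e < n) exon_len[(e + 1L):n] <- utr3_parts[-1L]
  stopifnot(sum(exon_len) == cfg$cdna_length)

  ## --- sequences ---------------------------------------------------------
  sense <- sense_codons()
  stops <- stop_codons()
  codons <- c("ATG", sample(sense, p - 1L, replace = TRUE),
              sample(stops, 1L))
  ## The junction codon (last codon before the retained donor) must not end
  ## in G, so the donor G deletion is left-aligned as emitted.
  jc <- p - cfg$replaced_tail_aa
  no_g <- sense[substr(sense, 3L, 3L) != "G" & sense != "ATG"]
  codons[jc] <- sample(no_g, 1L)
  cds_seq <- paste(codons, collapse = "")

  cdna <- paste0(random_dna(utr5), cds_seq, random_dna(utr3))
  stopifnot(nchar(cdna) == cfg$cdna_length)

  introns <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    len <- cfg$intron_lengths[i]
    if (i == k) {
      head_codons <- c(paste0("GT", sample(DNA_BASES, 1L)),
                       if (cfg$novel_aa_before_stop > 1L)
                         sample(sense, cfg$novel_aa_before_stop - 1L,
                                replace = TRUE),
                       sample(stops, 1L))
      head_seq <- paste(head_codons, collapse = "")
      tail_len <- len - nchar(head_seq) - 2L
      introns[i] <- paste0(head_seq, random_dna(tail_len), "AG")
    } else {
      introns[i] <- paste0("GT", random_dna(len - 4L), "AG")
    }
  }

  ## --- genomic assembly --------------------------------------------------
  pieces <- character(2L * n - 1L)
  exon_cdna_end <- cumsum(exon_len)
  exon_cdna_start <- exon_cdna_end - exon_len + 1L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- substr(cdna, exon_cdna_start[i], exon_cdna_end[i])
    if (i < n) pieces[2L * i] <- introns[i]
  }
  gene_seq <- paste(pieces, collapse = "")
  genome <- paste0(random_dna(cfg$flank), gene_seq, random_dna(cfg$flank))

  gene_start <- cfg$flank + 1L
  piece_len <- nchar(pieces)
  piece_end <- gene_start - 1L + cumsum(piece_len)
  piece_start <- piece_end - piece_len + 1L
  exon_idx <- seq(1L, 2L * n - 1L, by = 2L)
  exons <- data.frame(
    exon = seq_len(n),
    start = piece_start[exon_idx],
    end = piece_end[exon_idx]
  )

  gm <- structure(list(
    gene_id = cfg$gene_id,
    transcript_id = cfg$transcript_id,
    contig = cfg$contig,
    strand = "+",
    gene_start = gene_start,
    gene_end = gene_start + nchar(gene_seq) - 1L,
    exons = exons,
    cds_cdna_start = utr5 + 1L,
    cds_cdna_end = utr5 + cds_len,
    cdna = cdna,
    genome = genome,
    retained_intron = k,
    config = cfg
  ), class = "gene_model")
  stopifnot(identical(spliced_transcript(gm), cdna))
  gm
}

#' @export
print.gene_model <- function(x, ...) {
  n <- nrow(x$exons)
  cat("Synthetic gene model '", x$gene_id, "' on ", x$contig, ":",
      x$gene_start, "-", x$gene_end, " (", x$strand, ")\n", sep = "")
  cat("  ", n, " exons, cDNA ", nchar(x$cdna), " nt, CDS ",
      x$cds_cdna_start, "-", x$cds_cdna_end, " (",
      (x$cds_cdna_end - x$cds_cdna_start + 1L) / 3L - 1L, " aa)\n", sep = "")
  if (!is.na(x$retained_intron)) {
    cat("  retention-modelled intron: ", x$retained_intron, " (",
        intron_length(x, x$retained_intron), " nt)\n", sep = "")
  }
  invisible(x)
}

## --- accessors ------------------------------------------------------------

#' Intron coordinate table of a gene model
#'
#' @param gene A `gene_model`.
#' @return Data frame with columns `intron`, `start`, `end` (genomic, 1-based
#'   closed). Intron *k* separates exons *k* and *k + 1*.
#' @export
gene_introns <- function(gene) {
  ex <- gene$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(data.frame(intron = integer(0), start = integer(0),
                      end = integer(0)))
  }
  data.frame(
    intron = seq_len(n - 1L),
    start = ex$end[-n] + 1L,
    end = ex$start[-1L] - 1L
  )
}

#' @rdname gene_introns
#' @param k Intron index.
#' @export
intron_length <- function(gene, k) {
  intr <- gene_introns(gene)
  intr$end[k] - intr$start[k] + 1L
}

#' Sequence of one intron
#' @inheritParams intron_length
#' @return Character scalar.
#' @export
intron_sequence <- function(gene, k) {
  intr <- gene_introns(gene)
  substr(gene$genome, intr$start[k], intr$end[k])
}

#' Spliced transcript obtained from the genomic sequence
#'
#' Extracts and concatenates the exons from the contig; for a valid model
#' this equals the stored cDNA.
#' @param gene A `gene_model`.
#' @return Character scalar.
#' @export
spliced_transcript <- function(gene) {
  paste(substring(gene$genome, gene$exons$start, gene$exons$end),
        collapse = "")
}

#' Coding sequence (CDS) of the wild-type transcript
#' @param gene A `gene_model`.
#' @return Character scalar, `ATG`..stop inclusive.
#' @export
cds_sequence <- function(gene) {
  substr(gene$cdna, gene$cds_cdna_start, gene$cds_cdna_end)
}

#' Map a genomic position to transcript (cDNA) coordinates
#'
#' @param gene A `gene_model`.
#' @param pos Genomic position (1-based).
#' @return cDNA position, or `NA` for intronic/intergenic positions.
#' @export
genomic_to_cdna <- function(gene, pos) {
  ex <- gene$exons
  cum <- cumsum(ex$end - ex$start + 1L)
  vapply(pos, function(p) {
    i <- which(p >= ex$start & p <= ex$end)
    if (length(i) == 0L) return(NA_integer_)
    (if (i > 1L) cum[i - 1L] else 0L) + (p - ex$start[i] + 1L)
  }, integer(1))
}

#' @rdname genomic_to_cdna
#' @param cdna_pos cDNA position (1-based).
#' @export
cdna_to_genomic <- function(gene, cdna_pos) {
  ex <- gene$exons
  len <- ex$end - ex$start + 1L
  cum <- cumsum(len)
  vapply(cdna_pos, function(p) {
    if (is.na(p) || p < 1L || p > cum[length(cum)]) return(NA_integer_)
    i <- which(p <= cum)[1L]
    ex$start[i] + (p - (if (i > 1L) cum[i - 1L] else 0L)) - 1L
  }, integer(1))
}

#' The planted causal variant of a forged gene
#'
#' Returns the single-base deletion of the `+1 G` of the retention-modelled
#' intron's splice donor, in left-aligned, anchored VCF representation (the
#' anchor base is the last exonic base before the donor, which the forge
#' guarantees is not `G`).
#'
#' @param gene A `gene_model` produced by [forge_gene_model()].
#' @return One-row data frame: `chrom`, `pos`, `ref`, `alt`, `intron`.
#' @export
causal_variant <- function(gene) {
  k <- gene$retained_intron
  assert_that(!is.na(k), "gene model has no retention-modelled intron")
  anchor_pos <- gene$exons$end[k]
  anchor <- substr(gene$genome, anchor_pos, anchor_pos)
  donor <- substr(gene$genome, anchor_pos + 1L, anchor_pos + 1L)
  assert_that(donor == "G", "donor +1 base is not G")
  data.frame(
    chrom = gene$contig,
    pos = anchor_pos,
    ref = paste0(anchor, "G"),
    alt = anchor,
    intron = k,
    stringsAsFactors = FALSE
  )
}

## --- serialization --------------------------------------------------------

#' Write a gene model to FASTA and GFF3
#'
#' Emits the contig FASTA, the cDNA FASTA and a GFF3 with gene, mRNA, exon
#' and CDS features. Output is byte-deterministic for a given model.
#'
#' @param gene A `gene_model`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of paths (`genome`, `cdna`, `gff3`).
#' @export
write_gene_model <- function(gene, dir, prefix = "gene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_fa <- file.path(dir, paste0(prefix, "_genome.fa"))
  cdna_fa <- file.path(dir, paste0(prefix, "_cdna.fa"))
  gff3 <- file.path(dir, paste0(prefix, ".gff3"))

  gset <- Biostrings::DNAStringSet(setNames(gene$genome, gene$contig))
  Biostrings::writeXStringSet(gset, genome_fa)
  cset <- Biostrings::DNAStringSet(setNames(gene$cdna, gene$transcript_id))
  Biostrings::writeXStringSet(cset, cdna_fa)

  ex <- gene$exons
  cds_gstart <- cdna_to_genomic(gene, gene$cds_cdna_start)
  cds_gend <- cdna_to_genomic(gene, gene$cds_cdna_end)
  cds_pieces <- ex[ex$end >= cds_gstart & ex$start <= cds_gend, , drop = FALSE]
  cds_pieces$start <- pmax(cds_pieces$start, cds_gstart)
  cds_pieces$end <- pmin(cds_pieces$end, cds_gend)

  gr <- GenomicRanges::GRanges(
    seqnames = gene$contig,
    ranges = IRanges::IRanges(
      start = c(gene$gene_start, gene$gene_start, ex$start, cds_pieces$start),
      end = c(gene$gene_end, gene$gene_end, ex$end, cds_pieces$end)
    ),
    strand = gene$strand
  )
  n_ex <- nrow(ex)
  n_cds <- nrow(cds_pieces)
  gr$type <- c("gene", "mRNA", rep("exon", n_ex), rep("CDS", n_cds))
  gr$ID <- c(gene$gene_id, gene$transcript_id,
             paste0(gene$transcript_id, ":exon", ex$exon),
             paste0(gene$transcript_id, ":cds", seq_len(n_cds)))
  gr$Parent <- c(NA_character_, gene$gene_id,
                 rep(gene$transcript_id, n_ex + n_cds))
  gr$gene_biotype <- c("protein_coding", rep(NA_character_, 1L + n_ex + n_cds))
  piece_len <- cds_pieces$end - cds_pieces$start + 1L
  cds_phase <- (3L - c(0L, cumsum(piece_len)[-n_cds]) %% 3L) %% 3L
  gr$phase <- c(rep(NA_integer_, 2L + n_ex), cds_phase)
  rtracklayer::export(gr, gff3, format = "gff3")

  c(genome = genome_fa, cdna = cdna_fa, gff3 = gff3)
}

#' Read a gene model back from FASTA and GFF3
#'
#' Inverse of [write_gene_model()] up to the forge-only metadata (the
#' retained-intron index and the forge configuration are not representable in
#' GFF3 and come back as `NA`/`NULL`).
#'
#' @param genome_fa Contig FASTA path.
#' @param gff3 GFF3 path.
#' @return A `gene_model`.
#' @export
read_gene_model <- function(genome_fa, gff3) {
  gset <- Biostrings::readDNAStringSet(genome_fa)
  gr <- rtracklayer::import(gff3, format = "gff3")
  gene <- gr[gr$type == "gene"]
  mrna <- gr[gr$type == "mRNA"]
  exons <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  assert_that(length(gene) == 1L && length(mrna) == 1L,
              "expected exactly one gene and one mRNA feature")
  exons <- exons[order(GenomicRanges::start(exons))]
  cds <- cds[order(GenomicRanges::start(cds))]

  contig <- as.character(GenomeInfoDb::seqnames(gene)[1L])
  genome <- as.character(gset[[match(contig, names(gset))]])
  ex <- data.frame(
    exon = seq_along(exons),
    start = GenomicRanges::start(exons),
    end = GenomicRanges::end(exons)
  )
  gm <- structure(list(
    gene_id = gene$ID[1L],
    transcript_id = mrna$ID[1L],
    contig = contig,
    strand = as.character(GenomicRanges::strand(gene)[1L]),
    gene_start = GenomicRanges::start(gene)[1L],
    gene_end = GenomicRanges::end(gene)[1L],
    exons = ex,
    cds_cdna_start = NA_integer_,
    cds_cdna_end = NA_integer_,
    cdna = NA_character_,
    genome = genome,
    retained_intron = NA_integer_,
    config = NULL
  ), class = "gene_model")
  gm$cdna <- spliced_transcript(gm)
  gm$cds_cdna_start <- genomic_to_cdna(gm, GenomicRanges::start(cds)[1L])
  gm$cds_cdna_end <- genomic_to_cdna(gm, GenomicRanges::end(cds)[length(cds)])
  gm
}
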