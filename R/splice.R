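## Splice-consequence modelling.
##
## Classifies variants against a gene model, constructs the intron-retention
## transcript, translates to the first stop, compares wild-type and mutant
## C-termini with residue-class accounting and average molecular weights,
## and predicts RT-PCR amplicon sizes by exact primer matching.

CONSEQUENCE_TERMS <- c("splice_donor_variant", "splice_acceptor_variant",
                       "stop_gained", "frameshift_variant",
                       "missense_variant", "synonymous_variant",
                       "utr_variant", "intron_variant", "intergenic_variant")

## Bases actually changed by a normalized variant: the anchor base of an
## anchored indel is untouched.
affected_span <- function(pos, ref, alt) {
  nr <- nchar(ref)
  na <- nchar(alt)
  if (nr > na && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    c(pos + na, pos + nr - 1L)            # deletion: bases removed
  } else if (na > nr && substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    c(pos, pos + 1L)                       # insertion: flanking junction
  } else {
    c(pos, pos + nr - 1L)                  # substitution
  }
}

#' Classify a variant against a gene model
#'
#' Assigns exactly one consequence term. Variants whose changed bases touch
#' the first two (`+1`/`+2`, donor) or last two (`-2`/`-1`, acceptor)
#' intronic positions are splice-site variants - in particular a deletion
#' spanning the donor `+1` base of intron *k* is a `splice_donor_variant`
#' with intron index *k*. Coding substitutions are classified by their codon
#' effect; coding indels by frame disruption (length changes divisible by
#' three are reported with the nearest available term,
#' `missense_variant`). Exonic positions outside the CDS are `utr_variant`,
#' other intronic positions `intron_variant`, everything off the gene body
#' `intergenic_variant`. A cDNA-style name (`c.N+MdelX` for donor-region
#' deletions, `c.NX>Y` for coding substitutions) is emitted where the
#' supported subset applies.
#'
#' @param variant List or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt` (normalized; see [normalize_variant()]).
#' @param gene A `gene_model`.
#' @return One-row data frame: `chrom`, `pos`, `ref`, `alt`, `term`,
#'   `intron`, `exon`, `name`.
#' @export
classify_variant <- function(variant, gene) {
  pos <- as.integer(variant$pos)
  ref <- as.character(variant$ref)
  alt <- as.character(variant$alt)
  assert_that(identical(as.character(variant$chrom), gene$contig),
              paste0("variant contig '", variant$chrom,
                     "' does not match the gene model contig '",
                     gene$contig, "'"))
  assert_that(pos >= 1L && pos + nchar(ref) - 1L <= nchar(gene$genome),
              "variant lies outside the contig")

  span <- affected_span(pos, ref, alt)
  ex <- gene$exons
  intr <- gene_introns(gene)
  is_del <- nchar(ref) > nchar(alt)
  term <- NULL
  intron_idx <- NA_integer_
  exon_idx <- NA_integer_
  name <- NA_character_

  ## splice sites first: donor +1/+2, acceptor -2/-1
  if (nrow(intr)) {
    donor_hit <- which(span[2L] >= intr$start & span[1L] <= intr$start + 1L)
    accept_hit <- which(span[2L] >= intr$end - 1L & span[1L] <= intr$end)
    if (length(donor_hit)) {
      term <- "splice_donor_variant"
      intron_idx <- donor_hit[1L]
    } else if (length(accept_hit)) {
      term <- "splice_acceptor_variant"
      intron_idx <- accept_hit[1L]
    }
  }

  if (is.null(term)) {
    in_exon <- which(span[1L] <= ex$end & span[2L] >= ex$start)
    if (length(in_exon)) {
      exon_idx <- in_exon[1L]
      cds_g <- c(cdna_to_genomic(gene, gene$cds_cdna_start),
                 cdna_to_genomic(gene, gene$cds_cdna_end))
      cdna_pos <- genomic_to_cdna(gene, span[1L])
      in_cds <- !is.na(gene$cds_cdna_start) &&
        span[2L] >= cds_g[1L] && span[1L] <= cds_g[2L]
      if (!in_cds) {
        term <- "utr_variant"
      } else if (nchar(ref) != nchar(alt)) {
        term <- if ((abs(nchar(ref) - nchar(alt)) %% 3L) != 0L) {
          "frameshift_variant"
        } else {
          "missense_variant"
        }
      } else if (nchar(ref) == 1L) {
        cds_pos <- cdna_pos - gene$cds_cdna_start + 1L
        codon_i <- (cds_pos - 1L) %/% 3L + 1L
        offset <- (cds_pos - 1L) %% 3L + 1L
        cds <- cds_sequence(gene)
        codon <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
        mut_codon <- codon
        substr(mut_codon, offset, offset) <- alt
        aa_ref <- unname(Biostrings::GENETIC_CODE[codon])
        aa_alt <- unname(Biostrings::GENETIC_CODE[mut_codon])
        term <- if (identical(aa_ref, aa_alt)) {
          "synonymous_variant"
        } else if (identical(aa_alt, "*")) {
          "stop_gained"
        } else {
          "missense_variant"
        }
        name <- sprintf("c.%d%s>%s", cds_pos, ref, alt)
      } else {
        term <- "missense_variant"   # multi-nucleotide substitution
      }
    } else {
      inside_gene <- span[2L] >= gene$gene_start && span[1L] <= gene$gene_end
      term <- if (inside_gene) "intron_variant" else "intergenic_variant"
      if (term == "intron_variant") {
        hit <- which(span[1L] <= intr$end & span[2L] >= intr$start)
        if (length(hit)) intron_idx <- hit[1L]
      }
    }
  }

  ## c.-style name for donor-region deletions (the supported HGVS subset)
  if (term == "splice_donor_variant" && is_del && !is.na(intron_idx)) {
    k <- intron_idx
    last_exonic <- ex$end[k]
    cds_last <- genomic_to_cdna(gene, last_exonic) - gene$cds_cdna_start + 1L
    if (!is.na(cds_last) && cds_last >= 1L) {
      del_start <- span[1L]
      offset <- del_start - intr$start[k] + 1L
      deleted <- substr(ref, nchar(alt) + 1L, nchar(ref))
      name <- sprintf("c.%d+%ddel%s", cds_last, offset, deleted)
    }
  }

  data.frame(chrom = variant$chrom, pos = pos, ref = ref, alt = alt,
             term = term, intron = intron_idx, exon = exon_idx, name = name,
             stringsAsFactors = FALSE)
}

#' @rdname classify_variant
#' @param variants Variant table; one record per row.
#' @export
classify_variants <- function(variants, gene) {
  do.call(rbind, lapply(seq_len(nrow(variants)), function(i) {
    classify_variant(variants[i, ], gene)
  }))
}

#' Construct the intron-retention transcript
#'
#' Inserts the full intron sequence at the exon *k* / *k + 1* junction of
#' the spliced transcript; the result is `cdna length + intron length` nt.
#'
#' @param gene A `gene_model`.
#' @param intron_index Intron to retain; defaults to the forge's
#'   retention-modelled intron.
#' @return Character scalar, the mutant transcript.
#' @export
model_intron_retention <- function(gene,
                                   intron_index = gene$retained_intron) {
  k <- as.integer(intron_index)
  n_intr <- nrow(gene$exons) - 1L
  assert_that(!is.na(k) && k >= 1L && k <= n_intr,
              paste0("intron_index must be in 1..", n_intr))
  ex_len <- gene$exons$end - gene$exons$start + 1L
  cut <- sum(ex_len[seq_len(k)])
  paste0(substr(gene$cdna, 1L, cut),
         intron_sequence(gene, k),
         substr(gene$cdna, cut + 1L, nchar(gene$cdna)))
}

#' Translate a coding sequence up to the first stop codon
#'
#' Translates complete codons with the standard genetic code until the first
#' stop; returns the residues before the stop. When no stop is reached the
#' full translation is returned with `stop_absent = TRUE`. Sequences shorter
#' than one codon yield an empty protein with the flag set.
#'
#' @param cds Character scalar, starting at a codon boundary.
#' @return List with `protein` (character) and `stop_absent` (logical).
#' @export
translate_to_stop <- function(cds) {
  cds <- toupper(as.character(cds))
  n_codon <- nchar(cds) %/% 3L
  if (n_codon == 0L) {
    return(list(protein = "", stop_absent = TRUE))
  }
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (anyNA(aa)) {
    bad <- codons[which(is.na(aa))[1L]]
    stop("cannot translate codon '", bad, "'", call. = FALSE)
  }
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    list(protein = paste(aa[seq_len(stop_at[1L] - 1L)], collapse = ""),
         stop_absent = FALSE)
  } else {
    list(protein = paste(aa, collapse = ""), stop_absent = TRUE)
  }
}

BASIC_RESIDUES <- c("K", "R", "H")
ACIDIC_RESIDUES <- c("D", "E")

count_residues <- function(seq, residues) {
  if (nchar(seq) == 0L) return(0L)
  sum(strsplit(seq, "")[[1]] %in% residues)
}

#' Compare wild-type and mutant protein termini
#'
#' Finds the longest common prefix of the two proteins and treats the
#' remainders as the replaced (wild-type) and novel (mutant) tails; counts
#' basic (K, R, H) and acidic (D, E) residues in each tail and computes
#' average molecular masses of both full-length proteins.
#'
#' @param wt_protein,mut_protein Amino-acid sequences (single-letter code).
#' @return A list of class `protein_report`.
#' @export
compare_termini <- function(wt_protein, mut_protein) {
  assert_that(nchar(wt_protein) > 0L && nchar(mut_protein) > 0L,
              "both protein sequences must be non-empty")
  w <- strsplit(wt_protein, "")[[1]]
  m <- strsplit(mut_protein, "")[[1]]
  nmin <- min(length(w), length(m))
  eq <- w[seq_len(nmin)] == m[seq_len(nmin)]
  prefix <- if (all(eq)) nmin else which(!eq)[1L] - 1L
  wt_tail <- substr(wt_protein, prefix + 1L, nchar(wt_protein))
  mut_tail <- substr(mut_protein, prefix + 1L, nchar(mut_protein))
  structure(list(
    wt_protein = wt_protein,
    mut_protein = mut_protein,
    wt_length = nchar(wt_protein),
    mut_length = nchar(mut_protein),
    shared_prefix_length = prefix,
    replaced_tail_length = nchar(wt_protein) - prefix,
    novel_tail_length = nchar(mut_protein) - prefix,
    wt_tail = wt_tail,
    mut_tail = mut_tail,
    basic_count_wt = count_residues(wt_tail, BASIC_RESIDUES),
    basic_count_mut = count_residues(mut_tail, BASIC_RESIDUES),
    acidic_count_wt = count_residues(wt_tail, ACIDIC_RESIDUES),
    acidic_count_mut = count_residues(mut_tail, ACIDIC_RESIDUES),
    wt_mass_kda = protein_mass(wt_protein),
    mut_mass_kda = protein_mass(mut_protein)
  ), class = "protein_report")
}

#' @export
print.protein_report <- function(x, ...) {
  cat("Protein comparison: wild-type ", x$wt_length, " aa (",
      round(x$wt_mass_kda, 1), " kDa) vs mutant ", x$mut_length, " aa (",
      round(x$mut_mass_kda, 1), " kDa)\n", sep = "")
  cat("  shared prefix ", x$shared_prefix_length, " aa; replaced tail ",
      x$replaced_tail_length, " aa ('", x$wt_tail, "'), novel tail ",
      x$novel_tail_length, " aa ('", x$mut_tail, "')\n", sep = "")
  cat("  basic residues in tails (K/R/H): ", x$basic_count_wt, " vs ",
      x$basic_count_mut, "; acidic (D/E): ", x$acidic_count_wt, " vs ",
      x$acidic_count_mut, "\n", sep = "")
  invisible(x)
}

## Average (not monoisotopic) residue masses in Da, matching gel-estimated
## molecular weights.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

#' Average molecular mass of a protein in kDa
#'
#' Sum of average residue masses plus one water.
#'
#' @param sequence Amino-acid sequence (single-letter code, standard
#'   residues).
#' @return Mass in kDa.
#' @export
protein_mass <- function(sequence) {
  res <- strsplit(toupper(as.character(sequence)), "")[[1]]
  unknown <- setdiff(res, names(AA_RESIDUE_MASS))
  if (length(unknown)) {
    stop("unknown residue symbol: ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  }
  (sum(AA_RESIDUE_MASS[res]) + WATER_MASS) / 1000
}

#' In-silico PCR by exact primer matching
#'
#' Finds exact matches of the forward primer on the sense strand and of the
#' reverse complement of the reverse primer downstream of it; each
#' (forward, reverse) site pair yields a product spanning both primers
#' inclusively. All products are reported, so ambiguous (multi-site) primer
#' pairs list every product.
#'
#' @param template Template sequence (character scalar).
#' @param fwd_primer,rev_primer Primer sequences, at least 10 nt; the
#'   reverse primer is given 5'->3' on the antisense strand, as ordered.
#' @return Integer vector of product lengths (empty when there is no
#'   product); attribute `sites` holds a data frame of the product
#'   coordinates.
#' @export
insilico_pcr <- function(template, fwd_primer, rev_primer) {
  assert_that(nchar(fwd_primer) >= 10L && nchar(rev_primer) >= 10L,
              "primers must be at least 10 nt")
  tmpl <- Biostrings::DNAString(template)
  f_hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(fwd_primer), tmpl))
  rc <- Biostrings::reverseComplement(Biostrings::DNAString(rev_primer))
  r_m <- Biostrings::matchPattern(rc, tmpl)
  r_start <- Biostrings::start(r_m)
  r_end <- Biostrings::end(r_m)

  sites <- expand.grid(f = f_hits, r = seq_along(r_start),
                       KEEP.OUT.ATTRS = FALSE)
  if (nrow(sites)) {
    sites$r_start <- r_start[sites$r]
    sites$r_end <- r_end[sites$r]
    sites <- sites[sites$r_start >= sites$f + nchar(fwd_primer), ,
                   drop = FALSE]
  }
  if (!nrow(sites)) {
    out <- integer(0)
    attr(out, "sites") <- data.frame(fwd_start = integer(0),
                                     rev_end = integer(0),
                                     length = integer(0))
    return(out)
  }
  lens <- sites$r_end - sites$f + 1L
  ord <- order(lens)
  out <- as.integer(lens[ord])
  attr(out, "sites") <- data.frame(fwd_start = sites$f[ord],
                                   rev_end = sites$r_end[ord],
                                   length = out)
  out
}

#' Intron-retention consequence report from raw sequences
#'
#' The sequence-level core of the retention analysis, usable with any
#' supplied coding sequence and intron (for example a published cDNA's CDS
#' and the matching reference intron): builds the retained-intron CDS,
#' translates wild-type and mutant to their stops, and compares termini.
#'
#' @param cds Wild-type CDS (`ATG`..stop inclusive).
#' @param intron Intron sequence to retain.
#' @param junction_cds_pos CDS position of the last base before the donor
#'   (the intron is inserted after this base).
#' @return A `protein_report` with extra fields `wt_cds_length`,
#'   `mut_transcript_extra` (= intron length) and `stop_absent` flags.
#' @export
intron_retention_report <- function(cds, intron, junction_cds_pos) {
  j <- as.integer(junction_cds_pos)
  assert_that(j >= 1L && j < nchar(cds),
              "junction_cds_pos must lie strictly inside the CDS")
  wt <- translate_to_stop(cds)
  mut_cds <- paste0(substr(cds, 1L, j), intron,
                    substr(cds, j + 1L, nchar(cds)))
  mut <- translate_to_stop(mut_cds)
  rep <- compare_termini(wt$protein, mut$protein)
  rep$wt_cds_length <- nchar(cds)
  rep$mut_transcript_extra <- nchar(intron)
  rep$wt_stop_absent <- wt$stop_absent
  rep$mut_stop_absent <- mut$stop_absent
  rep
}

#' @rdname intron_retention_report
#' @param gene A forged `gene_model`; convenience wrapper using its CDS,
#'   retained intron and donor junction.
#' @param intron_index Intron to retain.
#' @export
splice_report <- function(gene, intron_index = gene$retained_intron) {
  k <- as.integer(intron_index)
  junction_g <- gene$exons$end[k]
  junction_cds <- genomic_to_cdna(gene, junction_g) - gene$cds_cdna_start + 1L
  assert_that(!is.na(junction_cds) && junction_cds >= 1L,
              "the retained intron's donor does not lie within the CDS")
  intron_retention_report(cds_sequence(gene), intron_sequence(gene, k),
                          junction_cds)
}
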