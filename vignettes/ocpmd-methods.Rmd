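---
title: "Methods: recessive variant discovery and contractility analysis for ovine TNNT1 myopathy"
author: "ocpmd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recessive variant discovery and contractility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocpmd)
```

## Scope and overall design

`ocpmd` re-implements, as tested and reusable code, the computational
analyses used to identify and validate a recessive splice-donor deletion in
ovine *TNNT1* (slow skeletal troponin T) as the cause of ovine congenital
progressive muscular dystrophy (OCPMD), a congenital myopathy of type I
(slow) myofibres. The package has five analysis layers:

1. **Synthetic data** (`forge_gene_model()`, `simulate_cohort()`,
   `simulate_snp_array()`, `simulate_force_pca()`) — generates every input
   the downstream stages consume, so the whole pipeline runs and is testable
   without any external download.
2. **ROH mapping** (`call_roh()`, `rank_regions()`) — runs of homozygosity
   from SNP-array genotypes, ranked with carrier-aware weighting.
3. **Variant prioritization** (`hard_filter()`, `intersect_homozygous()`,
   `genic_filter()`, `lowcov_adjudicate()`, `prioritize()`) — the filtering
   cascade from per-sample VCFs and low-coverage pileup summaries to a
   ranked candidate list.
4. **Splice consequence** (`classify_variant()`,
   `model_intron_retention()`, `translate_to_stop()`, `compare_termini()`,
   `protein_mass()`, `insilico_pcr()`) — consequence classification and the
   intron-retention protein model.
5. **Contractility** (`elliptical_csa()`, `normalize_curve()`,
   `fit_hill()`, `pca_at_fraction()`, `compare_groups()`) — Hill-equation
   force–pCa analysis of permeabilized single myofibres.

`run_discovery()` and `run_contractility()` orchestrate the chains; a thin
command-line wrapper (`inst/scripts/ocpmd`) exposes the same verbs to the
shell. Read alignment, variant calling, genome-wide association and
pedigree linkage are deliberately out of scope: the pipeline starts from
VCFs, pileup summaries and PED/MAP genotypes.

## Coordinate and format conventions

All internal coordinates are **1-based and closed**, the convention of the
Bioconductor interval stack (`GenomicRanges`/`IRanges`) that does the
interval arithmetic here, and the native convention of VCF and GFF3. BED
output is converted to its 0-based half-open form by `rtracklayer` at write
time. Variant records are held in minimal, left-aligned representation:
`normalize_variant()` trims shared suffix/prefix bases and, when the contig
sequence is supplied, left-shifts indels through repeat context before
records are matched across samples. Multi-allelic records are split into
biallelic rows on input.

## The forged gene

`gene_forge_config()` defaults encode a *TNNT1*-like architecture: 15
exons, a 1001-nt spliced transcript, translation starting in exon 2 and
terminating in exon 14, a 263-residue protein, and an 810-nt intron 13
designated for retention modelling. All introns are canonical (`GT`…`AG`).
Two published values exist for the retained intron's length (the 810-nt
RT-PCR size shift and an 809-nt stated total); both are exposed as
`TNNT1_INTRON13_LENGTHS` and neither is asserted as true — the forge
default uses 810 nt.

One design decision deserves emphasis. The C-terminal accounting of the
retention mechanism — a 263-residue wild-type protein whose terminal 14
residues are replaced by 12 intron-encoded residues, giving a 261-residue
mutant — fixes the donor of the retained intron at coding position
$3 \times (263 - 14) = 747$, a codon boundary. The forge therefore places
the exon 13/intron 13 junction at CDS position 747 (configurable through
`replaced_tail_aa`), and the derived cDNA-style name of the planted
deletion is `c.747+1delG`. Published variant nomenclature for the real gene
uses a different coordinate (`c.614+1`), which is mutually inconsistent
with the residue accounting above; the package follows the residue
accounting, because four independent quantities (wild-type length, mutant
length, replaced-tail length, novel-tail length) corroborate it and the
name is derived output, not an input.

Reading the retained intron in the coding frame from its donor yields
exactly `novel_aa_before_stop` (default 12) sense codons followed by a
stop; the intron's first codon is `GTx` (valine) because the donor
dinucleotide is fixed. The last exonic base before the donor is constrained
not to be `G`, so the single-base donor deletion has a unique left-aligned
anchored VCF representation — without this constraint the record's position
would shift under normalization and the planted-truth bookkeeping would
need repeat-aware matching.

Exon-length allocation is a seeded random integer composition under the
structural constraints (minimum exon size 8 nt, UTR exons on both ends,
the junction constraint above). Infeasible configurations fail with an
error naming the violated constraint. Forging is bit-reproducible given
the seed, and FASTA + GFF3 round-trips reproduce coordinates and sequences
exactly (tested).

## The simulated cohort

`cohort_config()` defaults mirror the sequencing design of the study: two
deep-coverage (~50×) affected animals with per-sample VCFs, four additional
low-coverage (~5×) affected animals, eight low-coverage unrelated controls,
and six carriers. The planted causal variant is homozygous-alt in every
affected animal, heterozygous in carriers, absent in controls, and its VCF
record is simulated at full quality (depth and QD truncated above the
hard-filter thresholds) — the causal call surviving the hard filter is a
study premise, not something the simulator should occasionally destroy.

Background variants emulate breed-versus-reference differences: biallelic
SNVs at `background_variant_rate` per kb (default 24/kb, chosen so the
default ~8.5-kb contig carries roughly 200 background variants — a
desk-scale stand-in for the millions of real breed-difference variants,
dense enough that every cascade stage does real work). Each background
variant gets an allele frequency uniform on [0.1, 0.9] and per-sample
Hardy–Weinberg genotypes independent of disease status.

Low-coverage samples are represented as per-locus read counts only. Depth
is Poisson with mean `mean_depth_lo` (default 5), the simplest law
consistent with a stated mean coverage; alternate-read counts are binomial
in the genotype dose. No sequencing error is modelled, so a single
alternate read in a control is always genuine — real data would require an
error-tolerant threshold in `lowcov_adjudicate()`, which is why its
`min_depth` rule is configurable.

## SNP array and ROH mapping

The array simulator places ~1000 markers uniformly on a 50-Mb synthetic
chromosome (the ~50-kb spacing of a 50k ovine chip) with the forged contig
embedded at its centre, so one marker can sit exactly at the causal
position and inherit each status group's zygosity. Affected individuals
share one identical homozygous haplotype across a 10-Mb autozygous window
centred on the causal locus; carriers carry a single copy of that
haplotype; all other genotypes are Hardy–Weinberg draws at per-marker
frequencies uniform on [0.05, 0.5]. Recombination and meiosis are not
modelled — the planted block *is* the identity-by-descent signal, which is
all the ROH stage consumes.

The ROH caller's run definition is a design decision (the original
analysis used an unpublished script, so no claim of matching its exact
boundaries is made): a run starts and ends on a homozygous call, tolerates
at most `max_het` embedded heterozygous calls (default 1), and missing
calls bridge runs without counting toward the `min_snps` threshold
(default 20; array no-calls are noise, not heterozygosity). Because
overlapping maximal windows exist whenever `max_het` ≥ 1, segments are
selected greedily left to right (leftmost start, maximal extension, resume
after the segment), which is deterministic and non-overlapping; the test
suite checks this against an exhaustive $O(n^2)$ enumeration oracle.
Region ranking intersects ROH across all affected individuals; a region
fully covered by a carrier's ROH is kept but down-weighted
(`shared_with_carriers`), and carrier runs overlapping no affected segment
are `excluded`.

## The prioritization cascade

Hard filtering keeps homozygous-alt records with `QD > 20` and `DP > 10` —
strict inequalities, read literally from the published thresholds; records
missing either annotation are dropped and tallied rather than raising an
error. Intersection matches normalized `(chrom, pos, ref, alt)` keys.
The genic filter keeps variants anywhere within `[gene start, gene end]`
of a protein-coding gene (exons and introns alike, UTR exons included).

Low-coverage adjudication applies the support/refute logic at the variant
position itself (not a surrounding window — the narrower reading of the
coverage rule, and the conservative one): any alternate read in a control
refutes the candidate, any reference read in an additional affected animal
refutes it, refutation is evaluated before coverage, and a candidate is
`supported` only when at least `ceiling(0.75 × subset)` samples of each
subset have ≥ 1 read at the locus. Carriers are never part of the control
subset — a carrier's alternate reads would veto the true recessive variant.

Ranking uses a fixed four-class severity table (splice donor/acceptor ±1–2
&gt; stop-gain/frameshift &gt; other coding &gt; other non-coding) with
positional tie-breaks; no external annotation service is consulted. The
classifier's term set is closed and exhaustive over gene positions: exonic
non-CDS positions get `utr_variant`, and in-frame coding indels are
reported with the nearest available term (`missense_variant`).

## Splice consequence modelling

Intron retention is modelled by inserting the full reference intron at the
exon junction, so mutant transcript length is cDNA + intron length
(1001 + 810 = 1811 nt for the default gene, the "~1.8 kb" RT-PCR product).
Translation proceeds codon-by-codon with the standard genetic code to the
first stop. Terminus comparison takes the longest common prefix of
wild-type and mutant proteins and counts basic (K, R, H) and acidic (D, E)
residues in the swapped tails; the residue-class sets are the conventional
ones, chosen here as a design decision. Protein masses use average (not
monoisotopic) residue masses plus one water, matching gel-estimated kDa
values. `intron_retention_report()` accepts raw sequences, so the same
analysis applies to a published cDNA's CDS plus its reference intron when
the user supplies them; the packaged tests exercise it on forged
sequences, whose tails are random — tail-composition values from the real
gene are not asserted against forged fixtures.

In-silico PCR is exact-match only (no melting-temperature or mismatch
model): all (forward, reverse-complement) site pairs with the reverse site
downstream yield products, and multi-site primers list every product.

## Contractility analysis

Forces are normalized to the measurement at pCa 4.5 (saturating calcium);
the relaxing point (pCa 9.0) is retained as data, not subtracted. The Hill
model is fitted in pCa space with a unit plateau and no offset,

$$F(\mathrm{pCa}) = \frac{1}{1 + 10^{\,n_H(\mathrm{pCa} - \mathrm{pCa}_{50})}},$$

by bounded Levenberg–Marquardt least squares (`minpack.lm::nlsLM`);
initialization takes pCa50 from the measured point nearest half-maximal
force and $n_H = 2$, with bounds pCa50 ∈ [4.5, 7.5], $n_H$ ∈ [0.1, 10].
Derived quantities are closed-form:
$\mathrm{pCa}_x = \mathrm{pCa}_{50} + \log_{10}((1-x)/x)/n_H$ and
$[\mathrm{Ca}^{2+}]$ in mM is $10^{-\mathrm{pCa}_x} \times 1000$, so
pCa10 ≥ pCa20 ≥ pCa50 whenever $n_H > 0$.

Fitting is per fibre by default, with group statistics over per-fibre
estimates (pooled-per-group fitting is available via `pooled = TRUE`;
which of the two the original analysis used is not stated, and per-fibre
is the mode that matches plotting individual fibre points). Group
comparison is a two-tailed unpaired t-test, equal-variance by default with
Welch available — "unpaired two-tailed" alone does not determine the
variance assumption, and the equal-variance form is the conventional
reading.

The fibre simulator draws each force as the Hill value at the group's
generative parameters (wild-type pCa50 5.804, affected 6.056, $n_H$ 2.0 —
back-transformed from the reported group calcium concentrations at
half-maximal force, 0.00157 and 0.00088 mM) plus Gaussian noise
(SD 0.02 of maximal force), truncated at zero, then re-normalizes the
curve at pCa 4.5. Because the Hill force at pCa 4.5 is slightly below 1,
this re-normalization shifts a noiseless curve by at most ~0.1% — the
price of honouring the experimental normalization exactly.

## Problem sizes and reproducibility

Every simulator takes an explicit integer seed and is bit-reproducible
given it; written outputs (FASTA, GFF3, VCF, TSV, JSON, PED/MAP, BED) are
byte-deterministic. The test suite runs the discovery chain across 20
seeded cohorts (~200 background variants each), the ROH recovery
experiment across 100 seeded arrays (~1000 markers, 20 individuals), the
Hill parameter-recovery study across 25 seeds, and brute-force oracle
comparisons at small n (≤ 50 markers for ROH, ≤ 200 records for the
cascade, 1-kb templates for PCR) — sizes at which the exhaustive oracles
are exact and the full suite stays fast.

## Known limitations

* Forged genes live on the plus strand; minus-strand gene models are not
  generated and the classifier assumes coding-strand orientation.
* No read-level simulation (FASTQ/BAM), no sequencing error in pileups,
  no recombination or pedigree meiosis beyond the planted block.
* The severity table is a four-class approximation, not a full
  consequence ontology; HGVS naming covers only donor-region deletions
  and coding SNVs.
* In-silico PCR ignores primer thermodynamics and mismatches.
* The contractility module takes pCa values as given; solution chemistry
  (EGTA/Ca-EGTA equilibria) is not computed.
* Synthetic cohorts state nothing about real-data performance beyond the
  logic they exercise: passing tests demonstrate that the cascade's rules
  are implemented exactly and recover a planted signal under the stated
  noise model, not that the thresholds are optimal for any particular
  sequencing platform.
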