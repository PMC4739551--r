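---
title: "Post-alignment mutation screening: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-alignment mutation screening: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mutscreen` implements the post-alignment core of a clinical mutation-screening
workflow for targeted, exome, or genome sequencing of patient panels. It takes
what external tools produce — aligned reads (SAM text) and per-caller VCFs
from several read mappers (BWA, Bowtie, Bowtie2, GSNAP, TMAP) and variant
callers (GATK, SAMTOOLS, Freebayes, VarScan2) — and turns them into a single
annotated variant summary table, one line per variant per patient. Read
mapping and variant calling themselves are out of scope: the package
consumes their outputs.

All internal coordinates are 0-based half-open. VCF (1-based) and
refFlat/BED (0-based) conventions are converted once, at the I/O boundary,
so no module ever reasons about mixed conventions.

# The processing model

## Read filters and pileups

Reads are filtered by minimum mapping quality, by the proper-pair flag
(applied only to reads that carry the paired flag, so single-end data is
unaffected), and by PCR-duplicate removal. Duplicates are grouped by
(contig, unclipped 5' start, strand, and mate 5' start when paired); the
group member with the highest base-quality sum survives, with lexicographic
read-name tie-breaks. This is the standard coordinate-and-strand criterion;
it is deterministic, so repeated marking is idempotent.

The pileup is a per-position tally built by a CIGAR walk: M/=/X deposit a
base and its quality, I consumes query only, D/N consume reference only,
clips deposit nothing. Deletions therefore contribute no allele to the
columns they span — the coverage decomposition is A/C/G/T only, reported
both raw (all policy-passing reads) and quality-filtered (base quality at or
above `min_base_qual`).

## Variant normalization and consensus

Callers spell the same indel differently (right-shifted positions, padded
alleles, merged multiallelic records). Calls are made comparable by reducing
each (position, ref, alt) to its left-aligned, parsimonious representation:
shared suffix bases are trimmed, extending leftward with the preceding
reference base whenever an allele would empty (which walks an indel through
a repeat tract to its smallest reachable start), then shared prefix bases
are trimmed. Multiallelic records are split into one call per alt allele
before normalization. The canonical key

```
{contig}.{assembly}:g.{pos}{ref}>{alt}     # SNV
{contig}.{assembly}:g.{start}_{end}del     # deletion
{contig}.{assembly}:g.{pos}_{pos+1}ins{seq}  # insertion
```

groups calls across mappers and callers into consensus records carrying the
set of supporting (mapper, caller) pairs. Venn-cell counts over those
support sets, computed separately for SNVs and indels, quantify
between-tool agreement; variants confirmed by at least two tools are the
high-confidence set.

Equal-length multi-base substitutions (MNVs) that survive trimming are
rejected with an explicit error rather than given a bogus type; the four
supported callers emit them rarely and the package's own outputs never do.

## Effect prediction

Variants are assigned to transcript features (exon/CDS/UTR/intron ordinals
counted from the transcript 5' end, so minus-strand genes are numbered in
transcription order). For coding SNVs the CDS offset is computed in coding
orientation against the spliced CDS — codons spanning splice junctions are
assembled from the spliced sequence, never from genomic adjacency — the
reference base is replaced by the (strand-complemented) variant base, and
both codons are translated with the standard nuclear code, reported as
3-letter names with `Ter` for stops and `Xaa` for ambiguous codons. For
indels, the number of inserted or deleted bases falling inside the exonic
CDS determines the frameshift flag (`length mod 3 != 0`) and the new reading
frame is reported alongside the original one.

## Per-variant statistics

Three summary statistics support interpretation:

* **Flanking base quality** — mean and median of all policy-passing base
  qualities within ±10 bases of the variant, excluding the variant base
  itself. "10 bp flanking region" is ambiguous between ±10 and 10 bases
  total; ±10 was chosen and is configurable (`flank_window`). The median is
  the lower middle value for even counts, so reported medians are always
  observed PHRED integers.
* **Coverage decomposition** — A/C/G/T counts, their total, and the
  variant-allele coverage: the filtered count of the alt base for SNVs; for
  indels the caller-reported alt depth (the pileup counts substitutions
  only).
* **Fisher's exact test** — for each variant, a 2×2 table of its (ref, alt)
  read counts against the component-wise *mean* (ref, alt) counts of all
  remaining variants of the same patient. An exact test needs integer
  cells, and no convention is established for fractional means; they are
  rounded half-up, which is deterministic and unbiased for .5 ties. The
  two-sided p-value uses the point-probability rule — the sum of
  hypergeometric probabilities of all tables with the observed margins whose
  point probability is at most that of the observed table, with a 1e-7
  relative tolerance for floating-point ties — the convention of mainstream
  statistics libraries, so results are directly cross-checkable.
  Benjamini–Hochberg correction is applied per patient, matching the
  per-sample cohort definition; a patient with a single variant has no
  cohort and reports no p-value.

## Filters

Variants pass when total coverage ≥ `min_total_cov`, variant-allele
coverage ≥ `min_alt_cov`, and allele frequency ≥ `min_af`. The defaults
(20, 4, 0.10) are the validation thresholds of the screening workflow.
Failures carry machine-readable reasons (`low_total_cov`, `low_alt_cov`,
`low_af`, `no_coverage`). When the variant-allele depth is unknown (an
indel whose caller reported no depths), the total-coverage check still
applies; the alt-coverage and frequency checks are recorded as
`alt_depth_unknown` without failing the variant — discarding a variant for
missing metadata would silently bias against indels from terse callers.

## Annotation and cross-referencing

A variant is **known** when a dbSNP record overlaps it (and agrees on
alleles when the track carries them), **novel** when genic without an rsID,
and **intergenic** otherwise. Membership flags are emitted for the
dbSnp_Common/Coding/Flagged/Mult/HapMap/Cpg_Island and GWAS-catalogue
subtracks, and hotspot BED intervals append `hotspot` to the caller
provenance of overlapping variants (lexicographic tie-break when several
hotspots overlap).

The 32 database links are configuration data — one URL template per output
column, each keyed by coordinates, rsID, Entrez ID, gene symbol, transcript,
protein, UniProt, KEGG, OMIM, or HGNC identifiers — because hosted URL
schemes drift while the applicability matrix does not. Coordinate links
apply to all classes; rsID links to known variants and to intergenic
variants with an rsID (PolyPhen-2 to known only); Entrez gene links to known
and novel; all remaining identifier classes to known variants only. A
variant lying outside genes uses the intergenic column of the matrix even
when an rsID classifies it as known. A builder whose identifier is missing
is skipped.

# Tunable parameters

| option | meaning | unit | default |
|---|---|---|---|
| `min_mapq` | post-mapping minimum mapping quality | PHRED | 20 |
| `require_proper_pair` | drop improper pairs (paired reads only) | flag | TRUE |
| `drop_duplicates` | drop PCR-duplicate reads | flag | TRUE |
| `min_base_qual` | base quality for filtered counts | PHRED | 20 |
| `min_total_cov` | variant filter: total coverage | reads | 20 |
| `min_alt_cov` | variant filter: alt-allele coverage | reads | 4 |
| `min_af` | variant filter: allele frequency | fraction | 0.10 |
| `flank_window` | flanking-quality half-width | bases | 10 |
| `assembly` | label minted into variant keys | text | GRCh37 |

The source workflow states a mapping-quality filter without a value;
20 is the conventional cutoff in this field (BWA-style mapping qualities)
and is exposed as a first-class option rather than hard-coded.

# The synthetic-data generator

`make_fixture_run()` emits a complete run directory (genome, refFlat gene
models, identifier side-table, membership tracks, hotspot BED, per-patient
SAM reads, per-mapper/per-caller VCFs, manifest, options) from a single
seed; identical seeds give byte-identical files. It emulates:

* a two-patient panel sequenced to ~60× with 80 bp single-end reads, base
  error rate 0.1%, 10% exact PCR duplicates — heterozygous variants at
  allele fraction 0.5 (0.3 at one deliberately multiallelic site);
* two-exon genes (CDS split 40/50 across an intron) on both strands, with
  fixed codons planted so synonymous, missense, frameshift and in-frame
  consequences all occur;
* homopolymer tracts (8–10 bp, boundaries forced to differ) holding indels
  whose caller spellings are jittered: suffix padding (freebayes-style),
  left padding (varscan-style), right-shifted anchors (samtools-style), and
  multiallelic merging (gatk-style) — all equivalent representations of the
  planted variants;
* a known Venn structure over four callers: a block called by all four,
  one-caller private variants, and a two-caller indel, so overlap fractions
  are recoverable exactly.

What it does **not** emulate: realistic quality ramps or context-dependent
errors, indel-containing read alignments (indel allele evidence arrives via
the caller VCFs, as the coverage decomposition is substitution-only),
strand bias, mate pairs, or Sanger chromatograms (Sanger data enters the
real workflow through the same SAM/VCF path after mapping). Passing tests
therefore demonstrate the correctness of the post-alignment logic, not the
behaviour of upstream mappers and callers on real error profiles.

# Numerical choices and degenerate inputs

* Fisher ties: probabilities within a factor of 1+1e-7 of the observed
  table's count as "at most as probable"; degenerate margins (an empty row
  or column) admit a single table and return p = 1; an all-zero table is an
  error.
* Medians use the lower-middle convention.
* Cohort mean counts are rounded half-up (`floor(x + 0.5)`).
* Normalization at the contig start that would need to extend past
  position 0 is an explicit error rather than a silent re-anchor.
* Unknown contigs in interval queries return empty results (tracks may
  legitimately not cover a contig); unknown contigs in sequence queries are
  errors (a reference must).
* Ambiguity codes other than N in the reference are collapsed to N at load
  time; codons containing N translate to `Xaa`.
* refFlat transcripts whose CDS length is not a multiple of 3 load with a
  warning flag (real annotation tables contain such models) instead of
  failing the run.

# Problem sizes used by the test suite

The suite regenerates everything at run time: the exhaustive two-sided
Fisher sweep covers all 2×2 tables with every margin ≤ 30 against an
independent log-factorial enumeration (≳10⁵ tables, ≤1e-12 absolute);
BH is checked on 1,000 random p-vectors against the step-up formula; the
codon oracle mutates and retranslates the full spliced CDS for every SNV at
every position of a 30-codon two-exon gene on both strands; normalization
convergence is checked for 500 seeded repeat-tract indels against a
haplotype-equality spelling enumerator; the pileup is compared to a
base-by-base expansion oracle on 100 random CIGAR mixes; and the end-to-end
pipeline runs on the two-patient fixture with base error 0, where planted
variant keys must be recovered exactly and repeated/concurrent runs must be
byte-identical. These sizes keep the whole suite under a few minutes on a
laptop while leaving every module covered by an independent oracle.

# Known limitations

* Genotypes are not called or reported; the output is coverage-based, per
  the summary-table schema.
* Indel allele coverage depends on caller-reported depths; callers that
  omit them yield `alt_depth_unknown` variants that pass only the
  total-coverage filter.
* MNVs are rejected rather than decomposed.
* The per-variant Fisher test compares against the mean of the *other*
  variants of the same patient; with very few variants per patient the
  cohort mean is noisy, and with one variant it is undefined.
* URL templates point at current hosted schemes; they are data and will
  need refreshing as databases move.
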