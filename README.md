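# mutscreen

Post-alignment mutation screening for clinical sequencing panels: per-base
pileups with quality filtering, cross-mapper/cross-caller variant consensus,
codon-level effect prediction, per-variant exact-test statistics, and a
one-line-per-variant annotated summary table.

## The problem

Mutation-screening workflows in human molecular genetics run several read
mappers (BWA, Bowtie2, GSNAP, ...) and several variant callers (GATK,
SAMTOOLS, Freebayes, VarScan2) over the same patients, then must reconcile
the results: the same indel is spelled differently by different callers,
coverage evidence must be recounted uniformly, coding consequences and
clinical annotations must be attached, and everything has to land in one
table a geneticist can filter. `mutscreen` implements that post-alignment
core for R users. Mapping and variant calling themselves are upstream tools;
this package consumes their SAM/VCF outputs.

The pieces:

* **Pileups** — a CIGAR walk over SAM text with read-level filters (minimum
  mapping quality, proper-pair, PCR-duplicate removal by the
  coordinate+strand best-quality criterion) producing per-position A/C/G/T
  counts before and after base-quality filtering.
* **Normalization & consensus** — every call is reduced to its left-aligned
  parsimonious representation, so all equivalent caller spellings of an
  indel in a repeat tract share one key,
  `chr13.GRCh37:g.18258370G>A`-style; consensus records accumulate the
  supporting (mapper, caller) pairs, and Venn-cell statistics quantify
  between-tool agreement.
* **Effect prediction** — feature assignment (`exon_2;CDS_2` labels, minus
  strands numbered in transcription order), reference/variant codons from
  the spliced CDS, 3-letter amino-acid changes, and frameshift calls from
  the in-CDS indel length mod 3.
* **Statistics** — for each variant, a two-tailed Fisher's exact test of its
  (ref, alt) read counts against the mean counts of the patient's remaining
  variants, with Benjamini–Hochberg FDR correction per patient; flanking
  base-quality summaries; coverage/allele-frequency filters (defaults:
  total ≥ 20, alt ≥ 4, AF ≥ 0.10).
* **Annotation** — known/novel/intergenic classification against dbSNP-style
  tracks, membership flags, hotspot BED co-annotation, and a 32-column
  matrix of database cross-reference links keyed by coordinates, rsID,
  Entrez/symbol/transcript/protein/UniProt/KEGG/OMIM/HGNC identifiers.
* **Fixtures** — a deterministic generator for synthetic genomes, gene
  models, reads, and caller-jittered VCFs, so the entire pipeline is
  testable offline.

## Worked example

Generate a two-patient synthetic run and execute the pipeline:

```r
library(mutscreen)
fx  <- make_fixture_run(file.path(tempdir(), "demo"), fixture_spec(seed = 1))
res <- run_pipeline(fx$options_file, fx$manifest_file)
s   <- res$summary
s[s$Patient_Id == "P000001",
  c("Var_Id", "Var_Type", "Var_Cov", "Total_Cov", "Var_Gene",
    "Var_Feature", "Var_AA", "Frameshift", "dbSnp_Id")][1:6, ]
```

```
              Var_Id Var_Type Var_Cov Total_Cov Var_Gene  Var_Feature  Var_AA Frameshift dbSnp_Id
  ctg1.SIM1:g.545A>G      SNV      48       110    GENE1 exon_1;CDS_1 Lys>Lys            rs910001
  ctg1.SIM1:g.556del      DEL      30        60    GENE1 exon_1;CDS_1           yes(0>2)
 ctg1.SIM1:g.2049G>C      SNV      37        60    GENE3 exon_1;CDS_1 Ala>Pro
 ctg1.SIM1:g.4001del      DEL      30        60            intergenic
 ctg1.SIM1:g.4201del      DEL      30        60            intergenic
 ctg1.SIM1:g.5000T>A      SNV      38        60            intergenic          rs910006
```

Each row is one consensus variant for one patient: the normalized genomic
key, read-count evidence (the synonymous SNV sits where two planted variants'
read tilings overlap, hence 110× total), the gene-model consequence
(`Lys>Lys` — a synonymous third-codon-position change; `yes(0>2)` — a 1 bp
coding deletion shifting the reading frame from 0 to 2), and the matched
dbSNP identifier. The full table carries 73 columns, including 32 database
cross-reference URLs, the Fisher/FDR statistics, membership flags, and the
supporting mapper/caller lists (`Bwa;Bowtie2;GSNAP`,
`gatk;freebayes;samtools;varscan`, with `;hotspot` appended for hotspot
overlaps).

The primitives are usable directly:

```r
ref <- load_reference(file.path(fx$dir, "genome.fa"), "SIM1")
nv  <- normalize_variant("ctg1", 4002, "TA", "T", ref)  # a caller's spelling
variant_key(nv, "SIM1")
#> "ctg1.SIM1:g.4001del"          # left-aligned canonical key
fisher_two_tailed(2, 8, 8, 2)
#> 0.02301414                     # = 4252/184756, exact two-sided
```

A thin command-line front end with `run`, `normalize`, `annotate`, `stats`
and `fixtures` subcommands is installed at `inst/scripts/mutscreen.R`.

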