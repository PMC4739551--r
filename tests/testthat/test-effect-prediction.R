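snv <- function(contig, start0, ref, alt) {
  structure(list(contig = contig, start = start0, ref = ref, alt = alt,
                 vtype = "SNV"), class = "normalized_variant")
}
del <- function(contig, start0, ref, alt) {
  structure(list(contig = contig, start = start0, ref = ref, alt = alt,
                 vtype = "DEL"), class = "normalized_variant")
}
ins <- function(contig, start0, ref, alt) {
  structure(list(contig = contig, start = start0, ref = ref, alt = alt,
                 vtype = "INS"), class = "normalized_variant")
}

test_that("codons translate to 3-letter names with Ter and Xaa", {
  expect_equal(translate_codon("AAA"), "Lys")
  expect_equal(translate_codon(c("TAA", "TAG", "TGA")), rep("Ter", 3))
  expect_equal(translate_codon("ANA"), "Xaa")
  expect_equal(translate_codon("ATG"), "Met")
  expect_error(translate_codon("AA"), "length 3")
})

test_that("coding sequence splices exons and reverse-complements minus strand", {
  # plus strand, single exon
  ref <- tmp_ref(list(chrT = paste0("TTTTT", "ATGAAACCC", "TTTTT")))
  gs <- make_gene_set(tx_start = 0, tx_end = 19, cds_start = 5, cds_end = 14,
                      exon_starts = 0, exon_ends = 19)
  expect_equal(coding_sequence(gs$models[[1]], ref)$seq, "ATGAAACCC")

  # minus strand: genomic CDS reads GGGTTTCAT -> coding ATGAAACCC
  ref2 <- tmp_ref(list(chrT = paste0("TTTTT", "GGGTTTCAT", "TTTTT")))
  gs2 <- make_gene_set(strand = "-", tx_start = 0, tx_end = 19,
                       cds_start = 5, cds_end = 14,
                       exon_starts = 0, exon_ends = 19)
  expect_equal(coding_sequence(gs2$models[[1]], ref2)$seq, "ATGAAACCC")

  # CDS split over two exons skips the intron
  g <- build_two_exon_gene("ATGAAACCCGGGTTTTAA")
  expect_equal(coding_sequence(g$model, g$ref)$seq, g$coding)
  g2 <- build_two_exon_gene("ATGAAACCCGGGTTTTAA", strand = "-")
  expect_equal(coding_sequence(g2$model, g2$ref)$seq, g2$coding)
})

test_that("feature assignment labels exons, CDS, UTRs, introns", {
  g <- build_two_exon_gene("ATGAAACCCGGGTTTTAA")
  m <- g$model
  # SNV in the 2nd exon's CDS
  pos2 <- m$exon_starts[2] + 1L
  f <- assign_features(snv(g$contig, pos2, "A", "G"), g$gs)
  expect_equal(f$region_class, "CDS")
  expect_equal(f$feature_label, "exon_2;CDS_2")
  # UTR5 in exon 1, before cdsStart (plus strand)
  f <- assign_features(snv(g$contig, m$tx_start + 2L, "A", "G"), g$gs)
  expect_equal(f$region_class, "UTR5")
  expect_equal(f$feature_label, "exon_1")
  # UTR3 at the tail of exon 2
  f <- assign_features(snv(g$contig, m$tx_end - 2L, "A", "G"), g$gs)
  expect_equal(f$region_class, "UTR3")
  # intron between the exons
  f <- assign_features(snv(g$contig, m$exon_ends[1] + 3L, "A", "G"), g$gs)
  expect_equal(f$region_class, "intron")
  expect_equal(f$feature_label, "intron_1")
  # intergenic
  f <- assign_features(snv(g$contig, m$tx_end + 10L, "A", "G"), g$gs)
  expect_equal(f$region_class, "intergenic")
})

test_that("minus-strand ordinals count from the transcript 5' end", {
  g <- build_two_exon_gene("ATGAAACCCGGGTTTTAA", strand = "-")
  m <- g$model
  # genomic-leftmost CDS base lies in the transcript's LAST coding exon
  f <- assign_features(snv(g$contig, m$cds_start + 1L, "A", "G"), g$gs)
  expect_equal(f$feature_label, "exon_2;CDS_2")
  # the genomic-leftmost exon start (before cdsStart) is the 3' UTR
  f <- assign_features(snv(g$contig, m$exon_starts[1] + 1L, "A", "G"), g$gs)
  expect_equal(f$region_class, "UTR3")
  expect_equal(f$feature_label, "exon_2")
  # genomic-rightmost CDS segment is transcript CDS_1
  f <- assign_features(snv(g$contig, m$cds_end - 2L, "A", "G"), g$gs)
  expect_equal(f$feature_label, "exon_1;CDS_1")
})

test_that("codon change replaces the variant base in coding orientation", {
  # plus strand: AAA -> AAG at codon 2, 3rd position (synonymous Lys)
  ref <- tmp_ref(list(chrT = paste0("TTTTT", "ATGAAACCCTAA", "TTTTT")))
  gs <- make_gene_set(tx_start = 0, tx_end = 22, cds_start = 5, cds_end = 17,
                      exon_starts = 0, exon_ends = 22)
  cc <- predict_codon_change(snv("chrT", 10, "A", "G"), gs$models[[1]], ref)
  expect_equal(cc$ref_codon, "AAA")
  expect_equal(cc$alt_codon, "AAG")
  expect_equal(cc$ref_aa, "Lys")
  expect_equal(cc$alt_aa, "Lys")
  expect_equal(cc$codon_number, 2)
  expect_equal(cc$position_in_codon, 3)
  # ATG -> ATA at codon 1 position 3: Met>Ile
  cc <- predict_codon_change(snv("chrT", 7, "G", "A"), gs$models[[1]], ref)
  expect_equal(cc$ref_aa, "Met")
  expect_equal(cc$alt_aa, "Ile")
  # not in CDS
  expect_error(predict_codon_change(snv("chrT", 2, "T", "A"),
                                    gs$models[[1]], ref), "not in the CDS")
})

test_that("minus-strand codon change complements the alt base", {
  # genomic GGGTTTCAT (minus) -> coding ATGAAACCC; genomic T>C at the
  # position mapping to coding ref A gives coding alt G
  ref <- tmp_ref(list(chrT = paste0("TTTTT", "GGGTTTCAT", "TTTTT")))
  gs <- make_gene_set(strand = "-", tx_start = 0, tx_end = 19,
                      cds_start = 5, cds_end = 14,
                      exon_starts = 0, exon_ends = 19)
  # coding offset 3 (codon 2 pos 1, ref "A") is genomic position 10 ("T")
  cc <- predict_codon_change(snv("chrT", 10, "T", "C"), gs$models[[1]], ref)
  expect_equal(cc$ref_codon, "AAA")
  expect_equal(cc$alt_codon, "GAA")
  expect_equal(cc$codon_number, 2)
  expect_equal(cc$position_in_codon, 1)
  expect_equal(cc$alt_aa, "Glu")
})

test_that("frameshift is in-CDS indel length mod 3", {
  g <- build_two_exon_gene("ATGAAACCCGGGTTTACGTCAGTTTAA")
  m <- g$model
  cs <- m$cds_start
  # 1 bp deletion inside CDS (anchor at cds_start): frameshift
  fs <- predict_frameshift(del(g$contig, cs, "NN", "N"), m)
  expect_true(fs$is_frameshift)
  expect_equal(fs$indel_len_in_cds, 1)
  expect_equal(fs$new_frame, (fs$original_frame - 1) %% 3)
  # 3 bp deletion fully in CDS: no frameshift
  fs <- predict_frameshift(del(g$contig, cs, "NNNN", "N"), m)
  expect_false(fs$is_frameshift)
  # deletion straddling the CDS end with 3 deleted bases inside
  ce <- m$cds_end
  fs <- predict_frameshift(del(g$contig, ce - 4L, "NNNNN", "N"), m)
  expect_equal(fs$indel_len_in_cds, 3)
  expect_false(fs$is_frameshift)
  # insertion inside CDS
  fs <- predict_frameshift(ins(g$contig, cs + 2L, "N", "NAA"), m)
  expect_equal(fs$indel_len_in_cds, 2)
  expect_true(fs$is_frameshift)
  # indel entirely outside the CDS errors
  expect_error(predict_frameshift(del(g$contig, m$tx_start, "NN", "N"), m),
               "outside the CDS")
})

test_that("every SNV at every CDS position matches mutate-and-translate", {
  # exhaustive oracle over a 10-codon gene on both strands
  coding <- "ATGGCTAAACCCGGGTTTACGTCACATTAA"
  aa3 <- Biostrings::AMINO_ACID_CODE
  oracle_translate <- function(cdn) {
    a <- Biostrings::GENETIC_CODE[[cdn]]
    if (a == "*") "Ter" else unname(aa3[a])
  }
  for (strand in c("+", "-")) {
    g <- build_two_exon_gene(coding, strand = strand)
    n <- nchar(coding)
    for (off in 0:(n - 1)) {
      gpos <- oracle_coding_to_genomic(g, off)
      gref <- ref_seq(g$ref, g$contig, gpos, gpos + 1L)
      for (galt in setdiff(c("A", "C", "G", "T"), gref)) {
        cc <- predict_codon_change(snv(g$contig, gpos, gref, galt),
                                   g$model, g$ref)
        # oracle: substitute in the full CDS string and translate
        alt_coding <- if (strand == "+") galt else chartr("ACGT", "TGCA", galt)
        mutated <- coding
        substr(mutated, off + 1L, off + 1L) <- alt_coding
        ci <- off %/% 3L + 1L
        want_ref <- substr(coding, (ci - 1L) * 3L + 1L, ci * 3L)
        want_alt <- substr(mutated, (ci - 1L) * 3L + 1L, ci * 3L)
        expect_equal(cc$ref_codon, want_ref)
        expect_equal(cc$alt_codon, want_alt)
        expect_equal(cc$ref_aa, oracle_translate(want_ref))
        expect_equal(cc$alt_aa, oracle_translate(want_alt))
        expect_equal(cc$codon_number, ci)
        expect_equal(cc$position_in_codon, off %% 3L + 1L)
      }
    }
  }
})
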