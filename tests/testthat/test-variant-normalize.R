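# reference with a homopolymer: 100 C, then AAAT, then G-tail
hp_ref <- function() {
  tmp_ref(list(chrT = paste0(strrep("C", 100), "AAAT", strrep("G", 50))),
          assembly = "T1")
}

test_that("VCF ingestion splits multiallelics and recovers caller depths", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chrT\t10\t.\tG\tA,T\t50\tPASS\tDP=30\tGT:AD:DP\t0/1:18,12,3:30",
    "chrT\t20\t.\tC\tG\t50\tLowQual\tDP=40\tGT:AD:DP\t0/1:28,12:40"
  ), vcf)
  calls <- read_vcf(vcf, "gatk", "bwa", "S1")
  expect_equal(nrow(calls), 3)            # two alts + one more record
  expect_equal(calls$alt[1:2], c("A", "T"))
  expect_equal(calls$depth_total[1], 30)
  expect_equal(calls$depth_alt[1:2], c(12, 3))
  expect_equal(calls$depth_alt[3], 12)
  expect_false(calls$pass[3])             # LowQual retained but flagged
  expect_true(all(calls$pass[1:2]))
})

test_that("VCF depth dialects: samtools DP4 and varscan RD/AD", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chrT\t10\t.\tG\tA\t50\tPASS\tDP4=10,8,7,5\tGT\t0/1"
  ), vcf)
  st <- read_vcf(vcf, "samtools", "bwa", "S1")
  expect_equal(st$depth_alt, 12)          # alt fwd + alt rev
  expect_equal(st$depth_total, 30)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chrT\t10\t.\tG\tA\t.\tPASS\t.\tGT:DP:RD:AD:FREQ\t0/1:30:18:12:40.00%"
  ), vcf)
  vs <- read_vcf(vcf, "varscan", "bwa", "S1")
  expect_equal(vs$depth_alt, 12)
  expect_equal(vs$depth_total, 30)
})

test_that("VCF ingestion validates the header and the REF allele", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "chrT\t10\t.\tG\tA\t.\tPASS\t."), vcf)
  expect_error(read_vcf(vcf, "gatk", "bwa", "S1"), "#CHROM")
  ref <- hp_ref()
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrT\t101\t.\tG\tA\t.\tPASS\t.",     # reference has A at 101
    "chrT\t150\t.\tG\tA\t.\tPASS\t."
  ), vcf)
  expect_warning(calls <- read_vcf(vcf, "gatk", "bwa", "S1", ref),
                 "disagrees")
  expect_equal(nrow(calls), 1)            # mismatching record skipped
  expect_equal(calls$pos, 150)
})

test_that("indel spellings left-align and converge in a homopolymer", {
  ref <- hp_ref()
  nv1 <- normalize_variant("chrT", 101, "AA", "A", ref)
  expect_equal(nv1$start, 99)
  expect_equal(nv1$ref, "CA")
  expect_equal(nv1$alt, "C")
  expect_equal(nv1$vtype, "DEL")
  # a different caller spelling of the same deletion
  nv2 <- normalize_variant("chrT", 102, "AA", "A", ref)
  expect_equal(unclass(nv1)[c("contig", "start", "ref", "alt", "vtype")],
               unclass(nv2)[c("contig", "start", "ref", "alt", "vtype")])
  # SNVs are fixed points
  nv3 <- normalize_variant("chrT", 150, "G", "A", ref)
  expect_equal(nv3$start, 149)
  expect_equal(nv3$vtype, "SNV")
  # degenerate inputs
  expect_error(normalize_variant("chrT", 150, "G", "G", ref), "identical")
  expect_error(normalize_variant("chrT", 150, "GA", "AG", ref), "MNV")
})

test_that("normalize is idempotent", {
  ref <- hp_ref()
  cases <- list(c(101, "AA", "A"), c(101, "A", "AAA"), c(150, "G", "A"),
                c(103, "AT", "A"))
  for (cs in cases) {
    nv <- normalize_variant("chrT", as.integer(cs[1]), cs[2], cs[3], ref)
    nv2 <- normalize_variant(nv$contig, nv$start + 1L, nv$ref, nv$alt, ref)
    expect_equal(unclass(nv)[-1], unclass(nv2)[-1])
  }
})

test_that("all equivalent spellings inside a repeat tract map to one key", {
  # brute-force oracle: a spelling is equivalent iff applying it to the
  # reference yields the same haplotype string
  set.seed(55)
  for (rep in 1:25) {
    tract_len <- sample(4:12, 1)
    unit <- sample(c("A", "C", "G", "T"), 1)
    seq <- paste0(
      paste(sample(setdiff(c("A", "C", "G", "T"), unit), 30, TRUE),
            collapse = ""),
      strrep(unit, tract_len),
      paste(sample(setdiff(c("A", "C", "G", "T"), unit), 30, TRUE),
            collapse = ""))
    ref <- tmp_ref(list(chrT = seq))
    k <- sample(1:3, 1)                       # indel size
    is_del <- runif(1) < 0.5 && tract_len > k
    tract_start0 <- 30L
    apply_del <- function(s0, k) {            # delete k bases at 0-based s0
      paste0(substr(seq, 1, s0), substr(seq, s0 + k + 1L, nchar(seq)))
    }
    apply_ins <- function(s0, ins) {          # insert after 0-based s0 - 1
      paste0(substr(seq, 1, s0), ins, substr(seq, s0 + 1L, nchar(seq)))
    }
    if (is_del) {
      truth <- apply_del(tract_start0, k)
    } else {
      truth <- apply_ins(tract_start0, strrep(unit, k))
    }
    keys <- character(0)
    for (a0 in (tract_start0 - 3L):(tract_start0 + tract_len + 2L)) {
      if (is_del) {
        hap <- apply_del(a0 + 1L, k)
        spell <- list(pos = a0 + 1L,
                      ref = substr(seq, a0 + 1L, a0 + 1L + k),
                      alt = substr(seq, a0 + 1L, a0 + 1L))
      } else {
        hap <- apply_ins(a0 + 1L, strrep(unit, k))
        spell <- list(pos = a0 + 1L,
                      ref = substr(seq, a0 + 1L, a0 + 1L),
                      alt = paste0(substr(seq, a0 + 1L, a0 + 1L),
                                   strrep(unit, k)))
      }
      if (hap != truth) next
      nv <- normalize_variant("chrT", spell$pos, spell$ref, spell$alt, ref)
      keys <- c(keys, variant_key(nv, "T1"))
    }
    expect_gte(length(keys), 2)               # repeat tract: several spellings
    expect_equal(length(unique(keys)), 1)
  }
})

test_that("variant keys follow the genomic identifier conventions", {
  nv <- structure(list(contig = "chr13", start = 18258369L, ref = "G",
                       alt = "A", vtype = "SNV"), class = "normalized_variant")
  expect_equal(variant_key(nv, "GRCh37"), "chr13.GRCh37:g.18258370G>A")
  del1 <- structure(list(contig = "chrT", start = 99L, ref = "CA", alt = "C",
                         vtype = "DEL"), class = "normalized_variant")
  expect_equal(variant_key(del1, "T1"), "chrT.T1:g.101del")
  del3 <- structure(list(contig = "chrT", start = 99L, ref = "CAAA",
                         alt = "C", vtype = "DEL"),
                    class = "normalized_variant")
  expect_equal(variant_key(del3, "T1"), "chrT.T1:g.101_103del")
  ins <- structure(list(contig = "chrT", start = 199L, ref = "G",
                        alt = "GTT", vtype = "INS"),
                   class = "normalized_variant")
  expect_equal(variant_key(ins, "T1"), "chrT.T1:g.200_201insTT")
  # keys parse back to their coordinates
  pk <- parse_variant_key("chr13.GRCh37:g.18258370G>A")
  expect_equal(pk[c("contig", "start", "end", "ref", "alt")],
               list(contig = "chr13", start = 18258370L, end = 18258370L,
                    ref = "G", alt = "A"))
  expect_equal(parse_variant_key("chrT.T1:g.101_103del")$end, 103L)
  expect_equal(parse_variant_key("chrT.T1:g.200_201insTT")$ins_seq, "TT")
})

test_that("consensus merges calls across mappers and callers", {
  ref <- hp_ref()
  calls <- rbind(
    make_call("chrT", 150, "G", "A", "gatk", "bwa"),
    make_call("chrT", 150, "G", "A", "samtools", "bwa"),
    # two spellings of the same homopolymer deletion
    make_call("chrT", 101, "AA", "A", "gatk", "bwa"),
    make_call("chrT", 102, "AA", "A", "freebayes", "bowtie2"),
    # disjoint variant
    make_call("chrT", 120, "C", "T", "varscan", "bwa")
  )
  cons <- build_consensus(calls, ref)
  expect_equal(nrow(cons), 3)
  snv <- cons[cons$vtype == "SNV" & cons$start == 149, ]
  expect_equal(snv$n_callers, 2)
  expect_equal(snv$n_mappers, 1)
  del <- cons[cons$vtype == "DEL", ]
  expect_equal(del$n_callers, 2)
  expect_equal(del$n_mappers, 2)
  expect_equal(del$start, 99)
  expect_equal(del$callers, "gatk;freebayes")   # canonical label order
  expect_equal(del$mappers, "Bwa;Bowtie2")
  # permutation invariance
  cons2 <- build_consensus(calls[sample(nrow(calls)), ], ref)
  expect_equal(cons[, c("contig", "start", "ref", "alt", "n_callers")],
               cons2[, c("contig", "start", "ref", "alt", "n_callers")])
})

test_that("overlap statistics count Venn cells and the >=2 fraction", {
  ref <- hp_ref()
  calls <- rbind(
    make_call("chrT", 110, "C", "A", "gatk", "bwa"),
    make_call("chrT", 120, "C", "A", "gatk", "bwa"),
    make_call("chrT", 120, "C", "A", "samtools", "bwa"),
    make_call("chrT", 130, "C", "A", "gatk", "bwa"),
    make_call("chrT", 130, "C", "A", "samtools", "bwa"),
    make_call("chrT", 130, "C", "A", "freebayes", "bwa")
  )
  ost <- overlap_statistics(build_consensus(calls, ref), "caller")
  cells <- setNames(ost$cells$count, ost$cells$members)
  expect_equal(unname(cells["gatk"]), 1)
  expect_equal(unname(cells["gatk+samtools"]), 1)
  expect_equal(unname(cells["gatk+freebayes+samtools"]), 1)
  expect_equal(unname(ost$ge2_fraction["SNV"]), 2 / 3)
  expect_equal(sum(ost$cells$count), 3)    # cells partition the variants

  # all variants supported by all labels -> fraction 1
  calls2 <- rbind(make_call("chrT", 110, "C", "A", "gatk", "bwa"),
                  make_call("chrT", 110, "C", "A", "samtools", "bwa"))
  expect_equal(unname(
    overlap_statistics(build_consensus(calls2, ref), "caller")$ge2_fraction["all"]),
    1)
  # single label: precondition violated
  calls3 <- make_call("chrT", 110, "C", "A", "gatk", "bwa")
  expect_error(overlap_statistics(build_consensus(calls3, ref), "caller"),
               ">=2")
  expect_error(overlap_statistics(build_consensus(calls3, ref), "mapper"),
               ">=2")
})

test_that("consensus VCF export writes one anchored record per variant", {
  ref <- hp_ref()
  calls <- rbind(make_call("chrT", 101, "AA", "A", "gatk", "bwa"),
                 make_call("chrT", 150, "G", "A", "samtools", "bwa"))
  cons <- build_consensus(calls, ref)
  out <- tempfile(fileext = ".vcf")
  write_consensus_vcf(cons, out, ref)
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2)
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(f1[2], "100")               # left-aligned anchor, 1-based
  expect_equal(f1[4], "CA")
  expect_match(f1[8], "NCALLERS=1")
})
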