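# Deterministic synthetic fixtures: genomes with embedded gene models and
# homopolymer tracts, planted variants with truth labels, tiled reads with
# injected duplicates, membership tracks, hotspots, and caller-jittered VCFs
# emulating the representation divergence of multiple mapper/caller runs.
#
# A single seed governs all randomness; the same spec yields byte-identical
# files.

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Fixture generation parameters
#'
#' Defaults describe the emulated study conditions: heterozygous germline
#' variants (allele fraction 0.5) sequenced to ~60x with 80 bp single-end
#' reads, a 0.1% base error rate, 10% PCR duplicates, three mappers and four
#' variant callers.
#'
#' @param seed integer seed governing all randomness.
#' @param n_contigs number of contigs (>= 2 for the default variant plan).
#' @param contig_length contig length in bp (>= 7500).
#' @param n_genes number of embedded genes (>= 3 for the default plan).
#' @param n_codons codons per gene (incl. start and stop).
#' @param read_length read length in bp.
#' @param depth read depth tiled over each variant locus.
#' @param base_error_rate per-base substitution error rate in reads.
#' @param af planted variant allele fraction.
#' @param dup_fraction fraction of reads duplicated verbatim.
#' @param patients patient identifiers (one SAM + VCF set each).
#' @param mappers,callers mapper and caller identifiers emulated.
#' @param caller_jitter subset of `c("right_shift_indels", "suffix_padding",
#'   "multiallelic_merge")` enabled when spelling caller VCFs.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_contigs = 2L, contig_length = 9000L,
                         n_genes = 3L, n_codons = 30L, read_length = 80L,
                         depth = 60L, base_error_rate = 0.001, af = 0.5,
                         dup_fraction = 0.1,
                         patients = c("P000001", "P000002"),
                         mappers = c("bwa", "bowtie2", "gsnap"),
                         callers = c("gatk", "freebayes", "samtools",
                                     "varscan"),
                         caller_jitter = c("right_shift_indels",
                                           "suffix_padding",
                                           "multiallelic_merge")) {
  stopifnot(contig_length >= 7500, n_contigs >= 2, n_genes >= 3,
            n_codons >= 12, depth >= 1)
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 n_genes = as.integer(n_genes),
                 n_codons = as.integer(n_codons),
                 read_length = as.integer(read_length),
                 depth = as.integer(depth),
                 base_error_rate = base_error_rate, af = af,
                 dup_fraction = dup_fraction, patients = patients,
                 mappers = mappers, callers = callers,
                 caller_jitter = caller_jitter),
            class = "fixture_spec")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))

# fixed codons planted into every gene so the variant plan always has
# synonymous / missense / indel-stable contexts to target:
#   codon 5 "AAA" (Lys; AAA>AAG synonymous), codon 7 "GCT" (Ala; G>C missense),
#   codons 8-10 "ACG","TCA","GTT" (shift-stable indel context around codon 9)
FIXED_CODONS <- c(`5` = "AAA", `7` = "GCT", `8` = "ACG", `9` = "TCA",
                  `10` = "GTT")

make_gene_coding <- function(n_codons) {
  pool <- setdiff(ALL_CODONS, STOP_CODONS)
  codons <- c("ATG", sample(pool, n_codons - 2L, replace = TRUE), "TAA")
  for (k in names(FIXED_CODONS)) codons[as.integer(k)] <- FIXED_CODONS[[k]]
  paste(codons, collapse = "")
}

#' Generate a synthetic genome with embedded genes and repeat tracts
#'
#' Each gene is a 2-exon transcript (UTR5 30 bp, CDS split 40/50 across an
#' intron of 120 bp, UTR3 30 bp) whose CDS starts with ATG, ends with a stop
#' and has length divisible by 3; strands alternate so at least one gene is
#' on the minus strand. Homopolymer tracts (8-10 bp, boundary bases forced to
#' differ) are embedded intergenically as left-alignment test beds.
#'
#' @param spec a [fixture_spec()].
#' @return list with `reference` (a `ref_genome`, assembly "SIM1"), `refflat`
#'   and `ids` data.frames, `genes` (layout records incl. the coding string),
#'   and `tracts` (data.frame contig/start/len/base, 0-based).
#' @export
make_genome <- function(spec) {
  set.seed(spec$seed)
  contigs <- setNames(vapply(seq_len(spec$n_contigs), function(i)
    random_dna(spec$contig_length), character(1)),
    paste0("ctg", seq_len(spec$n_contigs)))
  utr5 <- 30L; cds1 <- 40L; cds2 <- 50L; utr3 <- 30L; intron <- 120L
  stopifnot(spec$n_codons * 3L == cds1 + cds2)
  block_len <- utr5 + cds1 + intron + cds2 + utr3
  genes <- vector("list", spec$n_genes)
  for (g in seq_len(spec$n_genes)) {
    contig_i <- (g - 1L) %% spec$n_contigs + 1L
    t0 <- 500L + 1500L * ((g - 1L) %/% spec$n_contigs)
    strand <- if (g %% 2L == 1L) "+" else "-"
    coding <- make_gene_coding(spec$n_codons)
    block_plus <- paste0(random_dna(utr5), substr(coding, 1, cds1),
                         random_dna(intron),
                         substr(coding, cds1 + 1, cds1 + cds2),
                         random_dna(utr3))
    ex_rel_s <- c(0L, utr5 + cds1 + intron)
    ex_rel_e <- c(utr5 + cds1, block_len - 0L)
    ex_rel_e[2] <- utr5 + cds1 + intron + cds2 + utr3
    cds_rel <- c(utr5, utr5 + cds1 + intron + cds2)
    if (strand == "-") {
      block <- revcomp(block_plus)
      ex_s <- block_len - rev(ex_rel_e)
      ex_e <- block_len - rev(ex_rel_s)
      cds_s <- block_len - cds_rel[2]
      cds_e <- block_len - cds_rel[1]
    } else {
      block <- block_plus
      ex_s <- ex_rel_s; ex_e <- ex_rel_e
      cds_s <- cds_rel[1]; cds_e <- cds_rel[2]
    }
    ctg <- names(contigs)[contig_i]
    substr(contigs[[ctg]], t0 + 1L, t0 + block_len) <- block
    seg_s <- pmax(ex_s, cds_s) + t0
    seg_e <- pmin(ex_e, cds_e) + t0
    keep <- seg_s < seg_e
    genes[[g]] <- list(
      symbol = sprintf("GENE%d", g), tx = sprintf("NM_%06d", g),
      contig = ctg, strand = strand, t0 = t0,
      exon_starts = ex_s + t0, exon_ends = ex_e + t0,
      cds_start = cds_s + t0, cds_end = cds_e + t0,
      cds_seg_start = seg_s[keep], cds_seg_end = seg_e[keep],
      coding = coding)
  }
  # homopolymer tracts: two per contig, boundaries forced to differ
  tract_bases <- c("A", "T", "G", "C")
  tracts <- do.call(rbind, lapply(seq_len(spec$n_contigs), function(ci) {
    data.frame(contig = names(contigs)[ci],
               start = c(4000L, 4200L),
               len = c(10L, 8L),
               base = tract_bases[c(ci * 2L - 1L, ci * 2L) %% 4L + 1L],
               stringsAsFactors = FALSE)
  }))
  other_base <- function(b) setdiff(BASES, b)[1]
  for (i in seq_len(nrow(tracts))) {
    ctg <- tracts$contig[i]; s <- tracts$start[i]; l <- tracts$len[i]
    b <- tracts$base[i]
    substr(contigs[[ctg]], s + 1L, s + l) <- strrep(b, l)
    substr(contigs[[ctg]], s, s) <- other_base(b)           # base before
    substr(contigs[[ctg]], s + l + 1L, s + l + 1L) <- other_base(b)
  }
  refflat <- do.call(rbind, lapply(genes, function(gn) {
    data.frame(geneName = gn$symbol, name = gn$tx, chrom = gn$contig,
               strand = gn$strand, txStart = gn$t0,
               txEnd = gn$t0 + block_len, cdsStart = gn$cds_start,
               cdsEnd = gn$cds_end, exonCount = length(gn$exon_starts),
               exonStarts = paste0(paste(gn$exon_starts, collapse = ","), ","),
               exonEnds = paste0(paste(gn$exon_ends, collapse = ","), ","),
               stringsAsFactors = FALSE)
  }))
  ids <- do.call(rbind, lapply(seq_along(genes), function(g) {
    data.frame(transcript = genes[[g]]$tx, entrez = as.character(1000L + g),
               protein = sprintf("NP_%06d", g),
               uniprot = sprintf("P%05d", 10000L + g),
               kegg = sprintf("hsa%05d", g),
               omim = as.character(600000L + g),
               hgnc = sprintf("HGNC:%d", 7000L + g),
               stringsAsFactors = FALSE)
  }))
  reference <- structure(list(contigs = contigs, assembly = "SIM1"),
                         class = "ref_genome")
  list(reference = reference, refflat = refflat, ids = ids, genes = genes,
       tracts = tracts)
}

# genomic 0-based position of coding-orientation CDS offset `off0`
fixture_coding_to_genomic <- function(gene, off0) {
  widths <- gene$cds_seg_end - gene$cds_seg_start
  total <- sum(widths)
  g_off <- if (gene$strand == "+") off0 else total - 1L - off0
  cum <- cumsum(c(0L, widths))
  i <- findInterval(g_off, cum, rightmost.closed = FALSE)
  unname(gene$cds_seg_start[i] + (g_off - cum[i]))
}

fixture_aa3 <- function(codon) {
  aa1 <- Biostrings::GENETIC_CODE[codon]
  ifelse(aa1 == "*", "Ter", Biostrings::AMINO_ACID_CODE[aa1])
}

# SNV at coding offset off0 (0-based) changing the coding base to alt_coding;
# returns plan fields incl. genomic spelling and mutate-and-translate truth
plan_cds_snv <- function(gene, codon_idx, pos_in_codon, alt_coding) {
  off0 <- (codon_idx - 1L) * 3L + (pos_in_codon - 1L)
  gpos0 <- fixture_coding_to_genomic(gene, off0)
  ref_coding <- substr(gene$coding, off0 + 1L, off0 + 1L)
  stopifnot(ref_coding != alt_coding)
  gref <- if (gene$strand == "+") ref_coding else complement_base(ref_coding)
  galt <- if (gene$strand == "+") alt_coding else complement_base(alt_coding)
  mutated <- gene$coding
  substr(mutated, off0 + 1L, off0 + 1L) <- alt_coding
  ref_codon <- substr(gene$coding, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  alt_codon <- substr(mutated, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  ref_aa <- fixture_aa3(ref_codon); alt_aa <- fixture_aa3(alt_codon)
  list(contig = gene$contig, pos = gpos0 + 1L, ref = gref, alt = galt,
       vtype = "SNV", gene = gene$symbol,
       truth_effect = if (ref_aa == alt_aa) "synonymous" else "missense",
       truth_codon = sprintf("%s>%s", ref_codon, alt_codon),
       truth_aa = sprintf("%s>%s", ref_aa, alt_aa))
}

#' Plant the fixture variant set
#'
#' A deterministic plan over the synthetic genome: coding SNVs (synonymous on
#' the plus strand, missense on the minus strand), shift-stable coding
#' deletions (1 bp frameshift, 3 bp in-frame), intergenic SNVs including one
#' multiallelic site, and indels inside homopolymer tracts whose caller
#' spellings diverge. Support sets encode a known Venn structure: a shared
#' block called by every caller plus single-caller and two-caller private
#' variants.
#'
#' @param genome result of [make_genome()].
#' @param spec a [fixture_spec()].
#' @return data.frame plan; one row per planted alt allele with canonical
#'   (left-aligned) spelling, truth labels, per-patient carriage, support
#'   sets, rsID/flag/hotspot assignments.
#' @export
make_variant_plan <- function(genome, spec) {
  set.seed(spec$seed + 1L)
  ref <- genome$reference
  g1 <- genome$genes[[1]]; g2 <- genome$genes[[2]]; g3 <- genome$genes[[3]]
  all_p <- paste(spec$patients, collapse = ";")
  p1 <- spec$patients[1]; p2 <- spec$patients[2]
  all_c <- paste(spec$callers, collapse = ";")
  all_m <- paste(spec$mappers, collapse = ";")
  base_row <- function(id, x, zone, patients, callers, rsid = NA_character_,
                       hotspot = FALSE, af = spec$af) {
    data.frame(id = id, contig = x$contig, pos = x$pos, ref = x$ref,
               alt = x$alt, vtype = x$vtype, zone = zone,
               gene = x$gene %||% NA_character_,
               truth_effect = x$truth_effect %||% NA_character_,
               truth_codon = x$truth_codon %||% NA_character_,
               truth_aa = x$truth_aa %||% NA_character_,
               af = af, patients = patients, callers = callers,
               mappers = all_m, rsid = rsid, hotspot = hotspot,
               stringsAsFactors = FALSE)
  }
  # shift-stable CDS deletion: codon 9 is TCA flanked by ACG / GTT
  cds_del <- function(gene, n_del) {
    # delete n_del bases starting at the C of codon 9 (coding offsets 25..)
    off0 <- if (n_del == 1L) (9L - 1L) * 3L + 1L else (9L - 1L) * 3L
    gpos <- sort(vapply(off0 + 0:(n_del - 1L), function(o)
      fixture_coding_to_genomic(gene, o), integer(1)))
    stopifnot(all(diff(gpos) == 1L))
    anchor0 <- gpos[1] - 1L
    delseq <- ref_seq(ref, gene$contig, gpos[1], gpos[n_del] + 1L)
    list(contig = gene$contig, pos = anchor0 + 1L,
         ref = paste0(ref_seq(ref, gene$contig, anchor0, anchor0 + 1L), delseq),
         alt = ref_seq(ref, gene$contig, anchor0, anchor0 + 1L),
         vtype = "DEL", gene = gene$symbol,
         truth_effect = if (n_del %% 3L != 0L) "frameshift" else "inframe",
         truth_codon = NA_character_, truth_aa = NA_character_)
  }
  intergenic_snv <- function(contig, pos0) {
    rb <- ref_seq(ref, contig, pos0, pos0 + 1L)
    list(contig = contig, pos = pos0 + 1L, ref = rb,
         alt = setdiff(BASES, rb)[1], vtype = "SNV", gene = NA_character_,
         truth_effect = NA_character_, truth_codon = NA_character_,
         truth_aa = NA_character_)
  }
  tract_indel <- function(tr, type, n) {
    anchor0 <- tr$start - 1L   # base before the tract (differs from tract base)
    ab <- ref_seq(ref, tr$contig, anchor0, anchor0 + 1L)
    if (type == "DEL") {
      list(contig = tr$contig, pos = anchor0 + 1L,
           ref = paste0(ab, strrep(tr$base, n)), alt = ab, vtype = "DEL",
           gene = NA_character_, truth_effect = NA_character_,
           truth_codon = NA_character_, truth_aa = NA_character_)
    } else {
      list(contig = tr$contig, pos = anchor0 + 1L, ref = ab,
           alt = paste0(ab, strrep(tr$base, n)), vtype = "INS",
           gene = NA_character_, truth_effect = NA_character_,
           truth_codon = NA_character_, truth_aa = NA_character_)
    }
  }
  tr1 <- as.list(genome$tracts[1, ])  # ctg1 tract
  tr2 <- as.list(genome$tracts[2, ])  # ctg1 second tract
  tr3 <- as.list(genome$tracts[genome$tracts$contig == "ctg2", ][1, ])
  ctg1 <- "ctg1"; ctg2 <- "ctg2"
  ma_site <- intergenic_snv(ctg1, 5599L)
  ma2 <- ma_site
  ma2$alt <- setdiff(BASES, c(ma_site$ref, ma_site$alt))[1]
  rows <- list(
    base_row("v01", plan_cds_snv(g1, 5L, 3L, "G"), "CDS", all_p, all_c,
             rsid = "rs910001"),
    base_row("v02", plan_cds_snv(g2, 7L, 1L, "C"), "CDS", all_p, all_c,
             rsid = "rs910002"),
    base_row("v03", plan_cds_snv(g3, 7L, 1L, "C"), "CDS", p1, all_c,
             hotspot = TRUE),
    base_row("v04", cds_del(g1, 1L), "CDS", all_p, all_c),
    base_row("v05", cds_del(g3, 3L), "CDS", p2, all_c, rsid = "rs910005"),
    base_row("v06", intergenic_snv(ctg1, 4999L), "intergenic", all_p, all_c,
             rsid = "rs910006"),
    base_row("v07", tract_indel(tr1, "DEL", 1L), "tract", all_p, all_c),
    base_row("v08", tract_indel(tr3, "INS", 2L), "tract", all_p, all_c),
    base_row("v09", ma_site, "intergenic", all_p, all_c),
    base_row("v10", intergenic_snv(ctg2, 4999L), "intergenic", all_p, all_c,
             rsid = "rs910010"),
    base_row("v11", intergenic_snv(ctg1, 5399L), "intergenic", all_p,
             "varscan"),
    base_row("v12", intergenic_snv(ctg2, 5399L), "intergenic", all_p, "gatk"),
    base_row("v13", tract_indel(tr2, "DEL", 1L), "tract", all_p,
             "freebayes;samtools"),
    base_row("v14", ma2, "intergenic", all_p, all_c, af = 0.3)
  )
  # the multiallelic partner shares the site: carve allele fractions
  plan <- do.call(rbind, rows)
  plan$af[plan$id == "v09"] <- 0.3
  rownames(plan) <- NULL
  plan
}

# membership-flag truth: which plan ids fall in which track
FIXTURE_FLAG_PLAN <- list(
  dbSnp_Common = c("v01", "v06"),
  dbSnp_Coding = c("v01", "v02", "v05"),
  Gwas_Catalogue = "v06",
  dbSnp_Flagged = "v02",
  dbSnp_Mult = "v05",
  dbSnp_HapMap = "v01",
  dbSnp_Cpg_Island = "v10"
)

plan_footprint <- function(plan_row) {
  # canonical plan spellings are already anchored/normalized
  nr <- nchar(plan_row$ref); na <- nchar(plan_row$alt)
  start0 <- plan_row$pos - 1L
  if (nr == 1L && na == 1L) c(start0, start0 + 1L)
  else if (nr > na) c(start0 + 1L, start0 + nr)
  else c(start0, start0 + 2L)
}

#' Generate tiled reads over the planted variant loci as SAM text
#'
#' Reads of `spec$read_length` tile every locus the patient carries at
#' `spec$depth`, alternating strands. Carrier reads receive the planted alt
#' alleles at the planted allele fraction (multiallelic sites partition
#' reads); base errors are injected at `spec$base_error_rate`; a
#' `spec$dup_fraction` of reads is duplicated verbatim. Indel alleles are
#' not spelled into reads: their allele evidence arrives via the caller VCFs,
#' matching the coverage decomposition's SNV-only base counts.
#'
#' @param genome result of [make_genome()].
#' @param plan result of [make_variant_plan()].
#' @param spec a [fixture_spec()].
#' @param patient patient identifier.
#' @return character vector of SAM lines (header included).
#' @export
make_reads <- function(genome, plan, spec, patient) {
  set.seed(spec$seed + 10L * match(patient, spec$patients) + 2L)
  ref <- genome$reference
  carried <- plan[vapply(strsplit(plan$patients, ";", fixed = TRUE),
                         function(p) patient %in% p, logical(1)), ,
                  drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref$contigs),
                   nchar(ref$contigs)))
  rl <- spec$read_length
  # SNV sites grouped by position so multiallelic alleles stay exclusive
  snvs <- carried[carried$vtype == "SNV", , drop = FALSE]
  site_key <- paste(snvs$contig, snvs$pos)
  reads <- list(); k <- 0L
  loci <- unique(carried[, c("contig", "pos")])
  # (start, strand) pairs are kept unique per contig so that the only
  # duplicate groups are the verbatim copies injected below
  used <- list()
  for (li in seq_len(nrow(loci))) {
    ctg <- loci$contig[li]; pos0 <- loci$pos[li] - 1L
    clen <- nchar(ref$contigs[[ctg]])
    n_half <- ceiling(spec$depth / 2)
    for (flag in c(0L, 16L)) {
      ukey <- paste(ctg, flag)
      cand <- pos0 - (5:(rl - 6L))
      cand <- cand[cand >= 0 & cand <= clen - rl]
      avail <- setdiff(cand, used[[ukey]])
      starts <- if (length(avail) >= n_half) sample(avail, n_half)
                else c(avail, sample(cand, n_half - length(avail),
                                     replace = TRUE))
      used[[ukey]] <- c(used[[ukey]], starts)
      for (s in starts) {
        k <- k + 1L
        seqv <- strsplit(ref_seq(ref, ctg, s, s + rl), "", fixed = TRUE)[[1]]
        # allele assignment per overlapping SNV site
        for (sk in unique(site_key[snvs$contig == ctg &
                                   snvs$pos - 1L >= s &
                                   snvs$pos - 1L < s + rl])) {
          alleles <- snvs[site_key == sk, , drop = FALSE]
          u <- stats::runif(1)
          acc <- 0
          for (ai in seq_len(nrow(alleles))) {
            acc <- acc + alleles$af[ai]
            if (u < acc) {
              seqv[alleles$pos[ai] - 1L - s + 1L] <- alleles$alt[ai]
              break
            }
          }
        }
        err <- stats::runif(rl) < spec$base_error_rate
        if (any(err)) {
          seqv[err] <- vapply(seqv[err],
                              function(b) sample(setdiff(BASES, b), 1),
                              character(1))
        }
        quals <- sample(30:40, rl, replace = TRUE)
        reads[[k]] <- sprintf("r%s_%05d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                              patient, k, flag, ctg, s + 1L, rl,
                              paste(seqv, collapse = ""),
                              phred_to_string(quals))
      }
    }
  }
  reads <- unlist(reads)
  n_dup <- floor(spec$dup_fraction * length(reads))
  if (n_dup > 0) {
    idx <- sample(seq_along(reads), n_dup)
    dups <- vapply(seq_along(idx), function(j) {
      sub("^([^\t]+)", sprintf("\\1_dup%03d", j), reads[idx[j]])
    }, character(1))
    reads <- c(reads, dups)
  }
  # coordinate order keeps files tidy; the pileup does not require it
  pos_of <- as.integer(vapply(strsplit(reads, "\t", fixed = TRUE), `[[`,
                              character(1), 4))
  ctg_of <- vapply(strsplit(reads, "\t", fixed = TRUE), `[[`, character(1), 3)
  c(hdr, reads[order(ctg_of, pos_of)])
}

# caller-specific equivalent spelling of a planted (canonical) variant
jitter_spelling <- function(row, caller, reference, jitter) {
  pos <- row$pos; ref <- row$ref; alt <- row$alt
  if (row$vtype == "SNV" || caller == "gatk") {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  ctg <- row$contig
  if (caller == "freebayes" && "suffix_padding" %in% jitter) {
    nb <- ref_seq(reference, ctg, pos - 1L + nchar(ref), pos + nchar(ref))
    return(list(pos = pos, ref = paste0(ref, nb), alt = paste0(alt, nb)))
  }
  if (caller == "samtools" && "right_shift_indels" %in% jitter &&
      row$zone == "tract") {
    # respell anchored inside the homopolymer tract (equivalent variant)
    shift <- 3L
    if (row$vtype == "DEL") {
      ndel <- nchar(ref) - 1L
      new_anchor0 <- (pos - 1L) + shift
      return(list(pos = new_anchor0 + 1L,
                  ref = ref_seq(reference, ctg, new_anchor0,
                                new_anchor0 + 1L + ndel),
                  alt = ref_seq(reference, ctg, new_anchor0,
                                new_anchor0 + 1L)))
    }
    ins <- substr(alt, 2L, nchar(alt))
    new_anchor0 <- (pos - 1L) + shift
    ab <- ref_seq(reference, ctg, new_anchor0, new_anchor0 + 1L)
    return(list(pos = new_anchor0 + 1L, ref = ab, alt = paste0(ab, ins)))
  }
  if (caller == "varscan") {
    pb <- ref_seq(reference, ctg, pos - 2L, pos - 1L)
    return(list(pos = pos - 1L, ref = paste0(pb, ref),
                alt = paste0(pb, alt)))
  }
  # samtools outside tracts: left-pad by two reference bases
  pb <- ref_seq(reference, ctg, pos - 3L, pos - 1L)
  list(pos = pos - 2L, ref = paste0(pb, ref), alt = paste0(pb, alt))
}

caller_vcf_lines <- function(rows, caller, sample, reference, spec) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=%s", caller),
           sprintf("##contig=<ID=%s,length=%d>", names(reference$contigs),
                   nchar(reference$contigs)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref fwd/rev, alt fwd/rev\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=.,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=RD,Number=1,Type=Integer,Description=\"Ref depth\">",
           "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Alt frequency\">",
           sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
                   sample))
  if (nrow(rows) == 0) return(hdr)
  sp <- lapply(seq_len(nrow(rows)), function(i) {
    jitter_spelling(as.list(rows[i, ]), caller, reference, spec$caller_jitter)
  })
  dp <- spec$depth
  recs <- data.frame(contig = rows$contig,
                     pos = as.integer(vapply(sp, function(x)
                       as.numeric(x$pos), numeric(1))),
                     ref = vapply(sp, `[[`, character(1), "ref"),
                     alt = vapply(sp, `[[`, character(1), "alt"),
                     ad = as.integer(round(rows$af * dp)),
                     stringsAsFactors = FALSE)
  merged <- list()
  if (caller == "gatk" && "multiallelic_merge" %in% spec$caller_jitter) {
    grp <- split(seq_len(nrow(recs)), paste(recs$contig, recs$pos, recs$ref))
  } else {
    grp <- split(seq_len(nrow(recs)), seq_len(nrow(recs)))
  }
  body <- vapply(grp, function(ix) {
    r <- recs[ix, , drop = FALSE]
    alts <- paste(r$alt, collapse = ",")
    ads <- r$ad
    rd <- max(0L, dp - sum(ads))
    line <- switch(caller,
      gatk = , freebayes = sprintf(
        "%s\t%d\t.\t%s\t%s\t100\tPASS\tDP=%d\tGT:AD:DP\t0/1:%s:%d",
        r$contig[1], r$pos[1], r$ref[1], alts, dp,
        paste(c(rd, ads), collapse = ","), dp),
      samtools = sprintf(
        "%s\t%d\t.\t%s\t%s\t100\tPASS\tDP=%d;DP4=%d,%d,%d,%d\tGT\t0/1",
        r$contig[1], r$pos[1], r$ref[1], alts, dp,
        ceiling(rd / 2), floor(rd / 2), ceiling(ads[1] / 2),
        floor(ads[1] / 2)),
      varscan = sprintf(
        "%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d\tGT:DP:RD:AD:FREQ\t0/1:%d:%d:%d:%s",
        r$contig[1], r$pos[1], r$ref[1], alts, dp, dp, rd, ads[1],
        sprintf("%.2f%%", 100 * r$ad[1] / dp))
    )
    line
  }, character(1))
  ord <- order(vapply(grp, function(ix) recs$contig[ix[1]], character(1)),
               vapply(grp, function(ix) recs$pos[ix[1]], integer(1)))
  c(hdr, unname(body[ord]))
}

#' Write caller/mapper VCF files for one patient
#'
#' One VCF per (mapper, caller) pair containing the variants the patient
#' carries that the pair supports, spelled with caller-specific jitter
#' (suffix padding, left padding, right-shifted tract indels, merged
#' multiallelics) and caller-dialect depth fields.
#'
#' @param genome result of [make_genome()].
#' @param plan result of [make_variant_plan()].
#' @param spec a [fixture_spec()].
#' @param patient patient identifier.
#' @param dir output directory for `<patient>.<mapper>.<caller>.vcf` files.
#' @return character vector of written paths.
#' @export
make_caller_vcfs <- function(genome, plan, spec, patient, dir) {
  carried <- plan[vapply(strsplit(plan$patients, ";", fixed = TRUE),
                         function(p) patient %in% p, logical(1)), ,
                  drop = FALSE]
  paths <- character(0)
  for (m in spec$mappers) {
    for (cl in spec$callers) {
      sel <- carried[
        vapply(strsplit(carried$callers, ";", fixed = TRUE),
               function(x) cl %in% x, logical(1)) &
        vapply(strsplit(carried$mappers, ";", fixed = TRUE),
               function(x) m %in% x, logical(1)), , drop = FALSE]
      path <- file.path(dir, sprintf("%s.%s.%s.vcf", patient, m, cl))
      writeLines(caller_vcf_lines(sel, cl, patient, genome$reference, spec),
                 path)
      paths <- c(paths, path)
    }
  }
  paths
}

write_fixture_tracks <- function(plan, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(id) plan_footprint(as.list(plan[plan$id == id, ]))
  # dbSnp_Id: rsID records with normalized alleles
  known <- plan[!is.na(plan$rsid), , drop = FALSE]
  dbsnp <- do.call(rbind, lapply(seq_len(nrow(known)), function(i) {
    f <- plan_footprint(as.list(known[i, ]))
    data.frame(contig = known$contig[i], start = f[1], end = f[2],
               rsid = known$rsid[i], ref = known$ref[i], alt = known$alt[i],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(dbsnp, file.path(dir, "dbSnp_Id.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (tn in names(FIXTURE_FLAG_PLAN)) {
    ids <- FIXTURE_FLAG_PLAN[[tn]]
    df <- do.call(rbind, lapply(ids, function(id) {
      f <- fp(id)
      data.frame(contig = plan$contig[plan$id == id], start = f[1],
                 end = f[2], rsid = plan$rsid[plan$id == id] %||% "",
                 ref = "", alt = "", stringsAsFactors = FALSE)
    }))
    utils::write.table(df, file.path(dir, paste0(tn, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Emit a complete fixture run directory
#'
#' Writes genome.fa, genes.refflat, ids.tsv, tracks/*.tsv, hotspots.bed,
#' reads/<patient>.sam, calls/<patient>.<mapper>.<caller>.vcf, manifest.tsv
#' and options.txt under `dir`. The same spec yields byte-identical files.
#'
#' @param dir target directory (created).
#' @param spec a [fixture_spec()].
#' @return list with `dir`, `spec`, `genome`, `plan`, `options_file`,
#'   `manifest_file`, and `truth` (expected per-patient variant keys and
#'   caller Venn structure computed from the plan).
#' @export
make_fixture_run <- function(dir, spec = fixture_spec()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(spec)
  plan <- make_variant_plan(genome, spec)
  write_reference(genome$reference, file.path(dir, "genome.fa"))
  utils::write.table(genome$refflat, file.path(dir, "genes.refflat"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(genome$ids, file.path(dir, "ids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fixture_tracks(plan, file.path(dir, "tracks"))
  hot <- plan[plan$hotspot, , drop = FALSE]
  hot_lines <- vapply(seq_len(nrow(hot)), function(i) {
    f <- plan_footprint(as.list(hot[i, ]))
    sprintf("%s\t%d\t%d\tHS_%s", hot$contig[i], f[1], f[2], hot$id[i])
  }, character(1))
  writeLines(c(hot_lines, "ctg1\t8000\t8010\tHS_decoy"),
             file.path(dir, "hotspots.bed"))
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(seq_along(spec$patients), function(i) {
    p <- spec$patients[i]
    sam <- file.path(dir, "reads", paste0(p, ".sam"))
    writeLines(make_reads(genome, plan, spec, p), sam)
    vcfs <- make_caller_vcfs(genome, plan, spec, p, file.path(dir, "calls"))
    data.frame(Patient_Id = p, Family_Id = "F01",
               Lab_Analysis_Date = "2015-06-01_12-00-00",
               Seq_Platform = "Illumina", Seq_System = "HiSeq2000",
               Assay_Id = "SIM_Panel1",
               Fastq = file.path(dir, "reads", paste0(p, ".fq")),
               Sam = sam, Vcfs = paste(vcfs, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  manifest_file <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  opts <- default_options()
  opts$reference <- file.path(dir, "genome.fa")
  opts$genes <- file.path(dir, "genes.refflat")
  opts$ids <- file.path(dir, "ids.tsv")
  opts$tracks_dir <- file.path(dir, "tracks")
  opts$hotspots <- file.path(dir, "hotspots.bed")
  opts$output_dir <- file.path(dir, "out")
  opts$assembly <- "SIM1"
  options_file <- file.path(dir, "options.txt")
  write_options(opts, options_file)
  truth <- fixture_truth(genome, plan, spec)
  list(dir = dir, spec = spec, genome = genome, plan = plan,
       options_file = options_file, manifest_file = manifest_file,
       truth = truth)
}

# expected per-patient variant keys and caller Venn cells, from the plan alone
fixture_truth <- function(genome, plan, spec) {
  per_patient <- lapply(spec$patients, function(p) {
    carried <- plan[vapply(strsplit(plan$patients, ";", fixed = TRUE),
                           function(x) p %in% x, logical(1)), , drop = FALSE]
    keys <- vapply(seq_len(nrow(carried)), function(i) {
      nv <- structure(list(contig = carried$contig[i],
                           start = carried$pos[i] - 1L,
                           ref = carried$ref[i], alt = carried$alt[i],
                           vtype = carried$vtype[i]),
                      class = "normalized_variant")
      variant_key(nv, "SIM1")
    }, character(1))
    caller_sets <- strsplit(carried$callers, ";", fixed = TRUE)
    vclass <- ifelse(carried$vtype == "SNV", "SNV", "INDEL")
    cells <- table(vclass,
                   vapply(lapply(caller_sets, function(x)
                     CALLER_LEVELS[CALLER_LEVELS %in% x]),
                     paste, character(1), collapse = "+"))
    ge2 <- lengths(caller_sets) >= 2
    list(ids = carried$id, keys = keys, cells = cells,
         ge2_fraction = c(SNV = mean(ge2[vclass == "SNV"]),
                          INDEL = mean(ge2[vclass == "INDEL"]),
                          all = mean(ge2)))
  })
  names(per_patient) <- spec$patients
  per_patient
}
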