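# Feature assignment and codon / amino-acid / frameshift consequence
# prediction from gene models and the reference sequence.

# 3-letter amino-acid names from the standard nuclear code; stop is "Ter",
# unknown "Xaa" (codons containing N or other non-ACGT characters).
aa3_table <- local({
  gc1 <- Biostrings::GENETIC_CODE
  aa3 <- Biostrings::AMINO_ACID_CODE[gc1]
  aa3[gc1 == "*"] <- "Ter"
  names(aa3) <- names(gc1)
  aa3
})

#' Translate a codon to its 3-letter amino-acid name
#'
#' Standard nuclear genetic code; stop codons report `"Ter"`, codons with
#' ambiguous bases report `"Xaa"`.
#'
#' @param codon character vector of 3-mers.
#' @return character vector of 3-letter names.
#' @examples
#' translate_codon(c("AAA", "TAA", "ANA"))  # "Lys" "Ter" "Xaa"
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3)) stop("codons must have length 3", call. = FALSE)
  out <- unname(aa3_table[codon])
  out[is.na(out)] <- "Xaa"
  out
}

# exon ordinal in transcript orientation (1 = transcript 5' end)
tx_exon_ordinal <- function(model, genomic_index) {
  n <- length(model$exon_starts)
  if (model$strand == "+") genomic_index else n - genomic_index + 1L
}

# exonic CDS segments in genomic order: matrix with columns start, end
cds_segments <- function(model) {
  s <- pmax(model$exon_starts, model$cds_start)
  e <- pmin(model$exon_ends, model$cds_end)
  keep <- s < e
  cbind(start = s[keep], end = e[keep])
}

cds_length <- function(model) {
  seg <- cds_segments(model)
  if (nrow(seg) == 0) 0L else sum(seg[, "end"] - seg[, "start"])
}

#' Assign a variant to genomic features
#'
#' One assignment per transcript overlapping the variant footprint; a variant
#' overlapping no transcript is intergenic. Exon/CDS/intron ordinals count
#' from the transcript 5' end (minus-strand models included); labels follow
#' the `"exon_2;CDS_2"` style.
#'
#' @param nv a `normalized_variant`.
#' @param gene_models a `gene_model_set`.
#' @return data.frame with columns gene_symbol, refseq_mrna, strand,
#'   region_class (CDS, UTR5, UTR3, intron, noncoding_exon, intergenic) and
#'   feature_label. Every variant receives at least one row.
#' @export
assign_features <- function(nv, gene_models) {
  fp <- variant_footprint(nv)
  models <- genes_overlapping(gene_models, nv$contig, fp[1], fp[2])
  if (length(models) == 0) {
    return(data.frame(gene_symbol = NA_character_, refseq_mrna = NA_character_,
                      strand = NA_character_, region_class = "intergenic",
                      feature_label = "intergenic", stringsAsFactors = FALSE))
  }
  p <- if (nv$vtype == "DEL") nv$start + 1L else nv$start
  rows <- lapply(models, function(m) {
    n <- length(m$exon_starts)
    gi <- which(m$exon_starts <= p & p < m$exon_ends)
    if (length(gi) == 0) {
      # intron index: between genomic exons k and k+1; transcript-oriented
      k <- sum(m$exon_ends <= p)
      ord <- if (m$strand == "+") k else n - k
      cls <- "intron"; lab <- sprintf("intron_%d", ord)
    } else {
      e_ord <- tx_exon_ordinal(m, gi)
      if (!is_coding(m)) {
        cls <- "noncoding_exon"; lab <- sprintf("exon_%d", e_ord)
      } else if (p >= m$cds_start && p < m$cds_end) {
        seg <- cds_segments(m)
        j <- which(seg[, "start"] <= p & p < seg[, "end"])
        c_ord <- if (m$strand == "+") j else nrow(seg) - j + 1L
        cls <- "CDS"; lab <- sprintf("exon_%d;CDS_%d", e_ord, c_ord)
      } else {
        upstream <- p < m$cds_start
        cls <- if (upstream == (m$strand == "+")) "UTR5" else "UTR3"
        lab <- sprintf("exon_%d", e_ord)
      }
    }
    data.frame(gene_symbol = m$gene_symbol, refseq_mrna = m$refseq_mrna,
               strand = m$strand, region_class = cls, feature_label = lab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spliced coding sequence of a transcript
#'
#' Exonic CDS segments concatenated in transcript order (reverse-complemented
#' for minus-strand models). A CDS length that is not a multiple of 3
#' propagates a warning flag rather than failing.
#'
#' @param model a `gene_model` (coding).
#' @param reference a `ref_genome`.
#' @return list with `seq` (coding-oriented CDS string) and `frame_warning`.
#' @export
coding_sequence <- function(model, reference) {
  if (!is_coding(model)) stop("transcript has no CDS", call. = FALSE)
  seg <- cds_segments(model)
  parts <- vapply(seq_len(nrow(seg)), function(i) {
    ref_seq(reference, model$contig, seg[i, "start"], seg[i, "end"])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  warn <- nchar(s) %% 3L != 0L
  if (warn) {
    warning(sprintf("transcript %s: CDS length %d not a multiple of 3",
                    model$refseq_mrna, nchar(s)), call. = FALSE)
  }
  list(seq = s, frame_warning = warn)
}

# 0-based offset of genomic position gpos within the coding-oriented CDS
cds_offset <- function(model, gpos) {
  seg <- cds_segments(model)
  widths <- seg[, "end"] - seg[, "start"]
  cum <- cumsum(c(0L, widths))
  i <- which(seg[, "start"] <= gpos & gpos < seg[, "end"])
  if (length(i) == 0) return(NA_integer_)
  off <- unname(cum[i] + (gpos - seg[i, "start"]))
  if (model$strand == "+") off else sum(widths) - 1L - off
}

#' Predict the codon and amino-acid change of a coding SNV
#'
#' The variant base's CDS offset is computed in coding orientation (the alt
#' base is complemented for minus-strand transcripts); the reference allele
#' is replaced with the variant allele inside its codon and both codons are
#' translated with the standard code.
#'
#' @param nv a `normalized_variant` of type SNV inside the transcript's CDS.
#' @param model a coding `gene_model`.
#' @param reference a `ref_genome`.
#' @return list with `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `codon_number` (1-based) and `position_in_codon` (1-3).
#' @export
predict_codon_change <- function(nv, model, reference) {
  if (nv$vtype != "SNV") stop("codon change is defined for SNVs", call. = FALSE)
  off <- cds_offset(model, nv$start)
  if (is.na(off)) {
    stop(sprintf("variant %s:%d not in the CDS of %s",
                 nv$contig, nv$start, model$refseq_mrna), call. = FALSE)
  }
  cds <- coding_sequence(model, reference)$seq
  codon_number <- off %/% 3L + 1L
  pic <- off %% 3L + 1L
  ref_codon <- substr(cds, (codon_number - 1L) * 3L + 1L, codon_number * 3L)
  alt_base <- if (model$strand == "-") complement_base(nv$alt) else nv$alt
  if (substr(ref_codon, pic, pic) == alt_base) {
    stop("alt base equals the coding-strand reference base", call. = FALSE)
  }
  alt_codon <- ref_codon
  substr(alt_codon, pic, pic) <- alt_base
  list(ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = translate_codon(ref_codon), alt_aa = translate_codon(alt_codon),
       codon_number = codon_number, position_in_codon = pic)
}

#' Frameshift consequence of a coding indel
#'
#' The inserted or deleted bases falling within the (exonic) CDS are counted;
#' the indel is a frameshift iff that count is not a multiple of 3. The
#' original and new reading frames (CDS length mod 3 before and after
#' incorporating the indel) are reported.
#'
#' @param nv a `normalized_variant` of type INS or DEL.
#' @param model a coding `gene_model`.
#' @return list with `is_frameshift`, `indel_len_in_cds`, `original_frame`,
#'   `new_frame`.
#' @export
predict_frameshift <- function(nv, model) {
  if (!nv$vtype %in% c("INS", "DEL")) {
    stop("frameshift prediction is defined for indels", call. = FALSE)
  }
  seg <- cds_segments(model)
  if (nrow(seg) == 0) stop("transcript has no CDS", call. = FALSE)
  if (nv$vtype == "DEL") {
    del_s <- nv$start + 1L
    del_e <- nv$start + nchar(nv$ref)        # half-open [del_s, del_e)
    len_in <- sum(pmax(0L, pmin(seg[, "end"], del_e) -
                             pmax(seg[, "start"], del_s)))
    delta <- -len_in
  } else {
    n_ins <- nchar(nv$alt) - 1L
    inside <- any(seg[, "start"] <= nv$start & nv$start + 1L < seg[, "end"])
    len_in <- if (inside) n_ins else 0L
    delta <- len_in
  }
  if (len_in == 0L) {
    stop("indel lies entirely outside the CDS", call. = FALSE)
  }
  clen <- cds_length(model)
  list(is_frameshift = len_in %% 3L != 0L,
       indel_len_in_cds = len_in,
       original_frame = clen %% 3L,
       new_frame = (clen + delta) %% 3L)
}
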