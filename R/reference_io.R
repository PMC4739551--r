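# Reference genome, gene models, membership tracks, hotspots, run manifest.
#
# Internal coordinates are 0-based half-open everywhere in this package.
# VCF positions (1-based) and refFlat/BED (already 0-based) are converted
# at the I/O boundary.

#' Load a reference genome from FASTA
#'
#' Reads a (possibly line-wrapped) multi-record FASTA. Contigs are keyed by
#' the first whitespace-delimited header token; lowercase (masked) bases are
#' uppercased and IUPAC ambiguity codes other than N are collapsed to N, so
#' sequences contain only A, C, G, T, N.
#'
#' @param file path to a FASTA file with at least one record.
#' @param assembly assembly label used when minting variant identifiers
#'   (e.g. `"GRCh37"`).
#' @return an object of class `ref_genome`: a list with `contigs` (named
#'   character vector of uppercase sequences) and `assembly`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT test", "ACGTACGT"), fa)
#' ref <- load_reference(fa, assembly = "TEST1")
#' ref_seq(ref, "chrT", 2, 5)  # "GTA"
#' @export
load_reference <- function(file, assembly = "GRCh37") {
  seqs <- Biostrings::readDNAStringSet(file)
  if (length(seqs) == 0) stop("no FASTA records in ", file, call. = FALSE)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name in FASTA: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  s <- toupper(as.character(seqs))
  if (any(grepl("[^ACGTNRYSWKMBDHV]", s))) {
    stop("non-IUPAC character in reference sequence", call. = FALSE)
  }
  s <- gsub("[RYSWKMBDHV]", "N", s)
  names(s) <- nm
  structure(list(contigs = s, assembly = assembly), class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s: %d contig(s), %s bp total\n",
              x$assembly, length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Write a reference genome to FASTA
#'
#' @param ref a `ref_genome`.
#' @param file output path.
#' @param width line wrap width.
#' @return `file`, invisibly.
#' @export
write_reference <- function(ref, file, width = 70) {
  dna <- Biostrings::DNAStringSet(ref$contigs)
  Biostrings::writeXStringSet(dna, file, width = width)
  invisible(file)
}

#' Extract a reference subsequence (0-based half-open)
#'
#' @param ref a `ref_genome`.
#' @param contig contig name.
#' @param start,end 0-based half-open bounds; queries outside the contig fail.
#' @return character string of length `end - start`.
#' @export
ref_seq <- function(ref, contig, start, end) {
  if (!contig %in% names(ref$contigs)) {
    stop("unknown contig: ", contig, call. = FALSE)
  }
  seq <- ref$contigs[[contig]]
  n <- nchar(seq)
  if (start < 0 || end > n || start > end) {
    stop(sprintf("query [%d,%d) out of range for contig %s (length %d)",
                 start, end, contig, n), call. = FALSE)
  }
  substr(seq, start + 1, end)
}

contig_length <- function(ref, contig) {
  if (!contig %in% names(ref$contigs)) {
    stop("unknown contig: ", contig, call. = FALSE)
  }
  nchar(ref$contigs[[contig]])
}

# ---------------------------------------------------------------------------
# Gene models (refFlat dialect + identifier side-table)

parse_comma_list <- function(x) {
  # UCSC refFlat convention: comma-separated with tolerated trailing comma
  as.integer(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1]])
}

#' Load gene models from a refFlat table plus an identifier side-table
#'
#' The refFlat dialect carries, per transcript: geneName, transcript name,
#' chrom, strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds (coordinates 0-based half-open; exon lists comma-separated with
#' a tolerated trailing comma). The optional side-table maps transcript to
#' external identifiers (entrez, protein, uniprot, kegg, omim, hgnc) used by
#' the cross-reference link builders.
#'
#' Minus-strand models retain genomic-sorted exons; transcript-orientation
#' ordinals are computed downstream. A coding transcript whose CDS length is
#' not a multiple of 3 is loaded with `frame_warning = TRUE` (and a warning),
#' not rejected.
#'
#' @param refflat_file path to the refFlat-dialect table (headerless, or with
#'   a header line starting with `geneName` or `#`).
#' @param ids_file optional path to a tab-separated identifier side-table with
#'   header columns `transcript`, `entrez`, `protein`, `uniprot`, `kegg`,
#'   `omim`, `hgnc`.
#' @return an object of class `gene_model_set`.
#' @export
load_gene_models <- function(refflat_file, ids_file = NULL) {
  lines <- readLines(refflat_file)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(#|geneName\\t)", lines)]
  if (length(lines) == 0) stop("no gene models in ", refflat_file, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 11)) {
    stop("refFlat rows need 11 tab-separated columns", call. = FALSE)
  }
  ids <- NULL
  if (!is.null(ids_file)) {
    ids <- utils::read.delim(ids_file, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!"transcript" %in% names(ids)) {
      stop("identifier side-table needs a 'transcript' column", call. = FALSE)
    }
  }
  id_of <- function(tx, key) {
    if (is.null(ids) || !key %in% names(ids)) return(NA_character_)
    v <- ids[[key]][match(tx, ids$transcript)]
    if (length(v) == 0 || is.na(v) || !nzchar(v)) NA_character_ else v
  }
  models <- lapply(fields, function(f) {
    exon_starts <- parse_comma_list(f[10])
    exon_ends <- parse_comma_list(f[11])
    n_exons <- as.integer(f[9])
    if (length(exon_starts) != n_exons || length(exon_ends) != n_exons) {
      stop(sprintf("transcript %s: exonCount %d does not match exon lists",
                   f[2], n_exons), call. = FALSE)
    }
    if (is.unsorted(exon_starts) || any(exon_ends[-n_exons] > exon_starts[-1])) {
      stop(sprintf("transcript %s: exons not sorted/non-overlapping", f[2]),
           call. = FALSE)
    }
    m <- list(
      gene_symbol = f[1], refseq_mrna = f[2], contig = f[3], strand = f[4],
      tx_start = as.integer(f[5]), tx_end = as.integer(f[6]),
      cds_start = as.integer(f[7]), cds_end = as.integer(f[8]),
      exon_starts = exon_starts, exon_ends = exon_ends,
      entrez_id = id_of(f[2], "entrez"),
      refseq_protein = id_of(f[2], "protein"),
      uniprot_id = id_of(f[2], "uniprot"),
      kegg_id = id_of(f[2], "kegg"),
      omim_id = id_of(f[2], "omim"),
      hgnc_id = id_of(f[2], "hgnc"),
      frame_warning = FALSE
    )
    if (m$cds_start < m$tx_start || m$cds_end > m$tx_end ||
        m$cds_start > m$cds_end) {
      stop(sprintf("transcript %s: CDS outside transcript bounds", f[2]),
           call. = FALSE)
    }
    if (is_coding(m)) {
      len <- sum(pmax(0L, pmin(exon_ends, m$cds_end) -
                            pmax(exon_starts, m$cds_start)))
      if (len %% 3L != 0L) {
        warning(sprintf("transcript %s: CDS length %d not a multiple of 3",
                        f[2], len), call. = FALSE)
        m$frame_warning <- TRUE
      }
    }
    class(m) <- "gene_model"
    m
  })
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(models, `[[`, character(1), "contig"),
    ranges = IRanges::IRanges(
      start = vapply(models, `[[`, integer(1), "tx_start") + 1L,
      end = vapply(models, `[[`, integer(1), "tx_end")
    )
  )
  structure(list(models = models, gr = gr), class = "gene_model_set")
}

is_coding <- function(model) model$cds_start < model$cds_end

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d transcript(s)\n", length(x$models)))
  invisible(x)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d (%s), %d exon(s)\n",
              x$gene_symbol, x$refseq_mrna, x$contig, x$tx_start, x$tx_end,
              x$strand, length(x$exon_starts)))
  invisible(x)
}

#' Transcripts overlapping an interval
#'
#' @param gene_models a `gene_model_set`.
#' @param contig contig name.
#' @param start,end 0-based half-open query interval.
#' @return list of `gene_model` objects in genomic order (possibly empty).
#' @export
genes_overlapping <- function(gene_models, contig, start, end) {
  if (length(gene_models$models) == 0) return(list())
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, gene_models$gr))
  idx <- sort(S4Vectors::subjectHits(hits))
  gene_models$models[idx]
}

# ---------------------------------------------------------------------------
# Generic interval tracks: dbSNP-style membership tracks and hotspot BED

new_interval_track <- function(name, records) {
  stopifnot(all(c("contig", "start", "end") %in% names(records)))
  records <- records[order(records$contig, records$start, records$end), ,
                     drop = FALSE]
  rownames(records) <- NULL
  gr <- GenomicRanges::GRanges(
    records$contig, IRanges::IRanges(records$start + 1L, records$end))
  structure(list(name = name, records = records, gr = gr),
            class = "interval_track")
}

#' @export
print.interval_track <- function(x, ...) {
  cat(sprintf("<interval_track> %s: %d record(s)\n", x$name, nrow(x$records)))
  invisible(x)
}

#' Load a membership track (dbSNP-style TSV)
#'
#' Tab-separated with header columns `contig`, `start`, `end` (0-based
#' half-open) and optional `rsid`, `ref`, `alt`.
#'
#' @param file path to the TSV.
#' @param name track name (e.g. `"dbSnp_Common"`).
#' @return an `interval_track`.
#' @export
load_membership_track <- function(file, name) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  for (col in c("rsid", "ref", "alt")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  new_interval_track(name, df)
}

#' Load hotspot mutations from BED
#'
#' BED3+name: contig, start, end (0-based half-open), hotspot name.
#' An empty file yields a valid empty set.
#'
#' @param file path to the BED file.
#' @return an `interval_track` whose records carry a `name` column.
#' @export
load_hotspots <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0) {
    rec <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE)
    return(new_interval_track("hotspots", rec))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4)) stop("hotspot BED needs 4 columns", call. = FALSE)
  rec <- data.frame(
    contig = vapply(f, `[[`, character(1), 1),
    start = as.integer(vapply(f, `[[`, character(1), 2)),
    end = as.integer(vapply(f, `[[`, character(1), 3)),
    name = vapply(f, `[[`, character(1), 4),
    stringsAsFactors = FALSE
  )
  new_interval_track("hotspots", rec)
}

#' Records of a track overlapping an interval
#'
#' Returns all and only the records with a nonempty intersection with the
#' 0-based half-open query, in genomic order. An unknown contig yields an
#' empty result rather than an error.
#'
#' @param track an `interval_track`.
#' @param contig contig name.
#' @param start,end 0-based half-open query interval.
#' @return data.frame of matching records.
#' @export
query_overlaps <- function(track, contig, start, end) {
  empty <- track$records[0, , drop = FALSE]
  if (nrow(track$records) == 0) return(empty)
  if (!contig %in% as.character(GenomicRanges::seqnames(track$gr))) {
    return(empty)
  }
  q <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, track$gr))
  idx <- sort(S4Vectors::subjectHits(hits))
  out <- track$records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Run manifest

#' Load the per-patient run manifest
#'
#' Tab-separated, one row per patient, with header columns `Patient_Id`,
#' `Family_Id`, `Lab_Analysis_Date`, `Seq_Platform`, `Seq_System`, `Assay_Id`,
#' `Fastq`, `Sam`, `Vcfs` (semicolon-joined VCF paths named
#' `<patient>.<mapper>.<caller>.vcf`).
#'
#' @param file path to the manifest TSV.
#' @return data.frame with one row per patient.
#' @export
load_manifest <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("Patient_Id", "Family_Id", "Lab_Analysis_Date", "Seq_Platform",
            "Seq_System", "Assay_Id", "Fastq", "Sam", "Vcfs")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$Patient_Id)) {
    stop("duplicate Patient_Id in manifest", call. = FALSE)
  }
  df
}
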