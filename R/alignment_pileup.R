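# SAM-text alignment parsing, post-mapping read filters, and per-position
# base/quality pileups with raw and quality-filtered counts.

FLAG_PAIRED <- 0x1L
FLAG_PROPER_PAIR <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_DUP <- 0x400L

has_flag <- function(flag, bit) bitwAnd(flag, bit) != 0L

CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

# parse a CIGAR string into a two-column structure: lengths and ops
cigar_ops <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

cigar_query_len <- function(ops) sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
cigar_ref_len <- function(ops) sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])

#' Parse SAM-format text alignments
#'
#' Header lines (starting `@`) are skipped; unmapped records (flag 0x4 or
#' CIGAR `*`) are skipped and counted. SAM POS (1-based) is converted to the
#' package's 0-based convention.
#'
#' @param file path to a SAM text file.
#' @return list with `reads` (data.frame: qname, flag, contig, pos0, mapq,
#'   cigar, rnext, pnext0, seq, qual) and `skipped_unmapped` (count).
#' @export
parse_sam <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0) {
    reads <- data.frame(qname = character(0), flag = integer(0),
                        contig = character(0), pos0 = integer(0),
                        mapq = integer(0), cigar = character(0),
                        rnext = character(0), pnext0 = integer(0),
                        seq = character(0), qual = character(0),
                        stringsAsFactors = FALSE)
    return(list(reads = reads, skipped_unmapped = 0L))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11)) {
    stop("SAM alignment lines need at least 11 fields", call. = FALSE)
  }
  get <- function(i) vapply(f, `[[`, character(1), i)
  reads <- data.frame(
    qname = get(1), flag = as.integer(get(2)), contig = get(3),
    pos0 = as.integer(get(4)) - 1L, mapq = as.integer(get(5)),
    cigar = get(6), rnext = get(7), pnext0 = as.integer(get(8)) - 1L,
    seq = get(10), qual = get(11), stringsAsFactors = FALSE
  )
  unmapped <- has_flag(reads$flag, FLAG_UNMAPPED) | reads$cigar == "*"
  skipped <- sum(unmapped)
  reads <- reads[!unmapped, , drop = FALSE]
  if (nrow(reads) > 0) {
    bad <- !grepl(CIGAR_RE, reads$cigar)
    if (any(bad)) {
      stop("malformed CIGAR: ", reads$cigar[which(bad)[1]], call. = FALSE)
    }
    for (i in seq_len(nrow(reads))) {
      if (reads$seq[i] == "*") next
      ops <- cigar_ops(reads$cigar[i])
      if (cigar_query_len(ops) != nchar(reads$seq[i])) {
        stop(sprintf("read %s: CIGAR query length %d != sequence length %d",
                     reads$qname[i], cigar_query_len(ops),
                     nchar(reads$seq[i])), call. = FALSE)
      }
      if (reads$qual[i] != "*" && nchar(reads$qual[i]) != nchar(reads$seq[i])) {
        stop(sprintf("read %s: qual/seq length mismatch", reads$qname[i]),
             call. = FALSE)
      }
    }
  }
  rownames(reads) <- NULL
  list(reads = reads, skipped_unmapped = skipped)
}

# 5' start corrected for soft/hard clipping; for reverse-strand reads the 5'
# end is the rightmost aligned base plus trailing clips.
unclipped_start <- function(pos0, cigar, reverse) {
  ops <- cigar_ops(cigar)
  n <- length(ops$op)
  lead <- 0L
  for (i in seq_len(n)) {
    if (ops$op[i] %in% c("S", "H")) lead <- lead + ops$len[i] else break
  }
  trail <- 0L
  for (i in rev(seq_len(n))) {
    if (ops$op[i] %in% c("S", "H")) trail <- trail + ops$len[i] else break
  }
  if (reverse) pos0 + cigar_ref_len(ops) - 1L + trail else pos0 - lead
}

#' Mark PCR duplicates
#'
#' Reads sharing (contig, unclipped 5' start, strand, and mate 5' start when
#' paired) form a duplicate group; the member with the highest base-quality
#' sum is kept unflagged, ties broken by lexicographic qname. Marking is
#' idempotent: existing duplicate flags are recomputed from scratch.
#'
#' @param reads data.frame as returned by [parse_sam()].
#' @return the same data.frame with the 0x400 flag bit set on duplicates.
#' @export
mark_duplicates <- function(reads) {
  if (nrow(reads) == 0) return(reads)
  reads$flag <- bitwAnd(reads$flag, bitwNot(FLAG_DUP))  # reset, then recompute
  rev_strand <- has_flag(reads$flag, FLAG_REVERSE)
  u5 <- mapply(unclipped_start, reads$pos0, reads$cigar, rev_strand)
  paired <- has_flag(reads$flag, FLAG_PAIRED)
  mate <- ifelse(paired, reads$pnext0, -1L)
  key <- paste(reads$contig, u5, rev_strand, mate, sep = "\r")
  qsum <- vapply(reads$qual, function(q) sum(phred_from_string(q)), numeric(1),
                 USE.NAMES = FALSE)
  for (g in split(seq_len(nrow(reads)), key)) {
    if (length(g) < 2) next
    keep <- g[order(-qsum[g], reads$qname[g])][1]
    dup <- setdiff(g, keep)
    reads$flag[dup] <- bitwOr(reads$flag[dup], FLAG_DUP)
  }
  reads
}

#' Read-level filter policy
#'
#' Post-mapping filters: minimum mapping quality, proper-pair requirement
#' (applied only to reads with the paired flag set), and PCR-duplicate
#' removal.
#'
#' @param min_mapq minimum mapping quality (reads below are dropped).
#' @param require_proper_pair drop paired reads lacking the proper-pair flag.
#' @param drop_duplicates drop reads carrying the duplicate flag.
#' @return an object of class `read_filter_policy`.
#' @export
read_filter_policy <- function(min_mapq = 20L, require_proper_pair = TRUE,
                               drop_duplicates = TRUE) {
  stopifnot(min_mapq >= 0)
  structure(list(min_mapq = as.integer(min_mapq),
                 require_proper_pair = isTRUE(require_proper_pair),
                 drop_duplicates = isTRUE(drop_duplicates)),
            class = "read_filter_policy")
}

apply_read_policy <- function(reads, policy) {
  keep <- reads$mapq >= policy$min_mapq
  if (policy$require_proper_pair) {
    paired <- has_flag(reads$flag, FLAG_PAIRED)
    keep <- keep & (!paired | has_flag(reads$flag, FLAG_PROPER_PAIR))
  }
  if (policy$drop_duplicates) {
    keep <- keep & !has_flag(reads$flag, FLAG_DUP)
  }
  keep
}

# Expand one read into (refpos, base, qual) deposits via a CIGAR walk:
# M/=/X advance both and deposit; I consumes query only; D/N consume
# reference only; S consumes query only; H consumes nothing.
expand_read <- function(pos0, cigar, seq, qual) {
  ops <- cigar_ops(cigar)
  quals <- phred_from_string(qual)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(quals) == 0) quals <- rep(NA_integer_, length(bases))
  refpos <- integer(0); qidx <- integer(0)
  rp <- pos0; qp <- 0L
  for (i in seq_along(ops$op)) {
    len <- ops$len[i]
    switch(ops$op[i],
      M = , `=` = , X = {
        refpos <- c(refpos, rp + 0:(len - 1L))
        qidx <- c(qidx, qp + 1:len)
        rp <- rp + len; qp <- qp + len
      },
      I = , S = { qp <- qp + len },
      D = , N = { rp <- rp + len },
      H = NULL, P = NULL
    )
  }
  list(refpos = refpos, base = bases[qidx], qual = quals[qidx])
}

#' Build a per-position pileup over a region
#'
#' Applies the read filter policy first, then walks each read's CIGAR and
#' deposits aligned bases and qualities. `raw` counts come from all
#' policy-passing reads; `filtered` counts additionally require base quality
#' >= `min_base_qual`. Deletions contribute no base to the columns they span.
#'
#' @param reads data.frame as returned by [parse_sam()] (after
#'   [mark_duplicates()] if duplicate removal is wanted).
#' @param contig contig name.
#' @param start,end 0-based half-open region.
#' @param policy a [read_filter_policy()].
#' @param min_base_qual PHRED threshold for the filtered counts.
#' @param reference optional `ref_genome`; when given, the region is checked
#'   against the contig bounds.
#' @return an object of class `pileup`: list with `contig`, `start`, `end`,
#'   4 x L matrices `raw` and `filtered` (rows A,C,G,T), and `quals`, a list
#'   of per-column PHRED integer vectors from policy-passing reads.
#' @export
build_pileup <- function(reads, contig, start, end,
                         policy = read_filter_policy(),
                         min_base_qual = 20L, reference = NULL) {
  if (!is.null(reference)) {
    n <- contig_length(reference, contig)
    if (start < 0 || end > n) {
      stop(sprintf("region [%d,%d) outside contig %s (length %d)",
                   start, end, contig, n), call. = FALSE)
    }
  }
  if (start < 0 || end < start) stop("invalid region", call. = FALSE)
  L <- end - start
  raw <- matrix(0L, 4, L, dimnames = list(BASES, NULL))
  filt <- raw
  quals <- vector("list", L)
  for (i in seq_len(L)) quals[[i]] <- integer(0)
  keep <- reads$contig == contig & apply_read_policy(reads, policy)
  rows <- which(keep)
  if (length(rows) > 0 && L > 0) {
    allpos <- integer(0); allbase <- character(0); allqual <- integer(0)
    for (i in rows) {
      ex <- expand_read(reads$pos0[i], reads$cigar[i], reads$seq[i],
                        reads$qual[i])
      inreg <- ex$refpos >= start & ex$refpos < end
      allpos <- c(allpos, ex$refpos[inreg])
      allbase <- c(allbase, ex$base[inreg])
      allqual <- c(allqual, ex$qual[inreg])
    }
    col <- allpos - start + 1L
    bidx <- match(allbase, BASES)  # N and other codes count nowhere
    ok <- !is.na(bidx)
    if (any(ok)) {
      raw[] <- tabulate(bidx[ok] + 4L * (col[ok] - 1L), nbins = 4L * L)
      fok <- ok & !is.na(allqual) & allqual >= min_base_qual
      filt[] <- tabulate(bidx[fok] + 4L * (col[fok] - 1L), nbins = 4L * L)
    }
    qsplit <- split(allqual, factor(col, levels = seq_len(L)))
    quals <- lapply(qsplit, function(q) q[!is.na(q)])
  }
  structure(list(contig = contig, start = start, end = end,
                 raw = raw, filtered = filt, quals = quals,
                 min_base_qual = as.integer(min_base_qual)),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s:[%d,%d) (%d columns, min_base_qual=%d)\n",
              x$contig, x$start, x$end, x$end - x$start, x$min_base_qual))
  invisible(x)
}

#' Extract one pileup column
#'
#' @param pileup a `pileup`.
#' @param pos 0-based position inside the pileup region.
#' @return list with `contig`, `pos`, `raw_counts`, `filtered_counts` (named
#'   A/C/G/T integer vectors), `base_quals`, `total_raw`, `total_filtered`.
#' @export
pileup_column <- function(pileup, pos) {
  if (pos < pileup$start || pos >= pileup$end) {
    stop(sprintf("position %d outside pileup region [%d,%d)",
                 pos, pileup$start, pileup$end), call. = FALSE)
  }
  i <- pos - pileup$start + 1L
  raw <- pileup$raw[, i]
  filt <- pileup$filtered[, i]
  list(contig = pileup$contig, pos = pos,
       raw_counts = raw, filtered_counts = filt,
       base_quals = pileup$quals[[i]],
       total_raw = sum(raw), total_filtered = sum(filt))
}

#' Export a pileup as TSV (debugging aid)
#'
#' Columns: contig, pos1 (1-based), A, C, G, T raw counts, then A_f..T_f
#' quality-filtered counts.
#'
#' @param pileup a `pileup`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, file) {
  L <- pileup$end - pileup$start
  df <- data.frame(contig = pileup$contig,
                   pos1 = pileup$start + seq_len(L),
                   t(pileup$raw), t(pileup$filtered))
  names(df) <- c("contig", "pos1", BASES, paste0(BASES, "_f"))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
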