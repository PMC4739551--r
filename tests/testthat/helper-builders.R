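# Shared fixture builders. Everything is generated in code at test time.

tmp_ref <- function(seqs, assembly = "T1") {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), fa)
  load_reference(fa, assembly)
}

# independent reverse complement for oracle-side arithmetic
rc <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

qstr <- function(q) intToUtf8(q + 33L)

sam_line <- function(qname, flag, contig, pos1, mapq, cigar, seq, qual,
                     rnext = "*", pnext = 0) {
  paste(qname, flag, contig, pos1, mapq, cigar, rnext, pnext, 0, seq, qual,
        sep = "\t")
}

sam_file <- function(lines, contigs = c(chrT = 2000L)) {
  f <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
               lines), f)
  f
}

make_gene_set <- function(symbol = "G1", tx = "NM_000001", contig = "chrT",
                          strand = "+", tx_start, tx_end, cds_start, cds_end,
                          exon_starts, exon_ends, ids = NULL) {
  rf <- tempfile()
  writeLines(paste(symbol, tx, contig, strand, tx_start, tx_end, cds_start,
                   cds_end, length(exon_starts),
                   paste0(paste(exon_starts, collapse = ","), ","),
                   paste0(paste(exon_ends, collapse = ","), ","),
                   sep = "\t"), rf)
  idf <- NULL
  if (!is.null(ids)) {
    idf <- tempfile()
    ids$transcript <- tx
    write.table(as.data.frame(ids, stringsAsFactors = FALSE), idf,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  suppressWarnings(load_gene_models(rf, idf))
}

# a two-exon gene with the given coding sequence embedded in a synthetic
# contig; returns reference, gene set and the layout needed for oracles
build_two_exon_gene <- function(coding, strand = "+", utr5 = 6L, utr3 = 6L,
                                intron = 9L, cds1 = NULL, offset = 20L,
                                seed = 42L, contig = "chrT") {
  n <- nchar(coding)
  if (is.null(cds1)) cds1 <- (n %/% 2) + 1L   # junction inside a codon
  set.seed(seed)
  bg <- function(k) paste(sample(c("A", "C", "G", "T"), k, TRUE),
                          collapse = "")
  block_plus <- paste0(bg(utr5), substr(coding, 1, cds1), bg(intron),
                       substr(coding, cds1 + 1L, n), bg(utr3))
  L <- nchar(block_plus)
  ex_rel_s <- c(0L, utr5 + cds1 + intron)
  ex_rel_e <- c(utr5 + cds1, L)
  cds_rel <- c(utr5, utr5 + cds1 + intron + (n - cds1))
  if (strand == "-") {
    block <- rc(block_plus)
    ex_s <- L - rev(ex_rel_e); ex_e <- L - rev(ex_rel_s)
    cds_s <- L - cds_rel[2]; cds_e <- L - cds_rel[1]
  } else {
    block <- block_plus
    ex_s <- ex_rel_s; ex_e <- ex_rel_e
    cds_s <- cds_rel[1]; cds_e <- cds_rel[2]
  }
  contig_seq <- paste0(bg(offset), block, bg(40L))
  ref <- tmp_ref(setNames(list(contig_seq), contig))
  gs <- make_gene_set(contig = contig, strand = strand, tx_start = offset,
                      tx_end = offset + L, cds_start = offset + cds_s,
                      cds_end = offset + cds_e,
                      exon_starts = offset + ex_s, exon_ends = offset + ex_e,
                      ids = list(entrez = "1001", protein = "NP_000001",
                                 uniprot = "P10001", kegg = "hsa00001",
                                 omim = "600001", hgnc = "HGNC:1"))
  seg_s <- pmax(offset + ex_s, offset + cds_s)
  seg_e <- pmin(offset + ex_e, offset + cds_e)
  keep <- seg_s < seg_e
  list(ref = ref, gs = gs, model = gs$models[[1]], coding = coding,
       strand = strand, contig = contig,
       cds_seg_start = seg_s[keep], cds_seg_end = seg_e[keep])
}

# oracle-side map: coding-orientation CDS offset -> genomic 0-based position
oracle_coding_to_genomic <- function(gene, off0) {
  widths <- gene$cds_seg_end - gene$cds_seg_start
  g_off <- if (gene$strand == "+") off0 else sum(widths) - 1L - off0
  cum <- cumsum(c(0L, widths))
  i <- findInterval(g_off, cum)
  unname(gene$cds_seg_start[i] + (g_off - cum[i]))
}

make_call <- function(contig, pos, ref, alt, caller, mapper,
                      sample = "S1", dp = NA_integer_, da = NA_integer_,
                      pass = TRUE) {
  data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
             sample_id = sample, caller_id = caller, mapper_id = mapper,
             depth_total = dp, depth_alt = da, pass = pass,
             filter = if (pass) "PASS" else "fail",
             stringsAsFactors = FALSE)
}

track_from_df <- function(df, name = "trk") {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_membership_track(f, name)
}

# cached default fixture run + pipeline result, shared across test files
fixture_env <- new.env(parent = emptyenv())

get_fixture_run <- function() {
  if (is.null(fixture_env$fx)) {
    d <- file.path(tempdir(), "mutscreen-fixture-run")
    fixture_env$fx <- make_fixture_run(d, fixture_spec(seed = 101L,
                                                       base_error_rate = 0))
  }
  fixture_env$fx
}

get_pipeline_result <- function() {
  if (is.null(fixture_env$res)) {
    fx <- get_fixture_run()
    fixture_env$res <- run_pipeline(fx$options_file, fx$manifest_file,
                                    output_dir = file.path(fx$dir, "out-main"))
  }
  fixture_env$res
}

# independent pileup oracle: expand every read base-by-base and tally
oracle_pileup <- function(reads, contig, start, end, min_bq) {
  L <- end - start
  raw <- matrix(0L, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  filt <- raw
  for (i in seq_len(nrow(reads))) {
    if (reads$contig[i] != contig) next
    toks <- regmatches(reads$cigar[i],
                       gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[i]))[[1]]
    rp <- reads$pos0[i]; qp <- 0L
    sq <- strsplit(reads$seq[i], "")[[1]]
    qu <- utf8ToInt(reads$qual[i]) - 33L
    for (tk in toks) {
      len <- as.integer(sub("[A-Z=]$", "", tk))
      op <- sub("^[0-9]+", "", tk)
      if (op %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          pos <- rp + k - 1L; qi <- qp + k
          if (pos >= start && pos < end && sq[qi] %in% rownames(raw)) {
            raw[sq[qi], pos - start + 1L] <- raw[sq[qi], pos - start + 1L] + 1L
            if (qu[qi] >= min_bq) {
              filt[sq[qi], pos - start + 1L] <-
                filt[sq[qi], pos - start + 1L] + 1L
            }
          }
        }
        rp <- rp + len; qp <- qp + len
      } else if (op %in% c("I", "S")) qp <- qp + len
      else if (op %in% c("D", "N")) rp <- rp + len
    }
  }
  list(raw = raw, filtered = filt)
}

random_sam_reads <- function(n, ref_len = 150L) {
  lines <- vapply(seq_len(n), function(i) {
    pos <- sample(1:(ref_len - 40), 1)
    ops <- character(0); lens <- integer(0)
    if (runif(1) < 0.3) { ops <- "S"; lens <- sample(1:3, 1) }
    n_blocks <- sample(1:3, 1)
    for (b in seq_len(n_blocks)) {
      ops <- c(ops, "M"); lens <- c(lens, sample(3:10, 1))
      if (b < n_blocks) {
        op <- sample(c("I", "D"), 1)
        ops <- c(ops, op); lens <- c(lens, sample(1:3, 1))
      }
    }
    if (runif(1) < 0.3) { ops <- c(ops, "S"); lens <- c(lens, sample(1:3, 1)) }
    qlen <- sum(lens[ops %in% c("M", "I", "S")])
    sam_line(sprintf("r%04d", i), sample(c(0, 16), 1), "chrT", pos, 60,
             paste0(lens, ops, collapse = ""),
             paste(sample(c("A", "C", "G", "T", "N"), qlen, TRUE,
                          prob = c(.24, .24, .24, .24, .04)), collapse = ""),
             qstr(sample(2:41, qlen, TRUE)))
  }, character(1))
  parse_sam(sam_file(lines))$reads
}
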