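# Assembly of the one-line-per-variant summary table, per-patient VCF
# output, run options, and the end-to-end pipeline driver.

SUMMARY_FLAG_COLUMNS <- MEMBERSHIP_TRACKS  # Table-2 flag column order

#' Column names of the variant summary table
#'
#' Fixed order: patient block, variant block, genomic-effect block,
#' per-patient file links, the 32 database annotation columns, test
#' statistics, dbSNP id + membership flags, and provenance.
#'
#' @return character vector of column names.
#' @export
summary_columns <- function() {
  c("Patient_Id", "Family_Id", "Lab_Analysis_Date", "Seq_Platform",
    "Seq_System", "Assay_Id",
    "Var_Id", "Var_Type", "Var_Cov", "Total_Cov", "A", "C", "G", "T",
    "Var_Chr", "Var_Start", "Var_End", "Var_Strand",
    "Var_Gene", "Var_RefGene", "Var_Feature", "Var_DNA", "Var_Codon",
    "Var_AA", "Frameshift",
    "FASTQC_Report", "Patient_Fastq", "Patient_Bam", "Patient_Vcf",
    link_templates()$field,
    "Fishers_Exact_Test_pvalue", "Fishers_Exact_Test_pvalue_FDR_corrected",
    "dbSnp_Id", SUMMARY_FLAG_COLUMNS,
    "Mapper_Name", "Variant_Caller")
}

#' Default run options
#'
#' Thresholds default to the workflow's validation settings (base quality 20,
#' total coverage 20, variant-allele coverage 4, allele frequency 0.10) and a
#' minimum mapping quality of 20.
#'
#' @return named list of options.
#' @export
default_options <- function() {
  list(reference = "", genes = "", ids = "", tracks_dir = "", hotspots = "",
       output_dir = "out", assembly = "GRCh37",
       min_mapq = 20L, require_proper_pair = TRUE, drop_duplicates = TRUE,
       min_base_qual = 20L, min_total_cov = 20L, min_alt_cov = 4L,
       min_af = 0.10, flank_window = 10L)
}

OPTION_TYPES <- c(min_mapq = "int", min_base_qual = "int",
                  min_total_cov = "int", min_alt_cov = "int",
                  flank_window = "int", min_af = "num",
                  require_proper_pair = "bool", drop_duplicates = "bool")

#' Read a key=value options file
#'
#' Lines of `key=value`; `#` starts a comment. Unknown keys warn and are
#' ignored; missing keys take their defaults.
#'
#' @param file path to the options file.
#' @return named list of options.
#' @export
read_options <- function(file) {
  opts <- default_options()
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("bad options line: ", ln, call. = FALSE)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    if (!key %in% names(opts)) {
      warning("unknown option key: ", key, call. = FALSE)
      next
    }
    opts[[key]] <- switch(OPTION_TYPES[key] %||% "chr",
                          int = as.integer(val), num = as.numeric(val),
                          bool = toupper(val) %in% c("TRUE", "1", "YES"),
                          val)
  }
  opts
}

#' Write an options file
#'
#' @param opts named list of options.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_options <- function(opts, file) {
  writeLines(sprintf("%s=%s", names(opts),
                     vapply(opts, as.character, character(1))), file)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Per-variant assembly pieces

# (ref, alt) read counts of one consensus variant for the Fisher table
variant_allele_counts <- function(vtype, ref_allele, column, var_cov, total) {
  if (is.na(var_cov) || is.na(total)) return(c(NA_real_, NA_real_))
  if (vtype == "SNV" && !is.null(column)) {
    rc <- unname(column$filtered_counts[ref_allele])
    return(c(rc, var_cov))
  }
  c(max(0, total - var_cov), var_cov)
}

effect_block <- function(nv, gene_models, reference) {
  feats <- assign_features(nv, gene_models)
  genic <- feats[feats$region_class != "intergenic", , drop = FALSE]
  out <- list(features = feats,
              Var_Gene = "", Var_RefGene = "", Var_Feature = "intergenic",
              Var_DNA = sprintf("%s>%s", nv$ref, nv$alt),
              Var_Codon = "", Var_AA = "", Frameshift = "",
              Var_Strand = "+")
  if (nrow(genic) == 0) return(out)
  out$Var_Gene <- paste(unique(genic$gene_symbol), collapse = ";")
  out$Var_RefGene <- paste(unique(genic$refseq_mrna), collapse = ";")
  out$Var_Feature <- paste(genic$feature_label, collapse = ";")
  out$Var_Strand <- genic$strand[1]
  if (nv$vtype == "SNV" && genic$strand[1] == "-") {
    # coding orientation for minus-strand genes
    out$Var_DNA <- sprintf("%s>%s", complement_base(nv$ref),
                           complement_base(nv$alt))
  }
  coding_rows <- which(genic$region_class == "CDS")
  if (length(coding_rows) > 0) {
    txs <- genic$refseq_mrna[coding_rows]
    models <- Filter(function(m) m$refseq_mrna %in% txs, gene_models$models)
    if (nv$vtype == "SNV") {
      cc <- lapply(models, function(m) {
        tryCatch(suppressWarnings(predict_codon_change(nv, m, reference)),
                 error = function(e) NULL)
      })
      cc <- cc[!vapply(cc, is.null, logical(1))]
      if (length(cc) > 0) {
        out$Var_Codon <- paste(vapply(cc, function(x)
          sprintf("%s>%s", x$ref_codon, x$alt_codon), character(1)),
          collapse = ";")
        out$Var_AA <- paste(vapply(cc, function(x)
          sprintf("%s>%s", x$ref_aa, x$alt_aa), character(1)),
          collapse = ";")
      }
    } else {
      fs <- lapply(models, function(m) {
        tryCatch(suppressWarnings(predict_frameshift(nv, m)),
                 error = function(e) NULL)
      })
      fs <- fs[!vapply(fs, is.null, logical(1))]
      if (length(fs) > 0) {
        out$Frameshift <- paste(vapply(fs, function(x)
          sprintf("%s(%d>%d)", if (x$is_frameshift) "yes" else "no",
                  x$original_frame, x$new_frame), character(1)),
          collapse = ";")
      }
    }
  }
  out
}

# identifiers for the link builders, taken from the first genic transcript
link_identifiers <- function(features, gene_models, rsid) {
  genic <- features[features$region_class != "intergenic", , drop = FALSE]
  ids <- list(rsid = rsid)
  if (nrow(genic) > 0) {
    m <- Filter(function(x) x$refseq_mrna == genic$refseq_mrna[1],
                gene_models$models)[[1]]
    ids$entrez <- m$entrez_id
    ids$symbol <- m$gene_symbol
    ids$mrna <- m$refseq_mrna
    ids$protein <- m$refseq_protein
    ids$uniprot <- m$uniprot_id
    ids$kegg <- m$kegg_id
    ids$omim <- m$omim_id
    ids$hgnc <- m$hgnc_id
  }
  ids
}

# 1-based inclusive reference footprint for the Var_Start/Var_End columns
footprint_1based <- function(nv) {
  switch(nv$vtype,
    SNV = c(nv$start + 1L, nv$start + 1L),
    DEL = c(nv$start + 2L, nv$start + nchar(nv$ref)),
    INS = c(nv$start + 1L, nv$start + 2L))
}

#' Summarize one patient's consensus variants into summary rows
#'
#' Applies the coverage/frequency filters, predicts effects, classifies and
#' flags each variant, computes the per-variant Fisher test against the
#' patient's remaining variants with BH correction, and assembles one row per
#' passing variant in the fixed summary-column order.
#'
#' @param patient named list/row with Patient_Id, Family_Id,
#'   Lab_Analysis_Date, Seq_Platform, Seq_System, Assay_Id, Fastq, Sam.
#' @param consensus data.frame from [build_consensus()] for this patient.
#' @param pileups named list of `pileup` objects keyed by contig (may lack
#'   contigs without reads).
#' @param reference a `ref_genome`.
#' @param gene_models a `gene_model_set`.
#' @param tracks named list of `interval_track`s (including `dbSnp_Id`).
#' @param hotspots an `interval_track` (possibly empty).
#' @param options options list (see [default_options()]).
#' @return data.frame of summary rows (0 rows when nothing passes).
#' @export
summarize_patient <- function(patient, consensus, pileups, reference,
                              gene_models, tracks, hotspots,
                              options = default_options()) {
  cols <- summary_columns()
  empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(consensus) == 0) return(empty)
  fpolicy <- filter_policy(options$min_total_cov, options$min_alt_cov,
                           options$min_af)
  link_fields <- link_templates()$field
  pieces <- list(); counts <- list()
  for (i in seq_len(nrow(consensus))) {
    nv <- consensus_nv(consensus, i)
    pu <- pileups[[nv$contig]]
    col_pos <- if (nv$vtype == "DEL") nv$start + 1L else nv$start
    column <- NULL
    if (!is.null(pu) && col_pos >= pu$start && col_pos < pu$end) {
      column <- pileup_column(pu, col_pos)
    }
    caller_depth <- consensus$samples[[i]]
    caller_depth <- caller_depth[caller_depth$sample_id == patient$Patient_Id, ,
                                 drop = FALSE]
    d_alt <- if (nrow(caller_depth) > 0) caller_depth$depth_alt[1] else NA_integer_
    d_tot <- if (nrow(caller_depth) > 0) caller_depth$depth_total[1] else NA_integer_
    if (nv$vtype == "SNV") {
      decomp <- if (!is.null(column)) coverage_decomposition(column, nv$alt)
                else NULL
      var_cov <- if (!is.null(decomp)) decomp$var_cov else d_alt
      total <- if (!is.null(decomp)) decomp$total else d_tot
    } else {
      decomp <- if (!is.null(column)) coverage_decomposition(column) else NULL
      var_cov <- d_alt
      total <- if (!is.na(d_tot)) d_tot
               else if (!is.null(decomp)) decomp$total else NA_integer_
    }
    verdict <- apply_filters(total %||% NA_integer_, var_cov %||% NA_integer_,
                             fpolicy)
    if (!verdict$pass) next
    counts[[length(counts) + 1L]] <-
      variant_allele_counts(nv$vtype, nv$ref, column, var_cov, total)
    eff <- effect_block(nv, gene_models, reference)
    cl <- classify_variant(nv, eff$features, tracks$dbSnp_Id)
    flags <- membership_flags(nv, tracks)
    hot <- flag_hotspot(nv, hotspots)
    ids <- link_identifiers(eff$features, gene_models, cl$rsid)
    fp1 <- footprint_1based(nv)
    # link applicability follows the region matrix: variants outside genes
    # use the intergenic column even when an rsID makes them "known"
    genic <- any(eff$features$region_class != "intergenic")
    link_class <- if (genic) cl$class else "intergenic"
    links <- build_links(ids, link_class, nv$contig, fp1[1])
    link_cells <- setNames(rep("", length(link_fields)), link_fields)
    link_cells[links$field] <- links$url
    caller_str <- consensus$callers[i]
    if (!is.na(hot)) caller_str <- paste0(caller_str, ";hotspot")
    row <- c(
      list(Patient_Id = patient$Patient_Id, Family_Id = patient$Family_Id,
           Lab_Analysis_Date = patient$Lab_Analysis_Date,
           Seq_Platform = patient$Seq_Platform,
           Seq_System = patient$Seq_System, Assay_Id = patient$Assay_Id,
           Var_Id = variant_key(nv, options$assembly), Var_Type = nv$vtype,
           Var_Cov = as.character(var_cov %||% ""),
           Total_Cov = as.character(total %||% ""),
           A = as.character(if (!is.null(decomp)) decomp$A else ""),
           C = as.character(if (!is.null(decomp)) decomp$C else ""),
           G = as.character(if (!is.null(decomp)) decomp$G else ""),
           T = as.character(if (!is.null(decomp)) decomp$T else ""),
           Var_Chr = nv$contig, Var_Start = as.character(fp1[1]),
           Var_End = as.character(fp1[2]), Var_Strand = eff$Var_Strand,
           Var_Gene = eff$Var_Gene, Var_RefGene = eff$Var_RefGene,
           Var_Feature = eff$Var_Feature, Var_DNA = eff$Var_DNA,
           Var_Codon = eff$Var_Codon, Var_AA = eff$Var_AA,
           Frameshift = eff$Frameshift,
           FASTQC_Report = "", Patient_Fastq = patient$Fastq,
           Patient_Bam = patient$Sam,
           Patient_Vcf = paste0(patient$Patient_Id, ".vcf")),
      as.list(link_cells),
      list(Fishers_Exact_Test_pvalue = "",
           Fishers_Exact_Test_pvalue_FDR_corrected = "",
           dbSnp_Id = if (is.na(cl$rsid)) "" else cl$rsid),
      as.list(setNames(ifelse(flags, "X", ""), SUMMARY_FLAG_COLUMNS)),
      list(Mapper_Name = consensus$mappers[i], Variant_Caller = caller_str)
    )
    pieces[[length(pieces) + 1L]] <- as.data.frame(row, check.names = FALSE,
                                                   stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0) return(empty)
  rows <- do.call(rbind, pieces)
  # per-sample Fisher test: each variant against the mean counts of the rest
  cm <- do.call(rbind, counts)
  if (nrow(cm) >= 2) {
    ps <- vapply(seq_len(nrow(cm)), function(i) {
      if (any(is.na(cm[i, ]))) return(NA_real_)
      others <- cm[-i, , drop = FALSE]
      others <- others[stats::complete.cases(others), , drop = FALSE]
      variant_fisher(cm[i, ], others)$p
    }, numeric(1))
    padj <- adjust_fdr(ps)
    rows$Fishers_Exact_Test_pvalue <-
      ifelse(is.na(ps), "", format(ps, digits = 7, trim = TRUE, scientific = NA))
    rows$Fishers_Exact_Test_pvalue_FDR_corrected <-
      ifelse(is.na(padj), "", format(padj, digits = 7, trim = TRUE,
                                     scientific = NA))
  }
  ord <- order(rows$Var_Chr, as.integer(rows$Var_Start), rows$Var_Id)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Write the variant summary table
#'
#' UTF-8 TSV whose header is exactly [summary_columns()]; empty cells are
#' empty strings.
#'
#' @param rows data.frame of summary rows.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_summary <- function(rows, file) {
  cols <- summary_columns()
  stopifnot(identical(names(rows), cols))
  utils::write.table(rows, file, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(file)
}

#' Read back a written summary table
#'
#' @param file path written by [write_summary()].
#' @return data.frame with all columns as character.
#' @export
read_summary <- function(file) {
  utils::read.delim(file, check.names = FALSE, colClasses = "character",
                    stringsAsFactors = FALSE)
}

#' Write a per-patient VCF from summary rows
#'
#' VCF 4.2 text with one record per variant and INFO keys for supports,
#' coverage decomposition and flags. Indels are written in their anchored
#' left-aligned representation.
#'
#' @param rows summary rows of a single patient.
#' @param consensus the consensus data.frame the rows were built from.
#' @param file output path.
#' @param reference optional `ref_genome` for contig header lines.
#' @return `file`, invisibly.
#' @export
write_patient_vcf <- function(rows, consensus, file, reference = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=mutscreen")
  if (!is.null(reference)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference$contigs), nchar(reference$contigs)))
  }
  hdr <- c(hdr,
    "##INFO=<ID=SUPPORTS,Number=.,Type=String,Description=\"Supporting mapper:caller pairs\">",
    "##INFO=<ID=TOTAL_COV,Number=1,Type=Integer,Description=\"Total filtered coverage\">",
    "##INFO=<ID=VAR_COV,Number=1,Type=Integer,Description=\"Variant allele coverage\">",
    "##INFO=<ID=BASES,Number=4,Type=Integer,Description=\"Filtered A,C,G,T counts\">",
    "##INFO=<ID=RSID,Number=1,Type=String,Description=\"Matched dbSNP identifier\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(rows) > 0) {
    body <- vapply(seq_len(nrow(rows)), function(i) {
      pk <- parse_variant_key(rows$Var_Id[i])
      # Var_Id was minted from the consensus record, so re-minting each
      # consensus key with the row's assembly label gives an exact match
      ckey <- vapply(seq_len(nrow(consensus)), function(j) {
        variant_key(consensus_nv(consensus, j), pk$assembly)
      }, character(1))
      j <- match(rows$Var_Id[i], ckey)
      if (is.na(j)) stop("summary row has no consensus record: ",
                         rows$Var_Id[i], call. = FALSE)
      start0 <- consensus$start[j]
      ref <- consensus$ref[j]; alt <- consensus$alt[j]
      info <- sprintf("SUPPORTS=%s;TOTAL_COV=%s;VAR_COV=%s",
                      paste(consensus$supports[[j]], collapse = ","),
                      rows$Total_Cov[i] %||% ".", rows$Var_Cov[i] %||% ".")
      if (nzchar(rows$A[i])) {
        info <- paste0(info, sprintf(";BASES=%s,%s,%s,%s", rows$A[i],
                                     rows$C[i], rows$G[i], rows$T[i]))
      }
      if (nzchar(rows$dbSnp_Id[i])) {
        info <- paste0(info, ";RSID=", rows$dbSnp_Id[i])
      }
      id <- if (nzchar(rows$dbSnp_Id[i])) rows$dbSnp_Id[i] else "."
      sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
              rows$Var_Chr[i], start0 + 1L, id, ref, alt, info)
    }, character(1))
  }
  writeLines(c(hdr, body), file)
  invisible(file)
}

# ---------------------------------------------------------------------------
# Pipeline driver

# mapper/caller parsed from "<patient>.<mapper>.<caller>.vcf"
parse_vcf_filename <- function(path) {
  toks <- strsplit(basename(path), ".", fixed = TRUE)[[1]]
  if (length(toks) < 4) {
    stop("VCF filename must follow <patient>.<mapper>.<caller>.vcf: ",
         basename(path), call. = FALSE)
  }
  list(mapper = toks[length(toks) - 2L], caller = toks[length(toks) - 1L])
}

load_tracks_dir <- function(dir) {
  tracks <- list()
  if (nzchar(dir) && dir.exists(dir)) {
    for (f in list.files(dir, pattern = "\\.tsv$", full.names = TRUE)) {
      nm <- sub("\\.tsv$", "", basename(f))
      tracks[[nm]] <- load_membership_track(f, nm)
    }
  }
  tracks
}

process_patient <- function(patient, reference, gene_models, tracks,
                            hotspots, options, output_dir) {
  policy <- read_filter_policy(options$min_mapq, options$require_proper_pair,
                               options$drop_duplicates)
  sam <- parse_sam(patient$Sam)
  reads <- mark_duplicates(sam$reads)
  pileups <- list()
  for (ctg in unique(reads$contig)) {
    sel <- reads[reads$contig == ctg, , drop = FALSE]
    span_end <- max(vapply(seq_len(nrow(sel)), function(i) {
      sel$pos0[i] + cigar_ref_len(cigar_ops(sel$cigar[i]))
    }, numeric(1)))
    lo <- max(0L, min(sel$pos0))
    hi <- min(contig_length(reference, ctg), as.integer(span_end))
    pileups[[ctg]] <- build_pileup(reads, ctg, lo, hi, policy,
                                   options$min_base_qual, reference)
  }
  vcf_paths <- strsplit(patient$Vcfs, ";", fixed = TRUE)[[1]]
  calls <- do.call(rbind, lapply(vcf_paths, function(p) {
    mc <- parse_vcf_filename(p)
    read_vcf(p, mc$caller, mc$mapper, patient$Patient_Id, reference)
  }))
  consensus <- build_consensus(calls, reference)
  rows <- summarize_patient(patient, consensus, pileups, reference,
                            gene_models, tracks, hotspots, options)
  vcf_out <- file.path(output_dir, paste0(patient$Patient_Id, ".vcf"))
  write_patient_vcf(rows, consensus, vcf_out, reference)
  list(rows = rows,
       log = c(reads_parsed = nrow(sam$reads) + sam$skipped_unmapped,
               reads_unmapped = sam$skipped_unmapped,
               reads_policy_pass = sum(apply_read_policy(reads, policy)),
               calls_in = nrow(calls), consensus_variants = nrow(consensus),
               rows_written = nrow(rows)))
}

#' Run the full post-alignment screening pipeline
#'
#' Pre-flight checks every referenced input file (aborting with the complete
#' list of missing paths), then processes each patient independently:
#' SAM parsing, duplicate marking, pileup, per-caller VCF ingestion,
#' normalization and consensus, filtering, effect prediction, statistics,
#' annotation, and output. Per-patient processing order does not affect the
#' result; the summary is sorted by patient, contig, start.
#'
#' @param options options list or path to a key=value options file.
#' @param manifest data.frame or path to the manifest TSV.
#' @param output_dir output directory (created if needed); defaults to
#'   `options$output_dir`.
#' @param workers number of parallel workers for per-patient processing
#'   (forked via [parallel::mclapply()]; results are identical to serial).
#' @return invisibly, a list with `summary` (the rows), `summary_file`,
#'   `output_dir` and `log` (per-patient stage counters).
#' @export
run_pipeline <- function(options, manifest, output_dir = NULL, workers = 1L) {
  if (is.character(options)) options <- read_options(options)
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (is.null(output_dir)) output_dir <- options$output_dir
  needed <- c(options$reference, options$genes,
              if (nzchar(options$ids %||% "")) options$ids,
              if (nzchar(options$hotspots %||% "")) options$hotspots,
              manifest$Sam,
              unlist(strsplit(manifest$Vcfs, ";", fixed = TRUE)))
  missing <- needed[!file.exists(needed)]
  if (length(missing) > 0) {
    stop("missing input file(s):\n  ", paste(missing, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  reference <- load_reference(options$reference, options$assembly)
  gene_models <- suppressWarnings(load_gene_models(
    options$genes, if (nzchar(options$ids %||% "")) options$ids else NULL))
  tracks <- load_tracks_dir(options$tracks_dir %||% "")
  hotspots <- if (nzchar(options$hotspots %||% "") &&
                  file.exists(options$hotspots)) {
    load_hotspots(options$hotspots)
  } else {
    new_interval_track("hotspots",
                       data.frame(contig = character(0), start = integer(0),
                                  end = integer(0), name = character(0),
                                  stringsAsFactors = FALSE))
  }
  manifest <- manifest[order(manifest$Patient_Id), , drop = FALSE]
  run_one <- function(i) {
    process_patient(as.list(manifest[i, ]), reference, gene_models, tracks,
                    hotspots, options, output_dir)
  }
  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(manifest)), run_one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(manifest)), run_one)
  }
  err <- vapply(results, inherits, logical(1), "try-error")
  if (any(err)) stop("patient processing failed", call. = FALSE)
  rows <- do.call(rbind, lapply(results, `[[`, "rows"))
  ord <- order(rows$Patient_Id, rows$Var_Chr, as.integer(rows$Var_Start),
               rows$Var_Id)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  summary_file <- file.path(output_dir, "summary.tsv")
  write_summary(rows, summary_file)
  log <- lapply(results, `[[`, "log")
  names(log) <- manifest$Patient_Id
  log_file <- file.path(output_dir, "run.log")
  writeLines(unlist(lapply(names(log), function(p) {
    c(sprintf("[%s]", p),
      sprintf("  %s=%d", names(log[[p]]), log[[p]]))
  })), log_file)
  invisible(list(summary = rows, summary_file = summary_file,
                 output_dir = output_dir, log = log))
}
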