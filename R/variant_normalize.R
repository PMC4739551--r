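# Per-caller VCF ingestion, left-aligned parsimonious normalization,
# variant identifiers, and cross-mapper/cross-caller consensus.

MAPPER_LEVELS <- c("bwa", "bowtie", "bowtie2", "gsnap", "tmap", "other")
CALLER_LEVELS <- c("gatk", "freebayes", "samtools", "varscan", "other")
MAPPER_LABELS <- c(bwa = "Bwa", bowtie = "Bowtie", bowtie2 = "Bowtie2",
                   gsnap = "GSNAP", tmap = "TMAP", other = "Other")

mapper_label <- function(id) unname(MAPPER_LABELS[id])
caller_label <- function(id) id  # callers are printed lowercase

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))[[1]]
  if (length(m) < 2) NA_character_ else m[2]
}

parse_format_field <- function(format, sample, key) {
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  vals <- strsplit(sample, ":", fixed = TRUE)[[1]]
  i <- match(key, keys)
  if (is.na(i) || i > length(vals)) NA_character_ else vals[i]
}

# Per-caller depth dialects: AD (gatk/freebayes), DP4 (samtools),
# RD+AD (varscan). Absent fields leave depths NA; the pileup recount is the
# authoritative path for coverage columns downstream.
extract_depths <- function(caller_id, info, format, sample, alt_index) {
  dp <- suppressWarnings(as.integer(parse_info_field(info, "DP")))
  total <- dp; alt <- NA_integer_
  if (!is.na(format) && !is.na(sample)) {
    fdp <- suppressWarnings(as.integer(parse_format_field(format, sample, "DP")))
    if (!is.na(fdp)) total <- fdp
  }
  if (caller_id %in% c("gatk", "freebayes")) {
    ad <- if (!is.na(format) && !is.na(sample)) {
      parse_format_field(format, sample, "AD")
    } else NA_character_
    if (!is.na(ad)) {
      parts <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
      if (length(parts) >= alt_index + 1L) alt <- parts[alt_index + 1L]
      if (is.na(total)) total <- sum(parts, na.rm = TRUE)
    }
  } else if (caller_id == "samtools") {
    dp4 <- parse_info_field(info, "DP4")
    if (!is.na(dp4)) {
      parts <- suppressWarnings(as.integer(strsplit(dp4, ",", fixed = TRUE)[[1]]))
      if (length(parts) == 4) {
        alt <- parts[3] + parts[4]
        if (is.na(total)) total <- sum(parts)
      }
    }
  } else if (caller_id == "varscan") {
    if (!is.na(format) && !is.na(sample)) {
      advs <- suppressWarnings(as.integer(parse_format_field(format, sample, "AD")))
      rd <- suppressWarnings(as.integer(parse_format_field(format, sample, "RD")))
      if (!is.na(advs)) alt <- advs
      if (is.na(total) && !is.na(advs) && !is.na(rd)) total <- advs + rd
    }
  }
  list(total = total, alt = alt)
}

#' Read a per-caller VCF into variant calls
#'
#' One call per (record, ALT allele): multiallelic records are split before
#' normalization. Depth fields are recovered per caller dialect (per-sample
#' AD for gatk/freebayes, INFO DP4 alt-forward+alt-reverse for samtools,
#' RD/AD for varscan); absent fields leave depths NA. Records whose FILTER is
#' neither PASS nor `.` are retained but flagged `pass = FALSE`. When a
#' reference genome is supplied, records whose REF disagrees with it are
#' reported and skipped.
#'
#' @param file path to a VCF 4.x text file.
#' @param caller_id one of gatk, samtools, freebayes, varscan, other.
#' @param mapper_id one of bwa, bowtie, bowtie2, gsnap, tmap, other.
#' @param sample_id sample/patient identifier for the calls.
#' @param reference optional `ref_genome` for REF-allele validation.
#' @return data.frame of calls: contig, pos (1-based), ref, alt, sample_id,
#'   caller_id, mapper_id, depth_total, depth_alt, pass, filter.
#' @export
read_vcf <- function(file, caller_id, mapper_id, sample_id,
                     reference = NULL) {
  caller_id <- match.arg(caller_id, CALLER_LEVELS)
  mapper_id <- match.arg(mapper_id, MAPPER_LEVELS)
  hdr_ok <- any(startsWith(readLines(file), "#CHROM"))
  if (!hdr_ok) stop("VCF is missing the #CHROM header line", call. = FALSE)
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  empty <- data.frame(
    contig = character(0), pos = integer(0), ref = character(0),
    alt = character(0), sample_id = character(0), caller_id = character(0),
    mapper_id = character(0), depth_total = integer(0),
    depth_alt = integer(0), pass = logical(0), filter = character(0),
    stringsAsFactors = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) return(empty)
  gt <- if (ncol(v@gt) >= 2) v@gt else NULL
  out <- vector("list", nrow(fix))
  for (r in seq_len(nrow(fix))) {
    contig <- fix[r, "CHROM"]; pos <- as.integer(fix[r, "POS"])
    ref <- toupper(fix[r, "REF"])
    alts <- toupper(strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]])
    filt <- fix[r, "FILTER"]
    if (is.na(filt)) filt <- "."
    info <- fix[r, "INFO"]
    if (is.na(info)) info <- "."
    if (!is.null(reference)) {
      want <- tryCatch(ref_seq(reference, contig, pos - 1L, pos - 1L + nchar(ref)),
                       error = function(e) NA_character_)
      if (is.na(want) || want != ref) {
        warning(sprintf("%s:%d REF %s disagrees with reference; record skipped",
                        contig, pos, ref), call. = FALSE)
        next
      }
    }
    fmt <- if (!is.null(gt)) gt[r, 1] else NA_character_
    smp <- if (!is.null(gt)) gt[r, 2] else NA_character_
    rows <- lapply(seq_along(alts), function(ai) {
      d <- extract_depths(caller_id, info, fmt, smp, ai)
      data.frame(contig = contig, pos = pos, ref = ref, alt = alts[ai],
                 sample_id = sample_id, caller_id = caller_id,
                 mapper_id = mapper_id,
                 depth_total = d$total %||% NA_integer_,
                 depth_alt = d$alt %||% NA_integer_,
                 pass = filt %in% c("PASS", "."),
                 filter = filt, stringsAsFactors = FALSE)
    })
    out[[r]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Normalize a variant to its left-aligned parsimonious representation
#'
#' The canonical key shared across callers and mappers. Algorithm: shared
#' suffix bases are trimmed (extending left with the preceding reference base
#' whenever an allele would become empty, which walks indels leftward through
#' repeat tracts), then shared prefix bases are trimmed. The result is
#' parsimonious (no shared leading/trailing bases beyond the single anchor
#' base indels require) and left-aligned (no identical representation exists
#' at a smaller start).
#'
#' @param contig contig name.
#' @param pos 1-based VCF position.
#' @param ref,alt uppercase alleles, `ref != alt`.
#' @param reference a `ref_genome` covering the locus.
#' @return object of class `normalized_variant`: list with `contig`, `start`
#'   (0-based), `ref`, `alt`, `vtype` (SNV/INS/DEL).
#' @export
normalize_variant <- function(contig, pos, ref, alt, reference) {
  ref <- toupper(ref); alt <- toupper(alt)
  stop_if_not_dna(c(ref, alt))
  if (ref == alt) stop("ref and alt are identical: not a variant", call. = FALSE)
  start0 <- pos - 1L
  r <- ref; a <- alt
  repeat {
    nr <- nchar(r); na <- nchar(a)
    if (nr > 0 && na > 0 && substr(r, nr, nr) == substr(a, na, na)) {
      r <- substr(r, 1, nr - 1L); a <- substr(a, 1, na - 1L)
      if (nchar(r) == 0 || nchar(a) == 0) {
        if (start0 == 0L) {
          stop(sprintf("%s:%d cannot left-extend beyond contig start", contig, pos),
               call. = FALSE)
        }
        prev <- ref_seq(reference, contig, start0 - 1L, start0)
        r <- paste0(prev, r); a <- paste0(prev, a)
        start0 <- start0 - 1L
      }
    } else if (nchar(r) > 1 && nchar(a) > 1 &&
               substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a))
      start0 <- start0 + 1L
    } else break
  }
  if (r == a) stop("alleles identical after trimming: not a variant", call. = FALSE)
  nr <- nchar(r); na <- nchar(a)
  vtype <- if (nr == 1 && na == 1) "SNV"
           else if (nr > na) "DEL"
           else if (nr < na) "INS"
           else stop("multi-base substitution (MNV) is not a supported variant type",
                     call. = FALSE)
  structure(list(contig = contig, start = start0, ref = r, alt = a,
                 vtype = vtype), class = "normalized_variant")
}

#' @export
print.normalized_variant <- function(x, ...) {
  cat(sprintf("<normalized_variant> %s %s:%d %s>%s\n",
              x$vtype, x$contig, x$start, x$ref, x$alt))
  invisible(x)
}

# reference footprint of a normalized variant, 0-based half-open
variant_footprint <- function(nv) {
  switch(nv$vtype,
    SNV = c(nv$start, nv$start + 1L),
    DEL = c(nv$start + 1L, nv$start + nchar(nv$ref)),
    INS = c(nv$start, nv$start + 2L))
}

#' Mint the genomic variant identifier
#'
#' HGVS-style genomic keys: SNV `"{contig}.{assembly}:g.{pos}{ref}>{alt}"`;
#' deletion `"g.{start}_{end}del"` (single base: `"g.{pos}del"`); insertion
#' `"g.{pos}_{pos+1}ins{seq}"`. Positions are 1-based.
#'
#' @param nv a `normalized_variant`.
#' @param assembly assembly label (e.g. `"GRCh37"`).
#' @return character identifier.
#' @examples
#' \dontrun{
#' variant_key(nv, "GRCh37")  # e.g. "chr13.GRCh37:g.18258370G>A"
#' }
#' @export
variant_key <- function(nv, assembly) {
  prefix <- sprintf("%s.%s:g.", nv$contig, assembly)
  if (nv$vtype == "SNV") {
    return(sprintf("%s%d%s>%s", prefix, nv$start + 1L, nv$ref, nv$alt))
  }
  if (nv$vtype == "DEL") {
    s1 <- nv$start + 2L                      # first deleted base, 1-based
    e1 <- nv$start + nchar(nv$ref)           # last deleted base, 1-based
    if (s1 == e1) return(sprintf("%s%ddel", prefix, s1))
    return(sprintf("%s%d_%ddel", prefix, s1, e1))
  }
  p1 <- nv$start + 1L                        # anchor base, 1-based
  sprintf("%s%d_%dins%s", prefix, p1, p1 + 1L, substr(nv$alt, 2, nchar(nv$alt)))
}

#' Parse a variant identifier back into its parts
#'
#' Inverse of [variant_key()] for round-trip checks.
#'
#' @param key identifier produced by [variant_key()].
#' @return list with `contig`, `assembly`, `vtype`, and 1-based `start`,
#'   `end` of the reference footprint plus `ref`/`alt` for SNVs and `ins_seq`
#'   for insertions.
#' @export
parse_variant_key <- function(key) {
  m <- regmatches(key, regexec("^(.+)\\.([^.:]+):g\\.(.+)$", key))[[1]]
  if (length(m) != 4) stop("unparseable variant key: ", key, call. = FALSE)
  contig <- m[2]; assembly <- m[3]; g <- m[4]
  if (grepl("^[0-9]+[ACGT]>[ACGT]$", g)) {
    pos <- as.integer(sub("^([0-9]+).*$", "\\1", g))
    return(list(contig = contig, assembly = assembly, vtype = "SNV",
                start = pos, end = pos,
                ref = sub("^[0-9]+([ACGT])>.*$", "\\1", g),
                alt = sub("^.*>([ACGT])$", "\\1", g)))
  }
  if (grepl("del$", g)) {
    nums <- as.integer(strsplit(sub("del$", "", g), "_", fixed = TRUE)[[1]])
    if (length(nums) == 1) nums <- c(nums, nums)
    return(list(contig = contig, assembly = assembly, vtype = "DEL",
                start = nums[1], end = nums[2]))
  }
  m2 <- regmatches(g, regexec("^([0-9]+)_([0-9]+)ins([ACGT]+)$", g))[[1]]
  if (length(m2) == 4) {
    return(list(contig = contig, assembly = assembly, vtype = "INS",
                start = as.integer(m2[2]), end = as.integer(m2[3]),
                ins_seq = m2[4]))
  }
  stop("unparseable variant key: ", key, call. = FALSE)
}

#' Merge calls across mappers and callers into consensus records
#'
#' Every call is normalized and calls sharing (contig, start, ref, alt) are
#' merged. Supports accumulate distinct (mapper, caller) pairs; output is
#' sorted by contig then start.
#'
#' @param calls data.frame of calls as returned by [read_vcf()] (possibly
#'   rbind-ed across runs).
#' @param reference a `ref_genome`.
#' @return data.frame with one row per consensus variant: contig, start, ref,
#'   alt, vtype, plus list-columns `supports` (character vectors
#'   "mapper:caller"), `samples` (per-sample depth data.frames), and
#'   `n_callers`, `n_mappers`, `mappers`, `callers` (canonical-order,
#'   `;`-joined label strings), `pass_any`.
#' @export
build_consensus <- function(calls, reference) {
  empty <- data.frame(contig = character(0), start = integer(0),
                      ref = character(0), alt = character(0),
                      vtype = character(0), stringsAsFactors = FALSE)
  if (nrow(calls) == 0) {
    empty$supports <- list(); empty$samples <- list()
    empty$n_callers <- integer(0); empty$n_mappers <- integer(0)
    empty$mappers <- character(0); empty$callers <- character(0)
    empty$pass_any <- logical(0)
    return(empty)
  }
  nvs <- lapply(seq_len(nrow(calls)), function(i) {
    normalize_variant(calls$contig[i], calls$pos[i], calls$ref[i],
                      calls$alt[i], reference)
  })
  key <- vapply(nvs, function(nv) {
    paste(nv$contig, nv$start, nv$ref, nv$alt, sep = "\r")
  }, character(1))
  groups <- split(seq_len(nrow(calls)), key)
  rows <- lapply(groups, function(idx) {
    nv <- nvs[[idx[1]]]
    sup <- sort(unique(paste(calls$mapper_id[idx], calls$caller_id[idx],
                             sep = ":")))
    mappers <- unique(calls$mapper_id[idx])
    callers <- unique(calls$caller_id[idx])
    mappers <- MAPPER_LEVELS[MAPPER_LEVELS %in% mappers]
    callers <- CALLER_LEVELS[CALLER_LEVELS %in% callers]
    samples <- do.call(rbind, lapply(split(idx, calls$sample_id[idx]),
      function(j) {
        data.frame(sample_id = calls$sample_id[j[1]],
                   depth_total = suppressWarnings(
                     max(calls$depth_total[j], na.rm = TRUE)),
                   depth_alt = suppressWarnings(
                     max(calls$depth_alt[j], na.rm = TRUE)),
                   stringsAsFactors = FALSE)
      }))
    samples$depth_total[!is.finite(samples$depth_total)] <- NA_integer_
    samples$depth_alt[!is.finite(samples$depth_alt)] <- NA_integer_
    rownames(samples) <- NULL
    out <- data.frame(contig = nv$contig, start = nv$start, ref = nv$ref,
                      alt = nv$alt, vtype = nv$vtype,
                      n_callers = length(callers), n_mappers = length(mappers),
                      mappers = paste(mapper_label(mappers), collapse = ";"),
                      callers = paste(caller_label(callers), collapse = ";"),
                      pass_any = any(calls$pass[idx]),
                      stringsAsFactors = FALSE)
    out$supports <- list(sup)
    out$samples <- list(samples)
    out
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$contig, res$start, res$ref, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  res
}

consensus_nv <- function(consensus, i) {
  structure(list(contig = consensus$contig[i], start = consensus$start[i],
                 ref = consensus$ref[i], alt = consensus$alt[i],
                 vtype = consensus$vtype[i]), class = "normalized_variant")
}

#' Venn-cell membership counts across callers or mappers
#'
#' For each nonempty subset of the axis labels observed in the consensus,
#' counts the variants supported by exactly that subset, separately for SNVs
#' and indels, plus the fraction of variants supported by at least two
#' labels.
#'
#' @param consensus data.frame from [build_consensus()].
#' @param axis `"caller"` or `"mapper"`.
#' @return list with `cells` (data.frame: vclass, members, count),
#'   `ge2_fraction` (named vector: SNV, INDEL, all), and `labels`.
#' @export
overlap_statistics <- function(consensus, axis = c("caller", "mapper")) {
  axis <- match.arg(axis)
  part <- if (axis == "caller") 2L else 1L
  levels_all <- if (axis == "caller") CALLER_LEVELS else MAPPER_LEVELS
  memb <- lapply(consensus$supports, function(sup) {
    lab <- unique(vapply(strsplit(sup, ":", fixed = TRUE), `[[`,
                         character(1), part))
    levels_all[levels_all %in% lab]
  })
  labels <- levels_all[levels_all %in% unique(unlist(memb))]
  if (length(labels) < 2) {
    stop(sprintf("overlap statistics need >=2 %s labels (found %d)",
                 axis, length(labels)), call. = FALSE)
  }
  vclass <- ifelse(consensus$vtype == "SNV", "SNV", "INDEL")
  subset_key <- vapply(memb, paste, character(1), collapse = "+")
  cells <- as.data.frame(table(vclass = vclass, members = subset_key),
                         stringsAsFactors = FALSE)
  cells <- cells[cells$Freq > 0, , drop = FALSE]
  names(cells)[3] <- "count"
  rownames(cells) <- NULL
  ge2 <- lengths(memb) >= 2
  frac <- function(sel) if (!any(sel)) NA_real_ else mean(ge2[sel])
  list(cells = cells,
       ge2_fraction = c(SNV = frac(vclass == "SNV"),
                        INDEL = frac(vclass == "INDEL"),
                        all = mean(ge2)),
       labels = labels)
}

#' Write consensus records as VCF 4.2 text
#'
#' One record per normalized variant, with INFO keys NCALLERS, NMAPPERS and
#' SUPPORTS.
#'
#' @param consensus data.frame from [build_consensus()].
#' @param file output path.
#' @param reference optional `ref_genome` for contig header lines.
#' @return `file`, invisibly.
#' @export
write_consensus_vcf <- function(consensus, file, reference = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mutscreen")
  if (!is.null(reference)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(reference$contigs), nchar(reference$contigs)))
  }
  hdr <- c(hdr,
    "##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description=\"Distinct supporting variant callers\">",
    "##INFO=<ID=NMAPPERS,Number=1,Type=Integer,Description=\"Distinct supporting read mappers\">",
    "##INFO=<ID=SUPPORTS,Number=.,Type=String,Description=\"Supporting mapper:caller pairs\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(consensus) > 0) {
    body <- vapply(seq_len(nrow(consensus)), function(i) {
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tNCALLERS=%d;NMAPPERS=%d;SUPPORTS=%s",
              consensus$contig[i], consensus$start[i] + 1L, consensus$ref[i],
              consensus$alt[i], consensus$n_callers[i], consensus$n_mappers[i],
              paste(consensus$supports[[i]], collapse = ","))
    }, character(1))
  }
  writeLines(c(hdr, body), file)
  invisible(file)
}
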