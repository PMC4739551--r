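# Per-variant summary statistics: flanking base quality, coverage
# decomposition, two-tailed Fisher's exact test against the sample's mean
# allele counts, BH FDR correction, and coverage/frequency filters.

#' Base-quality statistics in the flanking window of a variant
#'
#' Mean and lower-median PHRED quality over all policy-passing base
#' qualities at positions `pos - window .. pos + window`, excluding the
#' variant position itself. Positions outside the pileup region contribute
#' nothing.
#'
#' @param pileup a `pileup`.
#' @param contig contig name (must match the pileup).
#' @param pos 0-based variant position.
#' @param window flank half-width in bases (default 10).
#' @return list with `mean_qual`, `median_qual` (NA when no flanking bases)
#'   and `n_bases`.
#' @export
flanking_quality <- function(pileup, contig, pos, window = 10L) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (!identical(contig, pileup$contig)) {
    stop("pileup is for contig ", pileup$contig, call. = FALSE)
  }
  positions <- setdiff(seq(pos - window, pos + window), pos)
  positions <- positions[positions >= pileup$start & positions < pileup$end]
  qs <- unlist(pileup$quals[positions - pileup$start + 1L], use.names = FALSE)
  n <- length(qs)
  if (n == 0) {
    return(list(mean_qual = NA_real_, median_qual = NA_real_, n_bases = 0L))
  }
  sq <- sort(qs)
  list(mean_qual = mean(qs),
       median_qual = as.numeric(sq[(n + 1L) %/% 2L]),  # lower middle for even n
       n_bases = n)
}

#' Coverage decomposition at a variant column
#'
#' Per-base A/C/G/T counts, totals, and the variant-allele coverage: the
#' filtered count of the alt base for SNVs; `NA` for indels (their alt depth
#' comes from the caller record).
#'
#' @param column a pileup column from [pileup_column()].
#' @param alt_base the alt base (A/C/G/T) for SNVs, or `NULL` for indels.
#' @return list with filtered `A`, `C`, `G`, `T`, `total`, `var_cov`, and the
#'   raw-side `raw` counts, `total_raw`, `var_cov_raw`.
#' @export
coverage_decomposition <- function(column, alt_base = NULL) {
  filt <- column$filtered_counts
  raw <- column$raw_counts
  var_cov <- NA_integer_
  var_cov_raw <- NA_integer_
  if (!is.null(alt_base)) {
    if (!alt_base %in% BASES) {
      stop("alt base must be one of A, C, G, T", call. = FALSE)
    }
    var_cov <- unname(filt[alt_base])
    var_cov_raw <- unname(raw[alt_base])
  }
  list(A = unname(filt["A"]), C = unname(filt["C"]), G = unname(filt["G"]),
       T = unname(filt["T"]), total = sum(filt), var_cov = var_cov,
       raw = raw, total_raw = sum(raw), var_cov_raw = var_cov_raw)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability is at most that of the observed table (relative
#' tolerance 1e-7 for floating-point ties).
#'
#' @param a,b,c,d non-negative integer cells of the table
#'   `rbind(c(a, b), c(c, d))`; at least one margin must be positive.
#' @return the two-sided p-value.
#' @examples
#' fisher_two_tailed(5, 5, 5, 5)   # 1
#' fisher_two_tailed(2, 8, 8, 2)   # 4252/184756
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("table cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("all four cells are zero", call. = FALSE)
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  # degenerate margins admit a single table
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == r1 + r2) return(1)
  xs <- max(0, c1 - r2):min(c1, r1)
  probs <- stats::dhyper(xs, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Per-variant Fisher test against the sample's mean allele counts
#'
#' Row 1 is the variant's (ref, alt) counts; row 2 is the component-wise
#' arithmetic mean of the (ref, alt) counts over all other variants of the
#' same sample, rounded half-up to integers.
#'
#' @param variant_counts length-2 numeric: (ref_count, alt_count).
#' @param cohort_counts matrix/data.frame with two columns (ref, alt), one
#'   row per *other* variant in the sample.
#' @return list with `table` (2x2 matrix) and `p`; both `NULL`/`NA` when the
#'   cohort is empty (single-variant sample).
#' @export
variant_fisher <- function(variant_counts, cohort_counts) {
  cohort_counts <- as.matrix(cohort_counts)
  if (nrow(cohort_counts) == 0) {
    return(list(table = NULL, p = NA_real_))
  }
  m <- round_half_up(colMeans(cohort_counts))
  tab <- rbind(as.numeric(variant_counts), as.numeric(m))
  dimnames(tab) <- list(c("variant", "cohort_mean"), c("ref", "alt"))
  p <- fisher_two_tailed(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  list(table = tab, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment (`p.adjust(method = "BH")`), returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values.
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Coverage / allele-frequency filter policy
#'
#' Defaults are the validation thresholds of the screening workflow:
#' total coverage >= 20, variant-allele coverage >= 4, allele frequency
#' >= 0.10.
#'
#' @param min_total_cov minimum total (filtered) coverage.
#' @param min_alt_cov minimum variant-allele coverage.
#' @param min_af minimum variant allele frequency in `[0, 1]`.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(min_total_cov = 20L, min_alt_cov = 4L,
                          min_af = 0.10) {
  stopifnot(min_total_cov >= 0, min_alt_cov >= 0, min_af >= 0, min_af <= 1)
  structure(list(min_total_cov = as.integer(min_total_cov),
                 min_alt_cov = as.integer(min_alt_cov),
                 min_af = as.numeric(min_af)),
            class = "filter_policy")
}

#' Apply coverage and allele-frequency filters to a variant
#'
#' Passes iff total coverage, variant-allele coverage and allele frequency
#' all meet the policy. Failures carry machine-readable reasons. An unknown
#' (NA) variant-allele coverage leaves the alt-coverage and frequency checks
#' undecided: the variant is not failed for them, and the note
#' `"alt_depth_unknown"` is recorded.
#'
#' @param total total coverage at the variant column.
#' @param var_cov variant-allele coverage (NA when unknown).
#' @param policy a [filter_policy()].
#' @return list with `pass` (logical) and `reasons` (character vector; empty
#'   when passing).
#' @export
apply_filters <- function(total, var_cov, policy = filter_policy()) {
  if (is.na(total) || total == 0) {
    return(list(pass = FALSE, reasons = "no_coverage"))
  }
  reasons <- character(0)
  notes <- character(0)
  if (total < policy$min_total_cov) reasons <- c(reasons, "low_total_cov")
  if (is.na(var_cov)) {
    notes <- c(notes, "alt_depth_unknown")
  } else {
    if (var_cov < policy$min_alt_cov) reasons <- c(reasons, "low_alt_cov")
    if (var_cov / total < policy$min_af) reasons <- c(reasons, "low_af")
  }
  list(pass = length(reasons) == 0, reasons = c(reasons, notes))
}
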