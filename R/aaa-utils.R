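# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

BASES <- c("A", "C", "G", "T")

#' Reverse-complement a nucleotide string
#'
#' Operates on plain character strings (uppercase DNA with N allowed).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

complement_base <- function(x) chartr("ACGTN", "TGCAN", x)

# round-half-up: Fisher tables need integers, R's round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

is_scalar_chr <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

stop_if_not_dna <- function(x, what = "allele") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters: %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# PHRED+33 decoding of a quality string into integer qualities
phred_from_string <- function(q) {
  if (is.na(q) || q == "*") return(integer(0))
  utf8ToInt(q) - 33L
}

phred_to_string <- function(q) intToUtf8(q + 33L)
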