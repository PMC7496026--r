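#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings. Only the
#' letters A/C/G/T/N are expected; N is its own complement.
#'
#' @param x Character vector of DNA sequences (uppercase).
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp(c("ACGT", "CCGGN"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# Split sequences into per-base character vectors; returns a list.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# 0-based, half-open substring: bases [start, end) of a 1-based R string.
substr0 <- function(x, start, end) substr(x, start + 1L, end)

DNA_BASES4 <- c("A", "C", "G", "T")

DINUCLEOTIDES <- as.vector(outer(DNA_BASES4, DNA_BASES4, paste0))

is_scalar_seq <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

assert_seq <- function(x, arg = deparse(substitute(x))) {
  if (!is_scalar_seq(x) || nchar(x) == 0L) {
    abort(sprintf("`%s` must be a single non-empty sequence string", arg))
  }
  invisible(x)
}
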