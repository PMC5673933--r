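# Internal helpers shared across modules. All genomic coordinates in this
# package are 0-based half-open [start, end) unless a reader/writer says
# otherwise; conversions happen only at file-format boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the DNA alphabet.
#'
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# substring(s) of a chromosome in 0-based half-open coordinates
# (substring, not substr: vectorised over start/end)
seq_slice <- function(chrom_seq, start0, end0) {
  substring(chrom_seq, start0 + 1L, end0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# draw a random DNA string of length n from the current RNG stream
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

assert_seed <- function(rng_seed) {
  if (!is.numeric(rng_seed) || length(rng_seed) != 1L || is.na(rng_seed))
    stop_invalid("rng_seed must be a single integer")
  invisible(as.integer(rng_seed))
}
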