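#' Build an exact-match anchor index over a genome
#'
#' Hashes every forward-strand k-mer of every chromosome. Queries are
#' resolved on both strands: a k-mer occurring at forward position `p`
#' yields locus `(chrom, p, "+")`; a k-mer whose reverse complement occurs
#' at forward position `p` yields `(chrom, p, "-")` (the minus-strand
#' spelling over `[p, p + k)`).
#'
#' @param genome named character vector of chromosome sequences.
#' @param k anchor length; must satisfy `12 <= k` (shorter anchors map too
#'   promiscuously to be useful).
#' @return object of class `anchor_index` wrapping a keyed `data.table`.
#' @export
index_genome <- function(genome, k) {
  if (k < 12L) stop_invalid("anchor length k must be >= 12")
  k <- as.integer(k)
  tabs <- lapply(names(genome), function(chrom) {
    s <- genome[[chrom]]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    data.table::data.table(
      kmer = substring(s, seq_len(n), seq_len(n) + k - 1L),
      chrom = chrom,
      pos = seq_len(n) - 1L)
  })
  dt <- data.table::rbindlist(tabs)
  data.table::setkey(dt, kmer)
  counts <- dt[, list(n_loci = .N), by = "kmer"]
  data.table::setkey(counts, kmer)
  structure(list(table = dt, counts = counts, k = k),
            class = "anchor_index")
}

#' @export
print.anchor_index <- function(x, ...) {
  cat(sprintf("anchor_index: k = %d, %d positions\n", x$k, nrow(x$table)))
  invisible(x)
}

#' Query an anchor index
#'
#' @param index an `anchor_index`.
#' @param kmers character vector of k-mers.
#' @return data.frame with columns `query` (index into `kmers`), `chrom`,
#'   `pos` (0-based), `strand`; absent k-mers contribute zero rows.
#' @export
query_anchor <- function(index, kmers) {
  dt <- index$table
  q_fw <- data.table::data.table(kmer = kmers, query = seq_along(kmers))
  q_rc <- data.table::data.table(kmer = revcomp(kmers),
                                 query = seq_along(kmers))
  h_fw <- dt[q_fw, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  h_rc <- dt[q_rc, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  out <- rbind(
    data.frame(query = h_fw$query, chrom = h_fw$chrom, pos = h_fw$pos,
               strand = rep("+", nrow(h_fw)), stringsAsFactors = FALSE),
    data.frame(query = h_rc$query, chrom = h_rc$chrom, pos = h_rc$pos,
               strand = rep("-", nrow(h_rc)), stringsAsFactors = FALSE))
  out[order(out$query, out$chrom, out$pos), , drop = FALSE]
}

# forward-strand-only unique lookup used by the caller: for each k-mer,
# its single forward locus, or NA when absent or mapping to more loci than
# `max_loci`. Returns list(chrom =, pos =) aligned with `kmers`.
lookup_unique_fwd <- function(index, kmers, max_loci = 1L) {
  first <- index$table[list(kmers), on = "kmer", mult = "first"]
  n <- index$counts[list(kmers), on = "kmer"]$n_loci
  n[is.na(n)] <- 0L
  bad <- n == 0L | n > max_loci
  list(chrom = ifelse(bad, NA_character_, first$chrom),
       pos = ifelse(bad, NA_integer_, first$pos))
}
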