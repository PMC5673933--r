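#' Detect head-to-tail back-splice junctions in one sample's reads
#'
#' Anchor split-mapping: for every read not explainable by a single
#' contiguous genome match, the terminal k-mers are looked up in the anchor
#' index. A read carries the head-to-tail signature when both anchors map
#' uniquely to the same chromosome and strand with the 5' anchor downstream
#' of the 3' anchor within `max_span`. Both anchors are then extended inward
#' and the breakpoint is placed at the leftmost genomic position consistent
#' with both extensions (the left-alignment tie-break for locally repetitive
#' junctions). One call per junction is emitted with the aggregated number
#' of supporting reads.
#'
#' Reads shorter than `2k` are skipped; reads whose anchors map to more
#' than `min_unique` loci are discarded as ambiguous. Counts of skipped /
#' ambiguous / linear reads are attached as attribute `"stats"`.
#'
#' @param reads named character vector of read sequences (one sample).
#' @param index an `anchor_index` from [index_genome()].
#' @param genome named character vector of chromosome sequences.
#' @param max_span maximum junction span in nt (default 2e6).
#' @param min_unique maximum number of loci an anchor may map to before the
#'   read is discarded (default 1: strictly unique).
#' @param require_gtag retain only junctions flanked by GT...AG on the call
#'   strand (default FALSE; synthetic genomes carry no splice motifs).
#' @param sample_id sample label attached to every call.
#' @return data.frame of calls: `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `read_count`, `sample_id`, `caller_id` (`"native"`).
#' @export
detect_backsplice <- function(reads, index, genome, max_span = 2e6,
                              min_unique = 1L, require_gtag = FALSE,
                              sample_id = "sample") {
  k <- index$k
  stats <- c(n_reads = length(reads), n_short = 0L, n_ambiguous = 0L,
             n_linear = 0L, n_unmapped = 0L)
  if (length(reads) == 0L) return(empty_calls(stats))
  lens <- nchar(reads)
  short <- lens < 2L * k
  stats["n_short"] <- sum(short)
  reads <- reads[!short]
  lens <- lens[!short]
  if (!length(reads)) return(empty_calls(stats))

  try1 <- split_map(reads, lens, index, genome, k, min_unique, "+")
  todo <- is.na(try1$status) | try1$status == "unmapped"
  if (any(todo)) {
    try2 <- split_map(revcomp(reads[todo]), lens[todo], index, genome, k,
                      min_unique, "-")
    for (fld in c("status", "chrom", "S", "E"))
      try1[[fld]][todo] <- try2[[fld]]
    try1$strand[todo] <- "-"
  }
  stats["n_linear"] <- sum(try1$status == "linear", na.rm = TRUE)
  stats["n_ambiguous"] <- sum(try1$status == "ambiguous", na.rm = TRUE)
  stats["n_unmapped"] <- sum(try1$status == "unmapped", na.rm = TRUE)
  hit <- which(try1$status == "call" &
               (try1$E - try1$S) <= max_span & try1$S >= 0L)
  if (!length(hit)) return(empty_calls(stats))
  calls <- data.frame(chrom = try1$chrom[hit], start = try1$S[hit],
                      end = try1$E[hit], strand = try1$strand[hit],
                      stringsAsFactors = FALSE)
  if (require_gtag) {
    keep <- gtag_ok(calls, genome)
    calls <- calls[keep, , drop = FALSE]
    if (!nrow(calls)) return(empty_calls(stats))
  }
  agg <- stats::aggregate(list(read_count = rep(1L, nrow(calls))),
                          calls, sum)
  agg <- agg[order(agg$chrom, agg$start, agg$end), , drop = FALSE]
  agg$sample_id <- sample_id
  agg$caller_id <- "native"
  rownames(agg) <- NULL
  attr(agg, "stats") <- stats
  agg[, c("chrom", "start", "end", "strand", "read_count", "sample_id",
          "caller_id")]
}

empty_calls <- function(stats = NULL) {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    strand = character(), read_count = integer(),
                    sample_id = character(), caller_id = character(),
                    stringsAsFactors = FALSE)
  if (!is.null(stats)) attr(out, "stats") <- stats
  out
}

# one orientation pass: returns per-read status and junction coordinates.
# status: "call", "linear" (contiguous match), "ambiguous" (multi-mapping
# anchor), "unmapped" (anchor absent in this orientation), "nosplit"
# (anchors mapped head-to-tail but no consistent breakpoint).
split_map <- function(reads, lens, index, genome, k, min_unique, strand) {
  n <- length(reads)
  a5 <- substr(reads, 1L, k)
  a3 <- substr(reads, lens - k + 1L, lens)
  lu5 <- lookup_unique_fwd(index, a5, min_unique)
  lu3 <- lookup_unique_fwd(index, a3, min_unique)
  # distinguish "absent" from "too many loci" for the ambiguous counter
  n5 <- index$counts[list(a5), on = "kmer"]$n_loci
  n3 <- index$counts[list(a3), on = "kmer"]$n_loci
  n5[is.na(n5)] <- 0L; n3[is.na(n3)] <- 0L
  status <- rep(NA_character_, n)
  S <- rep(NA_integer_, n); E <- rep(NA_integer_, n)
  chrom <- rep(NA_character_, n)
  status[n5 == 0L & n3 == 0L] <- "unmapped"
  status[is.na(status) & (n5 > min_unique | n3 > min_unique)] <- "ambiguous"
  open <- which(is.na(status) & !is.na(lu5$chrom) & !is.na(lu3$chrom))
  status[is.na(status)] <- "unmapped"  # one anchor absent
  for (i in open) {
    cs <- genome[[lu5$chrom[i]]]
    L <- lens[i]
    p5 <- lu5$pos[i]; p3 <- lu3$pos[i]
    # prefix extension from the 5' anchor locus
    g5 <- substr(cs, p5 + 1L, p5 + L)
    e5 <- prefix_match_len(reads[i], g5)
    if (e5 == L && p3 == p5 + L - k) { status[i] <- "linear"; next }
    if (lu5$chrom[i] != lu3$chrom[i] || p5 <= p3) {
      status[i] <- "unmapped"; next
    }
    # suffix extension ending at the 3' anchor's right edge
    g3_start <- max(0L, p3 + k - L)
    g3 <- substr(cs, g3_start + 1L, p3 + k)
    t <- suffix_match_len(reads[i], g3)
    e3 <- t - k
    s_lo <- max(k, L - k - e3)
    s_hi <- min(e5, L - k)
    if (s_lo > s_hi) { status[i] <- "nosplit"; next }
    s <- s_lo  # leftmost genomic representation
    status[i] <- "call"
    chrom[i] <- lu5$chrom[i]
    E[i] <- p5 + s
    S[i] <- p3 + k - (L - s)
  }
  list(status = status, chrom = chrom, S = S, E = E,
       strand = rep(strand, n))
}

# length of the common prefix of two strings
prefix_match_len <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0L)
  neq <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(neq)) neq[1L] - 1L else m
}

# length of the common suffix of two strings
suffix_match_len <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  m <- min(length(ra), length(rb))
  if (m == 0L) return(0L)
  neq <- which(ra[seq_len(m)] != rb[seq_len(m)])
  if (length(neq)) neq[1L] - 1L else m
}

# GT..AG flank check on the call strand
gtag_ok <- function(calls, genome) {
  vapply(seq_len(nrow(calls)), function(i) {
    cs <- genome[[calls$chrom[i]]]
    S <- calls$start[i]; E <- calls$end[i]
    if (calls$strand[i] == "+") {
      substr(cs, E + 1L, E + 2L) == "GT" &&
        S >= 2L && substr(cs, S - 1L, S) == "AG"
    } else {
      S >= 2L && substr(cs, S - 1L, S) == "AC" &&
        substr(cs, E + 1L, E + 2L) == "CT"
    }
  }, logical(1))
}

#' Run the caller over every sample of a simulated read set
#'
#' @param sim a `sim_reads` object (or a named list of read vectors).
#' @param index,genome,... passed to [detect_backsplice()].
#' @return data.frame of calls from all samples, row-bound.
#' @export
detect_samples <- function(sim, index, genome, ...) {
  reads_list <- if (inherits(sim, "sim_reads")) sim$reads else sim
  out <- lapply(names(reads_list), function(s)
    detect_backsplice(reads_list[[s]], index, genome, sample_id = s, ...))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
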