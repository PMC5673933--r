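#' Simulate junction-spanning and linear reads for every sample
#'
#' For each truth circRNA and sample, the number of junction reads is drawn
#' around the truth mean (NB, or Poisson when dispersion is 0) unless a
#' pre-drawn count matrix is supplied. Each junction read crosses the
#' back-splice point of the circ's spliced sequence, with the breakpoint
#' uniformly positioned at least `anchor_guard` nt from both read ends so an
#' anchor-based caller can always split-map it. Linear mRNA reads are added
#' as decoys. Reads are single-end; sequencing error is modelled as i.i.d.
#' substitutions.
#'
#' Circs whose spliced sequence is shorter than `read_len` are skipped with
#' a warning.
#'
#' @param genome named character vector of chromosome sequences.
#' @param transcripts exon table.
#' @param truth a `sim_truth`.
#' @param samples_per_group samples per group (default 8).
#' @param read_len read length in nt (default 150).
#' @param linear_depth expected number of decoy linear reads per transcript
#'   per sample (Poisson; default 2).
#' @param subst_rate per-base substitution probability, in \[0, 0.05\].
#' @param anchor_guard minimum distance of the breakpoint from either read
#'   end (default 20 nt; must be at least the caller's anchor length).
#' @param rng_seed integer seed; fixed seed gives byte-identical reads.
#' @param counts optional pre-drawn `circ_counts` whose rows are truth circ
#'   ids; its sample set overrides `samples_per_group`.
#' @return an object of class `sim_reads`: list with `reads` (named list
#'   sample_id -> named character vector of read sequences), `group`
#'   (named factor), `counts_truth` (circ x sample matrix of junction-read
#'   counts actually drawn), `read_len`.
#' @export
simulate_reads <- function(genome, transcripts, truth,
                           samples_per_group = 8L, read_len = 150L,
                           linear_depth = 2, subst_rate = 0,
                           anchor_guard = 20L, rng_seed = 1L,
                           counts = NULL) {
  if (subst_rate < 0 || subst_rate > 0.05)
    stop_invalid("subst_rate must be in [0, 0.05]")
  if (read_len < 2L * anchor_guard)
    stop_invalid("read_len must be >= 2 * anchor_guard")
  set.seed(assert_seed(rng_seed))
  if (is.null(counts))
    counts <- simulate_counts(truth, samples_per_group,
                              rng_seed = sample.int(2^31 - 1L, 1L))
  cm <- counts$counts
  group <- counts$group
  sample_ids <- colnames(cm)
  txs <- split_transcripts(transcripts)
  circs <- truth$circs
  # spliced sequence per circ; drop circs too short for a read
  spliced <- character(nrow(circs))
  for (i in seq_len(nrow(circs))) {
    spliced[i] <- spliced_sequence(genome, txs[[circs$transcript_id[i]]],
                                   circs$start[i], circs$end[i])
  }
  too_short <- nchar(spliced) < read_len
  if (any(too_short)) {
    warning(sprintf("skipping %d circ(s) with spliced length < read_len: %s",
                    sum(too_short),
                    paste(circs$circ_id[too_short], collapse = ", ")))
    cm[circs$circ_id[too_short], ] <- 0L
  }
  mrnas <- vapply(txs, function(tx) mrna_sequence(genome, tx), character(1))
  mrnas <- mrnas[nchar(mrnas) >= read_len]
  reads <- vector("list", length(sample_ids))
  names(reads) <- sample_ids
  for (s in sample_ids) {
    parts <- list()
    for (i in seq_len(nrow(circs))) {
      n <- cm[circs$circ_id[i], s]
      if (n == 0L) next
      sseq <- spliced[i]
      L <- nchar(sseq)
      b <- sample(seq(anchor_guard, read_len - anchor_guard), n,
                  replace = TRUE)
      rd <- paste0(substr(rep(sseq, n), L - b + 1L, L),
                   substr(rep(sseq, n), 1L, read_len - b))
      names(rd) <- sprintf("%s_%s_j%04d", s, circs$circ_id[i], seq_len(n))
      parts[[length(parts) + 1L]] <- rd
    }
    if (linear_depth > 0 && length(mrnas)) {
      nlin <- stats::rpois(length(mrnas), linear_depth)
      for (k in which(nlin > 0L)) {
        mlen <- nchar(mrnas[k])
        at <- sample(seq_len(mlen - read_len + 1L), nlin[k], replace = TRUE)
        rd <- substr(rep(mrnas[k], nlin[k]), at, at + read_len - 1L)
        names(rd) <- sprintf("%s_lin_%s_%04d", s, names(mrnas)[k],
                             seq_len(nlin[k]))
        parts[[length(parts) + 1L]] <- rd
      }
    }
    rds <- if (length(parts)) unlist(parts) else
      stats::setNames(character(), character())
    if (subst_rate > 0 && length(rds)) rds <- mutate_reads(rds, subst_rate)
    reads[[s]] <- rds
  }
  structure(list(reads = reads, group = group, counts_truth = cm,
                 read_len = read_len),
            class = "sim_reads")
}

# i.i.d. substitutions; a substituted base is always changed
mutate_reads <- function(reads, rate) {
  nm <- names(reads)
  mat <- do.call(rbind, strsplit(reads, ""))
  hit <- which(matrix(stats::runif(length(mat)) < rate, nrow = nrow(mat)))
  if (length(hit)) {
    repl <- vapply(mat[hit], function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    mat[hit] <- repl
  }
  out <- apply(mat, 1L, paste, collapse = "")
  names(out) <- nm
  out
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d samples, %d reads total, read length %d\n",
              length(x$reads), sum(lengths(x$reads)), x$read_len))
  invisible(x)
}

#' Write simulated reads as per-sample FASTQ files
#'
#' One file per sample, named `<sample_id>.fastq`; the sample id encodes the
#' group (e.g. `adjacent_s3.fastq`).
#'
#' @param sim a `sim_reads` object.
#' @param outdir output directory (created if missing).
#' @return invisible character vector of file paths.
#' @export
write_reads_fastq <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(sim$reads))
  for (i in seq_along(sim$reads)) {
    s <- names(sim$reads)[i]
    paths[i] <- file.path(outdir, paste0(s, ".fastq"))
    rds <- sim$reads[[i]]
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(rds), paths[i],
                                format = "fastq")
  }
  invisible(paths)
}

#' Read one FASTQ file as a named character vector of sequences
#'
#' @param path FASTQ file.
#' @return named character vector.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}
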