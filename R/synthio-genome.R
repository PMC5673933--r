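#' Generate a random genome
#'
#' Draws chromosome sequences uniformly over A/C/G/T. The genome is the
#' substrate for the synthetic gene models and reads used to exercise the
#' back-splice caller; it stands in for a reference assembly.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length length of every chromosome in nt (>= 1000).
#' @param rng_seed integer seed; identical seeds give byte-identical genomes.
#' @return named character vector of chromosome sequences
#'   (names `"chr1"`, `"chr2"`, ...).
#' @export
#' @examples
#' g <- generate_genome(1, 2000, rng_seed = 1)
#' nchar(g[["chr1"]])
generate_genome <- function(n_chrom, chrom_length, rng_seed) {
  if (!is.numeric(n_chrom) || n_chrom < 1)
    stop_invalid("n_chrom must be >= 1")
  if (!is.numeric(chrom_length) || chrom_length < 1000)
    stop_invalid("chrom_length must be >= 1000")
  set.seed(assert_seed(rng_seed))
  n_chrom <- as.integer(n_chrom)
  chrom_length <- as.integer(chrom_length)
  g <- vapply(seq_len(n_chrom), function(i) random_dna(chrom_length),
              character(1))
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

#' Write / read a genome as FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @return `write_genome_fasta` returns `path` invisibly; `read_genome_fasta`
#'   returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # keep only the first whitespace-delimited token of each FASTA header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Generate non-overlapping gene models on a genome
#'
#' Places `n_genes` single-transcript genes left-to-right on the genome's
#' chromosomes with random inter-gene gaps, alternating strand so that about
#' half the models are on each strand. Every transcript gets a CDS covering
#' its interior exons, leaving the terminal exons untranslated so that
#' 5'UTR/3'UTR origin classes are exercisable downstream.
#'
#' @param genome named character vector from [generate_genome()].
#' @param n_genes number of genes to place.
#' @param exons_per_gene integer range `c(min, max)` of exons per transcript.
#' @param exon_len integer range of exon lengths (nt).
#' @param intron_len integer range of intron lengths (nt).
#' @param rng_seed integer seed.
#' @return a `data.frame` with one row per exon and columns
#'   `transcript_id`, `gene_id`, `gene_symbol`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open genomic), `exon_rank` (ascending
#'   genomic order), `cds_start`, `cds_end`.
#' @export
generate_gene_models <- function(genome, n_genes,
                                 exons_per_gene = c(3L, 6L),
                                 exon_len = c(200L, 350L),
                                 intron_len = c(100L, 300L),
                                 rng_seed = 1L) {
  if (n_genes < 0) stop_invalid("n_genes must be >= 0")
  set.seed(assert_seed(rng_seed))
  if (n_genes == 0) return(empty_transcripts())
  chrom_names <- names(genome)
  chrom_len <- nchar(genome)
  cursor <- stats::setNames(rep(0L, length(genome)), chrom_names)
  rows <- vector("list", n_genes)
  ci <- 1L
  for (i in seq_len(n_genes)) {
    n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1L)
    ex_len <- sample(seq(exon_len[1], exon_len[2]), n_ex, replace = TRUE)
    in_len <- if (n_ex > 1)
      sample(seq(intron_len[1], intron_len[2]), n_ex - 1L, replace = TRUE)
    else integer()
    footprint <- sum(ex_len) + sum(in_len)
    gap <- sample(100:400, 1L)
    placed <- FALSE
    for (try in seq_along(chrom_names)) {
      chrom <- chrom_names[ci]
      at <- cursor[[chrom]] + gap
      if (at + footprint <= chrom_len[[chrom]]) {
        placed <- TRUE
        break
      }
      ci <- ci %% length(chrom_names) + 1L
    }
    if (!placed)
      stop_invalid("genome too small to place %d genes (failed at gene %d)",
                   n_genes, i)
    starts <- at + cumsum(c(0L, ex_len[-n_ex] + in_len))
    ends <- starts + ex_len
    cursor[[chrom]] <- ends[n_ex]
    ci <- ci %% length(chrom_names) + 1L
    strand <- if (i %% 2L == 1L) "+" else "-"
    cds <- interior_cds(starts, ends)
    rows[[i]] <- data.frame(
      transcript_id = sprintf("TX%04d", i),
      gene_id = sprintf("G%04d", i),
      gene_symbol = sprintf("GENE%d", i),
      chrom = chrom, strand = strand,
      start = starts, end = ends,
      exon_rank = seq_len(n_ex),
      cds_start = cds[1], cds_end = cds[2],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# CDS covering interior exons; degenerate gene shapes fall back to a CDS in
# the middle of the terminal exons so a CDS always exists.
interior_cds <- function(starts, ends) {
  n <- length(starts)
  if (n >= 3L) c(starts[2L], ends[n - 1L])
  else if (n == 2L) {
    c(starts[1L] + (ends[1L] - starts[1L]) %/% 2L,
      starts[2L] + (ends[2L] - starts[2L]) %/% 2L)
  } else {
    w <- ends[1L] - starts[1L]
    c(starts[1L] + w %/% 3L, starts[1L] + 2L * (w %/% 3L))
  }
}

empty_transcripts <- function() {
  data.frame(transcript_id = character(), gene_id = character(),
             gene_symbol = character(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             exon_rank = integer(), cds_start = integer(),
             cds_end = integer(), stringsAsFactors = FALSE)
}

# split an exon table into a list of per-transcript tables (genomic order)
split_transcripts <- function(transcripts) {
  split(transcripts, transcripts$transcript_id)
}

#' Write / read gene models as GTF
#'
#' Writes exon and CDS features with `gene_id`, `transcript_id` and
#' `gene_name` attributes. Coordinates are converted between the internal
#' 0-based half-open convention and GTF's 1-based inclusive one.
#'
#' @param transcripts exon table as returned by [generate_gene_models()].
#' @param path file path.
#' @return `write_gtf` returns `path` invisibly; `read_gtf` an exon table.
#' @export
write_gtf <- function(transcripts, path) {
  ex <- GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start + 1L,
                              end = transcripts$end),
    strand = transcripts$strand,
    type = "exon",
    gene_id = transcripts$gene_id,
    transcript_id = transcripts$transcript_id,
    gene_name = transcripts$gene_symbol,
    exon_number = as.character(transcripts$exon_rank),
    phase = NA_integer_
  )
  per_tx <- transcripts[!duplicated(transcripts$transcript_id), , drop = FALSE]
  has_cds <- !is.na(per_tx$cds_start)
  if (any(has_cds)) {
    cds_tx <- per_tx[has_cds, , drop = FALSE]
    cds <- GenomicRanges::GRanges(
      seqnames = cds_tx$chrom,
      ranges = IRanges::IRanges(start = cds_tx$cds_start + 1L,
                                end = cds_tx$cds_end),
      strand = cds_tx$strand,
      type = "CDS",
      gene_id = cds_tx$gene_id,
      transcript_id = cds_tx$transcript_id,
      gene_name = cds_tx$gene_symbol,
      exon_number = NA_character_,
      phase = 0L
    )
    gr <- c(ex, cds)
  } else gr <- ex
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' @rdname write_gtf
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_start <- stats::setNames(cds$start - 1L, cds$transcript_id)
  cds_end <- stats::setNames(cds$end, cds$transcript_id)
  # a transcript's CDS may be split over several CDS records; take the span
  if (nrow(cds)) {
    cds_start <- tapply(cds$start - 1L, cds$transcript_id, min)
    cds_end <- tapply(cds$end, cds$transcript_id, max)
  }
  out <- data.frame(
    transcript_id = as.character(ex$transcript_id),
    gene_id = as.character(ex$gene_id),
    gene_symbol = as.character(if (!is.null(ex$gene_name)) ex$gene_name
                               else ex$gene_id),
    chrom = as.character(ex$seqnames),
    strand = as.character(ex$strand),
    start = ex$start - 1L,
    end = ex$end,
    exon_rank = NA_integer_,
    cds_start = if (nrow(cds)) as.integer(cds_start[as.character(ex$transcript_id)])
                else NA_integer_,
    cds_end = if (nrow(cds)) as.integer(cds_end[as.character(ex$transcript_id)])
              else NA_integer_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  out$exon_rank <- stats::ave(out$start, out$transcript_id,
                              FUN = seq_along)
  rownames(out) <- NULL
  out
}
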