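# Junction annotation: host transcript resolution, origin classification,
# transcript-level features (exon count, spliced length/sequence) and
# dataset summaries.

ORIGIN_CLASSES <- c("exonic_cds", "exonic_utr5", "exonic_utr3",
                    "intronic", "intergenic", "exon_intron")

#' Resolve the host transcript of a junction
#'
#' Among transcripts overlapping the junction interval on the same strand,
#' prefers one whose exon boundaries coincide with both junction endpoints
#' (`boundary_match = TRUE`). Ties are broken by the number of exons fully
#' inside the junction, then total contained exon length, then transcript
#' id. Returns `NULL` host for junctions in gene deserts.
#'
#' @param junction list/one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param transcripts exon table.
#' @return list with `transcript_id` (or `NA`), `gene_id`, `gene_symbol`,
#'   `boundary_match` (logical).
#' @export
assign_host <- function(junction, transcripts) {
  tx_span <- span_table(transcripts)
  hit <- tx_span[tx_span$chrom == junction$chrom &
                 tx_span$strand == junction$strand &
                 tx_span$span_start < junction$end &
                 tx_span$span_end > junction$start, , drop = FALSE]
  if (nrow(hit) == 0L)
    return(list(transcript_id = NA_character_, gene_id = NA_character_,
                gene_symbol = NA_character_, boundary_match = FALSE))
  txs <- split_transcripts(transcripts)
  score <- lapply(hit$transcript_id, function(tid) {
    tx <- txs[[tid]]
    bm <- any(tx$start == junction$start) && any(tx$end == junction$end)
    inside <- contained_exons(tx, junction$start, junction$end)
    list(bm = bm, n_inside = nrow(inside),
         len = sum(inside$end - inside$start))
  })
  ord <- order(!vapply(score, `[[`, logical(1), "bm"),
               -vapply(score, `[[`, integer(1), "n_inside"),
               -vapply(score, `[[`, numeric(1), "len"),
               hit$transcript_id)
  best <- hit$transcript_id[ord[1]]
  tx <- txs[[best]]
  list(transcript_id = best, gene_id = tx$gene_id[1],
       gene_symbol = tx$gene_symbol[1],
       boundary_match = score[[ord[1]]]$bm)
}

span_table <- function(transcripts) {
  dt <- data.table::as.data.table(transcripts)
  as.data.frame(dt[, list(chrom = chrom[1], strand = strand[1],
                          span_start = min(start), span_end = max(end)),
                   by = "transcript_id"])
}

#' Classify the origin of a junction
#'
#' Classes: `intergenic` (no host), `intronic` (both endpoints inside one
#' intron of the host), `exonic_cds` / `exonic_utr5` / `exonic_utr3`
#' (boundary-matched, sub-typed by the contained exons' overlap with the
#' host CDS: any CDS overlap wins, else entirely within the 5'UTR, else
#' 3'UTR), and `exon_intron` for all remaining host-overlapping shapes
#' (one endpoint exonic, one intronic, and other non-boundary-matched
#' overlaps). The classification is total: every junction gets exactly one
#' class. Hosts without an annotated CDS are treated as coding over their
#' whole span for sub-typing purposes.
#'
#' @param junction as in [assign_host()].
#' @param transcripts exon table.
#' @param host result of [assign_host()] (computed if missing).
#' @return single character, one of [ORIGIN_CLASSES].
#' @export
classify_origin <- function(junction, transcripts, host = NULL) {
  if (is.null(host)) host <- assign_host(junction, transcripts)
  if (is.na(host$transcript_id)) return("intergenic")
  tx <- split_transcripts(transcripts)[[host$transcript_id]]
  s <- junction$start; e <- junction$end
  if (host$boundary_match) {
    inside <- contained_exons(tx, s, e)
    cds <- c(tx$cds_start[1], tx$cds_end[1])
    if (is.na(cds[1])) cds <- c(min(tx$start), max(tx$end))
    if (any(inside$start < cds[2] & inside$end > cds[1]))
      return("exonic_cds")
    # UTR side: 5'UTR is upstream of the CDS in transcript orientation
    utr5 <- if (tx$strand[1] == "+") all(inside$end <= cds[1])
            else all(inside$start >= cds[2])
    return(if (utr5) "exonic_utr5" else "exonic_utr3")
  }
  # intron index containing a point, or NA when the point is exonic /
  # outside the transcript body
  in_intron <- function(p) {
    n <- nrow(tx)
    if (n < 2L) return(NA_integer_)
    for (i in seq_len(n - 1L)) {
      if (p >= tx$end[i] && p < tx$start[i + 1L]) return(i)
    }
    NA_integer_
  }
  i1 <- in_intron(s)
  i2 <- in_intron(e - 1L)  # rightmost base covered
  if (!is.na(i1) && !is.na(i2) && i1 == i2) return("intronic")
  "exon_intron"
}

#' Transcript features of a boundary-matched junction
#'
#' @param junction as in [assign_host()].
#' @param transcripts exon table.
#' @param genome named character vector (omit to skip the sequence).
#' @param host result of [assign_host()] (computed if missing).
#' @param length_mode `"spliced"` (sum of contained exon lengths, the
#'   native definition) or `"genomic_span"` (`end - start`, the convention
#'   some databases report).
#' @return list `n_exons`, `spliced_length`, `spliced_sequence` (all `NA`
#'   when the junction is not boundary-matched).
#' @export
transcript_features <- function(junction, transcripts, genome = NULL,
                                host = NULL,
                                length_mode = c("spliced", "genomic_span")) {
  length_mode <- match.arg(length_mode)
  if (is.null(host)) host <- assign_host(junction, transcripts)
  if (is.na(host$transcript_id) || !host$boundary_match)
    return(list(n_exons = NA_integer_, spliced_length = NA_integer_,
                spliced_sequence = NA_character_))
  tx <- split_transcripts(transcripts)[[host$transcript_id]]
  inside <- contained_exons(tx, junction$start, junction$end)
  if (nrow(inside) == 0L)
    stop("boundary-matched junction contains no exons (inconsistent models)")
  len <- if (length_mode == "spliced") sum(inside$end - inside$start)
         else junction$end - junction$start
  seq <- if (is.null(genome)) NA_character_
         else spliced_sequence(genome, tx, junction$start, junction$end)
  list(n_exons = nrow(inside), spliced_length = as.integer(len),
       spliced_sequence = seq)
}

#' Annotate a set of junctions against gene models
#'
#' Runs host assignment, origin classification and feature extraction for
#' every distinct junction in `calls`.
#'
#' @param calls call data.frame (distinct junctions are taken over
#'   `chrom`, `start`, `end`, `strand`).
#' @param transcripts exon table.
#' @param genome optional named character vector; when given, spliced
#'   sequences are extracted.
#' @param length_mode see [transcript_features()].
#' @return data.frame with one row per distinct junction: `circ_id`,
#'   `chrom`, `start`, `end`, `strand`, `host_gene`, `host_gene_id`,
#'   `host_transcript`, `boundary_match`, `origin`, `n_exons`,
#'   `spliced_length`, `spliced_sequence`.
#' @export
annotate_junctions <- function(calls, transcripts, genome = NULL,
                               length_mode = "spliced") {
  j <- unique(calls[, c("chrom", "start", "end", "strand")])
  rows <- lapply(seq_len(nrow(j)), function(i) {
    junction <- j[i, ]
    host <- assign_host(junction, transcripts)
    origin <- classify_origin(junction, transcripts, host)
    feats <- transcript_features(junction, transcripts, genome, host,
                                 length_mode)
    data.frame(
      circ_id = native_circ_id(junction$chrom, junction$start,
                               junction$end, junction$strand),
      chrom = junction$chrom, start = junction$start, end = junction$end,
      strand = junction$strand,
      host_gene = host$gene_symbol, host_gene_id = host$gene_id,
      host_transcript = host$transcript_id,
      boundary_match = host$boundary_match, origin = origin,
      n_exons = feats$n_exons, spliced_length = feats$spliced_length,
      spliced_sequence = feats$spliced_sequence,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- empty_annotation()
  out
}

empty_annotation <- function() {
  data.frame(circ_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), host_gene = character(),
             host_gene_id = character(), host_transcript = character(),
             boundary_match = logical(), origin = character(),
             n_exons = integer(), spliced_length = integer(),
             spliced_sequence = character(), stringsAsFactors = FALSE)
}

#' Summaries of an annotated circRNA set
#'
#' @param circs annotated data.frame from [annotate_junctions()].
#' @return list of data.frames: `by_origin` (origin class counts),
#'   `by_chrom` (per-chromosome counts), `exon_histogram` (n_exons counts
#'   over boundary-matched circs), `isoforms_per_gene` (gene_id, symbol,
#'   distinct circ count, descending).
#' @export
summarize_circs <- function(circs) {
  by_origin <- as.data.frame(table(factor(circs$origin,
                                          levels = ORIGIN_CLASSES)),
                             stringsAsFactors = FALSE)
  names(by_origin) <- c("origin", "n")
  count_table <- function(values, name) {
    if (length(values) == 0L) {
      out <- data.frame(x = character(), n = integer(),
                        stringsAsFactors = FALSE)
    } else {
      out <- as.data.frame(table(values), stringsAsFactors = FALSE)
    }
    names(out) <- c(name, "n")
    out
  }
  by_chrom <- count_table(circs$chrom, "chrom")
  eh <- count_table(circs$n_exons[!is.na(circs$n_exons)], "n_exons")
  if (nrow(eh)) eh$n_exons <- as.integer(eh$n_exons)
  hosted <- circs[!is.na(circs$host_gene_id), , drop = FALSE]
  iso <- if (nrow(hosted)) {
    dt <- data.table::as.data.table(hosted)
    as.data.frame(dt[, list(gene_symbol = host_gene[1],
                            n_isoforms = length(unique(circ_id))),
                     by = "host_gene_id"][order(-n_isoforms, host_gene_id)])
  } else data.frame(host_gene_id = character(), gene_symbol = character(),
                    n_isoforms = integer(), stringsAsFactors = FALSE)
  list(by_origin = by_origin, by_chrom = by_chrom, exon_histogram = eh,
       isoforms_per_gene = iso)
}

#' Write annotated circRNAs as TSV and their spliced sequences as FASTA
#'
#' @param circs annotated data.frame.
#' @param tsv_path,fasta_path output paths (`NULL` to skip either).
#' @return invisible list of written paths.
#' @export
write_annotation <- function(circs, tsv_path = NULL, fasta_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(circs, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(fasta_path)) {
    has_seq <- !is.na(circs$spliced_sequence)
    seqs <- Biostrings::DNAStringSet(
      stats::setNames(circs$spliced_sequence[has_seq],
                      circs$circ_id[has_seq]))
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(list(tsv = tsv_path, fasta = fasta_path))
}
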