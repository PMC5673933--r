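# miRNA sponge-candidate nomination: validated-interaction lookup,
# seed-complement counting in the circularized spliced sequence, and
# intersection with a differentially-expressed miRNA list.

#' Extract the seed of a mature miRNA
#'
#' The seed is the substring at 1-based positions `definition[1]` to
#' `definition[2]` of the mature sequence (default 2-8, the canonical 7-nt
#' seed). `T` is accepted and normalized to `U`.
#'
#' @param mature_seq mature miRNA sequence (RNA or DNA alphabet), 18-26 nt
#'   for real miRNAs; anything of length >= `definition[2]` is accepted.
#' @param definition integer pair of 1-based positions, default `c(2, 8)`.
#' @return seed sequence in the RNA alphabet.
#' @export
#' @examples
#' seed_of("UGGAAUGUAAAGAAGUAUGUAU")  # "GGAAUGU"
seed_of <- function(mature_seq, definition = c(2L, 8L)) {
  s <- toupper(chartr("T", "U", mature_seq))
  if (!grepl("^[ACGU]+$", s))
    stop_invalid("mature sequence contains characters outside A/C/G/U(T)")
  if (nchar(s) < definition[2])
    stop_invalid("mature sequence shorter than seed definition end (%d nt)",
                 definition[2])
  substr(s, definition[1], definition[2])
}

#' Count seed-complement sites in a (circularized) spliced sequence
#'
#' The target motif is the reverse complement of the seed, in the DNA
#' alphabet. Counted are distinct start positions p in `[0, L)`; with
#' `circular = TRUE` the sequence is extended by its own first
#' `seed_len - 1` characters first, so sites spanning the back-splice
#' junction are found. Overlapping occurrences count as distinct sites.
#'
#' @param spliced_sequence DNA sequence of the circRNA (transcription order).
#' @param seed seed sequence (RNA or DNA alphabet).
#' @param circular scan wrap-aware (default TRUE; a circle has no ends).
#' @return non-negative integer site count.
#' @export
count_seed_matches <- function(spliced_sequence, seed, circular = TRUE) {
  seed_rna <- toupper(chartr("T", "U", seed))
  if (!grepl("^[ACGU]+$", seed_rna))
    stop_invalid("seed contains characters outside A/C/G/U(T)")
  motif <- revcomp(chartr("U", "T", seed_rna))
  L <- nchar(spliced_sequence)
  w <- nchar(motif)
  if (L < w) stop_invalid("sequence shorter than the seed")
  subject <- if (circular)
    paste0(spliced_sequence, substr(spliced_sequence, 1L, w - 1L))
  else spliced_sequence
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(subject))
  sum(BiocGenerics::start(hits) <= L)
}

#' Nominate miRNA sponge candidates
#'
#' Applies the three-filter procedure to the most expressed circRNAs:
#' (1) the miRNA must have a validated interaction with the circRNA-derived
#' host gene; (2) at least one seed-complement site must occur in the
#' circularized spliced sequence; (3) the miRNA must be on the supplied
#' differentially-expressed miRNA list. One candidate row is emitted per
#' surviving (circRNA, miRNA) pair.
#'
#' @param circs data.frame of annotated circRNAs (needs `circ_id`,
#'   `host_gene`, `spliced_sequence`; see [annotate_junctions()]). Restrict
#'   to the top expressed circs beforehand (e.g. via [top_expressed()]), or
#'   pass everything to scan all.
#' @param mirnas data.frame with `mirna_id`, `mature_seq`.
#' @param interactions data.frame with `mirna_id`, `gene_symbol` (validated
#'   miRNA-target rows; duplicate pairs are collapsed).
#' @param de_mirnas data.frame with `mirna_id` and optionally `direction`,
#'   or a character vector of DE miRNA ids.
#' @param seed_definition passed to [seed_of()].
#' @param circular wrap-aware scanning (default TRUE).
#' @return data.frame with columns `circ_id`, `host_gene`, `mirna_id`,
#'   `n_seed_matches`, `mirna_is_de`, `direction`; one row per candidate,
#'   all with `n_seed_matches >= 1` and `mirna_is_de = TRUE`.
#' @export
candidate_mirnas <- function(circs, mirnas, interactions, de_mirnas,
                             seed_definition = c(2L, 8L), circular = TRUE) {
  de_df <- if (is.character(de_mirnas))
    data.frame(mirna_id = de_mirnas, direction = NA_character_,
               stringsAsFactors = FALSE)
  else de_mirnas
  if (is.null(de_df$direction)) de_df$direction <- NA_character_
  interactions <- unique(interactions[c("mirna_id", "gene_symbol")])
  out <- list()
  for (i in seq_len(nrow(circs))) {
    circ <- circs[i, ]
    if (is.na(circ$spliced_sequence) || is.na(circ$host_gene)) {
      warning(sprintf("circ %s lacks spliced sequence or host gene; skipped",
                      circ$circ_id))
      next
    }
    hit_mirnas <- interactions$mirna_id[
      interactions$gene_symbol == circ$host_gene]
    for (mid in hit_mirnas) {
      mseq <- mirnas$mature_seq[mirnas$mirna_id == mid]
      if (length(mseq) == 0L) next
      n <- count_seed_matches(circ$spliced_sequence,
                              seed_of(mseq[1], seed_definition),
                              circular = circular)
      if (n < 1L) next
      de_row <- match(mid, de_df$mirna_id)
      if (is.na(de_row)) next
      out[[length(out) + 1L]] <- data.frame(
        circ_id = circ$circ_id, host_gene = circ$host_gene,
        mirna_id = mid, n_seed_matches = n, mirna_is_de = TRUE,
        direction = de_df$direction[de_row], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(circ_id = character(), host_gene = character(),
                      mirna_id = character(), n_seed_matches = integer(),
                      mirna_is_de = logical(), direction = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a miRNA FASTA into a data.frame
#'
#' @param path FASTA of mature miRNA sequences.
#' @return data.frame with `mirna_id`, `mature_seq` (RNA alphabet).
#' @export
read_mirna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  data.frame(mirna_id = sub("\\s.*$", "", names(x)),
             mature_seq = chartr("T", "U", toupper(as.character(x))),
             stringsAsFactors = FALSE)
}

#' Write mature miRNA sequences as FASTA
#' @param mirnas data.frame with `mirna_id`, `mature_seq`.
#' @param path output file.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  x <- Biostrings::BStringSet(stats::setNames(mirnas$mature_seq,
                                              mirnas$mirna_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
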