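# Spliced-sequence extraction shared by the read simulator, the annotator
# and the sponge planting code.

# exon rows of one transcript fully contained in [start, end)
contained_exons <- function(tx_exons, start, end) {
  tx_exons[tx_exons$start >= start & tx_exons$end <= end, , drop = FALSE]
}

# concatenated exon sequence in transcription order for the exons of one
# transcript fully inside [start, end); reverse-complemented on "-"
spliced_sequence <- function(genome, tx_exons, start, end) {
  ex <- contained_exons(tx_exons, start, end)
  if (nrow(ex) == 0L) return(NA_character_)
  chrom_seq <- genome[[ex$chrom[1]]]
  parts <- seq_slice(chrom_seq, ex$start, ex$end)
  s <- paste(parts, collapse = "")
  if (ex$strand[1] == "-") revcomp(s) else s
}

# full mature mRNA (all exons) of a transcript, transcription order
mrna_sequence <- function(genome, tx_exons) {
  spliced_sequence(genome, tx_exons, min(tx_exons$start), max(tx_exons$end))
}
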