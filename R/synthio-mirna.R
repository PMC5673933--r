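# Synthetic miRNA resources: mature sequences, a validated-interaction
# table, a DE-miRNA list, and seed-complement sites written into the genome
# so that each planted (circ, miRNA) pair carries an exact number of sites
# in the circ's spliced sequence.

#' Generate synthetic miRNA resources with planted seed sites
#'
#' For each planted `(circ_id, n_sites)` row a fresh miRNA is drawn and
#' exactly `n_sites` seed-complement sites are written into exon interiors
#' of that circ (each site at least a seed length away from the back-splice
#' breakpoint, unless a wrap site is requested, which is placed across the
#' junction). Every planted miRNA gets a validated-interaction row with the
#' circ's host gene and an entry on the DE-miRNA list. Three negative
#' controls are added: a miRNA with a site but no interaction row, one with
#' an interaction but no site, and one with site + interaction but absent
#' from the DE list. Each planted pair is verified against the seed-match
#' scanner; miRNAs producing spurious extra matches are re-drawn.
#'
#' Because sites are written into the genome, downstream stages must use the
#' `genome` element of the return value.
#'
#' @param genome named character vector of chromosome sequences.
#' @param transcripts exon table.
#' @param truth a `sim_truth`; planted circ ids must exist in it.
#' @param n_mirna total number of miRNAs to emit (planted + controls +
#'   unrelated padding). `0` gives empty resources.
#' @param planted_sites data.frame with columns `circ_id`, `n_sites` and
#'   optionally `wrap` (logical: one of the sites spans the junction).
#' @param rng_seed integer seed.
#' @param seed_definition seed positions, default `c(2, 8)`.
#' @return list with `mirnas` (data.frame `mirna_id`, `mature_seq`),
#'   `interactions` (`mirna_id`, `gene_symbol`, `evidence`), `de_mirnas`
#'   (`mirna_id`, `direction`), `genome` (updated sequences), `truth`
#'   (input truth with `planted_sites` filled in).
#' @export
generate_mirna_resources <- function(genome, transcripts, truth,
                                     n_mirna = 10L,
                                     planted_sites = NULL,
                                     rng_seed = 1L,
                                     seed_definition = c(2L, 8L)) {
  set.seed(assert_seed(rng_seed))
  empty <- list(
    mirnas = data.frame(mirna_id = character(), mature_seq = character(),
                        stringsAsFactors = FALSE),
    interactions = data.frame(mirna_id = character(),
                              gene_symbol = character(),
                              evidence = character(),
                              stringsAsFactors = FALSE),
    de_mirnas = data.frame(mirna_id = character(), direction = character(),
                           stringsAsFactors = FALSE),
    genome = genome, truth = truth)
  if (n_mirna == 0L) return(empty)
  if (is.null(planted_sites))
    planted_sites <- data.frame(circ_id = character(), n_sites = integer())
  if (is.null(planted_sites$wrap) && nrow(planted_sites))
    planted_sites$wrap <- FALSE
  bad <- setdiff(planted_sites$circ_id, truth$circs$circ_id)
  if (length(bad))
    stop_invalid("planted sites reference unknown circ(s): %s",
                 paste(bad, collapse = ", "))
  txs <- split_transcripts(transcripts)
  state <- list(genome = genome,
                used = list())  # circ_id -> matrix of used spliced intervals
  mirnas <- list(); interactions <- list(); de <- list(); planted <- list()
  seed_len <- seed_definition[2] - seed_definition[1] + 1L

  plant_one <- function(circ_id, k, wrap) {
    circ <- truth$circs[truth$circs$circ_id == circ_id, ]
    tx <- txs[[circ$transcript_id]]
    ex <- contained_exons(tx, circ$start, circ$end)
    L <- sum(ex$end - ex$start)
    mirna_id <- sprintf("syn-miR-%d", length(mirnas) + 1L)
    for (try in 1:50) {
      mature <- paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
                      collapse = "")
      seed <- seed_of(mature, seed_definition)
      motif <- revcomp(chartr("U", "T", seed))
      sseq <- spliced_sequence(state$genome, tx, circ$start, circ$end)
      if (count_seed_matches(sseq, seed, circular = TRUE) != 0L) next
      pos <- draw_site_positions(ex, L, k, wrap, seed_len,
                                 state$used[[circ_id]])
      if (is.null(pos)) stop_invalid(
        "cannot place %d sites of length %d in circ %s (spliced length %d)",
        k, seed_len, circ_id, L)
      g2 <- state$genome
      for (p in pos) {
        if (p + seed_len - 1L <= L) {
          g2 <- write_spliced(g2, ex, p, motif)
        } else {  # wrap site: split across the back-splice junction
          t1 <- L - p + 1L
          g2 <- write_spliced(g2, ex, p, substr(motif, 1L, t1))
          g2 <- write_spliced(g2, ex, 1L, substr(motif, t1 + 1L, seed_len))
        }
      }
      sseq2 <- spliced_sequence(g2, tx, circ$start, circ$end)
      if (count_seed_matches(sseq2, seed, circular = TRUE) == k &&
          (!any(pos + seed_len - 1L > L) ||
           count_seed_matches(sseq2, seed, circular = FALSE) == k - 1L)) {
        state$genome <<- g2
        state$used[[circ_id]] <<- rbind(state$used[[circ_id]],
                                        cbind(pos, pos + seed_len - 1L))
        return(list(mirna_id = mirna_id, mature = mature))
      }
    }
    stop_invalid("failed to plant %d clean sites for circ %s", k, circ_id)
  }

  for (i in seq_len(nrow(planted_sites))) {
    row <- planted_sites[i, ]
    if (row$n_sites > 0 || isTRUE(row$wrap)) {
      k <- max(row$n_sites, if (isTRUE(row$wrap)) 1L else 0L)
      m <- plant_one(row$circ_id, k, isTRUE(row$wrap))
    } else {
      # zero planted sites: a miRNA verified to have no match in this circ
      circ <- truth$circs[truth$circs$circ_id == row$circ_id, ]
      tx <- txs[[circ$transcript_id]]
      repeat {
        mature <- paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
                        collapse = "")
        sseq <- spliced_sequence(state$genome, tx, circ$start, circ$end)
        if (count_seed_matches(sseq, seed_of(mature, seed_definition),
                               circular = TRUE) == 0L) break
      }
      m <- list(mirna_id = sprintf("syn-miR-%d", length(mirnas) + 1L),
                mature = mature)
    }
    host <- truth$circs$gene_symbol[truth$circs$circ_id == row$circ_id]
    mirnas[[m$mirna_id]] <- m$mature
    interactions[[length(interactions) + 1L]] <-
      data.frame(mirna_id = m$mirna_id, gene_symbol = host,
                 evidence = "synthetic-validated", stringsAsFactors = FALSE)
    de[[length(de) + 1L]] <-
      data.frame(mirna_id = m$mirna_id,
                 direction = sample(c("up", "down"), 1L),
                 stringsAsFactors = FALSE)
    planted[[length(planted) + 1L]] <-
      data.frame(circ_id = row$circ_id, mirna_id = m$mirna_id,
                 n_sites = row$n_sites, stringsAsFactors = FALSE)
  }

  # negative controls, anchored on the first truth circ when available
  if (nrow(truth$circs)) {
    anchor <- truth$circs$circ_id[1]
    host <- truth$circs$gene_symbol[1]
    # site but no interaction row
    m <- plant_one(anchor, 1L, FALSE)
    mirnas[["syn-miR-noint"]] <- m$mature
    names(mirnas)[length(mirnas)] <- "syn-miR-noint"
    de[[length(de) + 1L]] <- data.frame(mirna_id = "syn-miR-noint",
                                        direction = "up",
                                        stringsAsFactors = FALSE)
    planted[[length(planted) + 1L]] <-
      data.frame(circ_id = anchor, mirna_id = "syn-miR-noint", n_sites = 1L,
                 stringsAsFactors = FALSE)
    # interaction + DE but no site
    circ1 <- truth$circs[1, ]
    tx1 <- txs[[circ1$transcript_id]]
    repeat {
      mature <- paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
                      collapse = "")
      sseq <- spliced_sequence(state$genome, tx1, circ1$start, circ1$end)
      if (count_seed_matches(sseq, seed_of(mature, seed_definition),
                             circular = TRUE) == 0L) break
    }
    mirnas[["syn-miR-nosite"]] <- mature
    interactions[[length(interactions) + 1L]] <-
      data.frame(mirna_id = "syn-miR-nosite", gene_symbol = host,
                 evidence = "synthetic-validated", stringsAsFactors = FALSE)
    de[[length(de) + 1L]] <- data.frame(mirna_id = "syn-miR-nosite",
                                        direction = "down",
                                        stringsAsFactors = FALSE)
    # interaction + site but not differentially expressed
    m <- plant_one(anchor, 1L, FALSE)
    mirnas[["syn-miR-node"]] <- m$mature
    names(mirnas)[length(mirnas)] <- "syn-miR-node"
    interactions[[length(interactions) + 1L]] <-
      data.frame(mirna_id = "syn-miR-node", gene_symbol = host,
                 evidence = "synthetic-validated", stringsAsFactors = FALSE)
    planted[[length(planted) + 1L]] <-
      data.frame(circ_id = anchor, mirna_id = "syn-miR-node", n_sites = 1L,
                 stringsAsFactors = FALSE)
  }

  # unrelated padding miRNAs up to n_mirna
  while (length(mirnas) < n_mirna) {
    mid <- sprintf("syn-miR-pad-%d", length(mirnas) + 1L)
    mirnas[[mid]] <- paste(sample(c("A", "C", "G", "U"),
                                  sample(21:22, 1L), replace = TRUE),
                           collapse = "")
  }

  mir_df <- data.frame(mirna_id = names(mirnas),
                       mature_seq = unlist(mirnas, use.names = FALSE),
                       stringsAsFactors = FALSE)
  int_df <- if (length(interactions)) do.call(rbind, interactions)
            else empty$interactions
  de_df <- if (length(de)) do.call(rbind, de) else empty$de_mirnas
  truth$planted_sites <- if (length(planted)) do.call(rbind, planted)
                         else truth$planted_sites
  list(mirnas = mir_df, interactions = int_df, de_mirnas = de_df,
       genome = state$genome, truth = truth)
}

# choose k non-overlapping site positions (1-based spliced coordinates);
# interior sites keep >= seed_len distance from both spliced ends; a wrap
# site starts in (L - seed_len, L]. Returns NULL if placement fails.
draw_site_positions <- function(ex, L, k, wrap, seed_len, used) {
  # positions whose [p, p + seed_len) stays inside one exon, away from ends
  widths <- ex$end - ex$start
  offs <- cumsum(c(0L, widths))
  ok <- integer()
  for (i in seq_len(nrow(ex))) {
    lo <- offs[i] + 1L + seed_len      # >= seed_len from exon start
    hi <- offs[i + 1L] - 2L * seed_len # and from exon end
    if (hi >= lo) ok <- c(ok, lo:hi)
  }
  # spliced-orientation position on "-" strand transcripts maps through the
  # same exon-offset arithmetic because write_spliced() handles the flip
  n_interior <- if (wrap) k - 1L else k
  pos <- integer()
  avail <- ok
  for (j in seq_len(n_interior)) {
    if (!length(avail)) return(NULL)
    p <- sample(avail, 1L)
    pos <- c(pos, p)
    avail <- avail[abs(avail - p) >= seed_len]
  }
  if (wrap) {
    split_at <- sample(seq_len(seed_len - 1L), 1L)
    pos <- c(pos, L - split_at + 1L)
  }
  if (!is.null(used) && nrow(used)) {
    for (p in pos) {
      if (any(p <= used[, 2] & p + seed_len - 1L >= used[, 1])) return(NULL)
    }
  }
  pos
}

# write `piece` (spliced orientation, DNA) into the genome at spliced
# position `s` (1-based) of the circ whose contained exons are `ex`
# (genomic ascending). The piece must lie within one exon in concatenated
# coordinates; the strand flip for "-" transcripts is handled here.
write_spliced <- function(genome, ex, s, piece) {
  widths <- ex$end - ex$start
  L <- sum(widths)
  l <- nchar(piece)
  if (ex$strand[1] == "-") {
    content <- revcomp(piece)
    cstart <- L - s - l + 2L
  } else {
    content <- piece
    cstart <- s
  }
  offs <- cumsum(c(0L, widths))
  i <- findInterval(cstart, offs + 1L)
  if (cstart + l - 1L > offs[i + 1L])
    stop_invalid("planted site crosses an exon boundary (internal error)")
  g0 <- ex$start[i] + (cstart - offs[i] - 1L)
  chrom <- ex$chrom[1]
  seqs <- genome
  substr(seqs[[chrom]], g0 + 1L, g0 + l) <- content
  seqs
}

#' Write / read the interaction and DE-miRNA tables as TSV
#'
#' @param x data.frame (`interactions`: mirna_id, gene_symbol, evidence;
#'   `de_mirnas`: mirna_id, direction).
#' @param path file path.
#' @return the data.frame (readers) or `path` invisibly (writers).
#' @export
write_interactions_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_interactions_tsv
#' @export
read_interactions_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
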