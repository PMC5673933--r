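# Truth-set construction for the synthetic study. Truth junctions always
# coincide with exon boundaries of their host transcript, so a perfect
# caller + annotator recovers them exactly.

#' Group abundance multipliers for the field-effect preset
#'
#' The three-group design models field cancerization: tumor-adjacent tissue
#' carries the most circRNA signal, tumor less, and no-cancer mucosa least.
#' The default multipliers (adjacent 1, tumor 0.35, no-cancer 0.1) follow the
#' roughly 620:220:66 ratio of detected circRNAs across the three tissue
#' groups that motivates the preset.
#' @keywords internal
FIELD_EFFECT_MULTIPLIERS <- c(no_cancer = 0.1, adjacent = 1, tumor = 0.35)

GROUP_LEVELS <- c("no_cancer", "adjacent", "tumor")

#' Generate a circRNA truth set
#'
#' Selects runs of consecutive exons from the supplied gene models as truth
#' back-splice junctions, assigns per-group mean junction-read counts under a
#' group profile, and optionally plants fold changes between the no-cancer
#' group and the pooled adjacent+tumor groups.
#'
#' Under `group_profile = "field_effect"` per-group means are the base mean
#' scaled by [FIELD_EFFECT_MULTIPLIERS], so expected detectability is ordered
#' adjacent > tumor > no-cancer. Under `"null"` all groups share the base
#' mean. Base means default to a right-skewed mixture (most circRNAs have
#' single-digit expected junction reads, a ~10% tail is roughly eightfold
#' higher), matching the observed shape of junction-read counts in tissue;
#' pass `base_mean = c(lo, hi)` for uniform means instead.
#'
#' @param transcripts exon table from [generate_gene_models()].
#' @param n_circ number of truth circRNAs.
#' @param group_profile `"field_effect"` or `"null"`.
#' @param fold_change_spec `NULL`, or `list(n =, fc =)` to plant fold
#'   changes (pooled / no-cancer ratio) on `n` randomly chosen circs cycling
#'   through the values in `fc`, or a named numeric vector keyed by circ id.
#' @param rng_seed integer seed.
#' @param base_mean `NULL` (skewed mixture) or numeric range `c(lo, hi)`.
#' @param group_multipliers named multipliers for the field-effect preset.
#' @param isoforms when `TRUE` (default), guarantee at least one host gene
#'   with two distinct circRNA isoforms when capacity allows.
#' @param dispersion NB dispersion attached to the truth (used by the count
#'   and read simulators); defaults to 0.2 for `field_effect`, 0 (Poisson)
#'   for `null`.
#' @param genome optional named character vector; when supplied, candidate
#'   exon runs whose junction is left-shift ambiguous (the genomic base just
#'   before the acceptor equals the base just before the donor end, so a
#'   left-aligning caller would report a shifted coordinate) are excluded,
#'   making truth junctions exactly recoverable.
#' @param max_exons_per_circ longest run of consecutive exons a circ spans.
#' @return an object of class `sim_truth`: a list with elements `circs`
#'   (data.frame: circ_id, transcript_id, gene_id, gene_symbol, chrom,
#'   strand, start, end, first_exon, last_exon, n_exons, base_mean,
#'   mean_no_cancer, mean_adjacent, mean_tumor, fold_change),
#'   `planted_sites` (empty until [generate_mirna_resources()]),
#'   `group_profile`, `dispersion`, `rng_seed`.
#' @export
generate_truth <- function(transcripts, n_circ,
                           group_profile = c("field_effect", "null"),
                           fold_change_spec = NULL,
                           rng_seed = 1L,
                           base_mean = NULL,
                           group_multipliers = FIELD_EFFECT_MULTIPLIERS,
                           isoforms = TRUE,
                           dispersion = NULL,
                           genome = NULL,
                           max_exons_per_circ = 4L) {
  group_profile <- match.arg(group_profile)
  set.seed(assert_seed(rng_seed))
  if (is.null(dispersion))
    dispersion <- if (group_profile == "field_effect") 0.2 else 0
  txs <- split_transcripts(transcripts)
  # enumerate candidate exon runs per transcript
  candidates <- list()
  for (tid in names(txs)) {
    tx <- txs[[tid]]
    n_ex <- nrow(tx)
    for (i in seq_len(n_ex)) {
      for (j in i:min(n_ex, i + max_exons_per_circ - 1L)) {
        if (!is.null(genome) &&
            junction_left_ambiguous(genome, tx$chrom[1], tx$start[i],
                                    tx$end[j]))
          next
        candidates[[length(candidates) + 1L]] <-
          list(tid = tid, i = i, j = j)
      }
    }
  }
  if (n_circ > length(candidates))
    stop_invalid("n_circ = %d exceeds the %d candidate exon runs",
                 n_circ, length(candidates))
  if (n_circ == 0) {
    return(new_sim_truth(empty_truth_circs(), group_profile, dispersion,
                         rng_seed))
  }
  pick <- sample(seq_along(candidates), n_circ)
  if (isoforms && n_circ >= 2L) {
    # ensure some gene carries >= 2 isoforms (distinct runs, same transcript)
    tids <- vapply(candidates[pick], `[[`, character(1), "tid")
    if (!anyDuplicated(tids)) {
      same_tx <- which(vapply(candidates, `[[`, character(1), "tid") ==
                       tids[1])
      extra <- setdiff(same_tx, pick)
      if (length(extra)) pick[2L] <- extra[1L]
    }
  }
  rows <- lapply(candidates[pick], function(cand) {
    tx <- txs[[cand$tid]]
    data.frame(
      circ_id = NA_character_,
      transcript_id = cand$tid,
      gene_id = tx$gene_id[1], gene_symbol = tx$gene_symbol[1],
      chrom = tx$chrom[1], strand = tx$strand[1],
      start = tx$start[cand$i], end = tx$end[cand$j],
      first_exon = cand$i, last_exon = cand$j,
      n_exons = cand$j - cand$i + 1L,
      stringsAsFactors = FALSE
    )
  })
  circs <- do.call(rbind, rows)
  circs$circ_id <- native_circ_id(circs$chrom, circs$start, circs$end,
                                  circs$strand)
  stopifnot(!anyDuplicated(circs$circ_id))
  # per-group means
  n <- nrow(circs)
  if (is.null(base_mean)) {
    lam <- stats::rexp(n, rate = 1 / 3) + 0.5
    tail_idx <- stats::runif(n) < 0.1
    lam[tail_idx] <- lam[tail_idx] * 8
  } else {
    lam <- stats::runif(n, base_mean[1], base_mean[2])
  }
  circs$base_mean <- lam
  mult <- if (group_profile == "field_effect") {
    group_multipliers[GROUP_LEVELS]
  } else stats::setNames(rep(1, 3), GROUP_LEVELS)
  circs$mean_no_cancer <- lam * mult[["no_cancer"]]
  circs$mean_adjacent <- lam * mult[["adjacent"]]
  circs$mean_tumor <- lam * mult[["tumor"]]
  circs$fold_change <- 1
  # plant fold changes: pooled(adjacent+tumor) / no_cancer ratio
  if (!is.null(fold_change_spec)) {
    if (is.list(fold_change_spec)) {
      n_fc <- fold_change_spec$n
      fcs <- rep_len(fold_change_spec$fc, n_fc)
      idx <- sample(seq_len(n), n_fc)
    } else {
      bad <- setdiff(names(fold_change_spec), circs$circ_id)
      if (length(bad))
        stop_invalid("fold change requested for unknown circ(s): %s",
                     paste(bad, collapse = ", "))
      idx <- match(names(fold_change_spec), circs$circ_id)
      fcs <- unname(fold_change_spec)
    }
    circs$fold_change[idx] <- fcs
    circs$mean_adjacent[idx] <- circs$mean_no_cancer[idx] * fcs
    circs$mean_tumor[idx] <- circs$mean_no_cancer[idx] * fcs
  }
  new_sim_truth(circs, group_profile, dispersion, rng_seed)
}

# TRUE when a left-aligning caller would shift the junction off the exon
# boundaries: the base preceding the acceptor equals the last base of the
# donor exon
junction_left_ambiguous <- function(genome, chrom, start, end) {
  if (start < 1L) return(TRUE)
  s <- genome[[chrom]]
  substr(s, start, start) == substr(s, end, end)
}

new_sim_truth <- function(circs, group_profile, dispersion, rng_seed) {
  structure(list(
    circs = circs,
    planted_sites = data.frame(circ_id = character(),
                               mirna_id = character(),
                               n_sites = integer(),
                               stringsAsFactors = FALSE),
    group_profile = group_profile,
    dispersion = dispersion,
    rng_seed = as.integer(rng_seed)
  ), class = "sim_truth")
}

empty_truth_circs <- function() {
  data.frame(circ_id = character(), transcript_id = character(),
             gene_id = character(), gene_symbol = character(),
             chrom = character(), strand = character(),
             start = integer(), end = integer(),
             first_exon = integer(), last_exon = integer(),
             n_exons = integer(), base_mean = numeric(),
             mean_no_cancer = numeric(), mean_adjacent = numeric(),
             mean_tumor = numeric(), fold_change = numeric(),
             stringsAsFactors = FALSE)
}

#' Native circRNA identifier
#'
#' `circ_<chrom>_<start+1>_<end>_<strand>`, i.e. 1-based inclusive
#' coordinates inside the id, matching the convention of public circRNA
#' coordinate ids. circBase-style accessions can be carried alongside as
#' aliases; they are never computed here.
#' @param chrom,start,end,strand junction fields (0-based half-open).
#' @return character vector of ids.
#' @export
native_circ_id <- function(chrom, start, end, strand) {
  sprintf("circ_%s_%d_%d_%s", chrom, start + 1L, end, strand)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d circRNAs, profile '%s', dispersion %.3g\n",
              nrow(x$circs), x$group_profile, x$dispersion))
  invisible(x)
}

#' Simulate a junction-read count matrix directly from a truth set
#'
#' Draws per-sample junction-read counts around each truth circ's group
#' mean: negative binomial with the given dispersion, or Poisson when
#' `dispersion = 0`. This bypasses read simulation and the caller; it is the
#' fast route for statistical work on the count model.
#'
#' @param truth a `sim_truth`.
#' @param samples_per_group samples per group (default 8, the study design).
#' @param dispersion NB dispersion; defaults to `truth$dispersion`.
#' @param rng_seed integer seed.
#' @return a `circ_counts` object (see [build_matrix()]).
#' @export
simulate_counts <- function(truth, samples_per_group = 8L,
                            dispersion = NULL, rng_seed = 1L) {
  set.seed(assert_seed(rng_seed))
  if (is.null(dispersion)) dispersion <- truth$dispersion
  circs <- truth$circs
  sample_ids <- unlist(lapply(GROUP_LEVELS, function(g)
    sprintf("%s_s%d", g, seq_len(samples_per_group))))
  group <- factor(rep(GROUP_LEVELS, each = samples_per_group),
                  levels = GROUP_LEVELS)
  names(group) <- sample_ids
  counts <- matrix(0L, nrow = nrow(circs), ncol = length(sample_ids),
                   dimnames = list(circs$circ_id, sample_ids))
  mean_cols <- c(no_cancer = "mean_no_cancer", adjacent = "mean_adjacent",
                 tumor = "mean_tumor")
  for (g in GROUP_LEVELS) {
    cols <- which(group == g)
    mu <- circs[[mean_cols[[g]]]]
    for (j in cols) {
      counts[, j] <- if (dispersion > 0)
        stats::rnbinom(nrow(circs), mu = mu, size = 1 / dispersion)
      else stats::rpois(nrow(circs), lambda = mu)
    }
  }
  new_circ_counts(counts, group)
}
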