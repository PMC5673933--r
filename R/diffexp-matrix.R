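# Count matrix container and set-level summaries.

#' Construct a circ x sample count matrix container
#'
#' @param counts non-negative integer matrix, rows = circ ids, columns =
#'   sample ids.
#' @param group factor (or character) over `no_cancer`, `adjacent`,
#'   `tumor`, named by sample id or aligned with columns.
#' @param lib_size per-sample library sizes; defaults to the column sums
#'   (total junction reads), the package's normalization reference. Must be
#'   at least the column sums and positive.
#' @return object of class `circ_counts`: list(counts, group, lib_size).
#' @export
new_circ_counts <- function(counts, group, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  group <- factor(group, levels = GROUP_LEVELS)
  if (length(group) != ncol(counts))
    stop_invalid("group must have one entry per sample")
  if (anyNA(group)) stop_invalid("unknown group label(s)")
  names(group) <- colnames(counts)
  cs <- colSums(counts)
  if (is.null(lib_size)) lib_size <- pmax(cs, 1)
  if (any(lib_size < cs))
    stop_invalid("lib_size below the column sum for some sample")
  names(lib_size) <- colnames(counts)
  structure(list(counts = counts, group = group, lib_size = lib_size),
            class = "circ_counts")
}

#' @export
print.circ_counts <- function(x, ...) {
  cat(sprintf("circ_counts: %d circRNAs x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  invisible(x)
}

#' Build a count matrix from per-sample junction calls
#'
#' Takes the union of junctions across samples (absent junctions count 0)
#' and drops junctions whose total read count is below `min_reads`.
#'
#' @param call_sets either a single call data.frame covering all samples
#'   (column `sample_id` distinguishes them) or a named list of per-sample
#'   call data.frames (names are sample ids and must be unique).
#' @param group named group vector (`no_cancer`/`adjacent`/`tumor` per
#'   sample id); when omitted the group is parsed from the sample id prefix
#'   (e.g. `"adjacent_s3"`).
#' @param min_reads minimum total read count to retain a junction
#'   (default 1).
#' @return a `circ_counts` object.
#' @export
build_matrix <- function(call_sets, group = NULL, min_reads = 1L) {
  if (is.data.frame(call_sets)) {
    calls <- call_sets
  } else {
    if (anyDuplicated(names(call_sets)))
      stop_invalid("duplicate sample ids in call_sets")
    calls <- do.call(rbind, Map(function(df, s) {
      df$sample_id <- s
      df
    }, call_sets, names(call_sets)))
  }
  samples <- unique(calls$sample_id)
  calls$circ_id <- native_circ_id(calls$chrom, calls$start, calls$end,
                                  calls$strand)
  # a junction may enter twice for one sample (e.g. two callers): sum
  dt <- data.table::as.data.table(calls)
  dt <- dt[, list(read_count = sum(read_count)),
           by = c("circ_id", "sample_id")]
  ids <- sort(unique(dt$circ_id))
  m <- matrix(0L, nrow = length(ids), ncol = length(samples),
              dimnames = list(ids, samples))
  m[cbind(match(dt$circ_id, ids), match(dt$sample_id, samples))] <-
    dt$read_count
  keep <- rowSums(m) >= min_reads
  m <- m[keep, , drop = FALSE]
  if (is.null(group)) group <- sub("_s[0-9]+$", "", samples)
  else group <- group[samples]
  new_circ_counts(m, group)
}

#' Counts per million
#' @param x a `circ_counts`.
#' @return numeric matrix of CPM values.
#' @export
cpm <- function(x) {
  sweep(x$counts, 2L, x$lib_size, "/") * 1e6
}

#' Most expressed circRNAs within a group
#'
#' Ranks by within-group summed junction-read count, descending; ties are
#' broken lexicographically by circ id.
#'
#' @param x a `circ_counts`.
#' @param group group name.
#' @param n number of rows to return (default 7, the length of the
#'   per-tissue top tables this mirrors).
#' @return data.frame `circ_id`, `total_reads`, at most `n` rows.
#' @export
top_expressed <- function(x, group, n = 7L) {
  if (n < 1L) stop_invalid("n must be >= 1")
  if (!group %in% levels(x$group)) stop_invalid("unknown group: %s", group)
  tot <- rowSums(x$counts[, x$group == group, drop = FALSE])
  ord <- order(-tot, names(tot))
  head_n <- min(n, length(tot))
  data.frame(circ_id = names(tot)[ord][seq_len(head_n)],
             total_reads = unname(tot[ord])[seq_len(head_n)],
             stringsAsFactors = FALSE)
}

#' Three-group presence overlaps (Venn regions)
#'
#' A circRNA is present in a group when its within-group summed count is at
#' least `presence_threshold`. The seven regions are disjoint and sum to
#' the union size.
#'
#' @param x a `circ_counts`.
#' @param presence_threshold minimum within-group total (default 1).
#' @return named integer vector over the regions `no_cancer_only`,
#'   `adjacent_only`, `tumor_only`, `no_cancer_adjacent`,
#'   `no_cancer_tumor`, `adjacent_tumor`, `all_three`, plus
#'   attribute `"union_size"`.
#' @export
group_overlaps <- function(x, presence_threshold = 1L) {
  pres <- vapply(GROUP_LEVELS, function(g)
    rowSums(x$counts[, x$group == g, drop = FALSE]) >= presence_threshold,
    logical(nrow(x$counts)))
  if (nrow(x$counts) == 1L) pres <- matrix(pres, nrow = 1L,
                                           dimnames = list(
                                             rownames(x$counts),
                                             GROUP_LEVELS))
  nc <- pres[, "no_cancer"]; ad <- pres[, "adjacent"]; tu <- pres[, "tumor"]
  out <- c(
    no_cancer_only = sum(nc & !ad & !tu),
    adjacent_only = sum(!nc & ad & !tu),
    tumor_only = sum(!nc & !ad & tu),
    no_cancer_adjacent = sum(nc & ad & !tu),
    no_cancer_tumor = sum(nc & !ad & tu),
    adjacent_tumor = sum(!nc & ad & tu),
    all_three = sum(nc & ad & tu))
  attr(out, "union_size") <- sum(nc | ad | tu)
  attr(out, "per_group") <- c(no_cancer = sum(nc), adjacent = sum(ad),
                              tumor = sum(tu))
  out
}

#' Write / read a count matrix as TSV
#'
#' The first header row carries `circ_id` then the sample ids; the second
#' row (`#group`) carries the group labels.
#'
#' @param x a `circ_counts` (writer) or path (reader).
#' @param path file path.
#' @return `path` invisibly / a `circ_counts`.
#' @export
write_counts_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("circ_id", colnames(x$counts)), collapse = "\t"), con)
  writeLines(paste(c("#group", as.character(x$group)), collapse = "\t"),
             con)
  utils::write.table(data.frame(circ_id = rownames(x$counts), x$counts,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  lines <- readLines(path, n = 2L)
  header <- strsplit(lines[1], "\t")[[1]]
  grp <- strsplit(lines[2], "\t")[[1]][-1]
  df <- utils::read.table(path, sep = "\t", skip = 2L, header = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(df[[1]], header[-1])
  new_circ_counts(m, grp)
}
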