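# Readers for external caller outputs and the native BED dialect. All
# coordinates are normalized to the internal 0-based half-open convention:
# CIRI2 TSV reports 1-based inclusive coordinates, BED dialects are already
# 0-based half-open.

#' Read back-splice junction calls from a caller output file
#'
#' Supported dialects:
#' \describe{
#'   \item{`ciri2`}{tab-separated with a header line; uses columns
#'     `circRNA_ID`, `chr`, `circRNA_start`, `circRNA_end` (1-based
#'     inclusive), `X.junction_reads` (the `#junction_reads` column) and
#'     `strand`.}
#'   \item{`circexplorer2`}{headerless BED12+6; columns 1-4, 6 are chrom,
#'     start, end, name, strand; column 13 (`readNumber`) carries the
#'     junction-read count.}
#'   \item{`native_bed`}{BED6+1 written by [write_junction_bed()]: chrom,
#'     start, end, circ_id, read_count, strand, caller_id.}
#' }
#'
#' @param path input file.
#' @param dialect one of `"ciri2"`, `"circexplorer2"`, `"native_bed"`.
#' @param sample_id sample label attached to the calls.
#' @return call data.frame as from [detect_backsplice()].
#' @export
read_caller_output <- function(path, dialect = c("ciri2", "circexplorer2",
                                                 "native_bed"),
                               sample_id = "sample") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  switch(dialect,
    ciri2 = read_ciri2(path, sample_id),
    circexplorer2 = read_circexplorer2(path, sample_id),
    native_bed = read_native_bed(path, sample_id))
}

read_ciri2 <- function(path, sample_id) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                      stringsAsFactors = FALSE, check.names = TRUE),
    error = function(e) stop_invalid("malformed ciri2 file %s: %s", path,
                                     conditionMessage(e)))
  need <- c("chr", "circRNA_start", "circRNA_end", "X.junction_reads")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_invalid("ciri2 file %s lacks column(s): %s", path,
                 paste(missing, collapse = ", "))
  bad <- which(is.na(df$circRNA_start) | is.na(df$circRNA_end))
  if (length(bad))
    stop_invalid("ciri2 file %s: unparseable coordinates at line %d",
                 path, bad[1] + 1L)
  data.frame(chrom = df$chr,
             start = as.integer(df$circRNA_start) - 1L,  # 1-based -> 0-based
             end = as.integer(df$circRNA_end),
             strand = if ("strand" %in% names(df)) df$strand else "+",
             read_count = as.integer(df$X.junction_reads),
             sample_id = sample_id, caller_id = "ciri2",
             stringsAsFactors = FALSE)
}

read_circexplorer2 <- function(path, sample_id) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop_invalid("malformed circexplorer2 file %s: %s",
                                     path, conditionMessage(e)))
  if (ncol(df) < 13L)
    stop_invalid("circexplorer2 file %s has %d columns; >= 13 required",
                 path, ncol(df))
  data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), strand = df[[6]],
             read_count = as.integer(df[[13]]),
             sample_id = sample_id, caller_id = "circexplorer2",
             stringsAsFactors = FALSE)
}

read_native_bed <- function(path, sample_id) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop_invalid("malformed bed file %s: %s", path,
                                     conditionMessage(e)))
  if (ncol(df) < 6L)
    stop_invalid("native bed file %s has %d columns; >= 6 required",
                 path, ncol(df))
  data.frame(chrom = df[[1]], start = as.integer(df[[2]]),
             end = as.integer(df[[3]]), strand = df[[6]],
             read_count = as.integer(df[[5]]),
             sample_id = sample_id,
             caller_id = if (ncol(df) >= 7L) df[[7]] else "native",
             stringsAsFactors = FALSE)
}

#' Write calls as the native BED6+1 dialect
#'
#' Columns: chrom, start, end, circ_id, read_count, strand, caller_id
#' (0-based half-open).
#'
#' @param calls call data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(calls, path) {
  bed <- data.frame(calls$chrom, calls$start, calls$end,
                    native_circ_id(calls$chrom, calls$start, calls$end,
                                   calls$strand),
                    calls$read_count, calls$strand, calls$caller_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
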