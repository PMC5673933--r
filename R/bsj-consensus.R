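#' Intersect two call sets into consensus calls
#'
#' Keeps junctions found by both callers, the dual-algorithm rule used to
#' improve prediction accuracy: a junction of `calls_a` survives when some
#' junction of `calls_b` on the same chromosome and strand matches both
#' endpoints within `slack` nt. The consensus call takes its coordinates
#' from `calls_a` and its `read_count` as the minimum of the two callers'
#' counts. With the default `slack = 0` the operation is a plain set
#' intersection and is commutative and idempotent.
#'
#' @param calls_a,calls_b call data.frames (see [detect_backsplice()]);
#'   expected to come from the same sample.
#' @param slack endpoint tolerance in nt (default 0; >= 0).
#' @return consensus call data.frame; `caller_id` becomes
#'   `"<caller_a>+<caller_b>"`.
#' @export
consensus <- function(calls_a, calls_b, slack = 0L) {
  if (slack < 0L) stop_invalid("slack must be >= 0")
  if (nrow(calls_a) == 0L || nrow(calls_b) == 0L) return(empty_calls())
  id_a <- if (length(unique(calls_a$caller_id)) == 1L)
    calls_a$caller_id[1] else "a"
  id_b <- if (length(unique(calls_b$caller_id)) == 1L)
    calls_b$caller_id[1] else "b"
  keep <- logical(nrow(calls_a))
  cnt <- integer(nrow(calls_a))
  for (i in seq_len(nrow(calls_a))) {
    m <- calls_b$chrom == calls_a$chrom[i] &
      calls_b$strand == calls_a$strand[i] &
      abs(calls_b$start - calls_a$start[i]) <= slack &
      abs(calls_b$end - calls_a$end[i]) <= slack
    if (any(m)) {
      keep[i] <- TRUE
      # closest partner when slack admits several
      j <- which(m)[which.min(abs(calls_b$start[m] - calls_a$start[i]) +
                              abs(calls_b$end[m] - calls_a$end[i]))]
      cnt[i] <- min(calls_a$read_count[i], calls_b$read_count[j])
    }
  }
  if (!any(keep)) return(empty_calls())
  out <- calls_a[keep, , drop = FALSE]
  out$read_count <- cnt[keep]
  out$caller_id <- paste0(id_a, "+", id_b)
  rownames(out) <- NULL
  out
}
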