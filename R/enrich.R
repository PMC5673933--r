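# Native gene-set over-representation: upper-tail hypergeometric test per
# term with Bonferroni correction. A plain hypergeometric is used (not the
# EASE-modified score of web enrichment services).

#' Hypergeometric over-representation of gene sets
#'
#' For each term with gene set of size `K` inside a background of `N`
#' genes, and a query of `n` genes hitting `k` of the term's genes, the
#' p-value is the upper tail `P(X >= k)` of the hypergeometric
#' distribution. Terms with no background genes are skipped. Bonferroni
#' correction is over the number of tested terms.
#'
#' @param query_genes character vector of query gene symbols (must be a
#'   subset of the background).
#' @param pathway_table named list: term id -> character vector of gene
#'   symbols (e.g. from [read_gmt()]).
#' @param background_genes character vector of background gene symbols;
#'   term gene sets are intersected with it.
#' @param term_names optional named character vector of display names.
#' @return data.frame sorted by ascending p-value: `term_id`, `term_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `p_bonferroni`.
#' @export
enrich <- function(query_genes, pathway_table, background_genes,
                   term_names = NULL) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  outside <- setdiff(query_genes, background_genes)
  if (length(outside))
    stop_invalid("query gene(s) absent from background: %s",
                 paste(outside, collapse = ", "))
  N <- length(background_genes)
  n <- length(query_genes)
  rows <- lapply(names(pathway_table), function(term) {
    genes <- intersect(unique(pathway_table[[term]]), background_genes)
    K <- length(genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(query_genes, genes))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = term,
               term_name = if (!is.null(term_names) &&
                               term %in% names(term_names))
                 term_names[[term]] else term,
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      p_bonferroni = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (term, description, genes... per tab-separated
#'   line).
#' @return named list of gene character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a named list of gene sets as GMT
#'
#' @param pathways named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(term)
    paste(c(term, "na", pathways[[term]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bar plot of enrichment results (-log10 p per term)
#'
#' The score axis is explicitly -log10 of the raw hypergeometric p-value.
#'
#' @param results data.frame from [enrich()] (or several, row-bound with a
#'   `group` column).
#' @param top_n terms to show per group.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 10L) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_enrichment requires ggplot2")
  res <- utils::head(results[order(results$p_value), , drop = FALSE], top_n)
  res$score <- -log10(pmax(res$p_value, .Machine$double.xmin))
  res$term_name <- stats::reorder(res$term_name, res$score)
  ggplot2::ggplot(res, ggplot2::aes(x = term_name, y = score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 p (hypergeometric)") +
    ggplot2::theme_minimal()
}
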