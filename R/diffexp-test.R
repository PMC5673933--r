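# Negative-binomial differential expression: method-of-moments common and
# tagwise dispersion, conditional exact test on library-size-equalized
# counts, BH FDR. This is a deliberately compact qCML-flavored approach
# with the same contract as the weighted-likelihood machinery of the large
# count-model packages, not a re-implementation of any of them.

#' Estimate common and tagwise NB dispersions
#'
#' Per circRNA, a method-of-moments dispersion is computed on counts scaled
#' to the geometric-mean library size, within each group (so group mean
#' differences do not inflate the variance), pooled across groups by
#' residual degrees of freedom, and floored at zero:
#' `phi_g = max(0, pooled (s^2 - m) / m^2)`. The common dispersion is the
#' count-weighted mean of the per-circ values. Tagwise values shrink the
#' per-circ estimate toward the common one with weight
#' `w = prior_df / (prior_df + d_g)` where `d_g` is the residual df for the
#' circ: `phi_tag = w * common + (1 - w) * phi_g`.
#'
#' @param x a `circ_counts`.
#' @param prior_df prior degrees of freedom of the shrinkage (default 10).
#' @return object of class `dispersion_estimates`: list with `common`
#'   (scalar), `tagwise` (named vector), `raw` (unshrunk per-circ values),
#'   `shrink_weight` (per-circ `w`), `prior_df`.
#' @export
estimate_dispersion <- function(x, prior_df = 10) {
  counts <- x$counts
  if (all(counts == 0)) stop("no expressed features")
  if (max(table(x$group)) < 2L)
    stop_invalid("dispersion estimation needs >= 2 samples in some group")
  gm <- exp(mean(log(x$lib_size)))
  eff <- sweep(counts, 2L, gm / x$lib_size, "*")
  num <- rep(0, nrow(counts))   # df-weighted sum of (s^2 - m)/m^2
  den <- rep(0, nrow(counts))
  for (g in levels(x$group)) {
    cols <- which(x$group == g)
    if (length(cols) < 2L) next
    m <- rowMeans(eff[, cols, drop = FALSE])
    v <- apply(eff[, cols, drop = FALSE], 1L, stats::var)
    ok <- m > 0
    contrib <- ifelse(ok, (v - m) / m^2, 0)
    df <- length(cols) - 1L
    num <- num + ifelse(ok, contrib * df, 0)
    den <- den + ifelse(ok, df, 0)
  }
  raw <- ifelse(den > 0, pmax(0, num / den), 0)
  w_counts <- rowSums(counts)
  common <- sum(raw * w_counts) / sum(w_counts)
  d_g <- pmax(den, 1)
  w <- prior_df / (prior_df + d_g)
  tagwise <- w * common + (1 - w) * raw
  names(tagwise) <- rownames(counts)
  structure(list(common = common, tagwise = tagwise, raw = raw,
                 shrink_weight = w, prior_df = prior_df),
            class = "dispersion_estimates")
}

#' @export
print.dispersion_estimates <- function(x, ...) {
  cat(sprintf("dispersion_estimates: common %.4f, tagwise range [%.4f, %.4f]\n",
              x$common, min(x$tagwise), max(x$tagwise)))
  invisible(x)
}

#' NB conditional exact test between two sample groups
#'
#' Counts are first equalized to the geometric-mean library size
#' (scaled and rounded). For each circRNA the total count is split between
#' the two contrast sides; under equal per-sample means the side total
#' follows the conditional distribution of a sum of NB variables given the
#' grand total, with side sizes `n_i / phi`. The two-sided p-value is the
#' sum of the probabilities of all splits at most as probable as the
#' observed one. Totals above `normal_cutoff` use a normal approximation to
#' the conditional distribution; `phi = 0` uses the exact Poisson
#' (binomial) conditional. Circs with zero total get `p = 1`.
#'
#' @param x a `circ_counts`.
#' @param dispersions a `dispersion_estimates`, a single numeric
#'   dispersion used for all circs, or `NULL` to estimate from `x`.
#' @param contrast `"pooled"` (no-cancer vs adjacent+tumor combined, the
#'   study's primary contrast) or a length-2 character vector of group
#'   names `c(side_a, side_b)`.
#' @param prior_cpm prior added to group mean CPM before the log2 fold
#'   change (default 0.5).
#' @param normal_cutoff total count above which the normal approximation is
#'   used (default 5000).
#' @return data.frame with one row per circRNA: `circ_id`, `cpm_no_cancer`,
#'   `cpm_adjacent`, `cpm_tumor`, `log2_fold_change` (side b over side a),
#'   `p_value`, `fdr`, `direction` (`"up"` = higher on side b, the pooled /
#'   second side), `dispersion`.
#' @export
nb_exact_test <- function(x, dispersions = NULL, contrast = "pooled",
                          prior_cpm = 0.5, normal_cutoff = 5000L) {
  if (identical(contrast, "pooled")) {
    side_a <- x$group == "no_cancer"
    side_b <- x$group %in% c("adjacent", "tumor")
  } else {
    if (length(contrast) != 2L || !all(contrast %in% levels(x$group)))
      stop_invalid("contrast must be 'pooled' or two group names")
    side_a <- x$group == contrast[1]
    side_b <- x$group == contrast[2]
  }
  if (!any(side_a) || !any(side_b))
    stop_invalid("both contrast sides must be non-empty")
  if (is.null(dispersions)) dispersions <- estimate_dispersion(x)
  phi <- if (inherits(dispersions, "dispersion_estimates"))
    dispersions$tagwise[rownames(x$counts)]
  else rep(dispersions, nrow(x$counts))
  gm <- exp(mean(log(x$lib_size)))
  pseudo <- round(sweep(x$counts, 2L, gm / x$lib_size, "*"))
  ya <- rowSums(pseudo[, side_a, drop = FALSE])
  yb <- rowSums(pseudo[, side_b, drop = FALSE])
  na <- sum(side_a); nb <- sum(side_b)
  p <- vapply(seq_len(nrow(pseudo)), function(i)
    exact_nb_p(ya[i], yb[i], na, nb, phi[i], normal_cutoff),
    numeric(1))
  cpm_all <- cpm(x)
  grp_cpm <- vapply(GROUP_LEVELS, function(g)
    rowMeans(cpm_all[, x$group == g, drop = FALSE]),
    numeric(nrow(cpm_all)))
  if (nrow(cpm_all) == 1L) grp_cpm <- matrix(grp_cpm, nrow = 1L,
                                             dimnames = list(
                                               rownames(cpm_all),
                                               GROUP_LEVELS))
  mean_a <- rowMeans(cpm_all[, side_a, drop = FALSE])
  mean_b <- rowMeans(cpm_all[, side_b, drop = FALSE])
  lfc <- log2((mean_b + prior_cpm) / (mean_a + prior_cpm))
  data.frame(
    circ_id = rownames(x$counts),
    cpm_no_cancer = grp_cpm[, "no_cancer"],
    cpm_adjacent = grp_cpm[, "adjacent"],
    cpm_tumor = grp_cpm[, "tumor"],
    log2_fold_change = lfc,
    p_value = p,
    fdr = adjust_fdr(p),
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "flat")),
    dispersion = unname(phi),
    row.names = NULL, stringsAsFactors = FALSE)
}

# two-sided conditional exact p for the split (ya, yb) of T = ya + yb
# between sides with na and nb samples and per-sample dispersion phi
exact_nb_p <- function(ya, yb, na, nb, phi, normal_cutoff = 5000L) {
  T <- ya + yb
  if (T == 0) return(1)
  if (phi <= 0) {
    pr <- stats::dbinom(0:T, T, na / (na + nb))
    obs <- pr[ya + 1L]
    return(min(1, sum(pr[pr <= obs * (1 + 1e-10)])))
  }
  ra <- na / phi; rb <- nb / phi
  if (T > normal_cutoff) {
    pi_a <- ra / (ra + rb)
    v <- T * pi_a * (1 - pi_a) * (T + ra + rb) / (ra + rb + 1)
    z <- (abs(ya - T * pi_a) - 0.5) / sqrt(v)
    return(min(1, 2 * stats::pnorm(z, lower.tail = FALSE)))
  }
  y <- 0:T
  lp <- lgamma(y + ra) - lgamma(ra) - lgamma(y + 1) +
    lgamma(T - y + rb) - lgamma(rb) - lgamma(T - y + 1)
  lp <- lp - max(lp)
  pr <- exp(lp); pr <- pr / sum(pr)
  obs <- pr[ya + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up FDR with monotonicity enforcement, capped at 1.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_invalid("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
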