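test_that("build_matrix takes the union, zero-fills and filters", {
  calls <- data.frame(
    chrom = "chr1", start = c(100L, 100L, 900L), end = c(600L, 600L, 1400L),
    strand = "+", read_count = c(6L, 3L, 4L),
    sample_id = c("no_cancer_s1", "adjacent_s1", "adjacent_s1"),
    caller_id = "native", stringsAsFactors = FALSE)
  x <- build_matrix(calls, group = c(no_cancer_s1 = "no_cancer",
                                     adjacent_s1 = "adjacent"))
  expect_equal(dim(x$counts), c(2L, 2L))
  j1 <- native_circ_id("chr1", 100L, 600L, "+")
  j2 <- native_circ_id("chr1", 900L, 1400L, "+")
  expect_equal(unname(x$counts[j1, ]), c(6L, 3L))
  expect_equal(unname(x$counts[j2, "adjacent_s1"]), 4L)
  expect_equal(unname(x$counts[j2, "no_cancer_s1"]), 0L)
  # min_reads drops low-total junctions
  x5 <- build_matrix(calls, group = c(no_cancer_s1 = "no_cancer",
                                      adjacent_s1 = "adjacent"),
                     min_reads = 5L)
  expect_equal(rownames(x5$counts), j1)
  # duplicate sample ids in a list input are rejected
  a <- calls[1, ]
  expect_error(build_matrix(stats::setNames(list(a, a), c("s", "s"))),
               "duplicate")
})

test_that("top_expressed ranks by within-group totals with lexicographic ties", {
  m <- matrix(c(41L, 37L, 3L, 10L, 10L, 10L), nrow = 3,
              dimnames = list(c("cB", "cA", "cC"), NULL))
  x <- counts_fixture(cbind(m, m, m)[, c(1, 2, 3, 4, 5, 6)], 2)
  # within no_cancer: totals cB=78, cA=40, cC=13
  top <- top_expressed(x, "no_cancer", 2)
  expect_equal(top$circ_id, c("cB", "cA"))
  # all tied -> lexicographic
  mt <- matrix(5L, nrow = 3, ncol = 6,
               dimnames = list(c("cB", "cA", "cC"), NULL))
  xt <- counts_fixture(mt, 2)
  expect_equal(top_expressed(xt, "tumor", 3)$circ_id, c("cA", "cB", "cC"))
  expect_equal(nrow(top_expressed(xt, "tumor", 7)), 3)
  expect_error(top_expressed(xt, "tumor", 0), "n must be")
  expect_error(top_expressed(xt, "nope", 1), "unknown group")
})

test_that("group overlaps match brute-force membership enumeration", {
  set.seed(12)
  n <- 60
  m <- matrix(rbinom(n * 6, 1, 0.5) * rpois(n * 6, 3), n, 6,
              dimnames = list(sprintf("c%02d", 1:n), NULL))
  x <- counts_fixture(m, 2)
  v <- group_overlaps(x, presence_threshold = 1)
  # oracle: enumerate membership per circ
  pres <- sapply(c("no_cancer", "adjacent", "tumor"), function(g)
    rowSums(m[, x$group == g, drop = FALSE]) >= 1)
  code <- paste0(pres[, 1] + 0, pres[, 2] + 0, pres[, 3] + 0)
  oracle <- c(no_cancer_only = sum(code == "100"),
              adjacent_only = sum(code == "010"),
              tumor_only = sum(code == "001"),
              no_cancer_adjacent = sum(code == "110"),
              no_cancer_tumor = sum(code == "101"),
              adjacent_tumor = sum(code == "011"),
              all_three = sum(code == "111"))
  expect_equal(unclass(v)[names(oracle)], oracle)
  expect_equal(sum(v), attr(v, "union_size"))
  # identical presence everywhere -> triple overlap only
  m27 <- matrix(2L, 27, 6, dimnames = list(sprintf("s%02d", 1:27), NULL))
  v27 <- group_overlaps(counts_fixture(m27, 2))
  expect_equal(unname(v27["all_three"]), 27)
  expect_equal(sum(v27) - v27[["all_three"]], 0)
})

test_that("dispersion estimation floors at zero and shrinks to common", {
  # constant counts within groups: variance 0 < mean -> floor at 0
  m <- matrix(rep(c(5L, 9L, 14L), each = 4), nrow = 1)
  x <- counts_fixture(m, 4)
  d <- estimate_dispersion(x)
  expect_equal(unname(d$raw), 0)
  # with shrink weight 1 the tagwise equals the common value
  d2 <- estimate_dispersion(random_nb_counts(50, 4, 20, 0.3, 5),
                            prior_df = 1e9)
  expect_true(all(abs(d2$tagwise - d2$common) < 1e-6))
  expect_error(estimate_dispersion(counts_fixture(
    matrix(0L, 2, 6), 2)), "no expressed")
})

test_that("dispersion recovery from simulated counts is calibrated", {
  # Poisson counts: common dispersion near zero
  set.seed(31)
  x0 <- counts_fixture(matrix(rpois(200 * 24, 50), 200, 24,
                              dimnames = list(sprintf("c%03d", 1:200),
                                              NULL)), 8)
  expect_lt(estimate_dispersion(x0)$common, 0.05)
  # NB phi = 0.2
  x2 <- random_nb_counts(200, 8, 50, 0.2, 32)
  expect_lt(abs(estimate_dispersion(x2)$common - 0.2), 0.05)
})

test_that("exact test reproduces hand-computed conditional probabilities", {
  # Poisson conditional = binomial: 0 vs 10 on 1-vs-1 samples
  expect_equal(circfield:::exact_nb_p(0, 10, 1, 1, 0), 2 / 1024)
  # symmetric sides with identical totals: observed split is the mode
  expect_equal(circfield:::exact_nb_p(25, 25, 4, 4, 0.2), 1)
  # symmetry under side swap
  p_ab <- circfield:::exact_nb_p(3, 40, 8, 16, 0.2)
  p_ba <- circfield:::exact_nb_p(40, 3, 16, 8, 0.2)
  expect_equal(p_ab, p_ba)
  # zero total -> p = 1 by convention
  expect_equal(circfield:::exact_nb_p(0, 0, 8, 16, 0.2), 1)
  # normal approximation tracks the exact tail for large totals
  p_exact <- circfield:::exact_nb_p(2000, 4000, 8, 16, 0.05,
                                    normal_cutoff = 1e9)
  p_norm <- circfield:::exact_nb_p(2000, 4000, 8, 16, 0.05,
                                   normal_cutoff = 10)
  expect_lt(abs(log10(p_exact) - log10(p_norm)), 0.2)
})

test_that("nb_exact_test output contract holds on a small matrix", {
  x <- random_nb_counts(40, 3, 20, 0.2, 77)
  de <- nb_exact_test(x)
  expect_equal(nrow(de), 40)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  expect_true(all(de$fdr >= 0 & de$fdr <= 1))
  # fdr is monotone in p-value rank
  o <- order(de$p_value)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
  expect_error(nb_exact_test(x, contrast = c("no_cancer", "nope")),
               "contrast")
})

test_that("exact test agrees with edgeR's exact test at fixed dispersion", {
  skip_if_not_installed("edgeR")
  set.seed(2)
  n <- 150
  x <- random_nb_counts(n, 4, 30, 0.2, 2)
  x$counts[1:15, x$group != "no_cancer"] <-
    matrix(rnbinom(15 * 8, mu = 120, size = 5), 15)
  de <- nb_exact_test(x, 0.2)
  dg <- edgeR::DGEList(counts = x$counts,
                       group = ifelse(x$group == "no_cancer", "a", "b"),
                       lib.size = unname(x$lib_size))
  et <- edgeR::exactTest(dg, pair = c("a", "b"), dispersion = 0.2)
  lp1 <- log10(de$p_value + 1e-300)
  lp2 <- log10(et$table$PValue + 1e-300)
  expect_gt(cor(lp1, lp2), 0.99)
  expect_lt(median(abs(lp1 - lp2)), 0.1)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(adjust_fdr(0.04), 0.04)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  # hand evaluation on an uneven vector
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_equal(adjust_fdr(p),
               rev(cummin(rev(pmin(1, sort(p) * 4 / seq_len(4))))))
  expect_error(adjust_fdr(c(0.2, 1.2)), "0, 1")
})

test_that("counts TSV round-trips the matrix and groups", {
  x <- random_nb_counts(12, 2, 15, 0.2, 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(x, path)
  back <- read_counts_tsv(path)
  expect_equal(back$counts, x$counts, ignore_attr = TRUE)
  expect_equal(as.character(back$group), as.character(x$group))
})
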