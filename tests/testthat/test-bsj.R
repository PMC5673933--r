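test_that("anchor index agrees with a pattern-matching oracle", {
  g <- generate_genome(1, 5000, 31)
  idx <- index_genome(g, 14)
  set.seed(32)
  starts <- sample(5000 - 13, 120)
  queries <- substring(g[[1]], starts, starts + 13)
  # some reverse-strand and absent queries
  queries <- c(queries, circfield:::revcomp(queries[1:20]),
               vapply(1:10, function(i)
                 paste(sample(c("A", "C", "G", "T"), 14, replace = TRUE),
                       collapse = ""), character(1)))
  hits <- query_anchor(idx, queries)
  subject <- Biostrings::DNAString(g[[1]])
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    fwd <- BiocGenerics::start(Biostrings::matchPattern(q, subject)) - 1L
    rev <- BiocGenerics::start(
      Biostrings::matchPattern(circfield:::revcomp(q), subject)) - 1L
    h <- hits[hits$query == qi, ]
    expect_setequal(h$pos[h$strand == "+"], fwd)
    expect_setequal(h$pos[h$strand == "-"], rev)
  }
  expect_error(index_genome(g, 5), "k must be")
})

test_that("constructed junction reads are called at the planted coordinates", {
  st <- tiny_study()
  txs <- split(st$tx, st$tx$transcript_id)
  circ <- st$truth$circs[1, ]
  ss <- circfield:::spliced_sequence(st$genome, txs[[circ$transcript_id]],
                                     circ$start, circ$end)
  rd <- paste0(substr(ss, nchar(ss) - 74, nchar(ss)), substr(ss, 1, 75))
  out <- detect_backsplice(c(r1 = rd), st$index, st$genome)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, circ$start)
  expect_equal(out$end, circ$end)
  expect_equal(out$strand, circ$strand)
  expect_equal(out$read_count, 1)
  # a contiguous genomic read yields no call
  lin <- substr(st$genome[[1]], 2001, 2150)
  out2 <- detect_backsplice(c(r1 = lin), st$index, st$genome)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "stats")[["n_linear"]], 1)
  # reads shorter than 2k are skipped, not called
  out3 <- detect_backsplice(c(r1 = substr(rd, 1, 30)), st$index, st$genome)
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "stats")[["n_short"]], 1)
})

test_that("caller recovers the full truth set on clean simulated reads", {
  st <- tiny_study()
  uj <- unique(st$calls[, c("chrom", "start", "end", "strand")])
  expect_equal(mean(junction_key(st$truth$circs) %in% junction_key(uj)), 1)
  expect_equal(mean(junction_key(uj) %in% junction_key(st$truth$circs)), 1)
  # per-sample counts match the simulated truth counts
  cm <- st$sim$counts_truth
  for (i in seq_len(nrow(st$calls))) {
    cl <- st$calls[i, ]
    cid <- native_circ_id(cl$chrom, cl$start, cl$end, cl$strand)
    expect_equal(cl$read_count, unname(cm[cid, cl$sample_id]))
  }
})

test_that("calls respect span and ordering invariants", {
  st <- tiny_study()
  expect_true(all(st$calls$start < st$calls$end))
  expect_true(all(st$calls$end - st$calls$start <= 2e6))
  expect_true(all(st$calls$read_count >= 1))
})

test_that("consensus is an intersection: identity, disjoint, partial", {
  st <- tiny_study()
  a <- st$calls[st$calls$sample_id == st$calls$sample_id[1], ]
  # identity
  cc <- consensus(a, a, slack = 0)
  expect_setequal(junction_key(cc), junction_key(a))
  expect_equal(cc$read_count[match(junction_key(a), junction_key(cc))],
               a$read_count)
  # disjoint
  b <- a
  b$start <- b$start + 10000L
  b$end <- b$end + 10000L
  expect_equal(nrow(consensus(a, b)), 0)
  # sets sharing exactly 7 junctions vs a brute-force oracle
  set.seed(42)
  mk <- function(n, off) data.frame(
    chrom = "chr9", start = off + (1:n) * 100L, end = off + (1:n) * 100L + 500L,
    strand = "+", read_count = sample(1:50, n, replace = TRUE),
    sample_id = "s", caller_id = "x", stringsAsFactors = FALSE)
  a2 <- mk(20, 0L)
  b2 <- rbind(a2[1:7, ], mk(13, 100000L))
  b2$read_count <- sample(1:50, nrow(b2), replace = TRUE)
  cc2 <- consensus(a2, b2)
  oracle <- intersect(junction_key(a2), junction_key(b2))
  expect_setequal(junction_key(cc2), oracle)
  expect_equal(length(oracle), 7)
  # commutativity of the junction set and min-count rule
  cc2r <- consensus(b2, a2)
  expect_setequal(junction_key(cc2r), junction_key(cc2))
  m <- match(junction_key(cc2), junction_key(a2))
  m2 <- match(junction_key(cc2), junction_key(b2))
  expect_equal(cc2$read_count, pmin(a2$read_count[m], b2$read_count[m2]))
  expect_error(consensus(a2, b2, slack = -1), "slack")
})

test_that("slack-based consensus tolerates breakpoint disagreement", {
  set.seed(7)
  a <- data.frame(chrom = "chr1", start = c(100L, 900L), end = c(500L, 1300L),
                  strand = "+", read_count = c(10L, 20L), sample_id = "s",
                  caller_id = "x", stringsAsFactors = FALSE)
  b <- a
  b$start <- b$start + 2L
  expect_equal(nrow(consensus(a, b, slack = 0)), 0)
  cc <- consensus(a, b, slack = 2)
  expect_equal(nrow(cc), 2)
  expect_equal(cc$start, a$start)  # coordinates come from the first caller
})

test_that("caller output dialects normalize coordinates correctly", {
  dir <- withr::local_tempdir()
  # ciri2: 1-based inclusive
  ciri <- file.path(dir, "x.ciri")
  writeLines(c(paste("circRNA_ID", "chr", "circRNA_start", "circRNA_end",
                     "#junction_reads", "circRNA_type", "strand", sep = "\t"),
               paste("c1", "chr1", "101", "200", "7", "exon", "+",
                     sep = "\t")), ciri)
  cc <- read_caller_output(ciri, "ciri2")
  expect_equal(cc$start, 100L)
  expect_equal(cc$end, 200L)
  expect_equal(cc$read_count, 7L)
  # circexplorer2: BED-style 0-based half-open, read count in column 13
  ce <- file.path(dir, "x.ce2")
  writeLines(paste(c("chr1", "100", "200", "circ/1", "0", "+", "100", "200",
                     "0,0,255", "1", "100", "0", "9", "1.0", "circRNA",
                     "g", "t", "n"), collapse = "\t"), ce)
  cc2 <- read_caller_output(ce, "circexplorer2")
  expect_equal(cc2$start, 100L)
  expect_equal(cc2$end, 200L)
  expect_equal(cc2$read_count, 9L)
  # native bed round-trip
  st <- tiny_study()
  a <- st$calls[st$calls$sample_id == st$calls$sample_id[1], ]
  bed <- file.path(dir, "x.bed")
  write_junction_bed(a, bed)
  back <- read_caller_output(bed, "native_bed",
                             sample_id = a$sample_id[1])
  expect_equal(back[, c("chrom", "start", "end", "strand", "read_count")],
               a[, c("chrom", "start", "end", "strand", "read_count")],
               ignore_attr = TRUE)
  expect_error(read_caller_output(file.path(dir, "missing.bed"),
                                  "native_bed"), "not found")
  writeLines("chr1\tnot_a_number", file.path(dir, "bad.bed"))
  expect_error(read_caller_output(file.path(dir, "bad.bed"), "native_bed"),
               "columns")
})
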