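test_that("genome generation is seed-deterministic with the right shape", {
  g1 <- generate_genome(2, 5000, 17)
  g2 <- generate_genome(2, 5000, 17)
  expect_identical(g1, g2)
  expect_named(g1, c("chr1", "chr2"))
  expect_equal(unname(nchar(g1)), c(5000, 5000))
  expect_true(all(strsplit(paste(g1, collapse = ""), "")[[1]] %in%
                  c("A", "C", "G", "T")))
  expect_error(generate_genome(0, 5000, 1), "n_chrom")
  expect_error(generate_genome(1, 10, 1), "chrom_length")
})

test_that("genome base composition is near-uniform", {
  g <- generate_genome(1, 10000, 23)
  freq <- table(strsplit(g[[1]], "")[[1]]) / 10000
  expect_true(all(abs(freq - 0.25) < 0.03))
})

test_that("gene models are placed without overlap and carry interior CDS", {
  g <- generate_genome(1, 100000, 5)
  tx <- generate_gene_models(g, 20, rng_seed = 6)
  expect_length(unique(tx$transcript_id), 20)
  # exons sorted and non-overlapping within transcripts
  for (tid in unique(tx$transcript_id)) {
    e <- tx[tx$transcript_id == tid, ]
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$start < e$end))
    expect_true(all(utils::head(e$end, -1) <= utils::tail(e$start, -1)))
    expect_true(e$cds_start[1] >= min(e$start) && e$cds_end[1] <= max(e$end))
  }
  # gene footprints non-overlapping per chromosome (interval oracle)
  spans <- do.call(rbind, lapply(split(tx, tx$transcript_id), function(e)
    data.frame(chrom = e$chrom[1], s = min(e$start), e = max(e$end))))
  for (ch in unique(spans$chrom)) {
    sp <- spans[spans$chrom == ch, ]
    sp <- sp[order(sp$s), ]
    expect_true(all(utils::head(sp$e, -1) <= utils::tail(sp$s, -1)))
  }
  expect_equal(nrow(generate_gene_models(g, 0, rng_seed = 1)), 0)
  expect_error(generate_gene_models(generate_genome(1, 1000, 1), 50,
                                    rng_seed = 1), "too small")
})

test_that("gtf round-trips the exon structure and CDS span", {
  g <- generate_genome(1, 50000, 8)
  tx <- generate_gene_models(g, 6, rng_seed = 9)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(tx, path)
  back <- read_gtf(path)
  ord <- function(d) d[order(d$transcript_id, d$start),
                       c("transcript_id", "gene_id", "chrom", "strand",
                         "start", "end", "cds_start", "cds_end")]
  a <- ord(tx); b <- ord(back)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("truth presets define the group structure", {
  g <- generate_genome(2, 60000, 3)
  tx <- generate_gene_models(g, 15, rng_seed = 4)
  tr0 <- generate_truth(tx, 20, "null", rng_seed = 5)
  expect_true(all(tr0$circs$mean_no_cancer == tr0$circs$mean_adjacent))
  expect_true(all(tr0$circs$mean_tumor == tr0$circs$mean_adjacent))
  tr1 <- generate_truth(tx, 20, "field_effect", rng_seed = 5)
  expect_true(sum(tr1$circs$mean_adjacent) > sum(tr1$circs$mean_tumor))
  expect_true(sum(tr1$circs$mean_tumor) > sum(tr1$circs$mean_no_cancer))
  # isoforms: some gene carries >= 2 distinct junctions
  expect_true(any(table(tr1$circs$gene_id) >= 2))
  # junction endpoints coincide with host exon boundaries
  txs <- split(tx, tx$transcript_id)
  for (i in seq_len(nrow(tr1$circs))) {
    circ <- tr1$circs[i, ]
    e <- txs[[circ$transcript_id]]
    expect_true(circ$start %in% e$start)
    expect_true(circ$end %in% e$end)
  }
  expect_equal(nrow(generate_truth(tx, 0, "null", rng_seed = 1)$circs), 0)
})

test_that("planted fold changes scale the pooled side only", {
  g <- generate_genome(1, 60000, 3)
  tx <- generate_gene_models(g, 12, rng_seed = 4)
  tr <- generate_truth(tx, 15, "null", rng_seed = 6, base_mean = c(40, 60),
                       fold_change_spec = list(n = 5, fc = 4))
  fc <- tr$circs[tr$circs$fold_change == 4, ]
  expect_equal(nrow(fc), 5)
  expect_equal(fc$mean_adjacent, fc$mean_no_cancer * 4)
  expect_equal(fc$mean_tumor, fc$mean_no_cancer * 4)
  expect_error(
    generate_truth(tx, 5, "null", rng_seed = 6,
                   fold_change_spec = c(not_a_circ = 2)),
    "unknown circ")
})

test_that("read simulation is deterministic and respects the count model", {
  st <- tiny_study()
  sim2 <- simulate_reads(st$genome, st$tx, st$truth, samples_per_group = 2,
                         linear_depth = 1, rng_seed = 14)
  expect_identical(st$sim$reads, sim2$reads)
  # empty truth, no linear depth -> no reads
  tr0 <- generate_truth(st$tx, 0, "null", rng_seed = 1)
  sim0 <- simulate_reads(st$genome, st$tx, tr0, samples_per_group = 1,
                         linear_depth = 0, rng_seed = 2)
  expect_equal(sum(lengths(sim0$reads)), 0)
  expect_error(simulate_reads(st$genome, st$tx, tr0, read_len = 30,
                              anchor_guard = 20, rng_seed = 1),
               "anchor_guard")
})

test_that("junction read yield for one circ follows the Poisson law", {
  g <- generate_genome(1, 30000, 41)
  tx <- generate_gene_models(g, 5, rng_seed = 42)
  tr <- generate_truth(tx, 1, "null", rng_seed = 43, base_mean = c(50, 50),
                       dispersion = 0, genome = g)
  sim <- simulate_reads(g, tx, tr, samples_per_group = 1, linear_depth = 0,
                        rng_seed = 44)
  reads <- sim$reads[["no_cancer_s1"]]
  # every junction read contains the exact 2 x anchor head-to-tail string
  txs <- split(tx, tx$transcript_id)
  ss <- with(tr$circs[1, ],
             circfield:::spliced_sequence(g, txs[[transcript_id]],
                                          start, end))
  jstring <- paste0(substr(ss, nchar(ss) - 19, nchar(ss)), substr(ss, 1, 20))
  n_hit <- sum(vapply(reads, function(r) grepl(jstring, r, fixed = TRUE),
                      logical(1)))
  bounds <- qpois(c(0.005, 0.995), 50)  # central 99% interval
  expect_gte(n_hit, bounds[1])
  expect_lte(n_hit, bounds[2])
})

test_that("fastq writing round-trips read sequences", {
  st <- tiny_study()
  dir <- withr::local_tempdir()
  paths <- write_reads_fastq(st$sim, dir)
  s1 <- names(st$sim$reads)[1]
  back <- read_fastq(file.path(dir, paste0(s1, ".fastq")))
  expect_identical(unname(back), unname(st$sim$reads[[s1]]))
})

test_that("miRNA resources plant exact site counts with working controls", {
  st <- tiny_study()
  planted <- data.frame(circ_id = st$truth$circs$circ_id[2:4],
                        n_sites = c(1L, 3L, 0L))
  res <- generate_mirna_resources(st$genome, st$tx, st$truth, n_mirna = 10,
                                  planted_sites = planted, rng_seed = 77)
  expect_equal(nrow(res$mirnas), 10)
  expect_true(all(nchar(res$mirnas$mature_seq) %in% 21:22))
  txs <- split(st$tx, st$tx$transcript_id)
  for (i in seq_len(nrow(res$truth$planted_sites))) {
    ps <- res$truth$planted_sites[i, ]
    circ <- st$truth$circs[st$truth$circs$circ_id == ps$circ_id, ]
    ss <- circfield:::spliced_sequence(res$genome, txs[[circ$transcript_id]],
                                       circ$start, circ$end)
    m <- res$mirnas$mature_seq[res$mirnas$mirna_id == ps$mirna_id]
    expect_equal(count_seed_matches(ss, seed_of(m)), ps$n_sites,
                 label = ps$mirna_id)
  }
  # negative controls are present with the advertised gaps
  expect_false("syn-miR-noint" %in% res$interactions$mirna_id)
  expect_true("syn-miR-nosite" %in% res$interactions$mirna_id)
  expect_false("syn-miR-node" %in% res$de_mirnas$mirna_id)
  # empty case
  res0 <- generate_mirna_resources(st$genome, st$tx, st$truth, n_mirna = 0,
                                   rng_seed = 1)
  expect_equal(nrow(res0$mirnas), 0)
})
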