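# Shared fixture builders. Expensive fixtures are cached per session so
# several test blocks can reuse the same simulated study.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small complete study: genome, models, truth, reads, index, calls
tiny_study <- function(seed = 11L, n_circ = 10L, samples_per_group = 2L,
                       base_mean = c(25, 40)) {
  key <- sprintf("study_%d_%d_%d", seed, n_circ, samples_per_group)
  cached(key, function() {
    genome <- generate_genome(2, 60000, seed)
    tx <- generate_gene_models(genome, 15, rng_seed = seed + 1L)
    truth <- generate_truth(tx, n_circ, "field_effect",
                            rng_seed = seed + 2L, base_mean = base_mean,
                            genome = genome)
    sim <- simulate_reads(genome, tx, truth,
                          samples_per_group = samples_per_group,
                          linear_depth = 1, rng_seed = seed + 3L)
    index <- index_genome(genome, 20L)
    calls <- detect_samples(sim, index, genome)
    list(genome = genome, tx = tx, truth = truth, sim = sim,
         index = index, calls = calls)
  })
}

junction_key <- function(d) paste(d$chrom, d$start, d$end, d$strand)

# hand-built two-exon plus-strand transcript on a fixed genome, for exact
# annotation arithmetic
toy_models <- function() {
  genome <- c(chrA = paste(rep("ACGT", 2500), collapse = ""))
  # overwrite with a random-ish stretch so anchors are unique where needed
  set.seed(99)
  genome[["chrA"]] <- paste(sample(c("A", "C", "G", "T"), 10000,
                                   replace = TRUE), collapse = "")
  tx <- data.frame(
    transcript_id = "T1", gene_id = "g1", gene_symbol = "GENEA",
    chrom = "chrA", strand = "+",
    start = c(1000L, 1500L, 2200L, 3000L),
    end = c(1100L, 1700L, 2500L, 3200L),
    exon_rank = 1:4, cds_start = 1500L, cds_end = 2500L,
    stringsAsFactors = FALSE)
  list(genome = genome, tx = tx)
}

# count matrix with fixed group layout
counts_fixture <- function(m, spg) {
  grp <- rep(c("no_cancer", "adjacent", "tumor"), each = spg)
  colnames(m) <- paste0(grp, "_s", rep(seq_len(spg), 3))
  new_circ_counts(m, grp)
}

random_nb_counts <- function(n, spg, mu, phi, seed) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n * spg * 3, mu = mu, size = 1 / phi),
              n, spg * 3, dimnames = list(sprintf("c%04d", seq_len(n)),
                                          NULL))
  counts_fixture(m, spg)
}
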