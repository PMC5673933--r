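# End-to-end orchestration: simulate -> detect -> consensus -> annotate ->
# quantify -> differential expression -> sponge -> enrichment -> report.
# Every stage writes plain files so stages can be rerun independently; the
# manifest records all parameters and output checksums, and a rerun with
# the same config reproduces identical checksums.

#' Default pipeline configuration
#'
#' Returns the full parameter list with defaults; override any subset via
#' `...`. Unknown keys are rejected.
#'
#' @param ... named overrides of the defaults.
#' @return named list of parameters (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    rng_seed = 17L,
    # simulate
    n_chrom = 2L, chrom_length = 100000L, n_genes = 25L,
    n_circ = 30L, group_profile = "field_effect",
    samples_per_group = 8L, read_len = 150L, linear_depth = 1,
    subst_rate = 0, n_mirna = 8L,
    planted_site_counts = c(1L, 3L, 1L),
    # detect / consensus
    anchor = 20L, max_span = 2e6, min_unique = 1L, require_gtag = FALSE,
    slack = 0L,
    # quantify / de
    min_reads = 1L, presence_threshold = 1L, prior_df = 10, top_n = 7L,
    alpha = 0.05,
    # annotation
    length_mode = "spliced",
    # optional external inputs (paths); NULL means simulate natively
    genome_fasta = NULL, gtf = NULL, reads_dir = NULL,
    caller_a_files = NULL, caller_b_files = NULL,
    mirna_fasta = NULL, interactions_tsv = NULL, de_mirnas_tsv = NULL,
    gmt = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#' @param path YAML file with a subset of the keys of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the whole pipeline
#'
#' Executes simulate (unless external inputs are configured), detect,
#' consensus, annotate, quantify, differential expression, sponge candidate
#' nomination, enrichment and reporting. All artifacts are written under
#' `outdir`; a manifest (`manifest.json`) echoes every parameter and the
#' md5 checksum of every written file.
#'
#' @param config a `pipeline_config`.
#' @param outdir output directory.
#' @return invisible list with the in-memory results of every stage
#'   (`truth`, `calls`, `consensus`, `annotation`, `counts`, `top_tables`,
#'   `venn`, `de`, `sponge`, `enrichment`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(path) { written <<- c(written, path); path }
  cfg <- config

  ## stage: simulate (or load external inputs)
  if (is.null(cfg$genome_fasta)) {
    genome <- generate_genome(cfg$n_chrom, cfg$chrom_length, cfg$rng_seed)
    transcripts <- generate_gene_models(genome, cfg$n_genes,
                                        rng_seed = cfg$rng_seed + 1L)
    truth <- generate_truth(transcripts, cfg$n_circ,
                            group_profile = cfg$group_profile,
                            rng_seed = cfg$rng_seed + 2L,
                            genome = genome)
    planted <- if (length(cfg$planted_site_counts) && nrow(truth$circs)) {
      idx <- seq_len(min(length(cfg$planted_site_counts),
                         nrow(truth$circs)))
      data.frame(circ_id = truth$circs$circ_id[idx],
                 n_sites = cfg$planted_site_counts[idx],
                 stringsAsFactors = FALSE)
    } else NULL
    res <- generate_mirna_resources(genome, transcripts, truth,
                                    n_mirna = cfg$n_mirna,
                                    planted_sites = planted,
                                    rng_seed = cfg$rng_seed + 3L)
    genome <- res$genome; truth <- res$truth
    mirnas <- res$mirnas; interactions <- res$interactions
    de_mirnas <- res$de_mirnas
    sim <- simulate_reads(genome, transcripts, truth,
                          samples_per_group = cfg$samples_per_group,
                          read_len = cfg$read_len,
                          linear_depth = cfg$linear_depth,
                          subst_rate = cfg$subst_rate,
                          anchor_guard = cfg$anchor,
                          rng_seed = cfg$rng_seed + 4L)
    emit(write_genome_fasta(genome, file.path(outdir, "genome.fa")))
    emit(write_gtf(transcripts, file.path(outdir, "models.gtf")))
    utils::write.table(truth$circs,
                       emit(file.path(outdir, "truth_circs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$planted_sites,
                       emit(file.path(outdir, "truth_planted_sites.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(write_mirna_fasta(mirnas, file.path(outdir, "mirnas.fa")))
    emit(write_interactions_tsv(interactions,
                                file.path(outdir, "interactions.tsv")))
    emit(write_interactions_tsv(de_mirnas,
                                file.path(outdir, "de_mirnas.tsv")))
    for (p in write_reads_fastq(sim, file.path(outdir, "reads"))) emit(p)
    reads_list <- sim$reads
  } else {
    genome <- read_genome_fasta(cfg$genome_fasta)
    transcripts <- read_gtf(cfg$gtf)
    truth <- NULL
    mirnas <- if (!is.null(cfg$mirna_fasta))
      read_mirna_fasta(cfg$mirna_fasta) else NULL
    interactions <- if (!is.null(cfg$interactions_tsv))
      read_interactions_tsv(cfg$interactions_tsv) else NULL
    de_mirnas <- if (!is.null(cfg$de_mirnas_tsv))
      read_interactions_tsv(cfg$de_mirnas_tsv) else NULL
    fq <- list.files(cfg$reads_dir, pattern = "\\.fastq$",
                     full.names = TRUE)
    reads_list <- lapply(fq, read_fastq)
    names(reads_list) <- sub("\\.fastq$", "", basename(fq))
  }

  ## stage: detect
  index <- index_genome(genome, cfg$anchor)
  calls <- detect_samples(reads_list, index, genome,
                          max_span = cfg$max_span,
                          min_unique = cfg$min_unique,
                          require_gtag = cfg$require_gtag)

  ## stage: consensus (dual-algorithm rule; the second caller is an
  ## ingested call set when configured, else the caller against itself)
  cons <- if (!is.null(cfg$caller_b_files)) {
    ext <- do.call(rbind, lapply(names(cfg$caller_b_files), function(s)
      read_caller_output(cfg$caller_b_files[[s]],
                         dialect = "ciri2", sample_id = s)))
    do.call(rbind, lapply(unique(calls$sample_id), function(s)
      consensus(calls[calls$sample_id == s, ],
                ext[ext$sample_id == s, ], slack = cfg$slack)))
  } else {
    do.call(rbind, lapply(unique(calls$sample_id), function(s)
      consensus(calls[calls$sample_id == s, ],
                calls[calls$sample_id == s, ], slack = cfg$slack)))
  }
  for (s in unique(cons$sample_id)) {
    emit(write_junction_bed(cons[cons$sample_id == s, ],
                            file.path(outdir, sprintf("calls_%s.bed", s))))
  }

  ## stage: annotate
  annotation <- annotate_junctions(cons, transcripts, genome,
                                   length_mode = cfg$length_mode)
  write_annotation(annotation,
                   emit(file.path(outdir, "circs_annotated.tsv")),
                   emit(file.path(outdir, "circs_spliced.fa")))
  summaries <- summarize_circs(annotation)

  ## stage: quantify
  counts <- build_matrix(cons, min_reads = cfg$min_reads)
  emit(write_counts_tsv(counts, file.path(outdir, "counts.tsv")))
  top_tables <- lapply(stats::setNames(nm = GROUP_LEVELS), function(g)
    top_expressed(counts, g, cfg$top_n))
  venn <- group_overlaps(counts, cfg$presence_threshold)
  jsonlite::write_json(
    list(regions = as.list(venn),
         union_size = attr(venn, "union_size"),
         per_group = as.list(attr(venn, "per_group"))),
    emit(file.path(outdir, "venn.json")), auto_unbox = TRUE)

  ## stage: differential expression
  disp <- estimate_dispersion(counts, prior_df = cfg$prior_df)
  de <- nb_exact_test(counts, disp, contrast = "pooled")
  de <- de[order(de$p_value), ]
  utils::write.table(de, emit(file.path(outdir, "de_results.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage: sponge candidates (top expressed circs per group)
  sponge <- NULL
  if (!is.null(mirnas) && !is.null(interactions) && !is.null(de_mirnas)) {
    top_ids <- unique(unlist(lapply(top_tables, function(t) t$circ_id)))
    scope <- annotation[annotation$circ_id %in% top_ids, , drop = FALSE]
    sponge <- candidate_mirnas(scope, mirnas, interactions, de_mirnas)
    utils::write.table(sponge,
                       emit(file.path(outdir, "sponge_candidates.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## stage: enrichment (circ-derived genes per group vs all model genes)
  background <- unique(transcripts$gene_symbol)
  pathways <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt)
              else synthetic_pathways(background)
  enrichment <- lapply(stats::setNames(nm = GROUP_LEVELS), function(g) {
    pres <- group_overlaps_presence(counts, g, cfg$presence_threshold)
    genes <- unique(stats::na.omit(
      annotation$host_gene[annotation$circ_id %in% pres]))
    genes <- intersect(genes, background)
    if (!length(genes)) return(NULL)
    enrich(genes, pathways, background)
  })
  for (g in GROUP_LEVELS) {
    if (!is.null(enrichment[[g]]))
      utils::write.table(enrichment[[g]],
                         emit(file.path(outdir,
                                        sprintf("enrichment_%s.tsv", g))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## stage: report / manifest
  rel <- sort(sub(paste0("^", normalizePath(outdir), "/?"), "",
                  normalizePath(written)))
  manifest <- list(
    parameters = unclass(cfg)[!vapply(unclass(cfg), is.null, logical(1))],
    files = lapply(stats::setNames(nm = rel), function(b)
      unname(tools::md5sum(file.path(outdir, b)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(truth = truth,
                 truth_counts = if (exists("sim", inherits = FALSE))
                   sim$counts_truth else NULL,
                 calls = calls, consensus = cons,
                 annotation = annotation, summaries = summaries,
                 counts = counts, top_tables = top_tables, venn = venn,
                 dispersion = disp, de = de, sponge = sponge,
                 enrichment = enrichment, manifest = manifest))
}

# circ ids present in one group at the given threshold
group_overlaps_presence <- function(x, group, presence_threshold = 1L) {
  tot <- rowSums(x$counts[, x$group == group, drop = FALSE])
  rownames(x$counts)[tot >= presence_threshold]
}

# deterministic fake pathway table over the model genes (artifact plumbing
# for report shape when no GMT is supplied): consecutive chunks of the
# sorted gene list
synthetic_pathways <- function(genes, chunk = 8L) {
  genes <- sort(genes)
  idx <- split(genes, ceiling(seq_along(genes) / chunk))
  stats::setNames(idx, sprintf("SYNSET%02d", seq_along(idx)))
}
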