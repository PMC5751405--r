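#' Specification of a synthetic metagenomic community
#'
#' Describes a community of genomes simulated from per-genome Markov
#' chains, fragmented into contigs and assigned coverages drawn from a
#' configurable number of distinct coverage distributions. Strain
#' structure is emulated by letting genomes of one group share a parent
#' transition table with a small multiplicative perturbation.
#'
#' @param n_genomes Number of genomes (default 30).
#' @param n_coverage_distributions Number of distinct coverage
#'   distribution centers, in 1..n_genomes (default 1).
#' @param coverage_range Low/high bounds for coverage values (default
#'   c(1, 300)).
#' @param contig_length_range Min/max contig length in bp (default
#'   c(1000, 20000)).
#' @param genome_length Genome length in bp (default 1e5, a desk-scale
#'   stand-in for full genomes).
#' @param markov_order Order of the per-genome composition model (default
#'   3; order-3 chains directly shape tetramer statistics).
#' @param gc_range Range the per-genome target GC fractions are drawn
#'   from (default c(0.3, 0.7)).
#' @param strain_groups Optional integer vector (length `n_genomes`)
#'   assigning genomes to strain groups; genomes in one group share a
#'   parent transition table. Default: every genome its own group.
#' @param strain_epsilon Log-scale sd of the within-group perturbation of
#'   transition probabilities (default 0.01; 0 makes strains identical).
#' @param gc_row_sd sd of the per-context GC jitter around the genome
#'   target (default 0.03).
#' @param coverage_noise_sd Log-scale sd of within-genome coverage noise
#'   (default 0.1).
#' @param coverage_centers Optional fixed coverage centers (length
#'   `n_coverage_distributions`); default draws them uniformly from
#'   `coverage_range`.
#' @param seed Optional integer seed; [simulate_community()] sets it when
#'   present, making regeneration byte-identical.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 30L,
                           n_coverage_distributions = 1L,
                           coverage_range = c(1, 300),
                           contig_length_range = c(1000L, 20000L),
                           genome_length = 100000L,
                           markov_order = 3L,
                           gc_range = c(0.3, 0.7),
                           strain_groups = NULL,
                           strain_epsilon = 0.01,
                           gc_row_sd = 0.03,
                           coverage_noise_sd = 0.1,
                           coverage_centers = NULL,
                           seed = NULL) {
  stopifnot(n_genomes >= 1L,
            n_coverage_distributions >= 1L,
            n_coverage_distributions <= n_genomes,
            coverage_range[1L] > 0, coverage_range[2L] > coverage_range[1L],
            contig_length_range[1L] >= 1L,
            contig_length_range[2L] >= contig_length_range[1L],
            genome_length >= contig_length_range[1L],
            markov_order >= 0L,
            gc_range[1L] > 0, gc_range[2L] < 1,
            strain_epsilon >= 0, gc_row_sd >= 0, coverage_noise_sd >= 0)
  if (is.null(strain_groups)) strain_groups <- seq_len(n_genomes)
  stopifnot(length(strain_groups) == n_genomes)
  if (!is.null(coverage_centers)) {
    stopifnot(length(coverage_centers) == n_coverage_distributions,
              all(coverage_centers >= coverage_range[1L]),
              all(coverage_centers <= coverage_range[2L]))
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    n_coverage_distributions = as.integer(n_coverage_distributions),
    coverage_range = coverage_range,
    contig_length_range = as.integer(contig_length_range),
    genome_length = as.integer(genome_length),
    markov_order = as.integer(markov_order),
    gc_range = gc_range,
    strain_groups = as.integer(strain_groups),
    strain_epsilon = strain_epsilon,
    gc_row_sd = gc_row_sd,
    coverage_noise_sd = coverage_noise_sd,
    coverage_centers = coverage_centers,
    seed = seed
  ), class = "community_spec")
}

#' Random Markov transition table with a target GC content
#'
#' For every context the GC total is the genome target jittered by
#' `gc_row_sd`, while the C-vs-G and A-vs-T splits are randomized per
#' context. This pins the chain's GC content to the target while leaving
#' ample tetramer-level variation between genomes.
#'
#' @param order Markov order (>= 0).
#' @param gc_target Target GC fraction, in (0, 1).
#' @param gc_row_sd Per-context GC jitter sd.
#' @return A 4^order x 4 row-stochastic matrix with columns A, C, G, T.
#' @export
simulate_transition_table <- function(order, gc_target, gc_row_sd = 0.03) {
  if (gc_target <= 0 || gc_target >= 1) {
    stop("GC target must be strictly between 0 and 1")
  }
  n_ctx <- 4L^order
  gc_row <- pmin(pmax(gc_target + rnorm(n_ctx, 0, gc_row_sd), 0.02), 0.98)
  u <- runif(n_ctx, 0.2, 0.8)  # C share of GC
  v <- runif(n_ctx, 0.2, 0.8)  # A share of AT
  tab <- cbind(A = (1 - gc_row) * v,
               C = gc_row * u,
               G = gc_row * (1 - u),
               T = (1 - gc_row) * (1 - v))
  tab
}

# multiplicative log-normal perturbation of a transition table; eps = 0
# leaves it unchanged
.perturb_table <- function(parent, eps) {
  if (eps == 0) return(parent)
  p <- parent * exp(matrix(rnorm(length(parent), 0, eps), nrow(parent)))
  p / rowSums(p)
}

#' Simulate one genome sequence from a transition table
#'
#' @param genome_length Sequence length in bp.
#' @param table Transition table from [simulate_transition_table()].
#' @param order Markov order matching the table.
#' @return Character string over A/C/G/T.
#' @export
simulate_genome <- function(genome_length, table, order) {
  base_probs <- colMeans(table)
  init <- if (order > 0) {
    sample(0:3, order, replace = TRUE, prob = base_probs)
  } else integer(0)
  idx <- markov_chain_cpp(as.integer(genome_length), table,
                          as.integer(order), as.integer(init))
  paste(c("A", "C", "G", "T")[idx + 1L], collapse = "")
}

#' Fragment a genome into contigs
#'
#' Cuts non-overlapping fragments left to right with lengths uniform in
#' the configured range; a trailing piece shorter than the minimum is
#' discarded, so the concatenated contigs reconstruct a prefix of the
#' genome.
#'
#' @param genome Character string (the genome sequence).
#' @param genome_id Identifier used to prefix contig ids.
#' @param length_range Min/max contig length in bp.
#' @return A [Biostrings::DNAStringSet] named `<genome_id>_c<k>`.
#' @export
fragment_to_contigs <- function(genome, genome_id,
                                length_range = c(1000L, 20000L)) {
  glen <- nchar(genome)
  if (glen < length_range[1L]) stop("genome shorter than minimum contig length")
  starts <- integer(0)
  ends <- integer(0)
  pos <- 1L
  while (glen - pos + 1L >= length_range[1L]) {
    len <- if (length_range[1L] == length_range[2L]) length_range[1L] else
      sample(length_range[1L]:length_range[2L], 1L)
    len <- min(len, glen - pos + 1L)
    starts <- c(starts, pos)
    ends <- c(ends, pos + len - 1L)
    pos <- pos + len
  }
  seqs <- substring(genome, starts, ends)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s_c%03d", genome_id, seq_along(seqs))
  out
}

#' Assign coverage distributions to genomes and draw contig coverages
#'
#' Draws `n_coverage_distributions` centers uniformly from the coverage
#' range (unless fixed in the spec), partitions the genomes as evenly as
#' possible among the centers, and samples each contig's coverage as its
#' genome center times log-normal noise, clipped to the range.
#'
#' @param spec A [community_spec()].
#' @param contig_genome Named character vector contig id -> genome id.
#' @return List with `centers`, `genome_center` (named by genome) and
#'   `coverage` (named by contig id).
#' @export
assign_coverages <- function(spec, contig_genome) {
  k <- spec$n_coverage_distributions
  centers <- if (!is.null(spec$coverage_centers)) spec$coverage_centers else
    runif(k, spec$coverage_range[1L], spec$coverage_range[2L])
  genomes <- unique(contig_genome)
  center_idx <- sort(rep_len(seq_len(k), length(genomes)))
  genome_center <- stats::setNames(centers[center_idx], genomes)
  cov <- genome_center[contig_genome] * rlnorm(length(contig_genome), 0,
                                               spec$coverage_noise_sd)
  cov <- pmin(pmax(cov, spec$coverage_range[1L]), spec$coverage_range[2L])
  list(centers = centers,
       genome_center = genome_center,
       coverage = stats::setNames(as.numeric(cov), names(contig_genome)))
}

#' Simulate a synthetic community
#'
#' Generates genomes, contigs, coverages and the ground-truth table for a
#' [community_spec()]. With a seed in the spec, regeneration is
#' byte-identical.
#'
#' @param spec A [community_spec()].
#' @return List of class `community` with `contigs`
#'   ([Biostrings::DNAStringSet]), `coverage` (named numeric), `truth`
#'   (data.frame id, genome), `genome_gc` (target GC per genome),
#'   `centers`, `genome_center` and `spec`.
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  genome_ids <- sprintf("g%02d", seq_len(spec$n_genomes))
  groups <- spec$strain_groups
  parent_tables <- list()
  parent_gc <- numeric(0)
  tables <- vector("list", spec$n_genomes)
  gc_targets <- numeric(spec$n_genomes)
  for (i in seq_len(spec$n_genomes)) {
    g <- as.character(groups[i])
    if (is.null(parent_tables[[g]])) {
      gc <- runif(1, spec$gc_range[1L], spec$gc_range[2L])
      parent_tables[[g]] <- simulate_transition_table(spec$markov_order, gc,
                                                      spec$gc_row_sd)
      parent_gc[g] <- gc
    }
    tables[[i]] <- .perturb_table(parent_tables[[g]], spec$strain_epsilon)
    gc_targets[i] <- parent_gc[g]
  }
  all_contigs <- vector("list", spec$n_genomes)
  for (i in seq_len(spec$n_genomes)) {
    genome <- simulate_genome(spec$genome_length, tables[[i]],
                              spec$markov_order)
    all_contigs[[i]] <- fragment_to_contigs(genome, genome_ids[i],
                                            spec$contig_length_range)
  }
  contigs <- do.call(c, all_contigs)
  contig_genome <- stats::setNames(
    rep(genome_ids, vapply(all_contigs, length, integer(1))),
    names(contigs))
  cov <- assign_coverages(spec, contig_genome)
  structure(list(
    contigs = contigs,
    coverage = cov$coverage,
    truth = data.frame(id = names(contig_genome),
                       genome = unname(contig_genome),
                       stringsAsFactors = FALSE),
    genome_gc = stats::setNames(gc_targets, genome_ids),
    centers = cov$centers,
    genome_center = cov$genome_center,
    spec = spec
  ), class = "community")
}

#' Write a community to disk
#'
#' Emits `contigs.fasta`, `coverage.tsv`, `truth.tsv` and
#' `manifest.json`.
#'
#' @param community A `community` from [simulate_community()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(community$contigs,
                              file.path(dir, "contigs.fasta"))
  cov <- data.frame(id = names(community$coverage),
                    coverage = unname(community$coverage))
  write.table(cov, file.path(dir, "coverage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(community$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  spec <- community$spec
  manifest <- list(
    n_genomes = spec$n_genomes,
    n_coverage_distributions = spec$n_coverage_distributions,
    seed = spec$seed,
    genome_length = spec$genome_length,
    n_contigs = length(community$contigs),
    coverage_centers = as.numeric(community$centers)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Specs for the coverage-distribution benchmark suite
#'
#' One spec per (number of distinct coverage distributions, replicate)
#' pair: counts 1, 2, 3, 5, 6, 10, 15 and 30 by default, each with
#' `n_replicates` replicate seeds derived from `seed`. The default base
#' spec is a 30-genome multi-strain community (6 parent species of 5
#' strains each) of 100 kbp genomes.
#'
#' @param base_spec Template [community_spec()]; its
#'   `n_coverage_distributions` and `seed` are overridden per dataset.
#' @param n_distinct Vector of distinct-coverage-distribution counts.
#' @param n_replicates Replicates per count (default 10).
#' @param seed Base seed the per-dataset seeds are derived from.
#' @return List with `manifest` (data.frame n_distinct, replicate, seed)
#'   and `specs` (list of [community_spec()]s, one per dataset).
#' @export
benchmark_suite_specs <- function(base_spec = NULL,
                                  n_distinct = c(1L, 2L, 3L, 5L, 6L, 10L, 15L, 30L),
                                  n_replicates = 10L,
                                  seed = 1L) {
  if (is.null(base_spec)) {
    base_spec <- community_spec(
      n_genomes = 30L,
      strain_groups = rep(seq_len(6L), each = 5L),
      strain_epsilon = 0.01)
  }
  manifest <- expand.grid(replicate = seq_len(n_replicates),
                          n_distinct = n_distinct)
  manifest <- manifest[, c("n_distinct", "replicate")]
  manifest$seed <- seed * 1000L + seq_len(nrow(manifest))
  specs <- lapply(seq_len(nrow(manifest)), function(i) {
    s <- base_spec
    s$n_coverage_distributions <- as.integer(manifest$n_distinct[i])
    s$seed <- manifest$seed[i]
    s
  })
  list(manifest = manifest, specs = specs)
}

#' Generate the coverage-distribution benchmark suite on disk
#'
#' Realizes every dataset of [benchmark_suite_specs()] (80 datasets with
#' the defaults: 8 distinct-coverage-distribution counts x 10 replicates)
#' under `out_dir/d<count>_r<replicate>/`, plus a `manifest.tsv` listing
#' the seeds.
#'
#' @inheritParams benchmark_suite_specs
#' @param out_dir Output directory.
#' @return The manifest data.frame, invisibly.
#' @export
generate_benchmark_suite <- function(out_dir, base_spec = NULL,
                                     n_distinct = c(1L, 2L, 3L, 5L, 6L, 10L, 15L, 30L),
                                     n_replicates = 10L, seed = 1L) {
  suite <- benchmark_suite_specs(base_spec, n_distinct, n_replicates, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(suite$manifest))) {
    sub <- sprintf("d%02d_r%02d", suite$manifest$n_distinct[i],
                   suite$manifest$replicate[i])
    write_community(simulate_community(suite$specs[[i]]),
                    file.path(out_dir, sub))
  }
  write.table(suite$manifest, file.path(out_dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(suite$manifest)
}
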