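test_that("community_spec validates its fields", {
  expect_error(community_spec(n_genomes = 3, n_coverage_distributions = 5))
  expect_error(community_spec(coverage_range = c(0, 300)))
  expect_error(community_spec(gc_range = c(0, 0.7)))
  spec <- community_spec(n_genomes = 5, n_coverage_distributions = 2)
  expect_s3_class(spec, "community_spec")
  expect_identical(spec$strain_groups, 1:5)
})

test_that("order-0 chains hit the target GC content", {
  set.seed(12)
  tab <- simulate_transition_table(0, 0.5, gc_row_sd = 0)
  g <- simulate_genome(100000, tab, 0)
  gc <- gc_content(g)
  expect_gte(gc, 0.48); expect_lte(gc, 0.52)
  set.seed(13)
  tab_low <- simulate_transition_table(0, 0.3, gc_row_sd = 0)
  gc_low <- gc_content(simulate_genome(100000, tab_low, 0))
  expect_gte(gc_low, 0.28); expect_lte(gc_low, 0.32)
  expect_error(simulate_transition_table(0, 1.5), "between 0 and 1")
})

test_that("order-3 chains track the target GC within the stated band", {
  set.seed(14)
  for (target in c(0.35, 0.5, 0.65)) {
    tab <- simulate_transition_table(3, target)
    gc <- gc_content(simulate_genome(100000, tab, 3))
    expect_lt(abs(gc - target), 0.02)
  }
})

test_that("strain perturbation of zero copies the parent table", {
  set.seed(15)
  parent <- simulate_transition_table(3, 0.45)
  expect_identical(tierbin:::.perturb_table(parent, 0), parent)
  child <- tierbin:::.perturb_table(parent, 0.05)
  expect_false(identical(child, parent))
  expect_equal(rowSums(child), rep(1, nrow(child)))
})

test_that("fragmentation covers a prefix with in-range lengths", {
  set.seed(16)
  tab <- simulate_transition_table(0, 0.5)
  genome <- simulate_genome(10000, tab, 0)
  ctg <- fragment_to_contigs(genome, "g1", c(1000L, 1000L))
  expect_length(ctg, 10L)
  expect_true(all(Biostrings::width(ctg) == 1000))
  expect_identical(paste(as.character(ctg), collapse = ""), genome)

  ctg2 <- fragment_to_contigs(genome, "g1", c(1500L, 4000L))
  expect_true(all(Biostrings::width(ctg2) >= 1500))
  expect_identical(paste(as.character(ctg2), collapse = ""),
                   substr(genome, 1, sum(Biostrings::width(ctg2))))
  expect_error(fragment_to_contigs("ACGT", "g", c(1000L, 2000L)), "shorter")
})

test_that("coverage assignment respects range and even partitioning", {
  spec <- community_spec(n_genomes = 6, n_coverage_distributions = 3,
                         coverage_range = c(1, 300))
  contig_genome <- stats::setNames(
    rep(sprintf("g%02d", 1:6), each = 10),
    paste0("c", 1:60))
  set.seed(18)
  cov <- assign_coverages(spec, contig_genome)
  expect_length(cov$centers, 3L)
  expect_true(all(cov$coverage >= 1 & cov$coverage <= 300))
  per_center <- table(match(cov$genome_center, cov$centers))
  expect_true(all(per_center == 2L))
  # n_distinct = 1: every genome shares the one center
  spec1 <- community_spec(n_genomes = 6, n_coverage_distributions = 1)
  set.seed(19)
  cov1 <- assign_coverages(spec1, contig_genome)
  expect_identical(length(unique(cov1$genome_center)), 1L)
})

test_that("communities are reproducible and internally consistent", {
  spec <- community_spec(n_genomes = 4, n_coverage_distributions = 2,
                         genome_length = 20000L,
                         contig_length_range = c(1000L, 4000L), seed = 33)
  com1 <- simulate_community(spec)
  com2 <- simulate_community(spec)
  expect_identical(as.character(com1$contigs), as.character(com2$contigs))
  expect_identical(com1$coverage, com2$coverage)
  expect_identical(com1$truth, com2$truth)
  # ground truth partitions all contigs, ids unique
  expect_identical(sort(com1$truth$id), sort(names(com1$contigs)))
  expect_identical(anyDuplicated(com1$truth$id), 0L)
  expect_identical(length(unique(com1$truth$genome)), 4L)
  # per-genome mean coverage near its center
  for (g in unique(com1$truth$genome)) {
    ids <- com1$truth$id[com1$truth$genome == g]
    m <- mean(com1$coverage[ids])
    center <- com1$genome_center[[g]]
    expect_lt(abs(log(m) - log(center)), 3 * spec$coverage_noise_sd)
  }
})

test_that("benchmark suite enumerates the full 8 x 10 design", {
  suite <- benchmark_suite_specs(n_replicates = 10, seed = 2)
  expect_identical(nrow(suite$manifest), 80L)
  expect_identical(sort(unique(suite$manifest$n_distinct)),
                   c(1L, 2L, 3L, 5L, 6L, 10L, 15L, 30L))
  expect_identical(unname(table(suite$manifest$n_distinct)),
                   table(suite$manifest$n_distinct) |> unname())
  expect_true(all(table(suite$manifest$n_distinct) == 10L))
  expect_identical(anyDuplicated(suite$manifest$seed), 0L)
  expect_length(suite$specs, 80L)
  expect_identical(suite$specs[[1]]$n_coverage_distributions, 1L)
  expect_identical(suite$specs[[80]]$n_coverage_distributions, 30L)
})

test_that("suite datasets are written with manifest and round-trip", {
  tiny <- community_spec(n_genomes = 4, genome_length = 6000L,
                         contig_length_range = c(1000L, 2000L),
                         strain_groups = rep(1:2, each = 2))
  out <- file.path(tempdir(), "suite_test")
  manifest <- generate_benchmark_suite(out, base_spec = tiny,
                                       n_distinct = c(1L, 2L),
                                       n_replicates = 2L, seed = 9)
  expect_identical(nrow(manifest), 4L)
  d <- file.path(out, "d01_r01")
  expect_true(all(file.exists(file.path(d, c("contigs.fasta", "coverage.tsv",
                                             "truth.tsv", "manifest.json")))))
  contigs <- read_contigs(file.path(d, "contigs.fasta"))
  cov <- read_coverage(file.path(d, "coverage.tsv"))
  expect_identical(sort(names(contigs)), sort(names(cov)))
  truth <- read.table(file.path(d, "truth.tsv"), sep = "\t",
                      col.names = c("id", "genome"))
  expect_identical(sort(truth$id), sort(names(contigs)))
  unlink(out, recursive = TRUE)
})
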