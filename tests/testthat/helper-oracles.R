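# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (string loops, explicit enumeration) so they cannot
# share a defect with the implementation they check.

random_dna <- function(len, p_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  s <- sample(alphabet, len, replace = TRUE)
  if (p_n > 0) {
    mask <- runif(len) < p_n
    s[mask] <- "N"
  }
  paste(s, collapse = "")
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# explicit 256-mer counting of s and revcomp(s), then canonical folding
oracle_tnf <- function(s) {
  tetramers <- canonical_tetramers()
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4))[, 4:1],
                1, paste, collapse = "")
  count256 <- function(x) {
    counts <- stats::setNames(rep(0, 256), all4)
    n <- nchar(x)
    if (n >= 4) {
      for (i in seq_len(n - 3)) {
        w <- substr(x, i, i + 3)
        if (w %in% all4) counts[w] <- counts[w] + 1
      }
    }
    counts
  }
  agg <- count256(s) + count256(revcomp_chr(s))
  folded <- stats::setNames(rep(0, length(tetramers)), tetramers)
  for (w in all4) {
    key <- min(w, revcomp_chr(w))
    folded[key] <- folded[key] + agg[w]
  }
  if (sum(folded) == 0) return(NULL)
  folded / sum(folded)
}

# DBSCAN oracle: core points from explicit neighbor counts, clusters as
# connected components of the epsilon-graph restricted to core points,
# border points attached to any adjacent core cluster
oracle_dbscan <- function(points, eps, min_pts) {
  n <- nrow(points)
  dmat <- as.matrix(dist(points))
  core <- vapply(seq_len(n), function(i) sum(dmat[i, ] <= eps) >= min_pts,
                 logical(1))
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in which(core)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    stack <- i
    while (length(stack) > 0L) {
      p <- stack[[1L]]; stack <- stack[-1L]
      if (!is.na(comp[p])) next
      comp[p] <- cid
      nb <- which(core & dmat[p, ] <= eps & is.na(comp))
      stack <- c(stack, nb)
    }
  }
  border <- rep(NA_integer_, n)
  for (i in which(!core)) {
    adj <- which(core & dmat[i, ] <= eps)
    if (length(adj) > 0L) border[i] <- comp[adj[1L]]
  }
  list(core = core, core_comp = comp, border_has_cluster = !core & !is.na(border))
}

# naive re-implementation of the four binning measures from raw label
# vectors (no matrix algebra)
oracle_metrics <- function(assignment, truth) {
  ids <- names(assignment)
  classified <- ids[!is.na(assignment)]
  n_uncl <- sum(is.na(assignment))
  total <- length(classified)
  prec <- NA_real_
  if (total > 0) {
    hits <- 0
    for (b in unique(assignment[classified])) {
      members <- classified[assignment[classified] == b]
      hits <- hits + max(table(truth[members]))
    }
    prec <- 100 * hits / total
  }
  rec_hits <- 0
  for (g in unique(truth[ids])) {
    gid <- classified[truth[classified] == g]
    if (length(gid) == 0) next
    rec_hits <- rec_hits + max(table(assignment[gid]))
  }
  rec <- 100 * rec_hits / (total + n_uncl)
  f1 <- if (is.na(prec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  discovered <- character(0)
  for (g in unique(truth)) {
    size_g <- sum(truth == g)
    for (b in unique(assignment[classified])) {
      members <- classified[assignment[classified] == b]
      in_bin <- sum(truth[members] == g)
      if (in_bin > 0.5 * length(members) && in_bin > 0.5 * size_g) {
        discovered <- c(discovered, g)
      }
    }
  }
  list(precision = prec, recall = rec, f1 = f1,
       discovered = sort(unique(discovered)))
}

# write a DNAStringSet (or character) to a temporary FASTA file
write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- tempfile(fileext = ".fasta")
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", ids[i]), as.character(seqs[i]))
  }
  writeLines(lines, path)
  path
}

# small strain community used by several tests
strain_community <- function(seed, n_genomes = 3, genome_length = 400000L,
                             centers = c(5, 50, 300)) {
  spec <- community_spec(
    n_genomes = n_genomes,
    n_coverage_distributions = length(centers),
    coverage_centers = centers,
    genome_length = genome_length,
    strain_groups = rep(1L, n_genomes),
    strain_epsilon = 0.01,
    seed = seed)
  simulate_community(spec)
}
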