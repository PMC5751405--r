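test_that("pca_reduce finds the intrinsic dimension of planar data", {
  set.seed(1)
  basis <- matrix(rnorm(136 * 2), ncol = 2)
  scores_true <- matrix(rnorm(40 * 2), ncol = 2)
  X <- scores_true %*% t(basis) + matrix(0.5, 40, 136)
  scores <- pca_reduce(X, 1.0)
  expect_identical(ncol(scores), 2L)
  expect_identical(nrow(scores), 40L)
})

test_that("pca_reduce signals degenerate inputs with NULL", {
  X <- matrix(rep(1:136, each = 5), nrow = 5)
  expect_null(pca_reduce(X, 0.9))             # identical rows
  expect_null(pca_reduce(matrix(1, 1, 10), 0.9))  # single row
})

test_that("pca_reduce keeps the dimensions of an isotropic Gaussian", {
  set.seed(2)
  basis <- qr.Q(qr(matrix(rnorm(136 * 5), ncol = 5)))
  X <- matrix(rnorm(400 * 5), ncol = 5) %*% t(basis)
  scores <- pca_reduce(X, 0.9)
  expect_identical(ncol(scores), 5L)
  # variances in decreasing order
  v <- apply(scores, 2, var)
  expect_true(all(diff(v) <= 1e-8))
})

test_that("dpgmm handles single points and rejects non-finite input", {
  fit <- dpgmm_gibbs(matrix(c(1, 2), 1, 2))
  expect_identical(fit$assignment, 1L)
  expect_identical(fit$k, 1L)
  expect_error(dpgmm_gibbs(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(dpgmm_gibbs(matrix(1:10, 5), burn_in = 10, n_iterations = 5))
})

test_that("collapsed predictive matches the closed-form multivariate t", {
  d <- 3
  m0 <- c(0.5, -1, 2); kappa0 <- 0.7; nu0 <- d + 4
  S0 <- diag(c(1.2, 0.5, 2)) + 0.1
  x <- c(0.3, 0.4, -0.2)
  # empty component: prior predictive
  lp <- tierbin:::niw_log_predictive_cpp(x, matrix(numeric(0), 0, d),
                                         m0, kappa0, nu0, S0, FALSE)
  df <- nu0 - d + 1
  Sc <- S0 * (kappa0 + 1) / (kappa0 * df)
  q <- drop(t(x - m0) %*% solve(Sc) %*% (x - m0))
  lp_ref <- lgamma((df + d) / 2) - lgamma(df / 2) - d / 2 * log(df * pi) -
    0.5 * as.numeric(determinant(Sc)$modulus) - (df + d) / 2 * log1p(q / df)
  expect_equal(lp, lp_ref, tolerance = 1e-10)
  # chain rule: marginal of {x1, x2} = pred(x1 | empty) + pred(x2 | {x1})
  set.seed(4)
  x1 <- rnorm(d); x2 <- rnorm(d)
  lm2 <- tierbin:::niw_log_marginal_cpp(rbind(x1, x2), m0, kappa0, nu0, S0, FALSE)
  chain <- tierbin:::niw_log_predictive_cpp(x1, matrix(numeric(0), 0, d),
                                            m0, kappa0, nu0, S0, FALSE) +
    tierbin:::niw_log_predictive_cpp(x2, rbind(x1), m0, kappa0, nu0, S0, FALSE)
  expect_equal(lm2, chain, tolerance = 1e-10)
  # same identities for the diagonal base measure
  lpd <- tierbin:::niw_log_predictive_cpp(x, matrix(numeric(0), 0, d),
                                          m0, kappa0, nu0, diag(diag(S0)), TRUE)
  lmd <- tierbin:::niw_log_marginal_cpp(rbind(x), m0, kappa0, nu0,
                                        diag(diag(S0)), TRUE)
  expect_equal(lpd, lmd, tolerance = 1e-10)
})

test_that("dpgmm is reproducible under a fixed seed", {
  set.seed(10)
  X <- rbind(matrix(rnorm(100), ncol = 2), matrix(rnorm(100, 6), ncol = 2))
  set.seed(123); f1 <- dpgmm_gibbs(X, 150, 50)
  set.seed(123); f2 <- dpgmm_gibbs(X, 150, 50)
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$log_posterior, f2$log_posterior)
})

test_that("dpgmm recovers well-separated components", {
  # two spherical Gaussians 10 sd apart
  hits <- 0
  for (s in 1:5) {
    set.seed(s)
    X <- rbind(matrix(rnorm(120), ncol = 2),
               matrix(rnorm(120, mean = 10), ncol = 2))
    set.seed(50 + s)
    fit <- dpgmm_gibbs(X, 300, 100)
    truth <- rep(1:2, each = 60)
    agree <- mean(outer(fit$assignment, fit$assignment, "==") ==
                    outer(truth, truth, "=="))
    if (fit$k == 2 && agree >= 0.99) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # one Gaussian stays together
  hits1 <- 0
  for (s in 1:5) {
    set.seed(s); X <- matrix(rnorm(400), ncol = 2)
    set.seed(70 + s)
    if (dpgmm_gibbs(X, 300, 100)$k == 1) hits1 <- hits1 + 1
  }
  expect_gte(hits1, 4)
})

test_that("posterior k distribution is exchangeable over row permutations", {
  set.seed(31)
  X <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 4), ncol = 2))
  perm <- sample(nrow(X))
  ks <- function(M, seeds) {
    vapply(seeds, function(s) {
      set.seed(s); dpgmm_gibbs(M, 150, 50)$k
    }, integer(1))
  }
  k_orig <- ks(X, 1:20)
  k_perm <- ks(X[perm, ], 101:120)
  expect_lt(abs(mean(k_orig) - mean(k_perm)), 0.75)
})

test_that("refinement splits a mixed bin and respects primary boundaries", {
  # two species with distinct composition but identical coverage end up in
  # one primary bin; refinement must separate them
  set.seed(55)
  parent <- simulate_transition_table(3, 0.45)
  tnf <- NULL; ids <- character(0); truth <- character(0)
  lens <- integer(0)
  for (g in 1:2) {
    tab <- tierbin:::.perturb_table(parent, 0.3)
    genome <- simulate_genome(250000, tab, 3)
    ctg <- fragment_to_contigs(genome, paste0("g", g), c(1000, 20000))
    profs <- t(vapply(as.character(ctg), tetranucleotide_profile,
                      numeric(136)))
    tnf <- rbind(tnf, profs)
    ids <- c(ids, names(ctg))
    lens <- c(lens, Biostrings::width(ctg))
    truth <- c(truth, rep(paste0("g", g), length(ctg)))
  }
  rownames(tnf) <- ids
  names(truth) <- ids
  primary <- stats::setNames(rep(0L, length(ids)), ids)
  set.seed(56)
  final <- refine_bins(primary, tnf, stats::setNames(lens, ids))
  ev <- evaluate_binning(final, truth)
  expect_gte(length(unique(final[!is.na(final)])), 2L)
  expect_gte(ev$precision, 90)
})

test_that("pure bins pass refinement largely intact", {
  hits <- 0
  for (s in 1:5) {
    set.seed(800 + s)
    tab <- simulate_transition_table(3, 0.5)
    genome <- simulate_genome(250000, tab, 3)
    ctg <- fragment_to_contigs(genome, "g1", c(1000, 20000))
    tnf <- t(vapply(as.character(ctg), tetranucleotide_profile, numeric(136)))
    rownames(tnf) <- names(ctg)
    primary <- stats::setNames(rep(0L, length(ctg)), names(ctg))
    set.seed(900 + s)
    final <- refine_bins(primary, tnf,
                         stats::setNames(Biostrings::width(ctg), names(ctg)))
    if (length(unique(final[!is.na(final)])) == 1L) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("refinement conserves contigs and dissolves undersized bins", {
  set.seed(60)
  tnf <- matrix(runif(3 * 136), nrow = 3)
  tnf <- tnf / rowSums(tnf)
  rownames(tnf) <- paste0("c", 1:3)
  primary <- stats::setNames(c(0L, 0L, 0L), rownames(tnf))
  final <- refine_bins(primary, tnf, min_bin_size = 5L)
  expect_true(all(is.na(final)))
  expect_identical(attr(final, "n_dissolved"), 3L)

  # never merges: contigs from different primary bins stay apart
  set.seed(61)
  n <- 40L
  tnf2 <- matrix(runif(n * 136), nrow = n)
  tnf2 <- tnf2 / rowSums(tnf2)
  rownames(tnf2) <- paste0("c", seq_len(n))
  primary2 <- stats::setNames(rep(c(0L, 1L), each = n / 2), rownames(tnf2))
  set.seed(62)
  final2 <- refine_bins(primary2, tnf2, min_bin_size = 2L)
  for (b in unique(final2[!is.na(final2)])) {
    members <- names(final2)[!is.na(final2) & final2 == b]
    expect_identical(length(unique(primary2[members])), 1L)
  }
  expect_identical(length(final2), n)
  expect_identical(sum(!is.na(final2)) + sum(is.na(final2)), n)
})
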