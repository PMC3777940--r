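fake_null <- function(pools, pool = "column") {
  structure(list(per_regulator_null = pools, per_gene_null = NULL,
                 B = 1L, seeds = 1L, pool = pool),
            class = "rca_null")
}

test_that("empirical p-values follow the add-one tail estimator", {
  Y <- matrix(c(10, 2.5, 0.5), 3, 1,
              dimnames = list(paste0("g", 1:3), "r1"))
  null <- fake_null(list(r1 = c(1, 2, 3, 4)))
  p <- empirical_pvalues(Y, null)
  expect_equal(p["g1", 1], 1 / 5)        # above every null value
  expect_equal(p["g2", 1], (1 + 2) / 5)  # two null values >= 2.5
  expect_equal(p["g3", 1], 1)            # below every null value
  expect_error(empirical_pvalues(matrix(1, 1, 1,
                                        dimnames = list("g", "rX")), null),
               "absent from the null: rX")
})

test_that("p-values are monotone in the observed coefficient", {
  set.seed(40)
  null <- fake_null(list(r1 = abs(rnorm(500))))
  y <- sort(abs(rnorm(50)))
  Y <- matrix(y, dimnames = list(paste0("g", 1:50), "r1"))
  p <- empirical_pvalues(Y, null)
  expect_true(all(diff(p[, 1]) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("permutation null is reproducible and pools B*N values per regulator", {
  sim <- make_disjoint_sim(n_genes = 40, n_regulators = 2, n_samples = 6,
                           support_size = 8, noise_sd = 0.3, seed = 13)
  cfg <- rca_config(sparseness = 0.7, max_iters = 100, tol = 1e-5, seed = 1)
  n1 <- permutation_null(sim$X, sim$C, cfg, B = 3, seed = 19)
  n2 <- permutation_null(sim$X, sim$C, cfg, B = 3, seed = 19)
  expect_identical(n1, n2)
  expect_equal(lengths(n1$per_regulator_null),
               c(r1 = 3 * 40, r2 = 3 * 40))
  n3 <- permutation_null(sim$X, sim$C, cfg, B = 3, seed = 20)
  expect_false(identical(n1$per_regulator_null, n3$per_regulator_null))
})

test_that("per-gene pooling stores and uses the full null array", {
  sim <- make_disjoint_sim(n_genes = 30, n_regulators = 2, n_samples = 6,
                           support_size = 6, noise_sd = 0.3, seed = 14)
  cfg <- rca_config(sparseness = 0.7, max_iters = 80, tol = 1e-5, seed = 1)
  null <- permutation_null(sim$X, sim$C, cfg, B = 4, seed = 3,
                           pool = "per_gene")
  expect_equal(dim(null$per_gene_null), c(30, 2, 4))
  fit <- rca_fit(sim$X, sim$C, cfg)
  p <- empirical_pvalues(fit$Y, null)
  expect_true(all(p >= 1 / 5 & p <= 1))
})

test_that("null p-values are valid: P[p <= a] stays at or below a", {
  # global null: connectivity carries no signal. Several independent
  # observed draws are pooled to tame the Monte-Carlo noise of the check.
  set.seed(55)
  N <- 60; L <- 4; M <- 6
  X <- matrix(rnorm(N * M), N,
              dimnames = list(paste0("g", 1:N), paste0("s", 1:M)))
  cfg <- rca_config(sparseness = 0.7, max_iters = 100, tol = 1e-4, seed = 2)
  C <- random_connectivity(N, rep(10, L), rownames(X), paste0("r", 1:L))
  null <- permutation_null(X, C, cfg, B = 200, seed = 77)
  p <- unlist(lapply(1:4, function(t) {
    Ct <- random_connectivity(N, rep(10, L), rownames(X), paste0("r", 1:L))
    cfg_t <- cfg; cfg_t$seed <- 100 + t
    empirical_pvalues(rca_fit(X, Ct, cfg_t)$Y, null)
  }))
  for (a in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(p <= a), a + 0.02)
})

test_that("module calling applies the score and p-value rule in order", {
  Y <- matrix(c(0.9, 0, 0.5), 3, 1, dimnames = list(c("g1", "g2", "g3"), "r1"))
  P <- matrix(c(0.001, 0.9, 0.01), 3, 1, dimnames = dimnames(Y))
  mod <- extract_modules(Y, P, p_cutoff = 0.05, min_score = 0)
  expect_equal(mod$gene, c("g1", "g3"))
  expect_equal(mod$score, c(0.9, 0.5))

  # no-filter case keeps every non-zero coefficient
  P2 <- matrix(c(0.2, 0.3, 0.4), 3, 1, dimnames = dimnames(Y))
  mod2 <- extract_modules(Y, P2, p_cutoff = 1, min_score = 0)
  expect_setequal(mod2$gene, c("g1", "g3"))

  # everything insignificant: empty module
  P3 <- matrix(1, 3, 1, dimnames = dimnames(Y))
  expect_equal(nrow(extract_modules(Y, P3, p_cutoff = 0.05)), 0)

  # top_k truncation and gene-order invariance
  set.seed(60)
  Yr <- matrix(runif(20), 20, 1,
               dimnames = list(sprintf("g%02d", 1:20), "r1"))
  Pr <- matrix(runif(20, 0, 0.04), 20, 1, dimnames = dimnames(Yr))
  m_all <- extract_modules(Yr, Pr, top_k = 5)
  perm <- sample.int(20)
  m_perm <- extract_modules(Yr[perm, , drop = FALSE],
                            Pr[perm, , drop = FALSE], top_k = 5)
  expect_equal(m_all, m_perm)
  expect_equal(nrow(m_all), 5)
  expect_true(all(diff(abs(m_all$score)) <= 0))
})

test_that("overlap statistic matches closed forms", {
  g <- function(n) paste0("g", seq_len(n))
  res <- overlap_significance(g(5), g(5), 10)
  expect_equal(res$p, 1 / choose(10, 5))
  res2 <- overlap_significance(g(20), c(g(6), paste0("x", 1:24)), 100)
  expect_equal(res2$ratio, 1.0)   # overlap 6 = expected 20*30/100
  res3 <- overlap_significance(g(20), c(g(12), paste0("x", 1:18)), 100)
  expect_equal(res3$ratio, 2.0)
  expect_error(overlap_significance(g(8), paste0("x", 1:8), 10), "smaller")
})

test_that("overlap p-value agrees with exhaustive enumeration", {
  # brute force: enumerate all size-|B| draws from the universe and count
  # how many share >= the observed overlap with A
  enum_p <- function(nA, nB, universe, observed) {
    A <- seq_len(nA)
    draws <- combn(universe, nB)
    mean(apply(draws, 2, function(d) sum(d %in% A) >= observed))
  }
  set.seed(70)
  for (i in 1:12) {
    universe <- sample(4:12, 1)
    nA <- sample(1:(universe - 1), 1)
    nB <- sample(1:(universe - 1), 1)
    max_ov <- min(nA, nB)
    ov <- sample(max(0, nA + nB - universe):max_ov, 1)
    ids <- paste0("u", seq_len(universe))
    setA <- ids[seq_len(nA)]
    setB <- c(ids[seq_len(ov)],
              ids[setdiff(seq_len(universe), seq_len(nA))][seq_len(nB - ov)])
    res <- overlap_significance(setA, setB, universe)
    expect_equal(res$p, enum_p(nA, nB, universe, ov), tolerance = 1e-12)
  }
})

test_that("co-target table attributes genes to regulators and groups", {
  modules <- tibble::tibble(
    regulator = c("relA", "relA", "p53", "cRel"),
    gene = c("gA", "gB", "gA", "gC"))
  tab <- intersect_regulator_targets(
    modules, groups = list(nfkb = c("relA", "cRel"), p53 = "p53"))
  expect_equal(tab$n_regulators[tab$gene == "gA"], 2L)
  expect_true(tab$nfkb[tab$gene == "gC"])   # union semantics: cRel suffices
  expect_false(tab$p53[tab$gene == "gC"])
  expect_equal(tab$regulators[tab$gene == "gA"], "p53,relA")
  expect_error(intersect_regulator_targets(modules,
                                           groups = list(bad = "nope")),
               "unknown regulator")
  # disjoint modules: no gene reaches two regulators
  disj <- tibble::tibble(regulator = c("r1", "r2"), gene = c("gX", "gY"))
  expect_true(all(intersect_regulator_targets(disj)$n_regulators == 1L))
})

test_that("with standardized activities the permutation test calls true targets", {
  sim <- simulate_regulatory_data(150, 10, 3, sparseness_true = 0.8,
                                  noise_sd = 0.2, seed = 91)
  cfg <- rca_config(sparseness = 0.8, seed = 1, standardize_z = TRUE,
                    max_iters = 400, tol = 1e-6)
  fit <- rca_fit(sim$X, sim$C, cfg)
  null <- permutation_null(sim$X, sim$C, cfg, B = 50, seed = 2)
  modules <- extract_modules(fit$Y, empirical_pvalues(fit$Y, null),
                             p_cutoff = 0.05)
  expect_gt(nrow(modules), 0)
  is_true_target <- mapply(function(g, r) sim$Y_true[g, r] > 0,
                           modules$gene, modules$regulator)
  expect_gte(mean(is_true_target), 0.9)
})
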