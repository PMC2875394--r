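sim_mapping_setup <- function(seed = 50, n_admixed = 60, L = 200) {
  cfg <- simulation_config(K = 2, F_k = c(0.45, 0.45), n_pure_per_pop = 15,
                           n_admixed = n_admixed,
                           chrom_layout = rice_chrom_layout(L, 4),
                           switch_rate = 3e-7, admix_alpha = 1, seed = seed)
  sim <- simulate_panel(cfg)
  fit <- structure(list(K = 2,
                        Q = sim$truth$Q_true,
                        P = sim$truth$ancestral_freqs),
                   class = "admixture_fit")
  dimnames(fit$P) <- list(colnames(fit$Q), sim$panel$markers$id)
  la <- posterior_ancestry(sim$panel, fit, 3e-7)
  list(sim = sim, la = la)
}

test_that("kinship is allele-sharing similarity with unit diagonal", {
  p <- random_panel(n = 10, L = 30, miss = 0.1, seed = 14)
  K <- kinship_matrix(p)
  D <- allele_sharing_distance(p)
  expect_equal(K, 1 - D, tolerance = 1e-12)  # D has zero diagonal
  expect_equal(unname(diag(K)), rep(1, 10))
  expect_true(all(K >= 0 & K <= 1))
})

test_that("admixture mapping returns NA at constant-ancestry SNPs and uniform null p-values", {
  s <- sim_mapping_setup(seed = 51, n_admixed = 80, L = 300)
  admixed <- s$sim$panel$accessions$id[s$sim$truth$pop_true == "ADMIXED"]
  # ancestry predictors are correlated across SNPs, so uniformity is a
  # marginal property: check it per SNP across replicate null traits
  pmat <- vapply(1:60, function(rep) {
    set.seed(900 + rep)
    ph <- data.frame(id = s$sim$panel$accessions$id,
                     value = rnorm(nrow(s$sim$panel$calls)))
    admixture_map(s$la, ph, admixed, "pop1",
                  s$sim$panel$markers)$table$p
  }, numeric(300))
  for (snp in c(40, 137, 260))   # iid across traits at a fixed SNP
    expect_gt(ks.test(pmat[snp, ], "punif")$p.value, 0.01)
  pool <- as.vector(pmat)
  pool <- pool[!is.na(pool)]
  expect_lt(abs(mean(pool < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(pool) - 0.5), 0.05)
  # constant donor component -> NA
  set.seed(9)
  ph <- data.frame(id = s$sim$panel$accessions$id,
                   value = rnorm(nrow(s$sim$panel$calls)))
  la2 <- s$la
  la2$posterior[, 5, 1] <- 0.3
  res2 <- admixture_map(la2, ph, admixed, "pop1", s$sim$panel$markers)
  expect_true(is.na(res2$table$p[5]))
  expect_true(is.na(res2$table$effect[5]))
})

test_that("admixture mapping localizes a subpopulation-divergent causal locus", {
  s <- sim_mapping_setup(seed = 52, n_admixed = 80, L = 300)
  panel <- s$sim$panel
  admixed <- panel$accessions$id[s$sim$truth$pop_true == "ADMIXED"]
  # a mappable trait locus has divergent frequencies between the donor
  # and recipient ancestries (the amylose/grain-length situation)
  P <- s$sim$truth$ancestral_freqs
  causal <- which.max(abs(P[1, ] - P[2, ]))
  ph <- simulate_phenotype(panel, data.frame(marker = causal, effect = 2),
                           h2 = 0.6, seed = 4)
  res <- bonferroni(admixture_map(s$la, ph, admixed, "pop1",
                                  panel$markers))
  best <- which.min(res$table$p)
  expect_equal(panel$markers$chrom[best], panel$markers$chrom[causal])
  expect_lt(abs(best - causal), 20)   # within the ancestry block
  expect_true(res$table$significant[best])
  expect_equal(res$table$n_used[1], length(admixed))
})

test_that("identity kinship reduces the mixed model to OLS", {
  p <- random_panel(n = 40, L = 25, miss = 0, seed = 16)
  set.seed(8)
  ph <- data.frame(id = p$accessions$id, value = rnorm(40))
  kin <- diag(40)
  dimnames(kin) <- list(p$accessions$id, p$accessions$id)
  res <- mixed_model_assoc(p, ph, Q = NULL, kin = kin)
  for (j in c(1, 7, 20)) {
    ols <- summary(lm(ph$value ~ p$calls[, j]))$coefficients
    expect_equal(res$table$p[j], ols[2, 4], tolerance = 1e-8)
    expect_equal(res$table$effect[j], ols[2, 1], tolerance = 1e-8)
  }
})

test_that("REML variance ratio matches a dense-matrix golden-section oracle", {
  set.seed(19)
  cfg <- simulation_config(K = 2, F_k = c(0.4, 0.4), n_pure_per_pop = 30,
                           n_admixed = 0,
                           chrom_layout = rice_chrom_layout(150, 2),
                           seed = 23)
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  ph <- simulate_phenotype(panel, data.frame(marker = 40, effect = 1),
                           h2 = 0.4, seed = 2)
  kin <- kinship_matrix(panel)
  res <- mixed_model_assoc(panel, ph, Q = NULL, kin = kin)
  y <- ph$value
  X <- matrix(1, 60, 1)
  oracle <- optimize(function(ld) reml_dense(exp(ld), y, X, kin),
                     c(-12, 12), maximum = TRUE, tol = 1e-9)
  expect_equal(res$delta, exp(oracle$maximum),
               tolerance = 1e-3)
  # and the criterion value itself agrees at the optimum
  expect_gt(res$h2_null, 0)
})

test_that("monomorphic SNPs are dropped as singular designs", {
  p <- random_panel(n = 30, L = 10, miss = 0, seed = 26)
  p$calls[, 4] <- 0L
  set.seed(2)
  ph <- data.frame(id = p$accessions$id, value = rnorm(30))
  kin <- diag(30)
  dimnames(kin) <- list(p$accessions$id, p$accessions$id)
  res <- mixed_model_assoc(p, ph, NULL, kin)
  expect_true(is.na(res$table$p[4]))
  expect_false(anyNA(res$table$p[-4]))
})

test_that("Bonferroni thresholds and flags follow the test count", {
  mk_res <- function(p) structure(list(method = "admixture_map",
                                       table = data.frame(p = p)),
                                  class = "mapping_result")
  r1 <- bonferroni(mk_res(0.04), alpha = 0.05)
  expect_equal(r1$bonferroni_threshold, 0.05)
  expect_true(r1$table$significant)
  r2 <- bonferroni(mk_res(runif(1311)), alpha = 0.05)
  expect_equal(r2$bonferroni_threshold, 0.05 / 1311, tolerance = 1e-12)
  expect_equal(signif(r2$bonferroni_threshold, 4), 3.814e-5)
  r3 <- bonferroni(mk_res(rep(1, 10)))
  expect_equal(sum(r3$table$significant), 0)
  # NA p-values do not count as tests
  r4 <- bonferroni(mk_res(c(0.01, NA, NA, 0.5)))
  expect_equal(r4$bonferroni_threshold, 0.05 / 2)
  expect_error(bonferroni(mk_res(NA_real_)), "no non-NA")
})
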