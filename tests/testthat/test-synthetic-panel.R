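small_layout <- function(L = 60, n_chrom = 3, spacing = 250000)
  rice_chrom_layout(L, n_chrom, spacing)

test_that("Balding-Nichols draws hit the degenerate limit and are reproducible", {
  fr0 <- draw_subpop_freqs(3, 50, c(0.2, 0.8), F_k = c(0, 0, 0), seed = 9)
  expect_equal(fr0$P[1, ], fr0$p_anc)
  expect_equal(fr0$P[2, ], fr0$P[3, ])
  a <- draw_subpop_freqs(4, 100, F_k = rep(0.3, 4), seed = 5)
  b <- draw_subpop_freqs(4, 100, F_k = rep(0.3, 4), seed = 5)
  expect_identical(a, b)
  expect_error(draw_subpop_freqs(2, 10, F_k = c(0.5, 1.2)), "F_k")
})

test_that("a pure panel has one-hot ancestry and constant mosaics", {
  cfg <- simulation_config(K = 3, F_k = c(.3, .3, .3), n_pure_per_pop = 5,
                           n_admixed = 0, chrom_layout = small_layout(),
                           seed = 2)
  sim <- simulate_panel(cfg)
  expect_true(all(rowSums(sim$truth$Q_true) == 1))
  expect_true(all(apply(sim$truth$Q_true, 1, max) == 1))
  expect_true(all(apply(sim$truth$local_ancestry_true, 1,
                        function(x) length(unique(x))) == 1))
})

test_that("Q_true rows sum to one and the same seed reproduces the panel", {
  cfg <- simulation_config(K = 4, F_k = rep(.3, 4), n_pure_per_pop = 4,
                           n_admixed = 10, chrom_layout = small_layout(),
                           seed = 11)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$panel$calls, s2$panel$calls)
  expect_identical(s1$truth$local_ancestry_true,
                   s2$truth$local_ancestry_true)
  expect_equal(unname(rowSums(s1$truth$Q_true)), rep(1, 26),
               tolerance = 1e-12)
  expect_true(all(s1$truth$local_ancestry_true %in% 1:4))
})

test_that("forced introgression events mark every recipient as carrier", {
  ev <- list(donor = 2, recipient = 1, chrom = 2, start_bp = 250000,
             end_bp = 250000 * 8, carrier_fraction = 1)
  cfg <- simulation_config(K = 2, F_k = c(.3, .3), n_pure_per_pop = 20,
                           n_admixed = 0, chrom_layout = small_layout(),
                           introgression_events = list(ev), seed = 4)
  sim <- simulate_panel(cfg)
  carriers <- sim$truth$introgression_carriers[[1]]
  pop1 <- sim$panel$accessions$id[sim$truth$pop_true == "pop1"]
  expect_setequal(carriers, pop1)
  span <- with(sim$panel$markers, which(chrom == 2 & pos_bp >= 250000 &
                                          pos_bp <= 250000 * 8))
  expect_true(all(sim$truth$local_ancestry_true[carriers, span] == 2))
  # events must stay inside the chromosome
  bad <- list(donor = 2, recipient = 1, chrom = 2, start_bp = 1,
              end_bp = 9e9, carrier_fraction = 1)
  expect_error(simulation_config(K = 2, F_k = c(.3, .3),
                                 chrom_layout = small_layout(),
                                 introgression_events = list(bad)),
               "beyond")
})

test_that("realized allele frequencies converge to the generating p_kl", {
  cfg <- simulation_config(K = 2, F_k = c(.4, .4), n_pure_per_pop = 400,
                           n_admixed = 0, chrom_layout = small_layout(40, 1),
                           seed = 8)
  sim <- simulate_panel(cfg)
  for (k in 1:2) {
    rows <- sim$truth$pop_true == paste0("pop", k)
    fhat <- colMeans(sim$panel$calls[rows, ])
    # binomial SE at n=400 is <= 0.025; allow 4 SEs
    expect_lt(max(abs(fhat - sim$truth$ancestral_freqs[k, ])), 0.1)
  }
})

test_that("mosaic switch counts are consistent with the switch rate", {
  lay <- rice_chrom_layout(400, 2, 200000)
  cfg <- simulation_config(K = 2, F_k = c(.3, .3), n_pure_per_pop = 0,
                           n_admixed = 60, chrom_layout = lay,
                           switch_rate = 2e-7, admix_alpha = 1, seed = 13)
  sim <- simulate_panel(cfg)
  anc <- sim$truth$local_ancestry_true
  chrom <- sim$panel$markers$chrom
  obs <- sum(vapply(seq_len(nrow(anc)), function(i)
    sum(vapply(unique(chrom), function(ch)
      sum(diff(anc[i, chrom == ch]) != 0), numeric(1))), numeric(1)))
  # expected visible switches: per gap, (1 - exp(-r d)) * P(redraw differs)
  gap_p <- 1 - exp(-2e-7 * 200000)
  Q <- sim$truth$Q_true
  exp_sw <- sum(vapply(seq_len(nrow(Q)), function(i)
    (398) * gap_p * (1 - sum(Q[i, ]^2)), numeric(1)))
  expect_gt(obs, 0.75 * exp_sw)
  expect_lt(obs, 1.25 * exp_sw)
})

test_that("phenotypes respect heritability and determinism", {
  cfg <- simulation_config(K = 2, F_k = c(.4, .4), n_pure_per_pop = 250,
                           n_admixed = 0, chrom_layout = small_layout(40, 1),
                           seed = 21)
  sim <- simulate_panel(cfg)
  panel <- sim$panel
  causal <- data.frame(marker = "snp0010", effect = 1.5)
  # h2 = 0: phenotype is independent noise
  y0 <- simulate_phenotype(panel, causal, h2 = 0, seed = 1)
  g <- panel$calls[, "snp0010"]
  expect_lt(abs(cor(y0$value, g)), 0.15)
  # determinism
  expect_identical(simulate_phenotype(panel, causal, h2 = 0.5, seed = 3),
                   simulate_phenotype(panel, causal, h2 = 0.5, seed = 3))
  # empirical genetic variance fraction near h2 over replicates
  fr <- vapply(1:20, function(s) {
    y <- simulate_phenotype(panel, causal, h2 = 0.5, seed = s)$value
    gv <- 1.5 * g
    var(gv) / var(y)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.1)
  expect_error(simulate_phenotype(panel,
                                  data.frame(marker = "nope", effect = 1),
                                  0.5, 1), "not present")
})
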