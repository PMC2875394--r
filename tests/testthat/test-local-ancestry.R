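make_fit <- function(Q, P, ids = NULL, pops = NULL) {
  K <- ncol(Q)
  pops <- pops %||% paste0("pop", seq_len(K))
  dimnames(Q) <- list(ids %||% paste0("s", seq_len(nrow(Q))), pops)
  dimnames(P) <- list(pops, paste0("m", seq_len(ncol(P))))
  structure(list(K = K, Q = Q, P = P), class = "admixture_fit")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

rdirichlet_la <- function(n, k) {
  x <- matrix(rgamma(n * k, 1), n, k)
  x / rowSums(x)
}

test_that("uninformative emissions return the global ancestry everywhere", {
  p <- random_panel(n = 4, L = 8, miss = 0, seed = 1)
  K <- 3
  P <- matrix(0.4, K, 8)  # identical frequencies across clusters
  Q <- rbind(c(.2, .3, .5), c(1, 0, 0), c(.6, .2, .2), c(1/3, 1/3, 1/3))
  la <- posterior_ancestry(p, make_fit(Q, P), r = 1e-7)
  for (l in 1:8)
    expect_equal(unname(la$posterior[, l, ]), unname(Q), tolerance = 1e-12)
})

test_that("the no-linkage limit factorizes over sites", {
  p <- random_panel(n = 5, L = 10, miss = 0.2, seed = 6)
  K <- 2
  set.seed(2)
  P <- matrix(runif(K * 10, .1, .9), K)
  Q <- cbind(runif(5, .1, .9)); Q <- cbind(Q, 1 - Q)
  la <- posterior_ancestry(p, make_fit(Q, P), r = Inf)
  for (i in 1:5) for (l in 1:10) {
    g <- p$calls[i, l]
    e <- if (is.na(g)) c(1, 1) else if (g == 1) P[, l] else 1 - P[, l]
    expect_equal(la$posterior[i, l, ], Q[i, ] * e / sum(Q[i, ] * e),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("forward-backward matches brute-force path enumeration", {
  for (seed in 1:8) {
    set.seed(seed)
    K <- sample(2:3, 1); L <- sample(4:8, 1)
    p <- random_panel(n = 1, L = L, miss = 0.2, n_chrom = 1, seed = seed)
    P <- matrix(runif(K * L, .05, .95), K)
    q <- as.vector(rdirichlet_la(1, K))
    r <- 10^runif(1, -7, -5.5)
    la <- posterior_ancestry(p, make_fit(matrix(q, 1), P), r)
    oracle <- hmm_brute_force(p$calls[1, ], q, P, p$markers$pos_bp, r)
    expect_lt(max(abs(la$posterior[1, , ] - oracle$post)), 1e-10)
    expect_equal(la$loglik[1], oracle$loglik, tolerance = 1e-10)
    expect_equal(la$loglik[1], la$loglik_backward[1], tolerance = 1e-8)
  }
})

test_that("posteriors are normalized and forward/backward likelihoods agree", {
  p <- random_panel(n = 12, L = 60, miss = 0.1, n_chrom = 3, seed = 4)
  set.seed(5)
  K <- 3
  P <- matrix(runif(K * 60, .05, .95), K)
  Q <- rdirichlet_la(12, K)
  la <- posterior_ancestry(p, make_fit(Q, P), 2e-7)
  expect_lt(max(abs(apply(la$posterior, c(1, 2), sum) - 1)), 1e-8)
  expect_lt(max(abs(la$loglik - la$loglik_backward)), 1e-8)
})

test_that("grid selection of the switch rate honors its contract", {
  p <- random_panel(n = 6, L = 30, miss = 0, n_chrom = 2, seed = 9)
  set.seed(1)
  P <- matrix(runif(60, .1, .9), 2)
  Q <- rdirichlet_la(6, 2)
  fit <- make_fit(Q, P)
  expect_equal(as.numeric(fit_switch_rate(p, fit, grid = 3e-8)), 3e-8)
  r <- fit_switch_rate(p, fit, grid = 10^seq(-9, -6, 0.5))
  ll <- attr(r, "grid_loglik")
  expect_equal(unname(ll[which.max(ll)]),
               sum(posterior_ancestry(p, fit, as.numeric(r))$loglik))
  expect_true(all(max(ll) >= ll))
  expect_error(fit_switch_rate(p, fit, grid = numeric(0)), "empty")
})

test_that("the selected switch rate tracks the generating rate", {
  rho <- 1e-7
  cfg <- simulation_config(K = 2, F_k = c(.5, .5), n_pure_per_pop = 5,
                           n_admixed = 40,
                           chrom_layout = rice_chrom_layout(600, 6),
                           switch_rate = rho, admix_alpha = 1, seed = 17)
  sim <- simulate_panel(cfg)
  fit <- make_fit(sim$truth$Q_true, sim$truth$ancestral_freqs,
                  ids = sim$panel$accessions$id)
  grid <- 10^seq(log10(rho) - 1, log10(rho) + 1, by = 0.25)
  r <- as.numeric(fit_switch_rate(sim$panel, fit, grid))
  expect_lte(abs(log10(r) - log10(rho)), 0.25 + 1e-9)
})

test_that("introgression profiles average the donor component with a nearest-rank cutoff", {
  # hand-built local ancestry: 2 recipients, 1 other, 100 SNPs, 2 clusters
  post <- array(0, c(3, 100, 2),
                dimnames = list(c("r1", "r2", "x"), paste0("m", 1:100),
                                c("pop1", "pop2")))
  donor_means <- c(rep(0.01, 95), rep(0.5, 5))
  post[1, , 2] <- donor_means; post[2, , 2] <- donor_means
  post[, , 1] <- 1 - post[, , 2]
  la <- structure(list(posterior = post, K = 2,
                       pop_names = c("pop1", "pop2")),
                  class = "local_ancestry")
  labels <- c(r1 = "pop1", r2 = "pop1", x = "pop2")
  prof <- mean_introgression(la, labels, "pop1", "pop2")
  expect_equal(unname(prof$values), donor_means)
  # nearest-rank: ceiling(0.95 * 100) = 95th smallest = 0.01
  expect_equal(prof$threshold_95, 0.01)
  expect_equal(prof$n_accessions, 2)
  expect_error(mean_introgression(la, labels, "pop1", "pop1"), "differ")
  expect_error(mean_introgression(la, labels, "nope", "pop2"), "labeled")
  # all-zero donor posterior gives a zero profile and zero threshold
  post0 <- post; post0[, , 2] <- 0; post0[, , 1] <- 1
  la0 <- structure(list(posterior = post0, K = 2,
                        pop_names = c("pop1", "pop2")),
                   class = "local_ancestry")
  prof0 <- mean_introgression(la0, labels, "pop1", "pop2")
  expect_true(all(prof0$values == 0))
  expect_equal(prof0$threshold_95, 0)
})

test_that("segment calling applies the >=5-SNP run rule", {
  mk <- data.frame(id = paste0("m", 1:20), chrom = rep(1:2, each = 10),
                   pos_bp = rep(seq(1e5, 1e6, length.out = 10), 2),
                   ref = "A", alt = "G")
  mkpost <- function(v) {
    post <- array(0, c(1, 20, 2),
                  dimnames = list("a1", mk$id, c("pop1", "pop2")))
    post[1, , 2] <- v; post[1, , 1] <- 1 - v
    structure(list(posterior = post, K = 2,
                   pop_names = c("pop1", "pop2")),
              class = "local_ancestry")
  }
  # 4-SNP run: below the minimum, no call
  v <- rep(0, 20); v[3:6] <- 0.9
  expect_equal(nrow(call_segments(mkpost(v), mk, "a1", "pop2")), 0)
  # exactly 5 SNPs: one call
  v <- rep(0, 20); v[3:7] <- 0.9
  cc <- call_segments(mkpost(v), mk, "a1", "pop2")
  expect_equal(nrow(cc), 1)
  expect_equal(cc$n_snps, 5)
  expect_equal(cc$start_bp, mk$pos_bp[3])
  expect_equal(cc$end_bp, mk$pos_bp[7])
  expect_equal(cc$chrom, 1)
  # 5 + 3 split by one sub-threshold SNP: only the 5-run is called
  v <- rep(0, 20); v[1:5] <- 0.9; v[6] <- 0.2; v[7:9] <- 0.9
  cc <- call_segments(mkpost(v), mk, "a1", "pop2")
  expect_equal(nrow(cc), 1)
  expect_equal(cc$n_snps, 5)
  # runs do not cross chromosome boundaries
  v <- rep(0, 20); v[8:13] <- 0.9
  cc <- call_segments(mkpost(v), mk, "a1", "pop2")
  expect_equal(nrow(cc), 0)  # 3 SNPs on chr1 + 3 on chr2
  # boundary: posterior must strictly exceed post_min
  v <- rep(0, 20); v[1:5] <- 0.5
  expect_equal(nrow(call_segments(mkpost(v), mk, "a1", "pop2",
                                  post_min = 0.5)), 0)
})

test_that("BED export converts to 0-based half-open intervals", {
  calls <- data.frame(accession_id = "a", donor_pop = "pop2", chrom = 3,
                      start_bp = 100001, end_bp = 400000, n_snps = 6,
                      mean_posterior = 0.8)
  f <- tempfile(fileext = ".bed")
  write_calls_bed(calls, f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, 100000)
  expect_equal(bed$V3, 400000)
})
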