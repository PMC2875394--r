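# Independent oracle implementations used to verify the package's fast
# paths on small instances. These deliberately use brute force / naive
# formulas and share no code with the implementation under test.

# Random small panel with given missingness.
random_panel <- function(n = 6, L = 10, miss = 0.1, n_chrom = 2,
                         seed = 1) {
  set.seed(seed)
  calls <- matrix(rbinom(n * L, 1, runif(L, 0.2, 0.8)[rep(1:L, each = n)]),
                  n, L)
  if (miss > 0) calls[runif(n * L) < miss] <- NA_integer_
  # ensure no all-missing column
  for (j in which(colSums(!is.na(calls)) == 0)) calls[1, j] <- 0L
  chrom <- sort(rep_len(seq_len(n_chrom), L))
  pos <- unlist(lapply(split(seq_len(L), chrom), function(ix)
    sort(sample.int(1e6, length(ix)))))
  markers <- data.frame(id = paste0("m", seq_len(L)), chrom = chrom,
                        pos_bp = pos, ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
  rownames(calls) <- paste0("s", seq_len(n))
  genotype_panel(calls, markers)
}

# Brute-force HMM posterior by enumeration over all K^L hidden paths
# (one accession, one chromosome).
hmm_brute_force <- function(g, q, P, pos, r) {
  L <- length(g); K <- length(q)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
  stay <- exp(-r * diff(pos))
  pr <- apply(paths, 1, function(z) {
    w <- q[z[1]]
    if (L > 1) for (j in 2:L)
      w <- w * (stay[j - 1] * (z[j] == z[j - 1]) +
                  (1 - stay[j - 1]) * q[z[j]])
    for (j in seq_len(L)) if (!is.na(g[j]))
      w <- w * (if (g[j] == 1) P[z[j], j] else 1 - P[z[j], j])
    w
  })
  tot <- sum(pr)
  post <- matrix(0, L, K)
  for (j in seq_len(L)) for (k in seq_len(K))
    post[j, k] <- sum(pr[paths[, j] == k]) / tot
  list(post = post, loglik = log(tot))
}

# Naive per-SNP Weir estimator, straight from the mean-square formulas.
fst_naive <- function(calls, labels, groups) {
  vapply(seq_len(ncol(calls)), function(l) {
    ps <- ns <- numeric(0)
    for (gr in groups) {
      x <- calls[labels == gr, l]
      x <- x[!is.na(x)]
      if (length(x) >= 2) { ps <- c(ps, mean(x)); ns <- c(ns, length(x)) }
    }
    m <- length(ns)
    if (m < 2) return(NA_real_)
    pbar <- sum(ns * ps) / sum(ns)
    MSG <- sum(ns * ps * (1 - ps)) / sum(ns - 1)
    MSP <- sum(ns * (ps - pbar)^2) / (m - 1)
    nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (m - 1)
    den <- MSP + (nc - 1) * MSG
    if (den <= 0) return(NA_real_)
    max((MSP - MSG) / den, 0)
  }, numeric(1))
}

# Dense-matrix REML criterion for y ~ N(Xb, sg2 (K + delta I)),
# computed with solve()/determinant() only.
reml_dense <- function(delta, y, X, Kmat) {
  n <- length(y); p <- ncol(X)
  V <- Kmat + delta * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  Pm <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  rss <- as.numeric(t(y) %*% Pm %*% y)
  sg2 <- rss / (n - p)
  as.numeric(-0.5 * ((n - p) * log(2 * pi * sg2) + (n - p) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus -
                       determinant(crossprod(X))$modulus))
}

# Panel built directly from explicit allele counts per group, for
# hand-derived F_ST cases: counts[[g]] = c(n_alt, n_total).
panel_from_counts <- function(counts) {
  calls <- do.call(rbind, lapply(counts, function(ct)
    matrix(c(rep(1L, ct[1]), rep(0L, ct[2] - ct[1])), ncol = 1)))
  calls <- cbind(calls, calls)  # two identical SNPs
  labels <- rep(names(counts), vapply(counts, `[`, 0, 2))
  rownames(calls) <- paste0("a", seq_len(nrow(calls)))
  markers <- data.frame(id = c("m1", "m2"), chrom = 1L,
                        pos_bp = c(100L, 200L), ref = "A", alt = "G")
  list(panel = genotype_panel(calls, markers), labels = labels)
}
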