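#' Admixture-model log-likelihood
#'
#' Log-likelihood of a haploid-coded panel under the admixture model: each
#' call g_il is Bernoulli with success probability sum_k q_ik p_kl, where
#' q_ik is accession i's ancestry proportion from cluster k and p_kl the
#' cluster's alternate-allele frequency. Missing calls contribute nothing.
#' Mixture probabilities are clipped to \[eps, 1-eps\] so fixed sites cannot
#' produce -Inf.
#'
#' @param panel a [genotype_panel()].
#' @param Q n x K ancestry proportion matrix (rows on the simplex).
#' @param P K x L allele-frequency matrix.
#' @param eps clipping bound for mixture probabilities.
#' @return scalar log-likelihood.
#' @export
admixture_loglik <- function(panel, Q, P, eps = 1e-12) {
  Q <- as.matrix(Q); P <- as.matrix(P)
  stopifnot(nrow(Q) == nrow(panel$calls), ncol(Q) == nrow(P),
            ncol(P) == ncol(panel$calls))
  M1 <- clamp(Q %*% P, eps, 1 - eps)
  g <- panel$calls
  obs <- !is.na(g)
  g0 <- ifelse(obs, g, 0L)
  sum(ifelse(obs, g0 * log(M1) + (1 - g0) * log(1 - M1), 0))
}

#' Fit the admixture model by multi-restart EM
#'
#' Maximum-likelihood point estimation of global ancestry proportions Q
#' (n x K) and cluster allele frequencies P (K x L) for a haploid-coded
#' inbred panel, via expectation-maximization from `n_restarts` random
#' starting points; the restart with the highest final log-likelihood is
#' returned (mirroring the best-of-ten-replicates protocol of
#' STRUCTURE-based analyses, with a deterministic ML fit in place of MCMC).
#'
#' Initialization draws each restart's P by perturbing the panel's observed
#' allele frequencies independently per cluster; Q starts uniform at 1/K.
#' Because the starting point does not depend on accession order, the fit
#' is exactly equivariant under permuting accessions. Frequencies are kept
#' in \[1e-6, 1 - 1e-6\] to avoid log(0) at fixed sites.
#'
#' @param panel a QC'd [genotype_panel()].
#' @param K number of clusters (1 <= K <= number of accessions).
#' @param n_restarts number of EM restarts.
#' @param seed integer seed; the fit is deterministic given it.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param max_iter iteration cap per restart.
#' @return object of class `admixture_fit`: list with `K`, `Q`, `P`,
#'   `loglik`, `loglik_trace` (winning restart), `n_iter`,
#'   `restart_index`, `restart_logliks`.
#' @export
fit_admixture <- function(panel, K, n_restarts = 10, seed = 1L,
                          tol = 1e-4, max_iter = 2000) {
  n <- nrow(panel$calls); L <- ncol(panel$calls)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K (", K, ") exceeds the number of accessions (", n, ")")
  f <- allele_freqs(panel)
  f[is.nan(f)] <- 0.5
  eps <- 1e-6
  best <- NULL
  logliks <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(stage_seed(seed, paste0("em_restart_", r)))
    P0 <- t(vapply(seq_len(K), function(k)
      clamp(f + runif(L, -0.2, 0.2), eps, 1 - eps), numeric(L)))
    if (K == 1L) P0 <- matrix(clamp(f, eps, 1 - eps), 1L, L)
    Q0 <- matrix(1 / K, n, K)
    res <- admixture_em_cpp(panel$calls, Q0, P0, tol, as.integer(max_iter),
                            eps)
    ll <- tail(res$loglik_trace, 1L)
    logliks[r] <- ll
    if (is.null(best) || ll > best$loglik) {
      best <- list(Q = res$Q, P = res$P, loglik = ll,
                   loglik_trace = res$loglik_trace, n_iter = res$n_iter,
                   restart_index = r)
    }
  }
  dimnames(best$Q) <- list(panel$accessions$id, paste0("pop", seq_len(K)))
  dimnames(best$P) <- list(paste0("pop", seq_len(K)), panel$markers$id)
  structure(list(K = K, Q = best$Q, P = best$P, loglik = best$loglik,
                 loglik_trace = best$loglik_trace, n_iter = best$n_iter,
                 restart_index = best$restart_index,
                 restart_logliks = logliks),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, ",", nrow(x$Q), "accessions,",
      ncol(x$P), "SNPs\n")
  cat(sprintf("  loglik %.3f after %d iterations (restart %d of %d)\n",
              x$loglik, x$n_iter, x$restart_index,
              length(x$restart_logliks)))
  invisible(x)
}

#' Classify accessions from an admixture fit
#'
#' Assigns each accession to the cluster holding its maximum ancestry
#' proportion; accessions whose maximum is less than `threshold` are
#' classified `"ADMIXED"` (the 80% rule: a maximum of exactly 0.80 is
#' assigned, since only "less than 80%" is admixed).
#'
#' @param fit an [fit_admixture()] result.
#' @param threshold minimum maximum-ancestry proportion for assignment.
#' @return named character vector of labels (cluster column names of Q, or
#'   `"ADMIXED"`), named by accession id.
#' @export
classify_accessions <- function(fit, threshold = 0.80) {
  stopifnot(threshold > 0, threshold <= 1)
  qmax <- apply(fit$Q, 1, max)
  lab <- colnames(fit$Q)[max.col(fit$Q, ties.method = "first")]
  lab[qmax < threshold] <- "ADMIXED"
  names(lab) <- rownames(fit$Q)
  lab
}

#' Resolve label switching against a reference
#'
#' Cluster labels of an admixture fit are arbitrary; this finds the
#' permutation of the fit's columns best matching a reference Q matrix,
#' maximizing the summed column-wise Pearson correlation (exhaustive over
#' permutations for K <= 8, greedy beyond). A constant (degenerate) column
#' has no defined correlation and is matched last, with a warning.
#'
#' @param fit an [fit_admixture()] result, or an n x K matrix.
#' @param reference_Q n x K reference ancestry matrix (e.g. simulation
#'   truth, or another fit).
#' @return integer permutation `perm` such that `Q[, perm]` aligns with
#'   `reference_Q`.
#' @export
align_components <- function(fit, reference_Q) {
  Q <- if (inherits(fit, "admixture_fit")) fit$Q else as.matrix(fit)
  reference_Q <- as.matrix(reference_Q)
  stopifnot(nrow(Q) == nrow(reference_Q), ncol(Q) == ncol(reference_Q))
  K <- ncol(Q)
  if (K == 1L) return(1L)
  cc <- matrix(-Inf, K, K)
  for (a in seq_len(K)) for (b in seq_len(K)) {
    if (sd(Q[, b]) > 0 && sd(reference_Q[, a]) > 0)
      cc[a, b] <- cor(reference_Q[, a], Q[, b])
  }
  if (any(!is.finite(cc)))
    warning("degenerate constant component; matched last")
  if (K <= 8L) {
    perms <- all_permutations(K)
    scores <- vapply(perms, function(p)
      sum(pmax(cc[cbind(seq_len(K), p)], -1)), numeric(1))
    perms[[which.max(scores)]]
  } else {
    perm <- integer(K)
    avail <- seq_len(K)
    for (a in order(apply(cc, 1, max), decreasing = TRUE)) {
      b <- avail[which.max(cc[a, avail])]
      perm[a] <- b
      avail <- setdiff(avail, b)
    }
    perm
  }
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(K)) {
    out[[length(out) + 1L]] <- append(p, K, after = pos - 1L)
  }
  lapply(out, as.integer)
}

#' Apply a component permutation to an admixture fit
#'
#' Reorders Q columns and P rows consistently by `perm` (as returned by
#' [align_components()]); column names follow the permutation.
#'
#' @param fit an [fit_admixture()] result.
#' @param perm integer permutation of `1:K`.
#' @return the permuted `admixture_fit`.
#' @export
permute_components <- function(fit, perm) {
  stopifnot(sort(perm) == seq_len(fit$K))
  fit$Q <- fit$Q[, perm, drop = FALSE]
  fit$P <- fit$P[perm, , drop = FALSE]
  fit
}
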