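#' Site-by-site ancestry posteriors from the linkage HMM
#'
#' Computes, for every accession and SNP, the posterior distribution over
#' the K ancestral clusters under a linkage model: the hidden state is the
#' cluster of origin of the chromosomal segment carrying the SNP, with
#' initial distribution the accession's global ancestry q_i, transitions
#' between adjacent SNPs at distance d bp that stay with probability
#' exp(-r d) and otherwise redraw the state from q_i, and emission
#' probabilities p_kl^g (1 - p_kl)^(1-g) from the cluster allele
#' frequencies (missing calls emit 1 for every state). Chromosomes are
#' independent. Exact posteriors come from a scaled forward-backward pass;
#' per-site normalization makes the recursion stable at panel scale.
#'
#' Global ancestry and cluster frequencies are taken from a previously
#' fitted admixture model (empirical-Bayes style), so the per-SNP
#' "ancestral component" consumed by the introgression and mapping stages
#' is conditioned on the same Q and P throughout.
#'
#' @param panel a [genotype_panel()], markers sorted (guaranteed by the
#'   container).
#' @param fit an [fit_admixture()] result covering the panel's SNPs.
#' @param r per-bp ancestry switch intensity; `Inf` gives the no-linkage
#'   limit (independent sites).
#' @param q_floor minimum weight given to every cluster in the HMM's
#'   initial/redraw distribution (rows re-normalized after flooring).
#'   The default 0 uses each accession's global ancestry exactly; a small
#'   positive floor (e.g. 0.01) keeps rare donor states reachable for
#'   accessions whose fitted ancestry is numerically one-hot, which is
#'   essential when scanning assigned accessions for short introgressed
#'   segments.
#' @param refine_iter number of linkage-EM refinement sweeps before the
#'   final pass. Each sweep re-estimates the cluster allele frequencies as
#'   local-posterior-weighted frequencies, then reruns forward-backward.
#'   This is EM on the linkage model itself and corrects a bias of the
#'   two-stage fit: when many accessions of one subpopulation share the
#'   same introgressed segment, the global (linkage-free) fit absorbs the
#'   segment into that subpopulation's frequency profile, hiding it from
#'   the HMM; the refinement lets the segment migrate to the donor's
#'   profile. 0 (default) keeps the global fit's parameters fixed.
#' @param refine_update_q also update each accession's mixing distribution
#'   to its mean posterior during refinement. Off by default: updating Q
#'   feeds posterior mass back into the transition prior and can inflate
#'   weak spurious segments.
#' @return object of class `local_ancestry`: list with `posterior`
#'   (n x L x K array), `switch_rate`, `loglik` (per-accession forward
#'   log-likelihoods), `loglik_backward` (same quantity from the backward
#'   pass, for verification), `K`, `pop_names`.
#' @export
posterior_ancestry <- function(panel, fit, r, q_floor = 0,
                               refine_iter = 0, refine_update_q = FALSE) {
  if (!is.finite(r) && !identical(r, Inf)) stop("switch rate must be finite or Inf")
  if (r < 0) stop("switch rate must be nonnegative")
  stopifnot(ncol(fit$P) == ncol(panel$calls),
            nrow(fit$Q) == nrow(panel$calls), q_floor >= 0, q_floor < 1)
  if (refine_iter > 0) {
    g <- panel$calls
    obs <- !is.na(g)
    g0 <- ifelse(obs, g, 0L)
    cur <- fit
    for (it in seq_len(refine_iter)) {
      la <- posterior_ancestry(panel, cur, r, q_floor = q_floor)
      for (k in seq_len(fit$K)) {
        W <- matrix(la$posterior[, , k], nrow(g)) * obs
        cur$P[k, ] <- clamp(colSums(W * g0) /
                              pmax(colSums(W), 1e-12), 1e-6, 1 - 1e-6)
      }
      if (refine_update_q) {
        qn <- apply(la$posterior, c(1, 3), mean)
        cur$Q <- qn / rowSums(qn)
        dimnames(cur$Q) <- dimnames(fit$Q)
      }
    }
    out <- posterior_ancestry(panel, cur, r, q_floor = q_floor)
    out$refined_fit <- cur
    return(out)
  }
  n <- nrow(panel$calls); L <- ncol(panel$calls); K <- fit$K
  Q <- unname(fit$Q); P <- unname(fit$P)
  if (q_floor > 0) {
    Q <- pmax(Q, q_floor)
    Q <- Q / rowSums(Q)
  }
  g <- panel$calls
  post <- array(NA_real_, c(n, L, K),
                dimnames = list(panel$accessions$id, panel$markers$id,
                                colnames(fit$Q)))
  ll_f <- numeric(n); ll_b <- numeric(n)

  emission <- function(l) {
    gl <- g[, l]
    obs <- !is.na(gl)
    E <- matrix(1, n, K)
    if (any(obs)) {
      g1 <- which(obs & gl == 1L)
      g0 <- which(obs & gl == 0L)
      if (length(g1)) E[g1, ] <- matrix(P[, l], length(g1), K, byrow = TRUE)
      if (length(g0)) E[g0, ] <- matrix(1 - P[, l], length(g0), K,
                                        byrow = TRUE)
    }
    E
  }

  for (ch in unique(panel$markers$chrom)) {
    idx <- which(panel$markers$chrom == ch)
    Lc <- length(idx)
    d <- diff(panel$markers$pos_bp[idx])
    stay <- if (identical(r, Inf)) rep(0, max(Lc - 1L, 0L)) else exp(-r * d)

    alpha <- array(0, c(n, K, Lc))
    ca <- matrix(0, n, Lc)
    A <- Q * emission(idx[1])
    ca[, 1] <- rowSums(A)
    alpha[, , 1] <- A / ca[, 1]
    if (Lc > 1L) for (j in 2:Lc) {
      Ap <- matrix(alpha[, , j - 1L], n, K)
      # transition: stay, or redraw from q_i (rowSums(Ap) == 1 after scaling)
      At <- stay[j - 1L] * Ap + (1 - stay[j - 1L]) * Q
      A <- At * emission(idx[j])
      ca[, j] <- rowSums(A)
      alpha[, , j] <- A / ca[, j]
    }
    ll_f <- ll_f + rowSums(log(ca))

    beta <- array(0, c(n, K, Lc))
    beta[, , Lc] <- 1
    cb <- matrix(1, n, Lc)
    if (Lc > 1L) for (j in (Lc - 1L):1L) {
      V <- matrix(beta[, , j + 1L], n, K) * emission(idx[j + 1L])
      B <- stay[j] * V + (1 - stay[j]) * rowSums(V * Q)
      cb[, j] <- rowSums(B)
      beta[, , j] <- B / cb[, j]
    }
    # backward total likelihood: sum_k q_k e_1k beta_1k, unscaled
    v0 <- rowSums(Q * emission(idx[1]) * matrix(beta[, , 1], n, K))
    ll_b <- ll_b + log(v0) + rowSums(log(cb))

    pj <- alpha * beta
    tot <- apply(pj, c(1, 3), sum)
    for (k in seq_len(K))
      post[, idx, k] <- matrix(pj[, k, ], n, Lc) / tot
  }

  structure(list(posterior = post, switch_rate = r, loglik = ll_f,
                 loglik_backward = ll_b, K = K,
                 pop_names = colnames(fit$Q)),
            class = "local_ancestry")
}

#' @export
print.local_ancestry <- function(x, ...) {
  d <- dim(x$posterior)
  cat("local_ancestry:", d[1], "accessions x", d[2], "SNPs x", d[3],
      "clusters; switch rate", format(x$switch_rate), "per bp\n")
  invisible(x)
}

#' Select the HMM switch rate by maximum likelihood on a grid
#'
#' Evaluates the total forward log-likelihood of the linkage HMM (summed
#' over accessions) at each candidate per-bp switch rate and returns the
#' maximizer.
#'
#' @param panel a [genotype_panel()].
#' @param fit an [fit_admixture()] result.
#' @param grid numeric vector of candidate rates (> 0).
#' @return the best rate, with attribute `grid_loglik` (named vector of
#'   total log-likelihoods).
#' @export
fit_switch_rate <- function(panel, fit,
                            grid = 10^seq(-9, -6.5, by = 0.25)) {
  if (!length(grid)) stop("empty rate grid")
  if (any(grid <= 0)) stop("rates must be positive")
  ll <- vapply(grid, function(r)
    sum(posterior_ancestry(panel, fit, r)$loglik), numeric(1))
  names(ll) <- format(grid)
  best <- grid[which.max(ll)]
  attr(best, "grid_loglik") <- ll
  best
}

#' Subpopulation-average introgression profile
#'
#' The mean donor-cluster posterior over all accessions assigned to a
#' recipient subpopulation, per SNP, plus the top-5-percent background
#' cutoff: the 95th nearest-rank percentile of the per-SNP means, the
#' threshold above which a locus shows more donor ancestry than the
#' genome-wide background of that recipient/donor pair.
#'
#' @param local a [posterior_ancestry()] result.
#' @param labels per-accession assignments (named by accession id, or in
#'   accession order), e.g. from [classify_accessions()].
#' @param recipient recipient subpopulation label.
#' @param donor donor cluster label (a `pop_names` entry), different from
#'   `recipient`.
#' @return object of class `introgression_profile`: list with
#'   `recipient_pop`, `donor_pop`, `values` (per-SNP means, named by
#'   marker), `threshold_95`, `n_accessions`.
#' @export
mean_introgression <- function(local, labels, recipient, donor) {
  if (identical(recipient, donor)) stop("donor must differ from recipient")
  ids <- dimnames(local$posterior)[[1]]
  if (!is.null(names(labels))) labels <- labels[ids]
  rows <- which(labels == recipient)
  if (!length(rows)) stop("no accessions labeled ", recipient)
  k <- match(donor, local$pop_names)
  if (is.na(k)) stop("unknown donor cluster: ", donor)
  vals <- colMeans(local$posterior[rows, , k, drop = FALSE])
  vals <- as.vector(vals)
  names(vals) <- dimnames(local$posterior)[[2]]
  structure(list(recipient_pop = recipient, donor_pop = donor,
                 values = vals,
                 threshold_95 = nearest_rank_quantile(vals, 0.95),
                 n_accessions = length(rows)),
            class = "introgression_profile")
}

#' Call introgressed segments in one accession
#'
#' Maximal runs of consecutive SNPs within a chromosome whose donor-cluster
#' posterior exceeds `post_min` are emitted as introgression calls when the
#' run spans at least `min_snps` SNPs (the >= 5-SNP rule). Segment bounds
#' are the first and last SNP positions of the run.
#'
#' @param local a [posterior_ancestry()] result.
#' @param markers the panel's marker table (columns `id`, `chrom`,
#'   `pos_bp`), in the same order as the posterior's SNP dimension.
#' @param accession accession id.
#' @param donor donor cluster label.
#' @param min_snps minimum run length in SNPs.
#' @param post_min posterior threshold for a SNP to join a run (strict).
#' @return data.frame with columns `accession_id`, `donor_pop`, `chrom`,
#'   `start_bp`, `end_bp`, `n_snps`, `mean_posterior` (possibly 0 rows).
#' @export
call_segments <- function(local, markers, accession, donor, min_snps = 5,
                          post_min = 0.5) {
  ids <- dimnames(local$posterior)[[1]]
  i <- match(accession, ids)
  if (is.na(i)) stop("unknown accession: ", accession)
  k <- match(donor, local$pop_names)
  if (is.na(k)) stop("unknown donor cluster: ", donor)
  p <- local$posterior[i, , k]
  out <- list()
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    above <- p[idx] > post_min
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (j in which(runs$values & runs$lengths >= min_snps)) {
      seg <- idx[starts[j]:ends[j]]
      out[[length(out) + 1L]] <- data.frame(
        accession_id = accession, donor_pop = donor, chrom = ch,
        start_bp = markers$pos_bp[seg[1]],
        end_bp = markers$pos_bp[seg[length(seg)]],
        n_snps = length(seg), mean_posterior = mean(p[seg]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(accession_id = character(), donor_pop = character(),
                      chrom = integer(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      mean_posterior = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write introgression calls as BED
#'
#' Converts 1-based inclusive SNP-bounded segments to 0-based half-open
#' BED intervals (`start_bp - 1`, `end_bp`).
#'
#' @param calls data.frame from [call_segments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$chrom, start = calls$start_bp - 1L,
                    end = calls$end_bp,
                    name = paste0(calls$accession_id, ":", calls$donor_pop),
                    score = round(1000 * calls$mean_posterior),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
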