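#' Kinship matrix from allele sharing
#'
#' Pairwise genetic relatedness as allele-sharing similarity,
#' 1 - [allele_sharing_distance()], with unit diagonal. Used as the
#' covariance structure of the polygenic random effect in mixed-model
#' association.
#'
#' @param panel a [genotype_panel()].
#' @return symmetric n x n matrix, entries in \[0, 1\], diagonal 1.
#' @export
kinship_matrix <- function(panel) {
  k <- 1 - allele_sharing_distance(panel)
  diag(k) <- 1
  k
}

#' Admixture mapping: regress a trait on local donor ancestry
#'
#' Within a subset of (admixed) accessions, regresses the phenotype on the
#' donor-cluster local-ancestry posterior at each SNP by ordinary least
#' squares, giving a per-SNP slope, standard error and two-sided t-test
#' p-value. Ancestry blocks extend over neighboring SNPs, so the signal
#' near a causal locus is shared across the block — the property that
#' makes this test powerful with sparse markers. SNPs where the donor
#' component does not vary in the subset get NA.
#'
#' @param local a [posterior_ancestry()] result.
#' @param phenotype data.frame with columns `id`, `value` (trait means).
#' @param subset accession ids to use (typically the `"ADMIXED"` class).
#' @param donor donor cluster label whose component is the predictor.
#' @param markers marker table matching the posterior's SNP dimension
#'   (for positions on the result).
#' @return object of class `mapping_result`: list with `method`
#'   (`"admixture_map"`), `table` (data.frame `id`, `chrom`, `pos_bp`,
#'   `effect`, `se`, `p`, `n_used`), plus Bonferroni fields once
#'   [bonferroni()] has run.
#' @export
admixture_map <- function(local, phenotype, subset, donor, markers) {
  ids <- dimnames(local$posterior)[[1]]
  subset <- intersect(subset, ids)
  y <- phenotype$value[match(subset, phenotype$id)]
  drop <- is.na(y)
  if (any(drop)) {
    message(sum(drop), " accession(s) without phenotype dropped")
    subset <- subset[!drop]; y <- y[!drop]
  }
  if (length(subset) < 3) stop("need >= 3 phenotyped accessions in subset")
  k <- match(donor, local$pop_names)
  if (is.na(k)) stop("unknown donor cluster: ", donor)
  X <- local$posterior[match(subset, ids), , k]
  n <- length(y)
  xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, yc))
  beta <- ifelse(sxx > 1e-12, sxy / sxx, NA_real_)
  rss <- sum(yc^2) - ifelse(sxx > 1e-12, beta^2 * sxx, 0)
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  se[sxx <= 1e-12] <- NA_real_
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  if (all(is.na(p))) stop("no SNP with varying donor ancestry in subset")
  tab <- data.frame(id = markers$id, chrom = markers$chrom,
                    pos_bp = markers$pos_bp, effect = beta, se = se,
                    p = p, n_used = n, stringsAsFactors = FALSE)
  structure(list(method = "admixture_map", table = tab,
                 donor = donor, trait = attr(phenotype, "trait") %||% "trait"),
            class = "mapping_result")
}

#' Mixed-model association mapping
#'
#' Single-SNP association with population-structure control: for each SNP,
#' y = mu + SNP b + Q g + u + e with u ~ N(0, sg^2 Kin) and
#' e ~ N(0, se^2 I). The variance ratio delta = se^2/sg^2 is estimated
#' once by REML on the null (no-SNP) model through a single spectral
#' decomposition of the kinship matrix, then reused for generalized least
#' squares at every SNP (the standard approximation that makes thousands
#' of tests cheap); p-values are two-sided Wald t-tests on the SNP
#' coefficient. One Q column is dropped to avoid collinearity with the
#' intercept. Missing genotype calls are mean-imputed for the design;
#' `n_used` reports the observed-call count.
#'
#' @param panel a [genotype_panel()].
#' @param phenotype data.frame with columns `id`, `value`.
#' @param Q optional n x K ancestry matrix (rows matching panel
#'   accessions); `NULL` fits without ancestry covariates.
#' @param kin kinship matrix as from [kinship_matrix()], dimnames ids.
#' @return object of class `mapping_result` with `method`
#'   (`"mixed_model"`), `table` as in [admixture_map()], and `delta`
#'   (REML variance ratio se^2/sg^2), `h2_null` (sg^2/(sg^2+se^2) on the
#'   null model).
#' @export
mixed_model_assoc <- function(panel, phenotype, Q = NULL, kin) {
  ids <- panel$accessions$id
  keep <- ids[ids %in% phenotype$id[!is.na(phenotype$value)]]
  y <- phenotype$value[match(keep, phenotype$id)]
  n <- length(y)
  X0 <- matrix(1, n, 1)
  if (!is.null(Q)) {
    Qm <- as.matrix(Q)[match(keep, rownames(Q) %||% ids), , drop = FALSE]
    if (ncol(Qm) > 1) X0 <- cbind(X0, Qm[, -ncol(Qm), drop = FALSE])
  }
  if (n < ncol(X0) + 3) stop("too few phenotyped accessions")
  Kmat <- kin[match(keep, rownames(kin)), match(keep, colnames(kin))]
  eg <- eigen(Kmat, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("kinship matrix is not positive semi-definite")
  lambda <- pmax(eg$values, 0)
  U <- eg$vectors
  yr <- as.vector(crossprod(U, y))
  X0r <- crossprod(U, X0)

  crit <- function(ldelta) reml_loglik(exp(ldelta), lambda, X0r, yr)
  opt <- optimize(crit, c(-12, 12), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)

  gmat <- panel$calls[match(keep, ids), , drop = FALSE]
  storage.mode(gmat) <- "double"
  f <- colMeans(gmat, na.rm = TRUE)
  n_used <- colSums(!is.na(gmat))
  for (j in seq_len(ncol(gmat)))
    gmat[is.na(gmat[, j]), j] <- f[j]

  w <- 1 / (lambda + delta)
  p0 <- ncol(X0)
  eff <- se <- pv <- rep(NA_real_, ncol(gmat))
  for (j in seq_len(ncol(gmat))) {
    Xr <- cbind(X0r, as.vector(crossprod(U, gmat[, j])))
    XtWX <- crossprod(Xr, w * Xr)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch) || min(diag(ch)) < 1e-7) next  # singular (e.g. monomorphic)
    XtWy <- crossprod(Xr, w * yr)
    b <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
    r <- yr - Xr %*% b
    sigma2 <- sum(w * r^2) / (n - p0 - 1)
    XtWXinv <- chol2inv(ch)
    sb <- sqrt(sigma2 * XtWXinv[p0 + 1, p0 + 1])
    tv <- b[p0 + 1] / sb
    eff[j] <- b[p0 + 1]; se[j] <- sb
    pv[j] <- 2 * pt(-abs(tv), df = n - p0 - 1)
  }
  tab <- data.frame(id = panel$markers$id, chrom = panel$markers$chrom,
                    pos_bp = panel$markers$pos_bp, effect = eff, se = se,
                    p = pv, n_used = n_used, stringsAsFactors = FALSE)
  # null-model variance components at the REML optimum
  fit0 <- wls_fit(w, X0r, yr)
  sg2 <- fit0$rss / (n - p0)
  structure(list(method = "mixed_model", table = tab, delta = delta,
                 sigma_g2 = sg2, sigma_e2 = sg2 * delta,
                 h2_null = 1 / (1 + delta),
                 trait = attr(phenotype, "trait") %||% "trait"),
            class = "mapping_result")
}

wls_fit <- function(w, Xr, yr) {
  XtWX <- crossprod(Xr, w * Xr)
  b <- solve(XtWX, crossprod(Xr, w * yr))
  r <- yr - Xr %*% b
  list(b = b, rss = sum(w * r^2), XtWX = XtWX)
}

# REML log-likelihood of the variance ratio delta = se^2/sg^2 for the
# model y ~ N(Xb, sg^2 (Kin + delta I)), after rotation by the kinship
# eigenvectors (lambda are the eigenvalues). sg^2 is profiled out.
reml_loglik <- function(delta, lambda, Xr, yr) {
  n <- length(yr); p <- ncol(Xr)
  w <- 1 / (lambda + delta)
  fit <- wls_fit(w, Xr, yr)
  sg2 <- fit$rss / (n - p)
  -0.5 * ((n - p) * log(2 * pi * sg2) + (n - p) +
            sum(log(lambda + delta)) +
            determinant(fit$XtWX, logarithm = TRUE)$modulus -
            determinant(crossprod(Xr), logarithm = TRUE)$modulus)
}

#' @export
print.mapping_result <- function(x, ...) {
  tab <- x$table
  cat("mapping_result (", x$method, "): ", nrow(tab), " SNPs, ",
      sum(is.na(tab$p)), " NA\n", sep = "")
  best <- which.min(tab$p)
  if (length(best))
    cat(sprintf("  top SNP %s (chr%d:%d), p = %.3g\n", tab$id[best],
                tab$chrom[best], tab$pos_bp[best], tab$p[best]))
  if (!is.null(x$bonferroni_threshold))
    cat(sprintf("  Bonferroni threshold %.3g; %d significant\n",
                x$bonferroni_threshold, sum(x$table$significant,
                                            na.rm = TRUE)))
  invisible(x)
}

#' Bonferroni correction for a mapping result
#'
#' Family-wise error control at level `alpha`: the per-test threshold is
#' `alpha / (number of non-NA tests)`; SNPs with p at or below it are
#' flagged significant.
#'
#' @param result a [mapping_result] from [admixture_map()] or
#'   [mixed_model_assoc()].
#' @param alpha family-wise error rate.
#' @return the result with `bonferroni_threshold`, `alpha`, and a logical
#'   `significant` column on `table`.
#' @export
bonferroni <- function(result, alpha = 0.05) {
  ntest <- sum(!is.na(result$table$p))
  if (ntest < 1) stop("no non-NA p-values")
  thr <- alpha / ntest
  result$bonferroni_threshold <- thr
  result$alpha <- alpha
  result$table$significant <- !is.na(result$table$p) &
    result$table$p <= thr
  result
}
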