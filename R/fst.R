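#' Per-SNP unbiased F_ST between subpopulations
#'
#' Weir's unbiased moment estimator, correcting for unequal sample sizes
#' over subpopulations. At each SNP, with m groups of n_i non-missing
#' haploid calls and within-group allele frequencies p_i, and the weighted
#' mean frequency p_bar = sum(n_i p_i) / sum(n_i):
#'
#' \deqn{MSG = \sum n_i p_i (1-p_i) / \sum (n_i - 1)}
#' \deqn{MSP = \sum n_i (p_i - \bar p)^2 / (m - 1)}
#' \deqn{n_c = (\sum n_i - \sum n_i^2 / \sum n_i) / (m - 1)}
#' \deqn{\hat F_{ST} = (MSP - MSG) / (MSP + (n_c - 1) MSG)}
#'
#' MSG and MSP are the observed mean squares within and between
#' subpopulations. Negative estimates, which carry no biological meaning,
#' are set to 0. A SNP needs at least two groups with >= 2 non-missing
#' calls each; groups below that are dropped at that SNP, and if fewer
#' than two remain the SNP's value is NA (counted in `n_undefined`).
#' Inbred accessions contribute one allele each, so n_i counts haploid
#' calls.
#'
#' @param panel a [genotype_panel()].
#' @param labels per-accession group labels (named by accession id or in
#'   panel order); defaults to the panel's `assigned_subpop`.
#' @param groups labels to include; defaults to all labels except
#'   `"ADMIXED"` and `"UNASSIGNED"`.
#' @return object of class `fst_result`: list with `pop_pair` (the group
#'   labels), `per_snp` (clamped per-SNP estimates), `components`
#'   (data.frame MSP, MSG, n_c per SNP), `overall` (ratio-of-sums
#'   estimate, see [fst_overall()]), `mean_per_snp`, `n_undefined`,
#'   `markers`.
#' @export
fst_per_snp <- function(panel, labels = NULL, groups = NULL) {
  if (is.null(labels)) labels <- panel$accessions$assigned_subpop
  if (!is.null(names(labels))) labels <- labels[panel$accessions$id]
  labels <- as.character(labels)
  if (is.null(groups))
    groups <- setdiff(unique(labels), c("ADMIXED", "UNASSIGNED", NA))
  if (length(groups) < 2) stop("need at least two groups")
  g <- panel$calls
  obs <- !is.na(g)
  g0 <- ifelse(obs, g, 0L)
  m_grp <- length(groups)
  Ni <- matrix(0, m_grp, ncol(g))   # n_i per group per SNP
  Si <- matrix(0, m_grp, ncol(g))   # alt-allele counts
  for (j in seq_len(m_grp)) {
    rows <- which(labels == groups[j])
    if (!length(rows)) stop("no accessions labeled ", groups[j])
    Ni[j, ] <- colSums(obs[rows, , drop = FALSE])
    Si[j, ] <- colSums(g0[rows, , drop = FALSE])
  }
  use <- Ni >= 2                     # group eligible at this SNP
  Ni[!use] <- 0
  Si[!use] <- 0
  m <- colSums(use)
  ok <- m >= 2

  Pi <- ifelse(Ni > 0, Si / Ni, 0)
  ntot <- colSums(Ni)
  pbar <- colSums(Si) / pmax(ntot, 1)
  MSG <- colSums(Ni * Pi * (1 - Pi)) / pmax(colSums(pmax(Ni - use, 0)), 1)
  MSP <- colSums(Ni * sweep(Pi, 2, pbar)^2) / pmax(m - 1, 1)
  n_c <- (ntot - colSums(Ni^2) / pmax(ntot, 1)) / pmax(m - 1, 1)
  denom <- MSP + (n_c - 1) * MSG
  raw <- ifelse(denom > 0, (MSP - MSG) / denom, NA_real_)
  raw[!ok] <- NA_real_
  MSG[!ok] <- NA_real_; MSP[!ok] <- NA_real_; n_c[!ok] <- NA_real_
  per_snp <- clamp(raw, 0, 1)

  res <- structure(list(pop_pair = groups,
                        per_snp = stats::setNames(per_snp,
                                                  panel$markers$id),
                        raw = raw,
                        components = data.frame(id = panel$markers$id,
                                                MSP = MSP, MSG = MSG,
                                                n_c = n_c),
                        n_undefined = sum(!ok),
                        markers = panel$markers,
                        windows = NULL),
                   class = "fst_result")
  res$overall <- fst_overall(res)
  res$mean_per_snp <- mean(per_snp, na.rm = TRUE)
  res
}

#' Genome-wide F_ST (ratio of sums)
#'
#' Aggregates per-SNP mean-square components into one genome-wide
#' estimate, sum(MSP - MSG) / sum(MSP + (n_c - 1) MSG) over SNPs with a
#' defined estimate, clamped at 0 (Weir's recommended ratio-of-sums form;
#' the mean of per-SNP values is also kept on the result for comparison).
#'
#' @param result an [fst_per_snp()] result.
#' @return scalar genome-wide estimate.
#' @export
fst_overall <- function(result) {
  cm <- result$components
  ok <- !is.na(cm$MSP)
  if (!any(ok)) stop("no SNPs with a defined F_ST estimate")
  num <- sum(cm$MSP[ok] - cm$MSG[ok])
  den <- sum(cm$MSP[ok] + (cm$n_c[ok] - 1) * cm$MSG[ok])
  max(num / den, 0)
}

#' Windowed F_ST along chromosomes
#'
#' Tiles each chromosome into non-overlapping half-open physical windows
#' \[w, w + window_bp) from position 0 to the last marker, and computes the
#' ratio-of-sums estimate within each window. Windows containing no SNP
#' with a defined estimate are reported NA with `n_snps = 0`.
#'
#' @param result an [fst_per_snp()] result (carries marker positions).
#' @param window_bp window width in bp (default 100 kb).
#' @return the `fst_result` with `windows` set: data.frame `chrom`,
#'   `start_bp`, `end_bp`, `fst`, `n_snps`.
#' @export
fst_windows <- function(result, window_bp = 100000) {
  if (window_bp <= 0) stop("window_bp must be positive")
  mk <- result$markers
  cm <- result$components
  out <- list()
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    chrom_end <- max(mk$pos_bp[idx])
    starts <- seq(0, chrom_end, by = window_bp)
    for (s in starts) {
      inw <- idx[mk$pos_bp[idx] >= s & mk$pos_bp[idx] < s + window_bp]
      inw <- inw[!is.na(cm$MSP[inw])]
      fst <- if (length(inw)) {
        num <- sum(cm$MSP[inw] - cm$MSG[inw])
        den <- sum(cm$MSP[inw] + (cm$n_c[inw] - 1) * cm$MSG[inw])
        max(num / den, 0)
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(chrom = ch, start_bp = s,
                                            end_bp = s + window_bp,
                                            fst = fst,
                                            n_snps = length(inw))
    }
  }
  result$windows <- do.call(rbind, out)
  result
}

#' @export
print.fst_result <- function(x, ...) {
  cat("fst_result: groups [", paste(x$pop_pair, collapse = ", "), "], ",
      length(x$per_snp), " SNPs (", x$n_undefined, " undefined)\n",
      sep = "")
  cat(sprintf("  genome-wide (ratio of sums): %.4f; mean per-SNP: %.4f\n",
              x$overall, x$mean_per_snp))
  if (!is.null(x$windows))
    cat("  windows:", nrow(x$windows), "of width",
        x$windows$end_bp[1] - x$windows$start_bp[1], "bp\n")
  invisible(x)
}

#' Pairwise genome-wide F_ST table
#'
#' Convenience wrapper producing the matrix of pairwise genome-wide
#' estimates between all given groups (upper triangle), as reported in
#' subpopulation divergence tables.
#'
#' @param panel a [genotype_panel()].
#' @param labels per-accession group labels (default: panel assignments).
#' @param groups group labels to include (default: all assigned).
#' @return symmetric matrix of pairwise genome-wide F_ST (NA diagonal).
#' @export
fst_pairwise <- function(panel, labels = NULL, groups = NULL) {
  if (is.null(labels)) labels <- panel$accessions$assigned_subpop
  if (is.null(groups))
    groups <- setdiff(unique(as.character(labels)),
                      c("ADMIXED", "UNASSIGNED", NA))
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) for (j in seq_along(groups)) {
    if (j <= i) next
    r <- fst_per_snp(panel, labels, groups[c(i, j)])
    m[i, j] <- m[j, i] <- r$overall
  }
  m
}
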