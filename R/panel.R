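#' Genotype panel of inbred accessions
#'
#' The central container of the package: an accessions x SNPs matrix of
#' haploid-coded biallelic calls (0 = reference allele, 1 = alternate,
#' `NA` = missing), together with a SNP map and accession metadata.
#' Accessions are inbred lines, so each contributes a single allele per
#' locus; diploid input is collapsed on read (see [read_panel()]).
#'
#' @param calls integer matrix, accessions x markers, entries 0/1/NA.
#' @param markers data.frame with columns `id`, `chrom` (positive integer),
#'   `pos_bp` (1-based physical position), `ref`, `alt` (single nucleotides).
#' @param accessions data.frame with columns `id`, `name`,
#'   `assigned_subpop`; defaults to ids taken from `rownames(calls)` with
#'   `assigned_subpop = "UNASSIGNED"`.
#'
#' @return an object of class `genotype_panel`: a list with elements
#'   `calls`, `markers`, `accessions`. Markers are sorted by
#'   (chrom, pos_bp) and the call matrix columns reordered to match.
#' @export
genotype_panel <- function(calls, markers, accessions = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos_bp", "ref", "alt")
  if (!all(need %in% names(markers)))
    stop("markers must have columns: ", paste(need, collapse = ", "))
  markers$id <- as.character(markers$id)
  markers$chrom <- as.integer(markers$chrom)
  markers$pos_bp <- as.integer(markers$pos_bp)

  if (is.null(accessions)) {
    ids <- rownames(calls) %||% paste0("acc", seq_len(nrow(calls)))
    accessions <- data.frame(id = ids, name = ids,
                             assigned_subpop = "UNASSIGNED",
                             stringsAsFactors = FALSE)
  }
  accessions <- as.data.frame(accessions, stringsAsFactors = FALSE)
  if (!"name" %in% names(accessions)) accessions$name <- accessions$id
  if (!"assigned_subpop" %in% names(accessions))
    accessions$assigned_subpop <- "UNASSIGNED"
  accessions$id <- as.character(accessions$id)

  if (nrow(calls) != nrow(accessions))
    stop("calls has ", nrow(calls), " rows but ", nrow(accessions),
         " accessions given")
  if (ncol(calls) != nrow(markers))
    stop("calls has ", ncol(calls), " columns but ", nrow(markers),
         " markers given")
  if (anyDuplicated(markers$id))
    stop("duplicate marker id: ",
         markers$id[duplicated(markers$id)][1])
  if (anyDuplicated(accessions$id))
    stop("duplicate accession id: ",
         accessions$id[duplicated(accessions$id)][1])
  bad <- !(calls %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("calls must be 0, 1 or NA")
  if (any(markers$pos_bp < 1L)) stop("pos_bp must be >= 1")
  if (any(markers$ref == markers$alt))
    stop("ref and alt alleles must differ (marker ",
         markers$id[markers$ref == markers$alt][1], ")")

  ord <- order(markers$chrom, markers$pos_bp)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  calls <- calls[, ord, drop = FALSE]
  dup <- ave(markers$pos_bp, markers$chrom, FUN = function(p) duplicated(p))
  if (any(dup == 1))
    stop("markers must have strictly increasing positions within a chromosome")
  dimnames(calls) <- list(accessions$id, markers$id)

  structure(list(calls = calls, markers = markers, accessions = accessions),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$calls), "accessions x", ncol(x$calls),
      "SNPs on", length(unique(x$markers$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  tab <- table(x$accessions$assigned_subpop)
  cat("  assignments:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$calls)

#' Alternate-allele frequencies of a panel
#'
#' Per-SNP frequency of the alternate (coded 1) allele over non-missing
#' calls.
#'
#' @param panel a [genotype_panel()].
#' @return named numeric vector, one entry per marker (NaN where all calls
#'   are missing).
#' @export
allele_freqs <- function(panel) colMeans(panel$calls, na.rm = TRUE)

#' Minor-allele frequencies of a panel
#' @param panel a [genotype_panel()].
#' @return named numeric vector, `pmin(f, 1 - f)` of [allele_freqs()].
#' @export
minor_allele_freqs <- function(panel) {
  f <- allele_freqs(panel)
  pmin(f, 1 - f)
}

#' Subset a panel
#'
#' @param x a [genotype_panel()].
#' @param i accession index (logical, integer or id character vector).
#' @param j marker index.
#' @param ... ignored.
#' @return a new `genotype_panel`.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$calls))
  if (missing(j)) j <- seq_len(ncol(x$calls))
  if (is.character(i)) i <- match(i, x$accessions$id)
  if (is.character(j)) j <- match(j, x$markers$id)
  genotype_panel(x$calls[i, j, drop = FALSE],
                 x$markers[j, , drop = FALSE],
                 x$accessions[i, , drop = FALSE])
}

#' Record subpopulation assignments on a panel
#'
#' @param panel a [genotype_panel()].
#' @param labels character vector of labels, either named by accession id or
#'   in panel accession order; values are subpopulation labels, `"ADMIXED"`
#'   or `"UNASSIGNED"`.
#' @return the panel with `accessions$assigned_subpop` updated.
#' @export
annotate_assignments <- function(panel, labels) {
  if (!is.null(names(labels))) {
    idx <- match(panel$accessions$id, names(labels))
    if (anyNA(idx)) stop("labels missing for some accessions")
    labels <- labels[idx]
  }
  stopifnot(length(labels) == nrow(panel$accessions))
  panel$accessions$assigned_subpop <- as.character(labels)
  panel
}
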