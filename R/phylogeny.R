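#' Allele-sharing distance matrix
#'
#' Pairwise distance between accessions: the proportion of mismatching
#' calls among SNPs non-missing in both (pairwise deletion). For haploid
#' codes this is the standard allele-sharing distance; 0 means identical
#' genotypes over the shared SNPs, 1 fully complementary.
#'
#' @param panel a [genotype_panel()].
#' @return symmetric n x n numeric matrix with zero diagonal, dimnames the
#'   accession ids.
#' @export
allele_sharing_distance <- function(panel) {
  x <- panel$calls
  A <- (!is.na(x) & x == 1L) * 1   # alt observed
  B <- (!is.na(x) & x == 0L) * 1   # ref observed
  mism <- A %*% t(B) + B %*% t(A)
  shared <- (A + B) %*% t(A + B)
  if (any(shared == 0)) {
    ij <- which(shared == 0, arr.ind = TRUE)[1, ]
    stop("accessions ", panel$accessions$id[ij[1]], " and ",
         panel$accessions$id[ij[2]], " share no non-missing SNP")
  }
  d <- mism / shared
  diag(d) <- 0
  dimnames(d) <- list(panel$accessions$id, panel$accessions$id)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) on a validated symmetric
#' nonnegative distance matrix, returning an unrooted `phylo` tree.
#' Negative branch-length estimates, an artifact of the NJ formulas on
#' non-additive data, are clamped to zero with the negative amount
#' transferred to the sibling branch so leaf-to-leaf path lengths through
#' the pair are preserved.
#'
#' @param D square numeric matrix (symmetric within 1e-8, zero diagonal,
#'   nonnegative), dimnames giving leaf ids.
#' @return an unrooted `phylo` object (class from \pkg{ape}).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 accessions")
  if (any(is.na(D))) stop("distance matrix has missing values")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(nrow(D)))
  tr <- ape::nj(stats::as.dist(D))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    len <- tr$edge.length[e]   # negative
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)
    # transfer so the path through the pair keeps its length
    if (length(sib))
      tr$edge.length[sib[1]] <- max(tr$edge.length[sib[1]] + len, 0)
  }
  tr
}

#' Write a tree as Newick with deterministic leaf order
#'
#' Serializes a `phylo` tree to a Newick string with branch lengths,
#' ordering the children of every node by the lexicographically smallest
#' leaf label in their subtree, so equivalent trees always produce the
#' same file. Labels containing Newick-reserved characters
#' (`(){}[]:;,'` or whitespace) are single-quoted with internal quotes
#' doubled. The output parses with standard readers (e.g.
#' `ape::read.tree`).
#'
#' @param tree a `phylo` object.
#' @param path output file path, or `NULL` to return the string only.
#' @return the Newick string, invisibly.
#' @export
write_newick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_label <- function(lab) {
    if (grepl("[](){}:;,'[[:space:]]|\\[", lab))
      paste0("'", gsub("'", "''", lab), "'") else lab
  }
  minlab <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    min(vapply(kids[[as.character(node)]], function(e)
      minlab(tree$edge[e, 2]), character(1)))
  }
  serialize <- function(node, len) {
    s <- if (node <= ntip) {
      fmt_label(tree$tip.label[node])
    } else {
      es <- kids[[as.character(node)]]
      ord <- order(vapply(es, function(e) minlab(tree$edge[e, 2]),
                          character(1)))
      inner <- vapply(es[ord], function(e)
        serialize(tree$edge[e, 2], tree$edge.length[e]), character(1))
      paste0("(", paste(inner, collapse = ","), ")")
    }
    if (is.na(len)) s else paste0(s, ":", format(len, digits = 10))
  }
  nwk <- paste0(serialize(root, NA_real_), ";")
  if (!is.null(path)) writeLines(nwk, path)
  invisible(nwk)
}
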