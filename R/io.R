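#' Read a genotype panel
#'
#' Reads haploid-coded biallelic SNP panels from one of three formats:
#'
#' * `tsv_matrix`: tab-separated matrix, header row of marker ids, first
#'   column accession id, cells 0/1/NA. A sidecar map file at
#'   `<path>.map` (columns `id`, `chrom`, `pos_bp`, `ref`, `alt`) supplies
#'   marker coordinates; an optional `<path>.acc` sidecar (columns `id`,
#'   `name`, `assigned_subpop`) supplies accession metadata.
#' * `vcf`: VCF v4.2 with GT field; only biallelic SNP records are used,
#'   others are skipped with a warning. Diploid genotypes are collapsed to
#'   haploid codes; heterozygous calls are handled per `het_policy`.
#' * `structure`: plain-text STRUCTURE format, header row of marker ids then
#'   two rows per individual (first field the id, then one allele per locus,
#'   -9 = missing). Discordant allele pairs are heterozygous and follow
#'   `het_policy`. No map sidecar is expected; synthetic unit positions are
#'   used unless `<path>.map` exists.
#'
#' Accessions are inbred, so the package stores one allele per locus.
#' `het_as_missing` (default) sets heterozygous calls to `NA`;
#' `het_as_major` replaces them with the marker's major allele computed
#' from the unambiguous calls (ties resolved to the reference allele).
#'
#' @param path file path.
#' @param format one of `"tsv_matrix"`, `"vcf"`, `"structure"`.
#' @param het_policy `"het_as_missing"` or `"het_as_major"`.
#' @return a [genotype_panel()].
#' @export
read_panel <- function(path,
                       format = c("tsv_matrix", "vcf", "structure"),
                       het_policy = c("het_as_missing", "het_as_major")) {
  format <- match.arg(format)
  het_policy <- match.arg(het_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         tsv_matrix = read_panel_tsv(path),
         vcf = read_panel_vcf(path, het_policy),
         structure = read_panel_structure(path, het_policy))
}

read_panel_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("parse error in ", path, ": empty file")
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nfield != nfield[1]))
    stop("parse error in ", path, " at line ",
         which(nfield != nfield[1])[1], ": expected ", nfield[1],
         " fields, found ", nfield[nfield != nfield[1]][1])
  x <- read.delim(path, check.names = FALSE, colClasses = "character",
                  na.strings = character())
  ids <- x[[1]]
  m <- as.matrix(x[, -1, drop = FALSE])
  bad <- matrix(!(m %in% c("0", "1", "NA")), nrow(m))
  if (any(bad)) {
    row <- which(apply(bad, 1, any))[1]
    stop("parse error in ", path, " at line ", row + 1L,
         ": calls must be 0/1/NA")
  }
  calls <- matrix(suppressWarnings(as.integer(m)), nrow(m), ncol(m))
  rownames(calls) <- ids
  colnames(calls) <- colnames(m)

  mapfile <- paste0(path, ".map")
  if (file.exists(mapfile)) {
    map <- read.delim(mapfile, colClasses = c("character", "integer",
                                              "integer", "character",
                                              "character"))
    idx <- match(colnames(calls), map$id)
    if (anyNA(idx))
      stop("map file ", mapfile, " is missing marker ",
           colnames(calls)[is.na(idx)][1])
    map <- map[idx, , drop = FALSE]
  } else {
    map <- default_map(colnames(calls))
  }
  accfile <- paste0(path, ".acc")
  acc <- if (file.exists(accfile)) {
    read.delim(accfile, colClasses = "character")
  } else NULL
  genotype_panel(calls, map, acc)
}

default_map <- function(ids) {
  data.frame(id = ids, chrom = 1L, pos_bp = seq_along(ids),
             ref = "A", alt = "C", stringsAsFactors = FALSE)
}

read_panel_vcf <- function(path, het_policy) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    fix$REF %in% bases & fix$ALT %in% bases
  if (any(!snp))
    warning(sum(!snp), " non-biallelic-SNP record(s) skipped")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  if (!nrow(fix)) stop("no biallelic SNP records in ", path)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt %in% c("0/0", "0")] <- 0L
  code[gt %in% c("1/1", "1")] <- 1L
  het <- !is.na(gt) & gt %in% c("0/1", "1/0")
  calls <- t(code)  # accessions x markers
  if (het_policy == "het_as_major" && any(het)) {
    hetT <- t(het)
    f <- colMeans(calls, na.rm = TRUE)
    f[is.nan(f)] <- 0
    major <- ifelse(f > 0.5, 1L, 0L)  # ties -> reference
    calls[hetT] <- major[col(calls)[hetT]]
  }
  ids <- fix$ID
  anon <- is.na(ids) | ids == "."
  ids[anon] <- paste0("snp_", fix$CHROM[anon], "_", fix$POS[anon])
  map <- data.frame(id = ids, chrom = as.integer(fix$CHROM),
                    pos_bp = as.integer(fix$POS), ref = fix$REF,
                    alt = fix$ALT, stringsAsFactors = FALSE)
  rownames(calls) <- colnames(gt)
  genotype_panel(calls, map)
}

read_panel_structure <- function(path, het_policy) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("parse error in ", path, ": too few lines")
  markers <- strsplit(lines[1], "[ \t]+")[[1]]
  body <- strsplit(trimws(lines[-1]), "[ \t]+")
  nf <- lengths(body)
  if (any(nf != length(markers) + 1L))
    stop("parse error in ", path, " at line ",
         which(nf != length(markers) + 1L)[1] + 1L,
         ": expected ", length(markers) + 1L, " fields")
  if (length(body) %% 2L != 0L)
    stop("parse error in ", path, ": odd number of genotype rows")
  ids <- vapply(body, `[`, "", 1L)
  n <- length(body) / 2L
  a1 <- do.call(rbind, lapply(body[seq(1, by = 2, length.out = n)],
                              function(x) as.integer(x[-1])))
  a2 <- do.call(rbind, lapply(body[seq(2, by = 2, length.out = n)],
                              function(x) as.integer(x[-1])))
  if (!all(ids[seq(1, by = 2, length.out = n)] ==
           ids[seq(2, by = 2, length.out = n)]))
    stop("parse error in ", path, ": the two rows of an individual disagree",
         " on its id")
  a1[a1 == -9L] <- NA_integer_
  a2[a2 == -9L] <- NA_integer_
  calls <- ifelse(is.na(a1), a2, a1)
  het <- !is.na(a1) & !is.na(a2) & a1 != a2
  calls[het] <- NA_integer_
  if (het_policy == "het_as_major" && any(het)) {
    f <- colMeans(calls, na.rm = TRUE)
    f[is.nan(f)] <- 0
    major <- ifelse(f > 0.5, 1L, 0L)
    calls[het] <- major[col(calls)[het]]
  }
  rownames(calls) <- ids[seq(1, by = 2, length.out = n)]
  mapfile <- paste0(path, ".map")
  map <- if (file.exists(mapfile)) {
    read.delim(mapfile, colClasses = c("character", "integer", "integer",
                                       "character", "character"))
  } else default_map(markers)
  colnames(calls) <- markers
  genotype_panel(calls, map)
}

#' Write a genotype panel
#'
#' Inverse of [read_panel()]. `tsv_matrix` writes the call matrix plus
#' `<path>.map` and `<path>.acc` sidecars. `vcf` encodes the haploid calls
#' as homozygous diploid genotypes (0 -> 0/0, 1 -> 1/1, NA -> ./.) under a
#' minimal VCF v4.2 header. `structure` writes the two-rows-per-individual
#' integer convention with -9 for missing (both rows equal, since calls
#' are haploid).
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @param format one of `"tsv_matrix"`, `"vcf"`, `"structure"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path,
                        format = c("tsv_matrix", "vcf", "structure")) {
  format <- match.arg(format)
  switch(format,
         tsv_matrix = write_panel_tsv(panel, path),
         vcf = write_panel_vcf(panel, path),
         structure = write_panel_structure(panel, path))
  invisible(path)
}

write_panel_tsv <- function(panel, path) {
  m <- panel$calls
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  write.table(panel$markers, paste0(path, ".map"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(panel$accessions, paste0(path, ".acc"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

write_panel_vcf <- function(panel, path) {
  gt <- matrix("./.", nrow(panel$markers), nrow(panel$accessions))
  x <- t(panel$calls)
  gt[!is.na(x) & x == 0L] <- "0/0"
  gt[!is.na(x) & x == 1L] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##source=paddymix",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$accessions$id), collapse = "\t"))
  body <- paste(panel$markers$chrom, panel$markers$pos_bp, panel$markers$id,
                panel$markers$ref, panel$markers$alt, ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
}

write_panel_structure <- function(panel, path) {
  m <- panel$calls
  m[is.na(m)] <- -9L
  rows <- character(2L * nrow(m))
  for (i in seq_len(nrow(m))) {
    line <- paste(c(rownames(m)[i], m[i, ]), collapse = " ")
    rows[2L * i - 1L] <- line
    rows[2L * i] <- line
  }
  writeLines(c(paste(colnames(m), collapse = " "), rows), path)
}

#' Quality-control filter for a panel
#'
#' Keeps SNPs whose minor allele frequency (computed over non-missing
#' calls) is strictly greater than `maf_min` and whose missing-call
#' fraction is at most `max_missing`. The accession set is unchanged and
#' the input panel is not modified.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor allele frequency, strict (default 0.01,
#'   i.e. ">1% minor allele frequency").
#' @param max_missing maximum tolerated fraction of missing calls per SNP.
#' @return a filtered [genotype_panel()].
#' @export
apply_qc <- function(panel, maf_min = 0.01, max_missing = 0.2) {
  stopifnot(maf_min >= 0, maf_min < 0.5, max_missing >= 0, max_missing <= 1)
  maf <- minor_allele_freqs(panel)
  maf[is.nan(maf)] <- 0
  missf <- colMeans(is.na(panel$calls))
  keep <- maf > maf_min & missf <= max_missing
  if (!any(keep)) stop("empty panel after QC")
  panel[, which(keep)]
}
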