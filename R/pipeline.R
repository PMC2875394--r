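pipeline_defaults <- function() {
  list(
    input = list(path = NULL, format = "tsv_matrix",
                 het_policy = "het_as_missing"),
    qc = list(maf_min = 0.01, max_missing = 0.2),
    structure = list(K = 5, restarts = 10, tol = 1e-4, max_iter = 2000,
                     admixed_threshold = 0.80),
    hmm = list(rate = "auto",
               rate_grid = 10^seq(-9, -6.5, by = 0.5),
               q_floor = 0.01,
               refine_iter = 10),
    introgression = list(min_snps = 5, post_min = 0.5),
    fst = list(window_bp = 100000, groups = NULL),
    tree = list(enabled = TRUE),
    mapping = list(),   # list of {trait, phenotype, method, donor}
    alpha = 0.05,
    seed = 1,
    outdir = "paddymix_out"
  )
}

#' Parse and validate a pipeline configuration
#'
#' Reads a YAML configuration file, fills defaults (QC minor allele
#' frequency > 0.01, K = 5 with 10 EM restarts, 80% assignment rule,
#' >= 5-SNP introgression segments, 100 kb F_ST windows, alpha = 0.05) and
#' validates keys and types. Unknown keys are an error, listing the valid
#' ones.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return object of class `pipeline_config` (a validated nested list).
#' @export
parse_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path) %||% list()
    cfg <- merge_config(cfg, user, "")
  }
  validate_config(cfg)
}

merge_config <- function(def, user, prefix) {
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(def))
      stop("unknown config key '", full, "'; valid keys here: ",
           paste(names(def), collapse = ", "))
    if (is.list(def[[key]]) && !is.null(names(def[[key]])) &&
        key != "mapping") {
      if (!is.list(user[[key]]))
        stop("config key '", full, "' must be a mapping")
      def[[key]] <- merge_config(def[[key]], user[[key]],
                                 paste0(full, "."))
    } else {
      def[key] <- list(user[[key]])  # keeps explicit NULLs
    }
  }
  def
}

validate_config <- function(cfg) {
  chk_num <- function(x, key, lo = -Inf, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      stop("config key '", key, "' must be a number in [", lo, ", ", hi,
           "]")
    x
  }
  chk_num(cfg$qc$maf_min, "qc.maf_min", 0, 0.5 - 1e-12)
  chk_num(cfg$qc$max_missing, "qc.max_missing", 0, 1)
  chk_num(cfg$structure$K, "structure.K", 1)
  chk_num(cfg$structure$restarts, "structure.restarts", 1)
  chk_num(cfg$structure$admixed_threshold, "structure.admixed_threshold",
          1e-12, 1)
  chk_num(cfg$introgression$min_snps, "introgression.min_snps", 1)
  chk_num(cfg$introgression$post_min, "introgression.post_min", 0, 1)
  chk_num(cfg$fst$window_bp, "fst.window_bp", 1)
  chk_num(cfg$alpha, "alpha", 0, 1)
  chk_num(cfg$seed, "seed")
  if (!cfg$input$format %in% c("tsv_matrix", "vcf", "structure"))
    stop("config key 'input.format' must be tsv_matrix, vcf or structure")
  if (!identical(cfg$hmm$rate, "auto"))
    chk_num(cfg$hmm$rate, "hmm.rate", 0)
  chk_num(cfg$hmm$q_floor, "hmm.q_floor", 0, 0.5)
  chk_num(cfg$hmm$refine_iter, "hmm.refine_iter", 0, 1000)
  for (m in cfg$mapping) {
    if (is.null(m$trait) || is.null(m$phenotype) || is.null(m$method))
      stop("each mapping entry needs trait, phenotype and method")
    if (!m$method %in% c("admixture_map", "mixed_model"))
      stop("mapping method must be admixture_map or mixed_model")
    if (m$method == "admixture_map" && is.null(m$donor))
      stop("admixture_map mapping entries need a donor")
  }
  structure(cfg, class = "pipeline_config")
}

#' Write the effective configuration as YAML
#'
#' @param cfg a [parse_config()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — load, QC, admixture-model fit
#' and classification, allele-sharing tree, pairwise F_ST (genome-wide and
#' windowed), linkage-HMM local ancestry, introgression profiles and
#' segment calls, then any configured trait mapping — writing TSV/BED/
#' Newick artifacts plus a JSON manifest (input hashes, seed, package
#' version, every file written) into the output directory. Stage seeds are
#' fanned out deterministically from the master seed, so results are
#' byte-identical across runs with the same inputs and configuration. A
#' failing stage aborts with an error naming the stage.
#'
#' @param config a [parse_config()] result (or path to a YAML file).
#' @param panel optionally, an in-memory [genotype_panel()]; otherwise the
#'   panel is read from `config$input$path`.
#' @return the manifest, invisibly (list with `artifacts` by class,
#'   `files`, `hashes`, `seed`, `version`).
#' @export
run_pipeline <- function(config, panel = NULL) {
  if (is.character(config)) config <- parse_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  cat("", file = logfile)
  files <- character()
  artifacts <- list()
  emit <- function(df, name, class) {
    f <- file.path(outdir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
    artifacts[[class]] <<- c(artifacts[[class]], name)
    f
  }
  stage <- function(name, expr) {
    msg_log("stage ", name, " ...", logfile = logfile)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  panel <- stage("load", {
    if (is.null(panel)) {
      if (is.null(config$input$path)) stop("no input path configured")
      read_panel(config$input$path, config$input$format,
                 config$input$het_policy)
    } else panel
  })

  panel <- stage("qc", apply_qc(panel, config$qc$maf_min,
                                config$qc$max_missing))
  qcf <- file.path(outdir, "panel_qc.tsv")
  write_panel(panel, qcf)
  files <- c(files, qcf, paste0(qcf, ".map"), paste0(qcf, ".acc"))
  artifacts[["qc_panel"]] <- "panel_qc.tsv"

  fit <- stage("structure", fit_admixture(
    panel, K = config$structure$K, n_restarts = config$structure$restarts,
    seed = stage_seed(config$seed, "structure"),
    tol = config$structure$tol, max_iter = config$structure$max_iter))
  labels <- classify_accessions(fit, config$structure$admixed_threshold)
  panel <- annotate_assignments(panel, labels)
  emit(data.frame(id = rownames(fit$Q), fit$Q, check.names = FALSE),
       "Q.tsv", "admixture")
  emit(data.frame(cluster = rownames(fit$P), fit$P, check.names = FALSE),
       "P.tsv", "admixture")
  emit(data.frame(id = names(labels), assigned_subpop = labels),
       "assignments.tsv", "admixture")

  if (isTRUE(config$tree$enabled)) stage("tree", {
    D <- allele_sharing_distance(panel)
    emit(data.frame(id = rownames(D), D, check.names = FALSE),
         "allele_sharing_dist.tsv", "tree")
    tr <- nj_tree(D)
    f <- file.path(outdir, "nj_tree.nwk")
    write_newick(tr, f)
    files <- c(files, f)
    artifacts[["tree"]] <- c(artifacts[["tree"]], "nj_tree.nwk")
  })

  stage("fst", {
    groups <- config$fst$groups %||%
      setdiff(unique(labels), c("ADMIXED", "UNASSIGNED"))
    if (length(groups) >= 2) {
      pw <- fst_pairwise(panel, labels, groups)
      emit(data.frame(group = rownames(pw), pw, check.names = FALSE),
           "fst_pairwise.tsv", "fst")
      win <- list()
      for (i in seq_along(groups)) for (j in seq_along(groups)) {
        if (j <= i) next
        r <- fst_windows(fst_per_snp(panel, labels, groups[c(i, j)]),
                         config$fst$window_bp)
        w <- r$windows
        w$pair <- paste0(groups[i], "-", groups[j])
        win[[length(win) + 1L]] <- w
      }
      emit(do.call(rbind, win), "fst_windows.tsv", "fst")
    } else message("fewer than 2 assigned groups; F_ST skipped")
  })

  local <- stage("local_ancestry", {
    rate <- config$hmm$rate
    if (identical(rate, "auto"))
      rate <- fit_switch_rate(panel, fit, config$hmm$rate_grid)
    posterior_ancestry(panel, fit, as.numeric(rate),
                       q_floor = config$hmm$q_floor,
                       refine_iter = config$hmm$refine_iter)
  })
  mk <- panel$markers
  summ <- data.frame(id = mk$id, chrom = mk$chrom, pos_bp = mk$pos_bp,
                     check.names = FALSE)
  for (k in seq_len(local$K))
    summ[[paste0("mean_", local$pop_names[k])]] <-
      as.vector(colMeans(matrix(local$posterior[, , k],
                                dim(local$posterior)[1])))
  emit(summ, "local_ancestry_mean.tsv", "local_ancestry")

  stage("introgression", {
    groups <- setdiff(unique(labels), c("ADMIXED", "UNASSIGNED"))
    prof <- list()
    for (rec in groups) for (don in setdiff(local$pop_names, rec)) {
      p <- mean_introgression(local, labels, rec, don)
      prof[[length(prof) + 1L]] <- data.frame(
        recipient = rec, donor = don, id = mk$id,
        mean_component = p$values, threshold_95 = p$threshold_95,
        stringsAsFactors = FALSE)
    }
    if (length(prof))
      emit(do.call(rbind, prof), "introgression_profiles.tsv",
           "introgression")
    calls <- list()
    for (i in seq_along(labels)) {
      own <- labels[i]
      for (don in setdiff(local$pop_names, own)) {
        cc <- call_segments(local, mk, names(labels)[i], don,
                            config$introgression$min_snps,
                            config$introgression$post_min)
        if (nrow(cc)) calls[[length(calls) + 1L]] <- cc
      }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
      data.frame(accession_id = character(), donor_pop = character(),
                 chrom = integer(), start_bp = integer(),
                 end_bp = integer(), n_snps = integer(),
                 mean_posterior = numeric())
    emit(calls, "introgression_calls.tsv", "introgression")
    f <- file.path(outdir, "introgression_calls.bed")
    write_calls_bed(calls, f)
    files <- c(files, f)
    artifacts[["introgression"]] <- c(artifacts[["introgression"]],
                                      "introgression_calls.bed")
  })

  for (m in config$mapping) stage(paste0("mapping_", m$trait), {
    ph <- read.delim(m$phenotype, colClasses = c("character", "numeric"))
    names(ph) <- c("id", "value")
    attr(ph, "trait") <- m$trait
    res <- if (m$method == "admixture_map") {
      admixture_map(local, ph, names(labels)[labels == "ADMIXED"],
                    m$donor, mk)
    } else {
      mixed_model_assoc(panel, ph, fit$Q, kinship_matrix(panel))
    }
    res <- bonferroni(res, config$alpha)
    emit(res$table, paste0("mapping_", m$trait, ".tsv"), "mapping")
  })

  cfgf <- file.path(outdir, "effective_config.yaml")
  write_config(config, cfgf)
  files <- c(files, cfgf)
  manifest <- list(
    artifacts = artifacts,
    files = basename(files),
    hashes = as.list(tools::md5sum(sort(files))),
    input = config$input$path %||% "in-memory panel",
    seed = config$seed,
    version = as.character(packageVersion("paddymix")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  msg_log("pipeline complete: ", length(files), " files in ", outdir,
          logfile = logfile)
  invisible(manifest)
}
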