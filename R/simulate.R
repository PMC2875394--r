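#' Default rice-like subpopulation divergence parameters
#'
#' Balding-Nichols divergence parameters for the five rice subpopulations.
#' Values were calibrated once, by least squares against the published
#' pairwise F_ST range for the five groups (0.23 between indica and aus up
#' to 0.53), so that simulated panels reproduce realized pairwise Weir
#' F_ST of roughly 0.2-0.55.
#'
#' @return named numeric vector of per-subpopulation F values.
#' @export
rice_divergence <- function() {
  c(indica = 0.18, aus = 0.25, temperate_japonica = 0.62,
    tropical_japonica = 0.35, groupV = 0.45)
}

#' Rice-like chromosome layout
#'
#' Spreads `L` markers over `n_chrom` chromosomes at fixed physical
#' spacing, emulating a genotyping array with one SNP roughly every 260 kb
#' across the 12 rice chromosomes.
#'
#' @param L total marker count.
#' @param n_chrom number of chromosomes.
#' @param spacing_bp distance between adjacent markers in bp.
#' @return data.frame with columns `chrom`, `n_markers`, `spacing_bp`.
#' @export
rice_chrom_layout <- function(L = 1311, n_chrom = 12, spacing_bp = 260000) {
  base <- L %/% n_chrom
  extra <- L %% n_chrom
  data.frame(chrom = seq_len(n_chrom),
             n_markers = base + as.integer(seq_len(n_chrom) <= extra),
             spacing_bp = as.integer(spacing_bp))
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-panel generator.
#' Defaults emulate the structure of the rice diversity panel the package
#' targets: five subpopulations at divergence spanning pairwise F_ST
#' 0.2-0.55, ~1,311 SNPs at ~260 kb spacing over 12 chromosomes, mostly
#' pure inbred accessions with a minority of admixed ones, and shared
#' identical-by-state donor introgression blocks.
#'
#' @param K number of ancestral subpopulations.
#' @param F_k per-subpopulation Balding-Nichols divergence, length K,
#'   values in \[0, 1) (0 means no divergence from the ancestral pool).
#' @param n_pure_per_pop pure accessions per subpopulation (scalar or
#'   length-K vector).
#' @param n_admixed number of admixed accessions.
#' @param chrom_layout data.frame as from [rice_chrom_layout()].
#' @param base_freq_range range of the ancestral allele frequency draw.
#' @param switch_rate expected ancestry switches per bp along admixed
#'   chromosomes (default one switch every ~20 Mb).
#' @param admix_alpha Dirichlet concentration for admixed ancestry
#'   proportions (over 2-3 randomly chosen components).
#' @param introgression_events list of events, each a list with fields
#'   `donor`, `recipient` (subpopulation indices or names), `chrom`,
#'   `start_bp`, `end_bp`, `carrier_fraction`.
#' @param pop_names subpopulation names, length K.
#' @param missing_rate fraction of calls set missing at random.
#' @param seed integer seed; the whole simulation is reproducible given it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(K = 5,
                              F_k = rice_divergence(),
                              n_pure_per_pop = 60,
                              n_admixed = 25,
                              chrom_layout = rice_chrom_layout(),
                              base_freq_range = c(0.05, 0.95),
                              switch_rate = 5e-8,
                              admix_alpha = 0.5,
                              introgression_events = list(),
                              pop_names = NULL,
                              missing_rate = 0,
                              seed = 1L) {
  stopifnot(K >= 1, length(F_k) == K, all(F_k >= 0), all(F_k < 1),
            all(n_pure_per_pop >= 0), n_admixed >= 0,
            switch_rate >= 0, missing_rate >= 0, missing_rate < 1)
  if (length(n_pure_per_pop) == 1L) n_pure_per_pop <- rep(n_pure_per_pop, K)
  stopifnot(length(n_pure_per_pop) == K)
  if (is.null(pop_names))
    pop_names <- names(F_k) %||% paste0("pop", seq_len(K))
  stopifnot(length(pop_names) == K)
  chrom_ends <- chrom_layout$n_markers * chrom_layout$spacing_bp
  for (ev in introgression_events) {
    ev <- normalize_event(ev, pop_names)
    ci <- match(ev$chrom, chrom_layout$chrom)
    if (is.na(ci)) stop("introgression event on unknown chromosome ",
                        ev$chrom)
    stopifnot(ev$start_bp >= 1, ev$end_bp >= ev$start_bp,
              ev$carrier_fraction >= 0, ev$carrier_fraction <= 1)
    if (ev$end_bp > chrom_ends[ci])
      stop("introgression event extends beyond chromosome ", ev$chrom)
  }
  structure(list(K = K, F_k = unname(F_k), n_pure_per_pop = n_pure_per_pop,
                 n_admixed = n_admixed, chrom_layout = chrom_layout,
                 base_freq_range = base_freq_range,
                 switch_rate = switch_rate, admix_alpha = admix_alpha,
                 introgression_events = introgression_events,
                 pop_names = pop_names, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

normalize_event <- function(ev, pop_names) {
  for (f in c("donor", "recipient")) {
    if (is.character(ev[[f]])) {
      idx <- match(ev[[f]], pop_names)
      if (is.na(idx)) stop("unknown subpopulation in event: ", ev[[f]])
      ev[[f]] <- idx
    }
  }
  ev
}

#' Draw subpopulation allele frequencies (Balding-Nichols)
#'
#' For each locus an ancestral frequency p is drawn uniformly on
#' `base_freq_range`; each subpopulation's frequency is then an independent
#' draw from Beta(p (1-F_k)/F_k, (1-p)(1-F_k)/F_k), whose mean is p and
#' variance F_k p (1-p). `F_k = 0` is the no-divergence limit and returns
#' p exactly.
#'
#' @param K number of subpopulations.
#' @param L number of loci.
#' @param base_freq_range interval for the ancestral frequency.
#' @param F_k length-K divergence vector, entries in \[0, 1).
#' @param seed integer seed.
#' @return list with `P` (K x L frequency matrix) and `p_anc` (length-L
#'   ancestral frequencies).
#' @export
draw_subpop_freqs <- function(K, L, base_freq_range = c(0.05, 0.95), F_k,
                              seed = 1L) {
  stopifnot(K >= 1, L >= 1, length(F_k) == K)
  if (any(F_k < 0 | F_k >= 1)) stop("F_k must lie in [0, 1)")
  set.seed(seed)
  p <- runif(L, base_freq_range[1], base_freq_range[2])
  P <- matrix(0, K, L)
  for (k in seq_len(K)) {
    P[k, ] <- if (F_k[k] == 0) p else {
      a <- (1 - F_k[k]) / F_k[k]
      rbeta(L, p * a, (1 - p) * a)
    }
  }
  list(P = P, p_anc = p)
}

#' Simulate a genotype panel with known ancestry truth
#'
#' Generates an inbred-accession SNP panel under the admixture model with
#' linkage. Pure accessions have one-hot ancestry and constant local
#' ancestry; admixed accessions draw global proportions from a Dirichlet
#' over 2-3 randomly selected subpopulations and a Markov local-ancestry
#' mosaic whose stationary distribution equals those proportions, with
#' per-bp switch intensity `switch_rate`. Introgression events then
#' overwrite local ancestry with the donor label over the stated interval
#' (markers with `start_bp <= pos_bp <= end_bp`) for a `carrier_fraction`
#' random subset of the recipient subpopulation's pure accessions. Calls
#' are Bernoulli draws from the local ancestry's subpopulation frequency.
#'
#' @param config a [simulation_config()].
#' @return list with elements `panel` (a [genotype_panel()]) and `truth`, a
#'   list with `Q_true` (n x K), `local_ancestry_true` (n x L, entries
#'   1..K), `ancestral_freqs` (K x L), `pop_true` (generating label per
#'   accession, `"ADMIXED"` for mosaics), `introgression_carriers` (list of
#'   accession-id vectors, one per event), and `pop_names`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  K <- config$K
  lay <- config$chrom_layout
  L <- sum(lay$n_markers)
  n <- sum(config$n_pure_per_pop) + config$n_admixed
  if (n == 0L) stop("zero accessions requested")

  fr <- draw_subpop_freqs(K, L, config$base_freq_range, config$F_k,
                          seed = config$seed)
  P <- fr$P
  set.seed(stage_seed(config$seed, "panel"))

  chrom <- rep(lay$chrom, lay$n_markers)
  pos <- unlist(lapply(seq_len(nrow(lay)), function(i)
    seq_len(lay$n_markers[i]) * lay$spacing_bp[i]))
  markers <- data.frame(id = sprintf("snp%04d", seq_len(L)),
                        chrom = chrom, pos_bp = pos,
                        ref = "A", alt = "C", stringsAsFactors = FALSE)

  pop_true <- c(rep(config$pop_names, config$n_pure_per_pop),
                rep("ADMIXED", config$n_admixed))
  ids <- sprintf("acc%03d", seq_len(n))
  Q <- matrix(0, n, K, dimnames = list(ids, config$pop_names))
  anc <- matrix(0L, n, L, dimnames = list(ids, markers$id))

  i <- 0L
  for (k in seq_len(K)) {
    for (j in seq_len(config$n_pure_per_pop[k])) {
      i <- i + 1L
      Q[i, k] <- 1
      anc[i, ] <- k
    }
  }
  for (j in seq_len(config$n_admixed)) {
    i <- i + 1L
    ncomp <- if (K == 1L) 1L else sample(2:min(3L, K), 1L)
    comp <- sample.int(K, ncomp)
    Q[i, comp] <- rdirichlet(1, rep(config$admix_alpha, ncomp))
    anc[i, ] <- ancestry_mosaic(Q[i, ], chrom, pos, config$switch_rate)
  }

  carriers <- vector("list", length(config$introgression_events))
  for (e in seq_along(config$introgression_events)) {
    ev <- normalize_event(config$introgression_events[[e]],
                          config$pop_names)
    rec <- which(pop_true == config$pop_names[ev$recipient])
    ncar <- round(ev$carrier_fraction * length(rec))
    car <- sort(sample(rec, ncar))
    span <- which(chrom == ev$chrom & pos >= ev$start_bp &
                    pos <= ev$end_bp)
    anc[car, span] <- ev$donor
    carriers[[e]] <- ids[car]
  }

  pr <- matrix(P[cbind(as.vector(anc), rep(seq_len(L), each = n))], n, L)
  calls <- matrix(rbinom(n * L, 1L, pr), n, L,
                  dimnames = list(ids, markers$id))
  if (config$missing_rate > 0)
    calls[runif(n * L) < config$missing_rate] <- NA_integer_

  panel <- genotype_panel(calls, markers,
                          data.frame(id = ids, name = ids,
                                     assigned_subpop = "UNASSIGNED",
                                     stringsAsFactors = FALSE))
  truth <- list(Q_true = Q, local_ancestry_true = anc, ancestral_freqs = P,
                pop_true = pop_true, introgression_carriers = carriers,
                pop_names = config$pop_names)
  list(panel = panel, truth = truth)
}

# Markov ancestry mosaic along chromosomes: between adjacent markers at
# distance d the state is redrawn from q with probability 1 - exp(-rate*d),
# so q is the stationary distribution and rate the per-bp switch intensity.
ancestry_mosaic <- function(q, chrom, pos, rate) {
  L <- length(pos)
  out <- integer(L)
  K <- length(q)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    state <- sample.int(K, 1L, prob = q)
    out[idx[1]] <- state
    if (length(idx) > 1L) {
      d <- diff(pos[idx])
      psw <- 1 - exp(-rate * d)
      for (j in seq_along(d)) {
        if (runif(1) < psw[j]) state <- sample.int(K, 1L, prob = q)
        out[idx[j + 1L]] <- state
      }
    }
  }
  out
}

#' Simulate a phenotype from causal loci
#'
#' Generates trait values y_i = sum_c effect_c * g_ic + e_i, with the
#' noise variance set so the genetic fraction of total variance equals
#' `h2` in expectation. Missing causal calls contribute the panel allele
#' frequency (mean imputation) to the genetic value. `h2 = 0` returns pure
#' standard-normal noise.
#'
#' @param panel a [genotype_panel()].
#' @param causal data.frame with columns `marker` (id or index) and
#'   `effect`.
#' @param h2 target heritability in \[0, 1\].
#' @param seed integer seed.
#' @param trait trait name recorded on the output.
#' @return data.frame with columns `id`, `value`; attribute `trait`.
#' @export
simulate_phenotype <- function(panel, causal, h2 = 0.5, seed = 1L,
                               trait = "trait") {
  stopifnot(h2 >= 0, h2 <= 1)
  idx <- if (is.character(causal$marker))
    match(causal$marker, panel$markers$id) else as.integer(causal$marker)
  if (anyNA(idx) || any(idx < 1L) || any(idx > ncol(panel$calls)))
    stop("causal marker not present in panel")
  set.seed(seed)
  n <- nrow(panel$calls)
  g <- panel$calls[, idx, drop = FALSE]
  storage.mode(g) <- "double"
  f <- colMeans(g, na.rm = TRUE)
  for (j in seq_along(idx)) g[is.na(g[, j]), j] <- f[j]
  gv <- as.vector(g %*% causal$effect)
  vg <- var(gv)
  if (h2 == 0) {
    y <- rnorm(n)
  } else {
    if (vg == 0) stop("zero genetic variance at the causal loci")
    ve <- vg * (1 - h2) / h2
    y <- gv + rnorm(n, sd = sqrt(ve))
  }
  out <- data.frame(id = panel$accessions$id, value = y,
                    stringsAsFactors = FALSE)
  attr(out, "trait") <- trait
  out
}
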