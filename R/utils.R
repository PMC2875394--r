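#' @useDynLib paddymix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rbinom rnorm runif rexp var cor optimize pt sd
#'   quantile median ks.test qchisq pchisq lm coef
#' @importFrom utils read.delim write.table head tail packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Nearest-rank percentile
#'
#' Empirical percentile under the nearest-rank (ceiling) convention:
#' the `ceiling(p * n)`-th smallest value. Used for the top-5-percent
#' introgression background cutoff, where the convention matters for
#' reproducibility.
#'
#' @param x numeric vector (NAs dropped).
#' @param p probability in (0, 1].
#' @return a single value of `x`.
#' @export
nearest_rank_quantile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) stop("no non-missing values")
  stopifnot(p > 0, p <= 1)
  unname(x[ceiling(p * length(x))])
}

# Dirichlet draw (rows of a matrix), via normalized gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  x / rowSums(x)
}

# Deterministic per-stage seed fan-out from one master seed, so pipeline
# stages can be re-run in isolation.  Kept below 2^31.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

msg_log <- function(..., logfile = NULL) {
  line <- paste0("[", format(Sys.time(), "%H:%M:%S"), "] ", ...)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
  invisible(line)
}
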