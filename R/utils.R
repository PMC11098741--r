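# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Default distance bin edges for LD refinement profiles
#'
#' The 13 physical-distance bins used to aggregate two- and three-locus
#' cosegregation scores: <100 bp, 100-250, 250-500, 500-1k, 1-2.5k, 2.5-5k,
#' 5-10k, 10-25k, 25-50k, 50-100k, 100-250k, 250-500k and >500 kb.
#'
#' @return Numeric vector of 14 bin edges (bp); bins are left-closed,
#'   right-open.
#' @export
ld_bins <- function() {
  c(0, 100, 250, 500, 1000, 2500, 5000, 10000, 25000,
    50000, 1e5, 2.5e5, 5e5, Inf)
}

# Assign distances (bp) to bin indices given edges; left-closed, right-open.
bin_index <- function(d, edges = ld_bins()) {
  findInterval(d, edges, rightmost.closed = FALSE, left.open = FALSE)
}

# Run code under a fixed seed when one is supplied, otherwise use the current
# RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    abort(sprintf("`%s` = %s is outside its valid range.", name, format(x)))
  }
  invisible(x)
}

# argmax over genotype triplet columns with ties broken toward the smaller g.
argmax_genotype <- function(m) {
  stopifnot(is.matrix(m), ncol(m) == 3L)
  max.col(m, ties.method = "first") - 1L
}

# Normalized Mann-Whitney rank-sum z statistic comparing x vs y, with tie
# correction; returns 0 when either side is empty or all values are tied
# (neutral imputation: a one-sided site carries no bias information).
rank_sum_z <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) return(0)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nties <- table(r)
  n <- n1 + n2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  (u - mu) / sqrt(sigma2)
}
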