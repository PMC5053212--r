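# Population (m-statistic) central moments; no small-sample correction.
central_moment <- function(x, k) mean((x - mean(x))^k)

#' Population skewness m3 / m2^(3/2)
#' @param x numeric sample
#' @return skewness, or NA if the sample has zero variance
#' @keywords internal
pop_skewness <- function(x) {
  m2 <- central_moment(x, 2)
  if (zero_variance(x, m2)) return(NA_real_)
  central_moment(x, 3) / m2^1.5
}

# Effectively-zero second moment (exact zeros and floating-point residue of
# constant samples both count as degenerate).
zero_variance <- function(x, m2) m2 <= 1e-20 * (mean(x^2) + 1e-300)

#' Population kurtosis m4 / m2^2 (Pearson, not excess)
#' @param x numeric sample
#' @return kurtosis, or NA if the sample has zero variance
#' @keywords internal
pop_kurtosis <- function(x) {
  m2 <- central_moment(x, 2)
  if (zero_variance(x, m2)) return(NA_real_)
  central_moment(x, 4) / m2^2
}

#' Shannon entropy of a binned sample, in bits
#'
#' Values are histogrammed into `bins` equal-width bins spanning `range`
#' (the sample range by default) and the entropy of the normalized counts
#' is returned, with 0 log 0 := 0. A constant sample has entropy 0.
#'
#' @param x numeric sample
#' @param bins number of histogram bins
#' @param range length-2 bin support; defaults to range(x)
#' @return entropy in bits
#' @keywords internal
shannon_entropy_bits <- function(x, bins = 256L, range = NULL) {
  if (length(x) == 0L) return(0)
  if (is.null(range)) range <- base::range(x)
  if (range[2] <= range[1]) return(0)
  idx <- pmin(bins, pmax(1L, 1L + floor((x - range[1]) / (range[2] - range[1]) * bins)))
  p <- tabulate(idx, nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Run expr with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is untouched, so simulation is reproducible without
# clobbering global state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Jaccard overlap of two logical masks.
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
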