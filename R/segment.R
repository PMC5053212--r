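#' Intensity histogram over the breast mask
#'
#' Counts of breast-pixel intensities in equal-width bins on the normalized
#' [0, 1] scale (default 256 bins, collapsing the 12-bit native resolution
#' 16:1, which stabilizes entropy estimates). All thresholding methods
#' operate on this histogram so results are invariant to adding empty bins.
#'
#' @param img normalized \code{\link{mammogram}}
#' @param mask logical breast mask
#' @param bins number of bins
#' @return object of class \code{intensity_histogram}: list with integer
#'   \code{counts}, numeric \code{edges} (length bins + 1) and \code{mids}
#' @export
intensity_histogram <- function(img, mask, bins = 256L) {
  vals <- if (inherits(img, "mammogram")) img$pixels[mask] else img[mask]
  if (length(vals) == 0L) stop("empty breast mask", call. = FALSE)
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(bins, pmax(1L, 1L + floor(vals * bins)))
  structure(list(counts = tabulate(idx, nbins = bins), edges = edges,
                 mids = (edges[-1] + edges[-(bins + 1L)]) / 2,
                 n = length(vals)),
            class = "intensity_histogram")
}

check_hist <- function(hist) {
  if (!inherits(hist, "intensity_histogram"))
    stop("expected an intensity_histogram", call. = FALSE)
  if (sum(hist$counts > 0) < 2L)
    stop("degenerate histogram: fewer than two occupied bins", call. = FALSE)
}

#' Otsu threshold from a histogram
#'
#' Returns the bin upper edge minimizing the weighted sum of within-class
#' intensity variances of the two classes (at or below versus strictly
#' above the threshold). Ties are broken toward the lowest threshold.
#'
#' @param hist an \code{\link{intensity_histogram}}
#' @return threshold on the normalized intensity scale
#' @export
threshold_otsu <- function(hist) {
  check_hist(hist)
  cnt <- hist$counts; mids <- hist$mids
  n <- sum(cnt)
  w0 <- cumsum(cnt)                      # class 0 = bins 1..t
  s0 <- cumsum(cnt * mids)
  q0 <- cumsum(cnt * mids^2)
  w1 <- n - w0; s1 <- s0[length(s0)] - s0; q1 <- q0[length(q0)] - q0
  var0 <- ifelse(w0 > 0, q0 / w0 - (s0 / w0)^2, 0)
  var1 <- ifelse(w1 > 0, q1 / w1 - (s1 / w1)^2, 0)
  obj <- (w0 * var0 + w1 * var1) / n
  cand <- which(w0 > 0 & w1 > 0)         # both classes nonempty
  t <- cand[which.min(obj[cand])]        # which.min takes the first = lowest
  hist$edges[t + 1L]
}

#' Percentile threshold from a histogram
#'
#' Threshold at the p-th percentile of breast-pixel intensities (default the
#' median): the smallest bin upper edge whose cumulative count reaches p% of
#' pixels. Dense pixels are those strictly above it, so the dense fraction
#' never exceeds (100 - p)%.
#'
#' @param hist an \code{\link{intensity_histogram}}
#' @param p percentile in [0, 100]
#' @return threshold on the normalized intensity scale
#' @export
threshold_percentile <- function(hist, p = 50) {
  if (!inherits(hist, "intensity_histogram"))
    stop("expected an intensity_histogram", call. = FALSE)
  stopifnot_scalar(p, "p", 0, 100)
  cum <- cumsum(hist$counts)
  t <- which(cum >= p / 100 * cum[length(cum)])[1]
  hist$edges[t + 1L]
}

#' Maximum-entropy (Kapur) threshold from a histogram
#'
#' Returns the bin upper edge maximizing the sum of Shannon entropies of
#' the below- and above-threshold normalized sub-histograms (maximum
#' information transfer between the two classes). Empty bins contribute
#' nothing (0 log 0 := 0); ties are broken toward the lowest threshold.
#'
#' @param hist an \code{\link{intensity_histogram}}
#' @return threshold on the normalized intensity scale
#' @export
threshold_max_entropy <- function(hist) {
  check_hist(hist)
  cnt <- hist$counts
  n <- sum(cnt)
  p <- cnt / n
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p); C0 <- cumsum(plogp)
  P1 <- 1 - P0; C1 <- C0[length(C0)] - C0
  H0 <- ifelse(P0 > 0, log(P0) - C0 / P0, 0)
  H1 <- ifelse(P1 > 0, log(P1) - C1 / P1, 0)
  obj <- H0 + H1
  cand <- which(P0 > 0 & P1 > 0)
  t <- cand[which.max(obj[cand])]
  hist$edges[t + 1L]
}

#' Dense-area mask for one thresholding method
#'
#' The dense area is the set of breast pixels with intensity strictly above
#' the method's threshold. It need not be a single continuous area and no
#' morphological cleanup is applied.
#'
#' @param img normalized \code{\link{mammogram}}
#' @param mask logical breast mask (pectoral already removed)
#' @param method "otsu", "percentile" or "entropy"
#' @param bins histogram bins
#' @param p percentile for \code{method = "percentile"}
#' @return logical dense mask with attributes \code{method} and
#'   \code{threshold}
#' @export
dense_mask <- function(img, mask, method = c("otsu", "percentile", "entropy"),
                       bins = 256L, p = 50) {
  method <- match.arg(method)
  hist <- intensity_histogram(img, mask, bins = bins)
  thr <- switch(method,
                otsu = threshold_otsu(hist),
                percentile = threshold_percentile(hist, p = p),
                entropy = threshold_max_entropy(hist))
  px <- if (inherits(img, "mammogram")) img$pixels else img
  out <- mask & px > thr
  attr(out, "method") <- method
  attr(out, "threshold") <- thr
  out
}

#' Dense-pixel fraction of the breast area, in percent
#'
#' A documented proxy for percent mammographic density on synthetic runs:
#' 100 times the number of dense pixels over the number of breast pixels.
#'
#' @param dense logical dense mask
#' @param breast logical breast mask
#' @return percent in [0, 100]
#' @export
percent_density_proxy <- function(dense, breast) {
  nb <- sum(breast)
  if (nb == 0L) stop("empty breast mask", call. = FALSE)
  100 * sum(dense & breast) / nb
}
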