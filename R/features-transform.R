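# Orthonormal DCT-II matrix of order n.
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * k + 1) / (2 * n))
  C[1, ] <- sqrt(1 / n)
  C
}

# 2-D orthonormal DCT-II.
dct2 <- function(x) dct_matrix(nrow(x)) %*% x %*% t(dct_matrix(ncol(x)))

# 3x3 local range filter (max - min), replicate padding.
local_range_filter <- function(x) {
  h <- nrow(x); w <- ncol(x)
  pad <- x[c(1, 1:h, h), c(1, 1:w, w), drop = FALSE]
  mx <- mn <- x
  mx[] <- -Inf; mn[] <- Inf
  for (dr in 0:2) for (dc in 0:2) {
    s <- pad[dr + 1:h, dc + 1:w, drop = FALSE]
    mx <- pmax(mx, s); mn <- pmin(mn, s)
  }
  mx - mn
}

# Determinant-of-Hessian response from second central differences at unit
# scale, replicate padding.
hessian_det <- function(x) {
  h <- nrow(x); w <- ncol(x)
  pad <- x[c(1, 1:h, h), c(1, 1:w, w), drop = FALSE]
  ctr <- pad[1 + 1:h, 1 + 1:w, drop = FALSE]
  xx <- pad[1 + 1:h, 2 + 1:w, drop = FALSE] - 2 * ctr + pad[1 + 1:h, 0 + 1:w, drop = FALSE]
  yy <- pad[2 + 1:h, 1 + 1:w, drop = FALSE] - 2 * ctr + pad[0 + 1:h, 1 + 1:w, drop = FALSE]
  xy <- (pad[2 + 1:h, 2 + 1:w, drop = FALSE] + pad[0 + 1:h, 0 + 1:w, drop = FALSE] -
           pad[2 + 1:h, 0 + 1:w, drop = FALSE] - pad[0 + 1:h, 2 + 1:w, drop = FALSE]) / 4
  xx * yy - xy^2
}

# Daubechies-4 analysis low-pass filter.
DB4_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))

# One periodic DWT analysis step along columns of x (approximation only).
dwt_step_cols <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n / 2, ncol(x))
  for (m in seq_along(DB4_H)) {
    idx <- (2 * (seq_len(n / 2) - 1) + m - 1) %% n + 1
    out <- out + DB4_H[m] * x[idx, , drop = FALSE]
  }
  out
}

# Level-L separable 2-D DWT approximation band (Daubechies-4, periodic,
# zero-padded up to a multiple of 2^L).
dwt2_approx <- function(x, levels = 3L) {
  blk <- 2^levels
  h <- ceiling(nrow(x) / blk) * blk
  w <- ceiling(ncol(x) / blk) * blk
  pad <- matrix(0, h, w)
  pad[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  a <- pad
  for (l in seq_len(levels)) a <- t(dwt_step_cols(t(dwt_step_cols(a))))
  a
}

#' Transform-domain features (F1, F2, F3, F11, F14, F16, F17)
#'
#' F1 = (0,0) coefficient of the orthonormal 2-D DCT-II (for a constant
#' patch c this equals c * sqrt(n * m)); F2 = mean of the level-3
#' approximation band of a periodic Daubechies-4 2-D wavelet transform;
#' F3 = max DFT magnitude of the 3x3 local-range-filtered patch; F11 = max
#' DFT magnitude excluding the DC bin (otherwise the max is trivially the
#' mean); F14 = max DFT magnitude of the determinant-of-Hessian response;
#' F16 = max of log(1 + |DCT|); F17 = max of log(1 + |DFT|) excluding DC
#' (algebraically log(1 + F11)). F3/F14 keep DC since their inputs are
#' filtered images whose mean is informative.
#'
#' @param patch a \code{\link{dense_patch}} (at least 8x8 after padding)
#' @return list with named \code{values} and \code{flags}
#' @export
transform_features <- function(patch) {
  x <- patch$values
  nm <- c("F1", "F2", "F3", "F11", "F14", "F16", "F17")
  if (nrow(x) < 3L || ncol(x) < 3L) return(flagged(nm))
  d <- dct2(x)
  f <- Mod(stats::fft(x))
  f_nodc <- f; f_nodc[1, 1] <- 0   # magnitudes are >= 0, so 0 never wins
  vals <- c(F1 = d[1, 1],
            F2 = mean(dwt2_approx(x, 3L)),
            F3 = max(Mod(stats::fft(local_range_filter(x)))),
            F11 = max(f_nodc),
            F14 = max(Mod(stats::fft(hessian_det(x)))),
            F16 = max(log1p(abs(d))),
            F17 = max(log1p(f_nodc)))
  feat_result(vals)
}
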