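# Log-Gabor transfer function on the DFT grid of an h x w patch.
# Radial term: log-Gaussian around center frequency f0 (cycles/pixel) with
# bandwidth parameter sigma_ratio = sigma/f0; zero DC gain by construction.
# Angular term: Gaussian in orientation around theta0 (one-sided filter, so
# the spatial response is complex).
log_gabor_transfer <- function(h, w, f0, theta0, sigma_ratio = 0.65,
                               sigma_theta = 0.6) {
  fy <- (seq_len(h) - 1) / h; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (seq_len(w) - 1) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  FY <- matrix(fy, h, w); FX <- matrix(fx, h, w, byrow = TRUE)
  f <- sqrt(FX^2 + FY^2)
  radial <- matrix(0, h, w)
  nz <- f > 0
  radial[nz] <- exp(-(log(f[nz] / f0))^2 / (2 * log(sigma_ratio)^2))
  dtheta <- atan2(FY, FX) - theta0
  dtheta <- atan2(sin(dtheta), cos(dtheta))   # wrap to (-pi, pi]
  radial * exp(-dtheta^2 / (2 * sigma_theta^2))
}

# Complex responses of the default bank (2 scales x 4 orientations),
# averaged over the bank.
log_gabor_response <- function(x, f0 = c(1 / 6, 1 / 12),
                               thetas = pi * (0:3) / 4) {
  h <- nrow(x); w <- ncol(x)
  X <- stats::fft(x)
  acc <- matrix(0 + 0i, h, w)
  for (f in f0) for (th in thetas)
    acc <- acc + stats::fft(X * log_gabor_transfer(h, w, f, th),
                            inverse = TRUE) / (h * w)
  acc / (length(f0) * length(thetas))
}

#' Log-Gabor filter-bank entropy features (F8, F9, F10)
#'
#' The patch is convolved with a small log-Gabor bank (2 scales x 4
#' orientations; center frequencies 1/6 and 1/12 cycles/pixel, sigma/f =
#' 0.65) and the complex responses are averaged over the bank. F8, F9 and
#' F10 are the Shannon entropies (256-bin histogram over dense pixels) of
#' the imaginary part, real part and magnitude of the pooled response.
#' Log-Gabor filters have zero DC gain, so a constant patch yields zero
#' response and zero entropies.
#'
#' @param patch a \code{\link{dense_patch}}
#' @return list with named \code{values} and \code{flags}
#' @export
gabor_entropy_features <- function(patch) {
  x <- patch$values
  if (nrow(x) < 4L || ncol(x) < 4L || sum(patch$mask) < 2L)
    return(flagged(c("F8", "F9", "F10")))
  resp <- log_gabor_response(x)
  feat_result(c(F8 = shannon_entropy_bits(Im(resp)[patch$mask]),
                F9 = shannon_entropy_bits(Re(resp)[patch$mask]),
                F10 = shannon_entropy_bits(Mod(resp)[patch$mask])))
}

# Clipped-window box sum via a summed-area table.
box_sum <- function(x, radius) {
  h <- nrow(x); w <- ncol(x)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1, -1] <- apply(apply(x, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(h) - radius, 1L); r2 <- pmin(seq_len(h) + radius, h)
  c1 <- pmax(seq_len(w) - radius, 1L); c2 <- pmin(seq_len(w) + radius, w)
  S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# Local-entropy filter: values quantized to `bins` levels over the patch
# range; per-pixel Shannon entropy (bits) of the level histogram in a
# (2r+1)^2 window clipped at the patch border.
local_entropy_filter <- function(x, radius = 4L, bins = 256L) {
  h <- nrow(x); w <- ncol(x)
  rng <- range(x)
  q <- matrix(1L, h, w)
  if (rng[2] > rng[1])
    q[] <- pmin(bins, pmax(1L, 1L + floor((x - rng[1]) / (rng[2] - rng[1]) * bins)))
  ntot <- box_sum(matrix(1, h, w), radius)
  H <- matrix(0, h, w)
  for (lev in sort(unique(as.vector(q)))) {
    cnt <- box_sum((q == lev) * 1, radius)
    p <- cnt / ntot
    nz <- p > 0
    H[nz] <- H[nz] - p[nz] * log2(p[nz])
  }
  H
}

#' Mean of the entropy-filtered dense area (F7)
#'
#' Applies a 9x9 local-entropy filter (256 quantization bins over the patch
#' range, windows clipped at the patch border) and averages the filtered
#' values over dense pixels. A constant patch gives 0.
#'
#' @param patch a \code{\link{dense_patch}}
#' @return list with \code{values} (F7) and \code{flags}
#' @export
entropy_filter_feature <- function(patch) {
  x <- patch$values
  if (nrow(x) < 3L || ncol(x) < 3L) return(flagged("F7"))
  H <- local_entropy_filter(x, radius = 4L, bins = 256L)
  feat_result(c(F7 = mean(H[patch$mask])))
}
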