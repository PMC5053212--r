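# Symmetric normalized gray-level co-occurrence matrix over dense-pixel
# pairs at offset (dr, dc); q is the level-quantized patch, levels in
# 1..nlev; returns NULL if no valid pair exists.
glcm <- function(q, mask, dr, dc, nlev = 32L) {
  h <- nrow(q); w <- ncol(q)
  if (abs(dr) >= h || abs(dc) >= w) return(NULL)
  r1 <- seq_len(h - abs(dr)); c1 <- seq_len(w - abs(dc))
  r2 <- r1 + abs(dr); c2 <- c1 + abs(dc)
  if (length(r1) == 0L || length(c1) == 0L) return(NULL)
  ok <- mask[r1, c1, drop = FALSE] & mask[r2, c2, drop = FALSE]
  if (!any(ok)) return(NULL)
  a <- q[r1, c1, drop = FALSE][ok]
  b <- q[r2, c2, drop = FALSE][ok]
  m <- matrix(0, nlev, nlev)
  tab <- table(factor(a, levels = seq_len(nlev)),
               factor(b, levels = seq_len(nlev)))
  m <- m + tab
  m <- m + t(m)                          # symmetrize
  m / sum(m)
}

quantize_levels <- function(x, mask, nlev = 32L) {
  vals <- x[mask]
  rng <- range(vals)
  q <- matrix(1L, nrow(x), ncol(x))
  if (rng[2] > rng[1])
    q[] <- pmin(nlev, pmax(1L, 1L + floor((x - rng[1]) / (rng[2] - rng[1]) * nlev)))
  q
}

#' Co-occurrence matrix features (F12, F41, F42)
#'
#' Dense-pixel gray levels are quantized to 32 levels; co-occurrence is
#' counted only over pixel pairs that are both inside the dense mask, then
#' symmetrized and normalized to sum 1. F12 = Shannon entropy (bits) of
#' the horizontal offset-1 matrix; F41 = energy (sum of squared entries)
#' at horizontal offset 2; F42 = energy at diagonal offset (8, 8). A
#' feature with no valid pixel pair at its offset is flagged undefined.
#'
#' @param patch a \code{\link{dense_patch}}
#' @return list with named \code{values} and \code{flags}
#' @export
cooccurrence_features <- function(patch) {
  q <- quantize_levels(patch$values, patch$mask)
  offs <- list(F12 = c(0L, 1L), F41 = c(0L, 2L), F42 = c(8L, 8L))
  vals <- c(F12 = 0, F41 = 0, F42 = 0)
  flags <- c(F12 = FALSE, F41 = FALSE, F42 = FALSE)
  for (nm in names(offs)) {
    m <- glcm(q, patch$mask, offs[[nm]][1], offs[[nm]][2])
    if (is.null(m)) { flags[nm] <- TRUE; next }
    p <- m[m > 0]
    vals[nm] <- if (nm == "F12") -sum(p * log2(p)) else sum(p^2)
  }
  feat_result(vals, flags)
}

#' Singular-value features (F24, F25)
#'
#' Singular values of the zero-filled patch matrix, normalized to sum 1.
#' F25 = largest normalized singular value (1 for a rank-1 patch); F24 =
#' population skewness of the normalized singular-value set divided by its
#' population standard deviation. With fewer than three singular values, or
#' equal singular values (zero spread), F24 is flagged undefined.
#'
#' @param patch a \code{\link{dense_patch}}
#' @return list with named \code{values} and \code{flags}
#' @export
svd_features <- function(patch) {
  s <- svd(patch$values, nu = 0, nv = 0)$d
  if (sum(s) <= 0) return(flagged(c("F24", "F25")))
  s <- s / sum(s)
  vals <- c(F24 = 0, F25 = max(s))
  flags <- c(F24 = FALSE, F25 = FALSE)
  sdev <- sqrt(central_moment(s, 2))
  sk <- pop_skewness(s)
  if (length(s) < 3L || sdev == 0 || is.na(sk)) flags["F24"] <- TRUE
  else vals["F24"] <- sk / sdev
  feat_result(vals, flags)
}
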