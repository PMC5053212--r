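#' First-order intensity-histogram features
#'
#' Statistics of the dense-pixel intensity distribution: F4 kurtosis
#' (Pearson m4/m2^2), F5 skewness (m3/m2^1.5), F6 Shannon entropy of the
#' 256-bin histogram on the normalized [0, 1] intensity scale (bits), F18
#' fourth central moment, F27 interquartile range, F37 mean, F39 median.
#' Population (m-statistic) moments throughout, no small-sample correction.
#' Zero-variance samples leave F4/F5 flagged undefined (stored as 0).
#'
#' @param patch a \code{\link{dense_patch}}
#' @return list with named \code{values} and logical \code{flags}
#' @export
histogram_features <- function(patch) {
  x <- patch$values[patch$mask]
  if (length(x) < 2L) return(flagged(c("F4", "F5", "F6", "F18", "F27", "F37", "F39")))
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  vals <- c(F4 = pop_kurtosis(x), F5 = pop_skewness(x),
            F6 = shannon_entropy_bits(x, 256L, range = c(0, 1)),
            F18 = central_moment(x, 4), F27 = q[2] - q[1],
            F37 = mean(x), F39 = stats::median(x))
  flags <- setNames(rep(FALSE, 7L), names(vals))
  if (is.na(vals[["F4"]])) { vals[c("F4", "F5")] <- 0; flags[c("F4", "F5")] <- TRUE }
  feat_result(vals, flags)
}

#' Skewness of the intensity gradient (F40)
#'
#' Gradient magnitude by central differences on the zero-filled patch; the
#' sample is restricted to interior dense pixels (all four neighbors dense),
#' so the statistic measures the internal texture of the dense tissue and is
#' not distorted by the artificial intensity step at the dense-area
#' silhouette. A high skewness reflects a dense area interspersed by fatty
#' streaks (scattered rather than consolidated dense tissue). Constant
#' gradient magnitude (e.g. a constant patch or a pure linear ramp) is
#' flagged undefined.
#'
#' @param patch a \code{\link{dense_patch}}
#' @return list with \code{values} (F40) and \code{flags}
#' @export
gradient_skewness <- function(patch) {
  v <- patch$values
  h <- nrow(v); w <- ncol(v)
  if (h < 3L || w < 3L) return(flagged("F40"))
  m <- patch$mask
  inner <- m[2:(h - 1), 2:(w - 1), drop = FALSE] &
    m[1:(h - 2), 2:(w - 1), drop = FALSE] & m[3:h, 2:(w - 1), drop = FALSE] &
    m[2:(h - 1), 1:(w - 2), drop = FALSE] & m[2:(h - 1), 3:w, drop = FALSE]
  if (!any(inner)) return(flagged("F40"))
  gx <- (v[2:(h - 1), 3:w, drop = FALSE] - v[2:(h - 1), 1:(w - 2), drop = FALSE]) / 2
  gy <- (v[3:h, 2:(w - 1), drop = FALSE] - v[1:(h - 2), 2:(w - 1), drop = FALSE]) / 2
  g <- sqrt(gx^2 + gy^2)[inner]
  s <- pop_skewness(g)
  if (is.na(s)) return(flagged("F40"))
  feat_result(c(F40 = s))
}

#' Kurtosis of the X/Y projection profiles (F33, F34)
#'
#' Dense-pixel intensities are summed along rows (projection onto the Y
#' axis, F33) and along columns (projection onto the X axis, F34); each
#' profile is treated as a sample of per-index sums and its kurtosis
#' (m4/m2^2) is returned. Constant profiles or single-row/column patches
#' are flagged.
#'
#' @param patch a \code{\link{dense_patch}}
#' @return list with \code{values} (F33, F34) and \code{flags}
#' @export
projection_features <- function(patch) {
  v <- patch$values
  vals <- c(F33 = NA_real_, F34 = NA_real_)
  flags <- c(F33 = FALSE, F34 = FALSE)
  prof <- list(F33 = rowSums(v), F34 = colSums(v))
  for (nm in names(prof)) {
    p <- prof[[nm]]
    k <- if (length(p) < 2L) NA_real_ else pop_kurtosis(p)
    if (is.na(k)) { vals[nm] <- 0; flags[nm] <- TRUE } else vals[nm] <- k
  }
  feat_result(vals, flags)
}
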