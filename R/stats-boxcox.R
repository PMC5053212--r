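#' Box-Cox transform and standardize a feature sample
#'
#' A positivity shift \code{max(0, 1 - min(x))} is applied, the Box-Cox
#' power lambda is chosen by profile maximum likelihood over [-3, 3]
#' (log transform at lambda = 0), and the transformed values are centered
#' and scaled to mean 0, SD 1, to attain near standard normal
#' distributions. The fitted shift/lambda/mean/SD are returned so the same
#' transform can be replayed on new data.
#'
#' @param x numeric sample (NAs dropped for fitting, preserved in output)
#' @param min_n minimum number of non-missing values required
#' @return list with \code{transformed} (same length as \code{x}) and
#'   \code{spec} (shift, lambda, mean, sd)
#' @export
box_cox_standardize <- function(x, min_n = 10L) {
  obs <- x[!is.na(x)]
  if (length(obs) < min_n)
    stop(sprintf("need at least %d non-missing values", min_n), call. = FALSE)
  if (stats::sd(obs) == 0)
    stop("constant sample: zero standard deviation", call. = FALSE)
  shift <- max(0, 1 - min(obs))
  y <- obs + shift
  slog <- sum(log(y))
  nobs <- length(y)
  prof <- function(lambda) {
    z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
    -nobs / 2 * log(mean((z - mean(z))^2)) + (lambda - 1) * slog
  }
  lambda <- stats::optimize(prof, c(-3, 3), maximum = TRUE)$maximum
  spec <- list(shift = shift, lambda = lambda, mean = NA_real_, sd = NA_real_)
  z <- bc_apply(obs, spec)
  spec$mean <- mean(z); spec$sd <- stats::sd(z)
  if (spec$sd == 0) stop("degenerate transform: zero SD", call. = FALSE)
  out <- rep(NA_real_, length(x))
  out[!is.na(x)] <- (z - spec$mean) / spec$sd
  list(transformed = out, spec = spec)
}

# Raw Box-Cox transform (no standardization) under a fitted spec.
bc_apply <- function(x, spec) {
  y <- x + spec$shift
  if (abs(spec$lambda) < 1e-12) log(y) else (y^spec$lambda - 1) / spec$lambda
}

#' Replay a fitted Box-Cox standardization on new data
#' @param x numeric values
#' @param spec the \code{spec} returned by \code{\link{box_cox_standardize}}
#' @return transformed and standardized values
#' @export
apply_box_cox <- function(x, spec) {
  (bc_apply(x, spec) - spec$mean) / spec$sd
}
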