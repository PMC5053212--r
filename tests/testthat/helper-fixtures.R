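# Programmatic fixtures shared across test files.

# Binary ellipse/disk mask on a (2n+1)^2 grid.
make_ellipse_mask <- function(a, b, n = max(a, b) + 5) {
  r <- matrix(seq(-n, n), 2 * n + 1, 2 * n + 1)
  cc <- t(r)
  (r / a)^2 + (cc / b)^2 <= 1
}

# Random dense patch: smooth random field thresholded to a mask, values on
# [0, 1]; guarantees a non-trivial connected dense region.
random_patch <- function(h, w, seed) {
  set.seed(seed)
  x <- matrix(runif(h * w), h, w)
  # mild smoothing so masks have structure
  x <- (x + x[c(1, 1:(h - 1)), ] + x[, c(1, 1:(w - 1))]) / 3
  mask <- x > quantile(x, 0.3)
  v <- x
  v[!mask] <- 0
  structure(list(values = v, mask = mask), class = "dense_patch")
}

# Null cohort plus three correlated synthetic feature tables (no imaging),
# used for the statistical-stage calibration tests.
make_null_battery <- function(n, seed, n_feat = 32L, signal = NULL) {
  set.seed(seed)
  ch <- data.frame(id = sprintf("w%05d", seq_len(n)),
                   outcome = "SC",
                   pd = exp(rnorm(n, log(19), 0.55)),
                   bmi = rnorm(n, 25.4, 4), age_dx = rnorm(n, 60.4, 8),
                   hrt = ifelse(rbinom(n, 1, 0.18) == 1, "yes", "no"),
                   stringsAsFactors = FALSE)
  base <- matrix(rnorm(n * n_feat), n)
  feats <- lapply(1:3, function(k) {
    m <- as.data.frame(0.7 * base + 0.3 * matrix(rnorm(n * n_feat), n))
    names(m) <- FEATURE_NAMES[seq_len(n_feat)]
    m$id <- ch$id
    m
  })
  names(feats) <- c("percentile", "entropy", "otsu")
  lp <- -1
  if (!is.null(signal))
    for (j in seq_along(signal)) lp <- lp + signal[j] * base[, j]
  ch$outcome <- ifelse(rbinom(n, 1, plogis(lp)) == 1, "IC", "SC")
  list(cohort = ch, features = feats)
}
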