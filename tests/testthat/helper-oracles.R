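# Independent naive oracles. Each deliberately uses a different code path
# from the package implementation (explicit loops, direct-summation
# transforms, flood fill, gift-wrapping hulls) so agreement is evidence of
# correctness, not of shared bugs.

# --- moments ------------------------------------------------------------
oracle_moment <- function(x, k) sum((x - sum(x) / length(x))^k) / length(x)
oracle_skew <- function(x) oracle_moment(x, 3) / oracle_moment(x, 2)^1.5
oracle_kurt <- function(x) oracle_moment(x, 4) / oracle_moment(x, 2)^2

# type-7 quantile by explicit interpolation
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  hh <- (length(s) - 1) * p + 1
  lo <- floor(hh)
  s[lo] + (hh - lo) * (s[pmin(lo + 1, length(s))] - s[lo])
}

oracle_entropy_bits <- function(x, bins = 256, rng = range(x)) {
  if (rng[2] <= rng[1]) return(0)
  cnt <- numeric(bins)
  for (v in x) {
    b <- min(bins, max(1, 1 + floor((v - rng[1]) / (rng[2] - rng[1]) * bins)))
    cnt[b] <- cnt[b] + 1
  }
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

# --- thresholds ---------------------------------------------------------
oracle_otsu <- function(counts, edges) {
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  best <- Inf; best_t <- NA
  for (t in seq_len(length(counts) - 1)) {
    c0 <- counts[1:t]; c1 <- counts[(t + 1):length(counts)]
    if (sum(c0) == 0 || sum(c1) == 0) next
    m0 <- mids[1:t]; m1 <- mids[(t + 1):length(counts)]
    mu0 <- sum(c0 * m0) / sum(c0); mu1 <- sum(c1 * m1) / sum(c1)
    v0 <- sum(c0 * (m0 - mu0)^2) / sum(c0)
    v1 <- sum(c1 * (m1 - mu1)^2) / sum(c1)
    obj <- (sum(c0) * v0 + sum(c1) * v1) / sum(counts)
    if (obj < best - 1e-15) { best <- obj; best_t <- t }
  }
  edges[best_t + 1]
}

oracle_kapur <- function(counts, edges) {
  p <- counts / sum(counts)
  ent <- function(q) { q <- q[q > 0] / sum(q); -sum(q * log(q)) }
  best <- -Inf; best_t <- NA
  for (t in seq_len(length(counts) - 1)) {
    if (sum(p[1:t]) == 0 || sum(p[-(1:t)]) == 0) next
    obj <- ent(p[1:t]) + ent(p[-(1:t)])
    if (obj > best + 1e-12) { best <- obj; best_t <- t }
  }
  edges[best_t + 1]
}

# --- gradients / projections -------------------------------------------
oracle_gradient_sample <- function(patch) {
  v <- patch$values; m <- patch$mask
  h <- nrow(v); w <- ncol(v)
  out <- c()
  for (i in 2:(h - 1)) for (j in 2:(w - 1)) {
    if (m[i, j] && m[i - 1, j] && m[i + 1, j] && m[i, j - 1] && m[i, j + 1]) {
      gx <- (v[i, j + 1] - v[i, j - 1]) / 2
      gy <- (v[i + 1, j] - v[i - 1, j]) / 2
      out <- c(out, sqrt(gx^2 + gy^2))
    }
  }
  out
}

# --- shape --------------------------------------------------------------
# flood-fill component count at the given connectivity
oracle_components <- function(mask, eight = TRUE) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (eight) expand.grid(dr = -1:1, dc = -1:1)[-5, ]
          else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  ncomp <- 0
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    ncomp <- ncomp + 1
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack) > 0) {
      px <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        i <- px[1] + offs$dr[k]; j <- px[2] + offs$dc[k]
        if (i >= 1 && i <= h && j >= 1 && j <= w && mask[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          stack[[length(stack) + 1]] <- c(i, j)
        }
      }
    }
  }
  ncomp
}

oracle_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  bg_comps <- oracle_components(!pad, eight = FALSE)
  bg_comps - 1   # one background component touches the border
}

oracle_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  per <- 0
  at <- function(i, j) i >= 1 && i <= h && j >= 1 && j <= w && mask[i, j]
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j]) next
    per <- per + sum(!at(i - 1, j), !at(i + 1, j), !at(i, j - 1), !at(i, j + 1))
  }
  per
}

# gift-wrapping convex hull area over pixel-corner points
oracle_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- unique(rbind(idx + rep(c(-0.5, -0.5), each = nrow(idx)),
                      idx + rep(c(-0.5, 0.5), each = nrow(idx)),
                      idx + rep(c(0.5, -0.5), each = nrow(idx)),
                      idx + rep(c(0.5, 0.5), each = nrow(idx))))
  start <- which.min(pts[, 2] + 1e-9 * pts[, 1])
  hull <- start; cur <- start
  repeat {
    nxt <- if (cur == 1) 2 else 1
    for (k in seq_len(nrow(pts))) {
      if (k == cur) next
      cr <- (pts[nxt, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[nxt, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      d_nxt <- sum((pts[nxt, ] - pts[cur, ])^2)
      d_k <- sum((pts[k, ] - pts[cur, ])^2)
      if (cr < -1e-12 || (abs(cr) <= 1e-12 && d_k > d_nxt)) nxt <- k
    }
    if (nxt == start) break
    hull <- c(hull, nxt); cur <- nxt
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

oracle_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  mr <- mean(idx[, 1]); mc <- mean(idx[, 2])
  srr <- mean((idx[, 1] - mr)^2); scc <- mean((idx[, 2] - mc)^2)
  src <- mean((idx[, 1] - mr) * (idx[, 2] - mc))
  tr <- srr + scc; dt <- srr * scc - src^2
  l1 <- tr / 2 + sqrt(max(0, tr^2 / 4 - dt))
  l2 <- tr / 2 - sqrt(max(0, tr^2 / 4 - dt))
  if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
}

# --- transforms ---------------------------------------------------------
# direct-summation DFT/IDFT via explicitly constructed exponential matrices
oracle_dft_mat <- function(n) {
  W <- matrix(0 + 0i, n, n)
  for (j in 1:n) for (k in 1:n)
    W[j, k] <- exp(-2i * pi * (j - 1) * (k - 1) / n)
  W
}
oracle_dft2 <- function(x) oracle_dft_mat(nrow(x)) %*% x %*% oracle_dft_mat(ncol(x))
oracle_idft2 <- function(X) {
  h <- nrow(X); w <- ncol(X)
  Conj(oracle_dft_mat(h)) %*% X %*% Conj(oracle_dft_mat(w)) / (h * w)
}

oracle_dct2 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(0, n, m)
  for (u in 0:(n - 1)) for (v in 0:(m - 1)) {
    cu <- cos(pi * (2 * (0:(n - 1)) + 1) * u / (2 * n))
    cv <- cos(pi * (2 * (0:(m - 1)) + 1) * v / (2 * m))
    au <- if (u == 0) sqrt(1 / n) else sqrt(2 / n)
    av <- if (v == 0) sqrt(1 / m) else sqrt(2 / m)
    out[u + 1, v + 1] <- au * av * sum(x * (cu %o% cv))
  }
  out
}

oracle_range_filter <- function(x) {
  h <- nrow(x); w <- ncol(x)
  out <- x
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- x[pmin(h, pmax(1, (i - 1):(i + 1))), pmin(w, pmax(1, (j - 1):(j + 1)))]
    out[i, j] <- max(win) - min(win)
  }
  out
}

oracle_hessian_det <- function(x) {
  h <- nrow(x); w <- ncol(x)
  g <- function(i, j) x[min(h, max(1, i)), min(w, max(1, j))]
  out <- x
  for (i in seq_len(h)) for (j in seq_len(w)) {
    xx <- g(i, j + 1) - 2 * g(i, j) + g(i, j - 1)
    yy <- g(i + 1, j) - 2 * g(i, j) + g(i - 1, j)
    xy <- (g(i + 1, j + 1) + g(i - 1, j - 1) - g(i + 1, j - 1) - g(i - 1, j + 1)) / 4
    out[i, j] <- xx * yy - xy^2
  }
  out
}

# periodic Daubechies-4 approximation band by direct convolution loops
oracle_dwt2_approx <- function(x, levels = 3) {
  hcoef <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
  step1 <- function(s) {
    n <- length(s)
    out <- numeric(n / 2)
    for (k in seq_len(n / 2)) {
      acc <- 0
      for (m in 1:4) acc <- acc + hcoef[m] * s[(2 * (k - 1) + m - 1) %% n + 1]
      out[k] <- acc
    }
    out
  }
  blk <- 2^levels
  h <- ceiling(nrow(x) / blk) * blk; w <- ceiling(ncol(x) / blk) * blk
  a <- matrix(0, h, w); a[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  for (l in seq_len(levels)) {
    tmp <- apply(a, 2, step1)          # columns
    a <- t(apply(t(tmp), 2, step1))    # then rows
  }
  a
}

oracle_local_entropy <- function(x, radius = 4, bins = 256) {
  h <- nrow(x); w <- ncol(x)
  rng <- range(x)
  q <- matrix(1, h, w)
  if (rng[2] > rng[1])
    for (i in seq_len(h)) for (j in seq_len(w))
      q[i, j] <- min(bins, max(1, 1 + floor((x[i, j] - rng[1]) /
                                              (rng[2] - rng[1]) * bins)))
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- q[max(1, i - radius):min(h, i + radius),
             max(1, j - radius):min(w, j + radius)]
    p <- table(win) / length(win)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

oracle_glcm <- function(q, mask, dr, dc, nlev = 32) {
  cnt <- matrix(0, nlev, nlev)
  h <- nrow(q); w <- ncol(q)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 >= 1 && i2 <= h && j2 >= 1 && j2 <= w && mask[i, j] && mask[i2, j2])
      cnt[q[i, j], q[i2, j2]] <- cnt[q[i, j], q[i2, j2]] + 1
  }
  if (sum(cnt) == 0) return(NULL)
  cnt <- cnt + t(cnt)
  cnt / sum(cnt)
}

# singular values as the positive eigenvalues of the symmetric augmented
# matrix [[0, X], [X', 0]] (linear, not squared, conditioning)
oracle_singular_values <- function(x) {
  n <- nrow(x); m <- ncol(x)
  A <- rbind(cbind(matrix(0, n, n), x), cbind(t(x), matrix(0, m, m)))
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  s <- sort(abs(ev), decreasing = TRUE)
  s[seq(1, 2 * min(n, m), by = 2)]
}

# log-Gabor pooled response via direct-summation transforms
oracle_log_gabor_response <- function(x, f0 = c(1 / 6, 1 / 12),
                                      thetas = pi * (0:3) / 4,
                                      sigma_ratio = 0.65, sigma_theta = 0.6) {
  h <- nrow(x); w <- ncol(x)
  X <- oracle_dft2(x)
  acc <- matrix(0 + 0i, h, w)
  for (f00 in f0) for (th in thetas) {
    G <- matrix(0, h, w)
    for (a in seq_len(h)) for (b in seq_len(w)) {
      fy <- (a - 1) / h; if (fy > 0.5) fy <- fy - 1
      fx <- (b - 1) / w; if (fx > 0.5) fx <- fx - 1
      fr <- sqrt(fx^2 + fy^2)
      if (fr > 0) {
        dth <- atan2(sin(atan2(fy, fx) - th), cos(atan2(fy, fx) - th))
        G[a, b] <- exp(-(log(fr / f00))^2 / (2 * log(sigma_ratio)^2)) *
          exp(-dth^2 / (2 * sigma_theta^2))
      }
    }
    acc <- acc + oracle_idft2(X * G)
  }
  acc / (length(f0) * length(thetas))
}
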