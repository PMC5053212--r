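const_patch <- function(c = 0.5, n = 12) {
  structure(list(values = matrix(c, n, n), mask = matrix(TRUE, n, n)),
            class = "dense_patch")
}

test_that("histogram features on degenerate and symmetric samples", {
  p <- const_patch(0.4)
  r <- histogram_features(p)
  expect_equal(unname(r$values[c("F37", "F39")]), c(0.4, 0.4))
  expect_equal(unname(r$values[c("F27", "F6")]), c(0, 0))
  expect_true(all(r$flags[c("F4", "F5")]))
  # symmetric two-point sample has zero skewness
  v <- matrix(rep(c(0.2, 0.8), each = 32), 8, 8)
  p2 <- structure(list(values = v, mask = matrix(TRUE, 8, 8)),
                  class = "dense_patch")
  expect_equal(unname(histogram_features(p2)$values[["F5"]]), 0, tolerance = 1e-12)
})

test_that("gradient skewness flags constant and pure-ramp patches", {
  expect_true(gradient_skewness(const_patch())$flags[["F40"]])
  ramp <- structure(list(values = outer(1:12, 1:12, function(i, j) j / 24),
                         mask = matrix(TRUE, 12, 12)), class = "dense_patch")
  r <- gradient_skewness(ramp)
  expect_true(r$flags[["F40"]])
  expect_equal(unname(r$values[["F40"]]), 0)
})

test_that("projection kurtosis is transpose-symmetric and flags constants", {
  r <- projection_features(const_patch())
  expect_true(all(r$flags))
  set.seed(3)
  v <- matrix(runif(144), 12, 12); v <- (v + t(v)) / 2
  p <- structure(list(values = v, mask = matrix(TRUE, 12, 12)),
                 class = "dense_patch")
  r2 <- projection_features(p)
  expect_equal(r2$values[["F33"]], r2$values[["F34"]])
})

test_that("shape features are exact on analytic regions", {
  disk <- make_ellipse_mask(50, 50)
  r <- shape_features(disk)
  expect_equal(unname(r$values[c("F19", "F22", "F26")]), c(1, 1, 0))
  expect_gte(r$values[["F20"]], 0.95)
  expect_lte(r$values[["F21"]], 0.15)

  ell <- make_ellipse_mask(80, 40)
  expect_equal(shape_features(ell)$values[["F21"]], sqrt(1 - 0.25),
               tolerance = 0.02)

  holed <- make_ellipse_mask(30, 30)
  holed[28:36, 28:36] <- FALSE   # interior hole
  rh <- shape_features(holed)
  expect_equal(unname(rh$values[c("F19", "F22", "F26")]), c(1, 0, 1))
})

test_that("shape features match flood-fill/gift-wrapping oracles on random masks", {
  for (s in 1:6) {
    p <- random_patch(24, 20, seed = 100 + s)
    m <- p$mask
    r <- shape_features(m)
    expect_equal(unname(r$values[["F19"]]), oracle_components(m, eight = TRUE))
    expect_equal(unname(r$values[["F26"]]), oracle_holes(m))
    expect_equal(unname(r$values[["F22"]]),
                 oracle_components(m, eight = TRUE) - oracle_holes(m))
    expect_equal(unname(r$values[["F35"]]), oracle_perimeter(m))
    expect_equal(unname(r$values[["F20"]]), sum(m) / oracle_hull_area(m),
                 tolerance = 1e-10)
    expect_equal(unname(r$values[["F21"]]), oracle_eccentricity(m),
                 tolerance = 1e-10)
  }
})

test_that("transform features obey their closed-form identities", {
  p <- const_patch(0.3, 16)
  r <- transform_features(p)
  expect_equal(unname(r$values[["F1"]]), 0.3 * sqrt(16 * 16), tolerance = 1e-10)
  expect_equal(unname(r$values[["F11"]]), 0, tolerance = 1e-9)
  set.seed(5)
  for (s in 1:5) {
    pr <- random_patch(16, 16, seed = 200 + s)
    rr <- transform_features(pr)
    expect_equal(unname(rr$values[["F17"]]), log1p(rr$values[["F11"]]),
                 tolerance = 1e-10)
  }
})

test_that("co-occurrence features on a constant patch collapse to one cell", {
  r <- cooccurrence_features(const_patch(0.6, 16))
  expect_equal(unname(r$values[c("F12", "F41", "F42")]), c(0, 1, 1))
  set.seed(8)
  pr <- random_patch(30, 30, seed = 300)
  rr <- cooccurrence_features(pr)
  expect_gt(rr$values[["F41"]], 0); expect_lte(rr$values[["F41"]], 1)
  expect_gt(rr$values[["F42"]], 0); expect_lte(rr$values[["F42"]], 1)
  expect_gte(rr$values[["F12"]], 0)
  # no valid pairs at the (8, 8) offset on a tiny patch
  small <- structure(list(values = matrix(runif(25), 5, 5),
                          mask = matrix(TRUE, 5, 5)), class = "dense_patch")
  expect_true(cooccurrence_features(small)$flags[["F42"]])
})

test_that("SVD features recognize rank-1 and equal-spectrum patches", {
  u <- runif(12); v <- runif(10)
  rank1 <- structure(list(values = outer(u, v), mask = matrix(TRUE, 12, 10)),
                     class = "dense_patch")
  r <- svd_features(rank1)
  expect_equal(unname(r$values[["F25"]]), 1, tolerance = 1e-10)
  eye <- structure(list(values = diag(6) * 0.7, mask = diag(6) > 0),
                   class = "dense_patch")
  re <- svd_features(eye)
  expect_true(re$flags[["F24"]])
  expect_equal(unname(re$values[["F25"]]), 1 / 6, tolerance = 1e-12)
})

test_that("log-Gabor entropies vanish on constants and grow with noise", {
  r <- gabor_entropy_features(const_patch(0.5, 24))
  expect_equal(unname(r$values), c(0, 0, 0), tolerance = 1e-9)
  set.seed(11)
  bigger <- vapply(1:5, function(s) {
    p <- structure(list(values = matrix(runif(24 * 24), 24, 24),
                        mask = matrix(TRUE, 24, 24)), class = "dense_patch")
    gabor_entropy_features(p)$values[["F10"]]
  }, numeric(1))
  expect_true(all(bigger > 1))
})

test_that("entropy filter: constants give 0, checkerboards approach 1 bit", {
  expect_equal(unname(entropy_filter_feature(const_patch())$values[["F7"]]), 0)
  n <- 41
  cb <- outer(1:n, 1:n, function(i, j) (i + j) %% 2) * 0.5 + 0.25
  p <- structure(list(values = cb, mask = matrix(TRUE, n, n)),
                 class = "dense_patch")
  f7 <- entropy_filter_feature(p)$values[["F7"]]
  expect_gt(f7, 0.95); expect_lte(f7, 1)
})

test_that("every feature matches its independent naive oracle on random patches", {
  for (s in 1:4) {
    p <- random_patch(18, 16, seed = 400 + s)
    x <- p$values[p$mask]

    hf <- histogram_features(p)$values
    expect_equal(unname(hf[["F4"]]), oracle_kurt(x), tolerance = 1e-8)
    expect_equal(unname(hf[["F5"]]), oracle_skew(x), tolerance = 1e-8)
    expect_equal(unname(hf[["F6"]]), oracle_entropy_bits(x, rng = c(0, 1)),
                 tolerance = 1e-8)
    expect_equal(unname(hf[["F18"]]), oracle_moment(x, 4), tolerance = 1e-12)
    expect_equal(unname(hf[["F27"]]),
                 oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25),
                 tolerance = 1e-10)

    g <- oracle_gradient_sample(p)
    expect_equal(unname(gradient_skewness(p)$values[["F40"]]),
                 oracle_skew(g), tolerance = 1e-8)

    pj <- projection_features(p)$values
    expect_equal(unname(pj[["F33"]]), oracle_kurt(rowSums(p$values)),
                 tolerance = 1e-8)
    expect_equal(unname(pj[["F34"]]), oracle_kurt(colSums(p$values)),
                 tolerance = 1e-8)

    tf <- transform_features(p)$values
    D <- oracle_dct2(p$values)
    FT <- Mod(oracle_dft2(p$values))
    FT_nodc <- FT; FT_nodc[1, 1] <- 0
    expect_equal(unname(tf[["F1"]]), D[1, 1], tolerance = 1e-6)
    expect_equal(unname(tf[["F2"]]), mean(oracle_dwt2_approx(p$values)),
                 tolerance = 1e-8)
    expect_equal(unname(tf[["F3"]]),
                 max(Mod(oracle_dft2(oracle_range_filter(p$values)))),
                 tolerance = 1e-6)
    expect_equal(unname(tf[["F11"]]), max(FT_nodc), tolerance = 1e-6)
    expect_equal(unname(tf[["F14"]]),
                 max(Mod(oracle_dft2(oracle_hessian_det(p$values)))),
                 tolerance = 1e-6)
    expect_equal(unname(tf[["F16"]]), max(log1p(abs(D))), tolerance = 1e-6)
    expect_equal(unname(tf[["F17"]]), max(log1p(FT_nodc)), tolerance = 1e-6)

    ef <- entropy_filter_feature(p)$values
    expect_equal(unname(ef[["F7"]]),
                 mean(oracle_local_entropy(p$values)[p$mask]),
                 tolerance = 1e-8)

    gb <- gabor_entropy_features(p)$values
    resp <- oracle_log_gabor_response(p$values)
    expect_equal(unname(gb[["F8"]]),
                 oracle_entropy_bits(Im(resp)[p$mask]), tolerance = 1e-5)
    expect_equal(unname(gb[["F9"]]),
                 oracle_entropy_bits(Re(resp)[p$mask]), tolerance = 1e-5)
    expect_equal(unname(gb[["F10"]]),
                 oracle_entropy_bits(Mod(resp)[p$mask]), tolerance = 1e-5)

    co <- cooccurrence_features(p)$values
    q <- mammodense:::quantize_levels(p$values, p$mask)
    m01 <- oracle_glcm(q, p$mask, 0, 1)
    m02 <- oracle_glcm(q, p$mask, 0, 2)
    m88 <- oracle_glcm(q, p$mask, 8, 8)
    pnz <- m01[m01 > 0]
    expect_equal(unname(co[["F12"]]), -sum(pnz * log2(pnz)), tolerance = 1e-10)
    expect_equal(unname(co[["F41"]]), sum(m02^2), tolerance = 1e-10)
    expect_equal(unname(co[["F42"]]), sum(m88^2), tolerance = 1e-10)

    sv <- svd_features(p)$values
    s_orc <- oracle_singular_values(p$values)
    s_orc <- s_orc / sum(s_orc)
    expect_equal(unname(sv[["F25"]]), max(s_orc), tolerance = 1e-8)
    expect_equal(unname(sv[["F24"]]),
                 oracle_skew(s_orc) / sqrt(oracle_moment(s_orc, 2)),
                 tolerance = 1e-6)
  }
})

test_that("intensity shift moves location features and leaves shape statistics alone", {
  p <- random_patch(20, 20, seed = 55)
  shifted <- p
  shifted$values[shifted$mask] <- shifted$values[shifted$mask] + 0.1
  a <- histogram_features(p)$values; b <- histogram_features(shifted)$values
  expect_equal(b[["F4"]], a[["F4"]], tolerance = 1e-10)
  expect_equal(b[["F5"]], a[["F5"]], tolerance = 1e-10)
  expect_equal(b[["F27"]], a[["F27"]], tolerance = 1e-10)
  expect_equal(b[["F37"]], a[["F37"]] + 0.1, tolerance = 1e-10)
  expect_equal(b[["F39"]], a[["F39"]] + 0.1, tolerance = 1e-10)
  ga <- gradient_skewness(p)$values[["F40"]]
  gb <- gradient_skewness(shifted)$values[["F40"]]
  expect_equal(gb, ga, tolerance = 1e-10)
})

test_that("mirror-invariant features are unchanged under horizontal flips", {
  p <- random_patch(22, 18, seed = 77)
  fl <- structure(list(values = p$values[, rev(seq_len(ncol(p$values)))],
                       mask = p$mask[, rev(seq_len(ncol(p$mask)))]),
                  class = "dense_patch")
  inv <- c("F4", "F5", "F6", "F18", "F27", "F37", "F39")
  expect_equal(histogram_features(p)$values[inv],
               histogram_features(fl)$values[inv], tolerance = 1e-10)
  expect_equal(shape_features(p$mask)$values, shape_features(fl$mask)$values,
               tolerance = 1e-10)
  expect_equal(gradient_skewness(p)$values, gradient_skewness(fl)$values,
               tolerance = 1e-10)
  expect_equal(projection_features(p)$values[["F33"]],
               projection_features(fl)$values[["F33"]], tolerance = 1e-10)
  # symmetrized co-occurrence at horizontal offsets is flip-invariant
  a <- cooccurrence_features(p)$values; b <- cooccurrence_features(fl)$values
  expect_equal(a[["F12"]], b[["F12"]], tolerance = 1e-10)
  expect_equal(a[["F41"]], b[["F41"]], tolerance = 1e-10)
  expect_equal(svd_features(p)$values, svd_features(fl)$values,
               tolerance = 1e-8)
})

test_that("extract_features assembles a complete deterministic vector", {
  sim <- generate_breast_image(image_sim_params(seed = 33))
  pre <- preprocess_image(sim$image)
  dm <- dense_mask(pre$image, pre$mask, "otsu")
  f1 <- extract_features(pre$image, dm)
  f2 <- extract_features(pre$image, dm)
  expect_identical(as.numeric(f1), as.numeric(f2))
  expect_length(as.numeric(f1), 32)
  expect_named(unclass(f1)[seq_along(FEATURE_NAMES)], FEATURE_NAMES)
  expect_true(all(is.finite(as.numeric(f1))))
  expect_false(any(attr(f1, "flags")))
  sub <- extract_features(pre$image, dm, features = c("F40", "F21"))
  expect_equal(as.numeric(sub), as.numeric(f1[c("F40", "F21")]))
})
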