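test_that("Box-Cox recovers known transformation powers and standardizes exactly", {
  set.seed(10)
  x <- rlnorm(5000, meanlog = 3, sdlog = 0.5)   # log-normal: lambda near 0
  r <- box_cox_standardize(x)
  expect_gte(r$spec$lambda, -0.15); expect_lte(r$spec$lambda, 0.15)
  expect_lt(abs(mean(r$transformed)), 1e-10)
  expect_lt(abs(sd(r$transformed) - 1), 1e-10)

  y <- rnorm(5000, 20, 2)                       # already normal: lambda near 1
  ry <- box_cox_standardize(y)
  expect_gte(ry$spec$lambda, 0.7); expect_lte(ry$spec$lambda, 1.3)

  expect_error(box_cox_standardize(rep(3, 50)), "constant")
  expect_error(box_cox_standardize(rnorm(5)), "at least 10")
  # replay reproduces the fit
  expect_equal(apply_box_cox(x, r$spec), r$transformed, tolerance = 1e-12)
  # NAs pass through
  xna <- c(x[1:100], NA)
  expect_true(is.na(box_cox_standardize(xna)$transformed[101]))
})

test_that("the lean IRLS matches stats::glm coefficients, SEs and Wald p", {
  set.seed(2)
  for (i in 1:5) {
    n <- 400
    X <- cbind(1, rnorm(n), rexp(n))
    y <- rbinom(n, 1, plogis(-0.5 + 0.6 * X[, 2] - 0.2 * X[, 3]))
    fit <- mammodense:::logit_wald(y, X)
    g <- glm(y ~ X[, -1], family = binomial())
    expect_equal(fit$coef, unname(coef(g)), tolerance = 1e-6)
    expect_equal(fit$se, unname(summary(g)$coefficients[, 2]), tolerance = 1e-4)
    expect_false(fit$flagged)
  }
})

test_that("batched per-feature fits agree with one-at-a-time fits", {
  d <- make_null_battery(300, seed = 31)
  prep <- mammodense:::prepare_test_models(d$cohort, d$features)
  groups <- mammodense:::group_test_models(prep$models)
  expect_length(groups, 1)  # no missingness: one shared row set
  g <- groups[[1]]
  p_batch <- mammodense:::batch_feature_wald_p(prep$y[g$idx], g$F, g$pd)
  p_single <- vapply(seq_len(ncol(g$F)), function(j) {
    fit <- mammodense:::logit_wald(prep$y[g$idx], cbind(1, g$F[, j], g$pd))
    mammodense:::wald_p(fit, 2)
  }, numeric(1))
  expect_equal(unname(p_batch), p_single, tolerance = 1e-6)
})

test_that("the test battery is shaped like the 3 x 32 grid and flags constants", {
  d <- make_null_battery(300, seed = 7)
  d$features$otsu$F1 <- 1   # constant feature must flag, not crash
  tests <- per_feature_tests(d$cohort, d$features)
  expect_equal(nrow(tests), 96)
  expect_setequal(unique(tests$method), c("percentile", "entropy", "otsu"))
  row <- tests[tests$method == "otsu" & tests$term == "F1", ]
  expect_true(row$flagged); expect_true(is.na(row$p))
})

test_that("percent-density adjustment absorbs PD-driven outcome differences", {
  set.seed(12)
  n <- 4000
  pd <- exp(rnorm(n, log(19), 0.55))
  y <- rbinom(n, 1, plogis(-1 + 0.06 * (pd - 19)))   # outcome driven by PD only
  ch <- data.frame(id = sprintf("w%d", 1:n),
                   outcome = ifelse(y == 1, "IC", "SC"), pd = pd)
  # feature = PD signal + noise: conditional on PD it carries nothing
  zpd <- scale(pd)[, 1]
  f <- data.frame(F1 = zpd + rnorm(n, 0, 0.4), id = ch$id)
  tests <- per_feature_tests(ch, list(otsu = f))
  expect_lt(abs(tests$estimate[1]), 0.2)
  # the same feature unadjusted would show a strong marginal effect
  marg <- glm(y ~ scale(f$F1), family = binomial())
  expect_gt(abs(coef(marg)[2]), 0.5)
})

test_that("Wald and likelihood-ratio p-values agree in rank across simulations", {
  set.seed(3)
  pw <- plr <- numeric(50)
  for (i in 1:50) {
    n <- 500
    x <- rnorm(n); pd <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + runif(1, -0.4, 0.4) * x))
    g1 <- glm(y ~ x + pd, family = binomial())
    g0 <- glm(y ~ pd, family = binomial())
    pw[i] <- summary(g1)$coefficients["x", 4]
    plr[i] <- pchisq(deviance(g0) - deviance(g1), 1, lower.tail = FALSE)
  }
  expect_gt(cor(rank(pw), rank(plr)), 0.99)
})

test_that("the permutation test is deterministic, consistent and seed-stable", {
  d <- make_null_battery(250, seed = 17)
  tests <- per_feature_tests(d$cohort, d$features)
  g1 <- global_permutation_test(d$cohort, d$features, n_perm = 60, seed = 5)
  g2 <- global_permutation_test(d$cohort, d$features, n_perm = 60, seed = 5)
  expect_identical(g1$perm_stats, g2$perm_stats)
  expect_equal(g1$observed, sum(tests$p < 0.05, na.rm = TRUE))
  ga <- global_permutation_test(d$cohort, d$features, n_perm = 200, seed = 1)
  gb <- global_permutation_test(d$cohort, d$features, n_perm = 200, seed = 2)
  tol <- 3 * sqrt(max(ga$p, 0.02) * (1 - max(ga$p, 0.02)) / 200)
  expect_lt(abs(ga$p - gb$p), max(tol, 0.15))
  expect_error(global_permutation_test(d$cohort, d$features, n_perm = 0),
               "n_perm")
})

test_that("a maximal observed statistic cannot be exceeded by any permutation", {
  d <- make_null_battery(400, seed = 23, n_feat = 2,
                         signal = c(3, 3))
  g <- global_permutation_test(d$cohort, d$features, n_perm = 40, seed = 9)
  if (g$observed == 6) expect_equal(g$p, 0)
  expect_true(all(g$perm_stats <= g$n_tests))
})

test_that("forward selection returns the base model without candidates and drops duplicates", {
  ch <- generate_cohort(cohort_sim_params(n = 800, seed = 41))
  empty <- data.frame(id = ch$id)
  sel0 <- forward_select(ch, empty, candidates = character(0))
  expect_length(sel0$selected, 0)

  set.seed(5)
  f <- data.frame(id = ch$id, F1 = ch$f40 + rnorm(800, 0, 0.1))
  f$F2 <- f$F1                       # exact duplicate column
  sel <- forward_select(ch, f)
  expect_lte(sum(c("F1", "F2") %in% sel$selected), 1)
})

test_that("forward selection finds a genuinely associated feature", {
  hits <- 0
  for (s in 1:10) {
    ch <- generate_cohort(cohort_sim_params(
      n = 1500, beta_f40 = log(1.5), beta_f21 = 0, seed = 300 + s,
      missing_rates = c(bmi = 0)))
    f <- data.frame(id = ch$id, F1 = rnorm(1500), F40 = ch$f40,
                    F41 = rnorm(1500))
    sel <- forward_select(ch, f)
    if ("F40" %in% sel$selected) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the final model output is shaped like an odds-ratio table", {
  ch <- generate_cohort(cohort_sim_params(n = 1200, seed = 13))
  res <- fit_final_model(ch, ch[, c("id", "f40", "f21")],
                         features = c("f40", "f21"))
  expect_setequal(res$term, c("pd", "bmi", "hrt", "age", "f40", "f21"))
  expect_true(all(res$ci_lower < res$effect & res$effect < res$ci_upper))
  expect_true(all(res$p >= 0 & res$p <= 1))
  res_t <- fit_final_model(ch, ch[, c("id", "f40", "f21")],
                           features = c("f40", "f21"), include_time = TRUE)
  expect_true("months_to_dx" %in% res_t$term)
})

test_that("tumor-size models validate input and recover a null", {
  ch <- generate_cohort(cohort_sim_params(n = 1500, gamma_sc_f40 = 0,
                                          seed = 19))
  r <- tumor_size_regression(ch, ch[, c("id", "f40")], "f40", "SC")
  expect_true(r$ci_lower < 0 && r$ci_upper > 0)
  bad <- ch; bad$tumor_size[3] <- 0; bad$outcome[3] <- "SC"
  bad$tumor_size[is.na(bad$tumor_size)] <- 10
  expect_error(tumor_size_regression(bad, bad[, c("id", "f40")], "f40", "SC"),
               "non-positive tumor size")
  expect_error(tumor_size_regression(ch[ch$outcome == "SC", ],
                                     ch[ch$outcome == "SC", c("id", "f40")],
                                     "f40", "IC"), "empty stratum")
})

test_that("feature-risk-factor models detect identity and reject degenerate factors", {
  ch <- generate_cohort(cohort_sim_params(n = 800, seed = 29,
                                          missing_rates = c(bmi = 0)))
  f <- data.frame(id = ch$id, F1 = ch$bmi)
  r <- feature_risk_factor_models(ch, f, "F1", "bmi")
  # slope of standardized feature on its own source: 1 SD per SD
  expect_equal(r$effect * sd(ch$bmi), 1, tolerance = 0.05)
  ch2 <- ch; ch2$bmi <- 25
  expect_error(feature_risk_factor_models(ch2, f, "F1", "bmi"),
               "constant risk factor")
  f2 <- data.frame(id = ch$id, F1 = rnorm(800))
  r2 <- feature_risk_factor_models(ch, f2, "F1", "bmi")
  expect_true(r2$ci_lower < 0 && r2$ci_upper > 0)
})

test_that("the cohort summary reproduces printed counts and percentages", {
  # reconstruct the categorical rows of a characteristics table from counts
  counts <- list(hrt = c(ic_yes = 93, ic_no = 280, sc_yes = 156, sc_no = 802),
                 family_history = c(84, 284, 162, 762))
  expand <- function(cnt) {
    data.frame(outcome = rep(c("IC", "IC", "SC", "SC"), cnt),
               value = rep(c("yes", "no", "yes", "no"), cnt),
               stringsAsFactors = FALSE)
  }
  hrt <- expand(counts$hrt)
  ch <- data.frame(outcome = hrt$outcome, hrt = hrt$value)
  s <- cohort_summary(ch, data.frame(variable = "hrt", type = "categorical"))
  expect_equal(s$ic_pct[s$level == "yes"], 25)
  expect_equal(s$sc_pct[s$level == "yes"], 16)
  expect_lt(s$p[1], 0.001)

  fh <- expand(counts$family_history)
  ch2 <- data.frame(outcome = fh$outcome, family_history = fh$value)
  s2 <- cohort_summary(ch2, data.frame(variable = "family_history",
                                       type = "categorical"))
  expect_equal(s2$ic_pct[s2$level == "yes"], 23)
  expect_equal(s2$sc_pct[s2$level == "yes"], 18)
})

test_that("the cohort summary handles continuous rows and fails on empty groups", {
  ch <- generate_cohort(cohort_sim_params(n = 600, seed = 37))
  s <- cohort_summary(ch)
  expect_true(all(c("age_dx", "pd", "hrt", "tumor_size") %in% s$variable))
  expect_true(all(s$p >= 0 & s$p <= 1, na.rm = TRUE))
  bad <- ch
  bad$bmi[bad$outcome == "IC"] <- NA
  expect_error(cohort_summary(bad), "entirely missing")
})
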