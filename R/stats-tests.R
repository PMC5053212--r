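# Align a feature table to the cohort rows (by id when both carry ids,
# otherwise positionally), returning the numeric feature columns with
# flagged values set to NA.
align_features <- function(cohort, feats) {
  if ("id" %in% names(feats) && "id" %in% names(cohort)) {
    feats <- feats[match(cohort$id, feats$id), , drop = FALSE]
  } else if (nrow(feats) != nrow(cohort)) {
    stop("feature table rows do not match the cohort", call. = FALSE)
  }
  keep <- setdiff(names(feats)[vapply(feats, is.numeric, logical(1))],
                  c("id", "method", grep("_flag$", names(feats), value = TRUE)))
  keep <- c(intersect(FEATURE_NAMES, keep), setdiff(keep, FEATURE_NAMES))
  out <- feats[, keep, drop = FALSE]
  for (nm in keep) {
    fl <- feats[[paste0(nm, "_flag")]]
    if (!is.null(fl)) out[[nm]][as.logical(fl)] <- NA
  }
  out
}

# Precompute the design matrix of every (method, feature) model:
# outcome ~ Box-Cox-standardized feature + PD, complete cases per model.
prepare_test_models <- function(cohort, feature_tables) {
  y_all <- as.integer(cohort$outcome == "IC")
  models <- list()
  for (method in names(feature_tables)) {
    fx <- align_features(cohort, feature_tables[[method]])
    for (feat in names(fx)) {
      vals <- fx[[feat]]
      idx <- which(!is.na(vals) & !is.na(cohort$pd) & !is.na(cohort$outcome))
      entry <- list(method = method, feature = feat, idx = idx,
                    X = NULL, n = length(idx))
      if (length(idx) >= 10 && stats::sd(vals[idx]) > 0) {
        z <- box_cox_standardize(vals[idx])$transformed
        entry$X <- cbind(1, z, cohort$pd[idx])
      }
      models[[paste(method, feat, sep = ".")]] <- entry
    }
  }
  list(models = models, y = y_all)
}

#' Percent-density-adjusted per-feature association tests
#'
#' For every thresholding method and feature, fits the logistic model
#' IC-vs-SC status ~ Box-Cox-standardized feature + continuous percent
#' density on the model's complete cases, and reports the two-sided Wald
#' p-value for the feature term. With three methods and 32 features this
#' is the 3 x 32 test battery. Models that do not converge, separate, or
#' have a constant/undersized feature sample are flagged with missing p
#' and are excluded from the global statistic.
#'
#' @param cohort cohort data.frame with columns \code{outcome} ("IC"/"SC")
#'   and \code{pd}
#' @param feature_tables named list (one entry per thresholding method) of
#'   feature tables as produced by \code{\link{feature_table}}, or any
#'   data.frame with feature columns
#' @return data.frame with one row per (method, feature): per-SD estimate,
#'   SE, OR with 95% CI, p, n and a \code{flagged} column
#' @export
per_feature_tests <- function(cohort, feature_tables) {
  prep <- prepare_test_models(cohort, feature_tables)
  rows <- lapply(prep$models, function(m) {
    if (is.null(m$X)) {
      fit <- NULL
    } else {
      fit <- logit_wald(prep$y[m$idx], m$X)
    }
    if (is.null(fit) || fit$flagged) {
      out <- data.frame(term = m$feature, estimate = NA_real_, se = NA_real_,
                        effect = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_, n = m$n,
                        stringsAsFactors = FALSE)
    } else {
      out <- association_row(m$feature, fit$coef[2], fit$se[2], m$n)
    }
    out$method <- m$method
    out$flagged <- is.null(fit) || fit$flagged
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("method", "term", "estimate", "se", "effect", "ci_lower",
          "ci_upper", "p", "n", "flagged")]
}

# Batched IRLS for k logistic models over the same rows, model j:
# y ~ 1 + F[, j] + pd (the models share the intercept and pd columns, so
# only per-model sufficient statistics are needed). Compiled hot loop of
# the permutation test; returns the two-sided Wald p-value of each feature
# coefficient, NA where a model failed to converge or (quasi-)separated.
# Agreement with the one-model-at-a-time fits is covered by unit tests.
batch_feature_wald_p <- function(y, F, pd, maxit = 25L, tol = 1e-8) {
  p <- cpp_batch_feature_wald(as.numeric(y), F, as.numeric(pd),
                              maxit = maxit, tol = tol)
  names(p) <- colnames(F)
  p
}

# Group the prepared models by shared complete-case row sets so the batch
# fitter can run each group in one pass.
group_test_models <- function(models) {
  models <- Filter(function(m) !is.null(m$X), models)
  keys <- vapply(models, function(m) paste(m$idx, collapse = ","), character(1))
  lapply(split(models, keys), function(grp) {
    list(idx = grp[[1]]$idx,
         F = do.call(cbind, lapply(grp, function(m) m$X[, 2])),
         pd = grp[[1]]$X[, 3])
  })
}

#' Global permutation test over the whole test battery
#'
#' The global statistic is the number of the per-feature Wald tests
#' significant at level \code{alpha}. Its null distribution is obtained by
#' permuting IC-vs-SC labels over the women (covariates and features stay
#' attached to the woman; only the labels shuffle, so feature correlation
#' is respected) and the empirical p-value is the fraction of permuted
#' statistics strictly larger than the observed one (an add-one corrected
#' variant is available). Features are Box-Cox standardized once, before
#' permuting: under the null the labels are exchangeable given the fixed
#' features. Non-converged models are excluded from the statistic, with
#' their count reported.
#'
#' @inheritParams per_feature_tests
#' @param n_perm number of label permutations (>= 1)
#' @param alpha per-test significance level for the counting statistic
#' @param seed seed for the permutation stream
#' @param add_one if TRUE use (b + 1) / (n_perm + 1) instead of the plain
#'   fraction
#' @return list of class \code{global_test_result}: observed statistic,
#'   permuted statistics, empirical p, number of tests, number excluded,
#'   n_perm, alpha, seed
#' @export
global_permutation_test <- function(cohort, feature_tables, n_perm = 10000L,
                                    alpha = 0.05, seed = 1L,
                                    add_one = FALSE) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  prep <- prepare_test_models(cohort, feature_tables)
  n_tests <- length(prep$models)
  n_fit <- length(Filter(function(m) !is.null(m$X), prep$models))
  groups <- group_test_models(prep$models)
  stat_of <- function(y) {
    sig <- 0L
    for (g in groups) {
      p <- batch_feature_wald_p(y[g$idx], g$F, g$pd)
      sig <- sig + sum(!is.na(p) & p < alpha)
    }
    sig
  }
  obs <- stat_of(prep$y)
  perm_stats <- integer(n_perm)
  with_local_seed(seed, {
    n <- length(prep$y)
    for (b in seq_len(n_perm)) {
      yp <- prep$y[sample.int(n)]
      perm_stats[b] <- stat_of(yp)
    }
  })
  p_emp <- if (add_one) (sum(perm_stats > obs) + 1) / (n_perm + 1)
           else mean(perm_stats > obs)
  structure(list(observed = obs, perm_stats = perm_stats, p = p_emp,
                 n_tests = n_tests, n_excluded = n_tests - n_fit,
                 n_perm = n_perm, alpha = alpha, seed = seed),
            class = "global_test_result")
}

#' @export
print.global_test_result <- function(x, ...) {
  cat(sprintf(
    "Global permutation test: %d of %d tests significant at %.2f (%d excluded)\n",
    x$observed, x$n_tests - x$n_excluded, x$alpha, x$n_excluded))
  cat(sprintf("empirical p = %.4g (%d permutations, seed %d)\n",
              x$p, x$n_perm, x$seed))
  invisible(x)
}
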