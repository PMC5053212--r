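# Lean logistic regression by iteratively reweighted least squares,
# returning Wald statistics. Used in the per-feature test battery and the
# permutation test, where stats::glm overhead dominates at 96 models x
# thousands of permutations. Agreement with stats::glm is covered by unit
# tests.
#
# y: 0/1 response; X: design matrix including the intercept column.
# Returns list(coef, se, converged, flagged); `flagged` marks
# non-convergence or (quasi-)separation, whose Wald p is meaningless.
logit_wald <- function(y, X, maxit = 25L, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(max(1e-6, min(1 - 1e-6, mean(y))))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) return(list(coef = rep(NA_real_, p),
                                  se = rep(NA_real_, p),
                                  converged = FALSE, flagged = TRUE))
    new_beta <- drop(fit)
    if (max(abs(new_beta - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- new_beta; converged <- TRUE; break
    }
    beta <- new_beta
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- tryCatch(solve(t(X * w) %*% X), error = function(e) NULL)
  if (is.null(cov)) return(list(coef = beta, se = rep(NA_real_, p),
                                converged = converged, flagged = TRUE))
  se <- sqrt(diag(cov))
  flagged <- !converged || any(!is.finite(se)) || max(abs(beta)) > 30 ||
    max(se) > 100
  list(coef = beta, se = se, converged = converged, flagged = flagged)
}

# Two-sided Wald p-value for one coefficient of a logit_wald fit.
wald_p <- function(fit, j) {
  if (fit$flagged || is.na(fit$se[j])) return(NA_real_)
  2 * stats::pnorm(-abs(fit$coef[j] / fit$se[j]))
}

# AssociationResult row constructor: per-SD OR scale for logistic terms,
# beta scale for linear ones.
association_row <- function(term, estimate, se, n, exponentiate = TRUE) {
  ci <- estimate + c(-1, 1) * stats::qnorm(0.975) * se
  p <- 2 * stats::pnorm(-abs(estimate / se))
  data.frame(term = term, estimate = estimate, se = se,
             effect = if (exponentiate) exp(estimate) else estimate,
             ci_lower = if (exponentiate) exp(ci[1]) else ci[1],
             ci_upper = if (exponentiate) exp(ci[2]) else ci[2],
             p = p, n = n, stringsAsFactors = FALSE)
}
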