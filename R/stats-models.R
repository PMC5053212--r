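# Standardize continuous covariates so logistic coefficients are per-SD
# log-odds; binary HRT enters as an indicator.
base_covariate_frame <- function(cohort, include_time = FALSE) {
  zs <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
  out <- data.frame(
    y = as.integer(cohort$outcome == "IC"),
    pd = zs(cohort$pd), bmi = zs(cohort$bmi), age = zs(cohort$age_dx),
    hrt = as.integer(cohort$hrt == "yes"))
  if (include_time) out$months_to_dx <- zs(cohort$months_to_dx)
  out
}

# Box-Cox standardized feature columns aligned to the cohort.
standardized_feature_frame <- function(cohort, feats, features = NULL) {
  fx <- align_features(cohort, feats)
  if (!is.null(features)) fx <- fx[, intersect(features, names(fx)), drop = FALSE]
  for (nm in names(fx)) {
    v <- fx[[nm]]
    ok <- !is.na(v)
    if (sum(ok) >= 10 && stats::sd(v[ok]) > 0)
      fx[[nm]] <- box_cox_standardize(v)$transformed
    else fx[[nm]] <- NA_real_
  }
  fx
}

#' Forward AIC selection of dense-area features
#'
#' Greedy forward selection on top of the base logistic model IC-vs-SC ~
#' PD + age + BMI + HRT: at each step the candidate feature whose addition
#' minimizes the AIC is added; selection stops when no candidate lowers
#' the AIC. The complete-case set is fixed at the start (rows missing any
#' candidate or base covariate are dropped) so that AICs are comparable
#' across steps; ties are broken by candidate order F1 to F42.
#'
#' @param cohort cohort data.frame
#' @param feats feature table for one thresholding method (typically Otsu,
#'   the primary approach)
#' @param candidates candidate feature names (default: all feature columns)
#' @return list with \code{selected} (character vector in selection order),
#'   \code{fit} (the final \code{glm}), \code{aic_path} and \code{n}
#' @export
forward_select <- function(cohort, feats, candidates = NULL) {
  base <- base_covariate_frame(cohort)
  fx <- standardized_feature_frame(cohort, feats, candidates)
  cand <- names(fx)[!vapply(fx, function(v) all(is.na(v)), logical(1))]
  dat <- cbind(base, fx[, cand, drop = FALSE])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 10 || length(unique(dat$y)) < 2)
    stop("base model cannot be fitted on complete cases", call. = FALSE)
  base_terms <- c("pd", "age", "bmi", "hrt")
  fit <- stats::glm(stats::reformulate(base_terms, "y"), family = stats::binomial(),
                    data = dat)
  selected <- character(0)
  aic_path <- stats::AIC(fit)
  repeat {
    remaining <- setdiff(cand, selected)
    if (length(remaining) == 0) break
    aics <- vapply(remaining, function(f) {
      stats::AIC(stats::glm(stats::reformulate(c(base_terms, selected, f), "y"),
                            family = stats::binomial(), data = dat))
    }, numeric(1))
    best <- remaining[which.min(aics)]   # first minimum = lowest F order
    if (min(aics) >= aic_path[length(aic_path)] - 1e-8) break
    selected <- c(selected, best)
    aic_path <- c(aic_path, min(aics))
    fit <- stats::glm(stats::reformulate(c(base_terms, selected), "y"),
                      family = stats::binomial(), data = dat)
  }
  list(selected = selected, fit = fit, aic_path = aic_path, n = nrow(dat))
}

#' Final multivariate odds-ratio model
#'
#' Logistic model IC-vs-SC ~ PD + BMI + HRT + age + the selected features
#' (by default the gradient-skewness feature F40 and the eccentricity
#' feature F21), all continuous covariates standardized and features
#' Box-Cox standardized, so odds ratios are per SD. Optionally adds the
#' time from mammogram to diagnosis as a sensitivity covariate.
#'
#' @param cohort cohort data.frame
#' @param feats feature table (Otsu method in the primary analysis); may
#'   also be a data.frame holding raw feature columns (e.g. latent
#'   simulated features)
#' @param features feature names to include
#' @param include_time add standardized months-to-diagnosis
#' @return data.frame of association results (per-SD OR, 95% CI, p, n) for
#'   every non-intercept term, with attribute \code{fit} holding the glm
#' @export
fit_final_model <- function(cohort, feats, features = c("F40", "F21"),
                            include_time = FALSE) {
  base <- base_covariate_frame(cohort, include_time = include_time)
  fx <- standardized_feature_frame(cohort, feats, features)
  dat <- cbind(base, fx)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$y)) < 2)
    stop("both outcome classes must be present in complete cases", call. = FALSE)
  terms <- setdiff(names(dat), "y")
  fit <- stats::glm(stats::reformulate(terms, "y"), family = stats::binomial(),
                    data = dat)
  sm <- summary(fit)$coefficients
  rows <- do.call(rbind, lapply(rownames(sm)[-1], function(tm)
    association_row(tm, sm[tm, 1], sm[tm, 2], nrow(dat))))
  rownames(rows) <- NULL
  attr(rows, "fit") <- fit
  rows
}

#' Tumor-size regression for one feature
#'
#' Univariate linear model of square-root-transformed tumor size (tumor
#' size is left-skewed) on the Box-Cox standardized feature, within a
#' detection-mode stratum ("all", "SC" or "IC"). The coefficient is the
#' change in sqrt tumor size (mm^0.5) per SD of the feature.
#'
#' @param cohort cohort data.frame with \code{tumor_size} in mm
#' @param feats feature table or data.frame with the feature column
#' @param feature feature name
#' @param stratum "all", "SC" or "IC"
#' @return one-row association data.frame (beta scale)
#' @export
tumor_size_regression <- function(cohort, feats, feature = "F40",
                                  stratum = c("all", "SC", "IC")) {
  stratum <- match.arg(stratum)
  fx <- standardized_feature_frame(cohort, feats, feature)[[feature]]
  keep <- if (stratum == "all") rep(TRUE, nrow(cohort)) else cohort$outcome == stratum
  keep <- keep & !is.na(cohort$outcome)
  if (!any(keep)) stop("empty stratum", call. = FALSE)
  size <- cohort$tumor_size[keep]
  f <- fx[keep]
  ok <- !is.na(size) & !is.na(f)
  if (any(size[ok] <= 0))
    stop("non-positive tumor size: sqrt transform undefined", call. = FALSE)
  fit <- stats::lm(sqrt(size[ok]) ~ f[ok])
  sm <- summary(fit)$coefficients
  out <- association_row(feature, sm[2, 1], sm[2, 2], sum(ok),
                         exponentiate = FALSE)
  out$stratum <- stratum
  out
}

#' Association between a feature and a risk factor
#'
#' Linear model of the Box-Cox standardized feature on one risk factor
#' (continuous factors enter as-is, categorical ones indicator-coded).
#'
#' @param cohort cohort data.frame
#' @param feats feature table or data.frame with the feature column
#' @param feature feature name
#' @param risk_factor name of a cohort column
#' @return association data.frame (beta scale), one row per non-intercept
#'   term
#' @export
feature_risk_factor_models <- function(cohort, feats, feature, risk_factor) {
  fx <- standardized_feature_frame(cohort, feats, feature)[[feature]]
  rf <- cohort[[risk_factor]]
  if (is.null(rf)) stop("unknown risk factor column", call. = FALSE)
  ok <- !is.na(fx) & !is.na(rf)
  if (sum(ok) < 10) stop("fewer than 10 complete cases", call. = FALSE)
  rf <- rf[ok]
  if (length(unique(rf)) < 2)
    stop("constant risk factor", call. = FALSE)
  dat <- data.frame(f = fx[ok], rf = if (is.character(rf)) factor(rf) else rf)
  fit <- stats::lm(f ~ rf, data = dat)
  sm <- summary(fit)$coefficients
  rows <- do.call(rbind, lapply(rownames(sm)[-1], function(tm)
    association_row(tm, sm[tm, 1], sm[tm, 2], sum(ok), exponentiate = FALSE)))
  rownames(rows) <- NULL
  rows
}
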