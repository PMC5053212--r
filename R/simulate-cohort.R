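#' Parameters for the synthetic cohort generator
#'
#' The cohort is a synthetic twin of a case-case study sample of interval
#' (IC) versus screen-detected (SC) breast cancer. The IC indicator follows
#' a logistic model in standardized percent density, HRT use, BMI and age
#' plus two latent standardized image features (the gradient-skewness and
#' eccentricity features F40/F21); square-root tumor size follows
#' stratum-specific linear models. Default effect sizes are per-SD log-odds
#' of ln 1.32 (F40) and ln 1.20 (F21), and tumor-size effects of 0.20 per
#' SD of F40 among SC and -0.18 per SD of F21 among IC.
#'
#' @param n number of women (>= 2)
#' @param beta0 log-odds intercept (controls the IC fraction)
#' @param beta_pd,beta_bmi,beta_age per-SD log-odds for the covariates
#' @param beta_hrt log-odds for HRT use (binary indicator)
#' @param beta_f40,beta_f21 per-SD log-odds for the latent features
#' @param gamma_sc_f40 effect of F40 on sqrt tumor size (mm^0.5) among SC
#' @param gamma_ic_f21 effect of F21 on sqrt tumor size among IC
#' @param missing_rates named per-field missingness probabilities
#' @param seed integer seed for the cohort's private random stream
#' @return a list of class \code{cohort_sim_params}
#' @export
cohort_sim_params <- function(n = 1403L, beta0 = -1.0,
                              beta_pd = log(1.23), beta_hrt = log(1.57),
                              beta_bmi = log(0.84), beta_age = log(0.98),
                              beta_f40 = log(1.32), beta_f21 = log(1.20),
                              gamma_sc_f40 = 0.20, gamma_ic_f21 = -0.18,
                              missing_rates = NULL, seed = 1L) {
  if (n < 2L) stop("n must be at least 2", call. = FALSE)
  if (is.null(missing_rates))
    missing_rates <- c(menopausal = 0.064, bmi = 0.032, hrt = 0.051,
                       oc_use = 0.031, parity_status = 0.022,
                       family_history = 0.078, tumor_size = 0.073,
                       grade = 0.42, er = 0.27, pr = 0.28,
                       lymph_node = 0.004)
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("missing_rates must be probabilities in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), beta0 = beta0, beta_pd = beta_pd,
                 beta_hrt = beta_hrt, beta_bmi = beta_bmi,
                 beta_age = beta_age, beta_f40 = beta_f40,
                 beta_f21 = beta_f21, gamma_sc_f40 = gamma_sc_f40,
                 gamma_ic_f21 = gamma_ic_f21,
                 missing_rates = missing_rates, seed = as.integer(seed)),
            class = "cohort_sim_params")
}

#' Generate a synthetic IC/SC cohort with known ground truth
#'
#' Covariates follow documented conventions: percent density is lognormal
#' (right-skewed, median about 19%), BMI and age at diagnosis are normal,
#' HRT use is Bernoulli, and the latent features f40/f21 are standard
#' normal. The IC indicator is Bernoulli with logistic probability in the
#' standardized covariates; sqrt tumor size is a stratum-specific linear
#' predictor plus unit-SD noise, squared, with a 1 mm floor so the sqrt
#' transform stays well-defined. Receptor, node and grade fields are drawn
#' with stratum-specific frequencies. Requested missingness is applied
#' last. The true coefficient vector is attached as attribute
#' \code{"truth"}.
#'
#' @param params a \code{\link{cohort_sim_params}} object
#' @return data.frame with one row per woman
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  with_local_seed(p$seed, {
    n <- p$n
    z_pd <- stats::rnorm(n); z_bmi <- stats::rnorm(n); z_age <- stats::rnorm(n)
    pd <- pmin(95, pmax(0.5, exp(log(19) + 0.55 * z_pd)))
    bmi <- 25.4 + 4 * z_bmi
    age_dx <- 60.4 + 8 * z_age
    hrt <- stats::rbinom(n, 1, 0.18)
    f40 <- stats::rnorm(n); f21 <- stats::rnorm(n)

    lp <- p$beta0 + p$beta_pd * z_pd + p$beta_hrt * hrt +
      p$beta_bmi * z_bmi + p$beta_age * z_age +
      p$beta_f40 * f40 + p$beta_f21 * f21
    ic <- stats::rbinom(n, 1, stats::plogis(lp))
    outcome <- ifelse(ic == 1, "IC", "SC")

    sqrt_size <- ifelse(ic == 1,
                        4.30 + p$gamma_ic_f21 * f21,
                        3.82 + p$gamma_sc_f40 * f40) + stats::rnorm(n)
    tumor_size <- pmax(1, sqrt_size^2)
    months_to_dx <- exp(ifelse(ic == 1, log(15.3) + 0.45 * stats::rnorm(n),
                               log(24.6) + 0.35 * stats::rnorm(n)))

    parous <- stats::rbinom(n, 1, 0.845)
    births <- ifelse(parous == 1, 1 + stats::rpois(n, 1.14), NA)
    age_first_birth <- ifelse(parous == 1, stats::rnorm(n, 25.5, 4), NA)

    draw2 <- function(p_ic, p_sc) stats::rbinom(n, 1, ifelse(ic == 1, p_ic, p_sc))
    cohort <- data.frame(
      id = sprintf("w%05d", seq_len(n)),
      outcome = outcome, pd = pd, age_dx = age_dx, bmi = bmi,
      hrt = ifelse(hrt == 1, "yes", "no"),
      oc_use = ifelse(stats::rbinom(n, 1, 0.77) == 1, "yes", "no"),
      parity_status = ifelse(parous == 1, "parous", "nulliparous"),
      births = births, age_first_birth = age_first_birth,
      family_history = ifelse(draw2(0.23, 0.18) == 1, "yes", "no"),
      menopausal = ifelse(draw2(0.81, 0.84) == 1, "yes", "no"),
      er = ifelse(draw2(0.81, 0.90) == 1, "positive", "negative"),
      pr = ifelse(draw2(0.62, 0.72) == 1, "positive", "negative"),
      lymph_node = ifelse(draw2(0.09, 0.04) == 1, "yes", "no"),
      grade = ifelse(draw2(0.34, 0.21) == 1, 3L,
                     ifelse(stats::rbinom(n, 1, 0.7) == 1, 2L, 1L)),
      tumor_size = tumor_size, months_to_dx = months_to_dx,
      f40 = f40, f21 = f21,
      stringsAsFactors = FALSE)

    for (field in names(p$missing_rates)) {
      rate <- p$missing_rates[[field]]
      if (rate > 0 && field %in% names(cohort)) {
        miss <- stats::runif(n) < rate
        cohort[[field]][miss] <- NA
      }
    }
    attr(cohort, "truth") <- unclass(p)
    cohort
  })
}

#' Write/read a cohort table as CSV
#' @param cohort data.frame from \code{\link{generate_cohort}}
#' @param path CSV path
#' @return the path (write) or the cohort data.frame (read)
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
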