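#' Simulate a cohort whose outcome is driven by image properties
#'
#' The end-to-end generative path: each woman gets latent standard-normal
#' traits u40 and u21 that set her image's fatty-streak amplitude and
#' dense-region eccentricity; her IC-vs-SC status is drawn from a logistic
#' model in those latent image properties. Each image is then run through
#' the full pipeline (preprocess, dense-area segmentation, feature
#' extraction), so regressing the measured features on the outcome should
#' recover positive per-SD log-odds for the gradient-skewness (F40) and
#' eccentricity (F21) features.
#'
#' @param n number of women/images
#' @param seed integer seed
#' @param beta_streak,beta_ecc log-odds per SD of the latent traits
#' @param beta0 log-odds intercept
#' @param method thresholding method for segmentation
#' @param features features to measure (default the two under study plus
#'   none others, keeping the image size small and the run fast)
#' @param image_args overrides for \code{\link{image_sim_params}} (e.g.
#'   smaller images)
#' @return list with \code{cohort} (covariates incl. the percent-density
#'   proxy and latent truths) and \code{features} (measured feature table)
#' @export
simulate_imaging_cohort <- function(n, seed = 1L, beta_streak = log(2),
                                    beta_ecc = log(2), beta0 = -1,
                                    method = "otsu",
                                    features = c("F40", "F21"),
                                    image_args = list()) {
  with_local_seed(seed, {
    u40 <- stats::rnorm(n); u21 <- stats::rnorm(n)
    ic <- stats::rbinom(n, 1, stats::plogis(beta0 + beta_streak * u40 +
                                              beta_ecc * u21))
    bmi <- stats::rnorm(n, 25.4, 4); age <- stats::rnorm(n, 60.4, 8)
    hrt <- ifelse(stats::rbinom(n, 1, 0.18) == 1, "yes", "no")
    img_seeds <- sample.int(2^30, n)
  })
  # monotone knob maps into the rising range of the amplitude ->
  # gradient-skewness response
  streak <- 0.15 + 0.85 * stats::pnorm(u40)
  ecc <- 0.10 + 0.8 * stats::pnorm(u21)
  rows <- vector("list", n)
  pd <- numeric(n)
  for (i in seq_len(n)) {
    args <- c(list(dense_eccentricity = ecc[i], streak_intensity = streak[i],
                   seed = img_seeds[i]), image_args)
    sim <- do.call(generate_breast_image, args = list(do.call(image_sim_params, args)))
    pre <- preprocess_image(sim$image)
    dm <- dense_mask(pre$image, pre$mask, method = method)
    pd[i] <- percent_density_proxy(dm, pre$mask)
    fv <- extract_features(pre$image, dm, features = features)
    rows[[i]] <- c(list(id = sprintf("w%05d", i)), as.list(as.numeric(fv)))
    names(rows[[i]])[-1] <- features
  }
  feats <- do.call(rbind, lapply(rows, as.data.frame))
  cohort <- data.frame(id = feats$id,
                       outcome = ifelse(ic == 1, "IC", "SC"),
                       pd = pd, bmi = bmi, age_dx = age, hrt = hrt,
                       u40 = u40, u21 = u21,
                       stringsAsFactors = FALSE)
  list(cohort = cohort, features = feats)
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate, preprocess, segment, extract and analyze with a
#' single configuration list (or YAML file path): generates a cohort and
#' one synthetic image per woman, extracts the feature table for each
#' thresholding method, runs the statistical stage, and writes feature
#' CSVs, a JSON report with the characteristics/associations tables, and a
#' reproducibility manifest (parameters, seeds, package version). Rerunning
#' with the same configuration reproduces all outputs.
#'
#' @param config list (or path to a YAML file) with optional blocks
#'   \code{n_images}, \code{seed}, \code{methods}, \code{bins},
#'   \code{image} (overrides for \code{\link{image_sim_params}}),
#'   \code{cohort} (overrides for \code{\link{cohort_sim_params}}),
#'   \code{stats} (\code{n_perm}, \code{alpha}, \code{include_time}) and
#'   \code{out_dir}
#' @return list with the cohort, feature tables, test battery, global test,
#'   selection, final model, tumor-size models and summary table; written
#'   under \code{out_dir} when given
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml_load_file(config)
  n <- config$n_images %||% 60L
  seed <- config$seed %||% 1L
  methods <- config$methods %||% c("otsu", "percentile", "entropy")
  bad <- setdiff(methods, c("otsu", "percentile", "entropy"))
  if (length(bad) > 0)
    stop("unknown thresholding method: ", paste(bad, collapse = ", "),
         call. = FALSE)
  bins <- config$bins %||% 256L
  stats_cfg <- config$stats %||% list()
  n_perm <- stats_cfg$n_perm %||% 500L
  alpha <- stats_cfg$alpha %||% 0.05

  cohort <- generate_cohort(do.call(cohort_sim_params,
                                    c(list(n = n, seed = seed),
                                      config$cohort %||% list())))
  images <- lapply(seq_len(n), function(i) {
    prm <- do.call(image_sim_params,
                   c(list(seed = seed * 100000L + i), config$image %||% list()))
    preprocess_image(generate_breast_image(prm)$image)
  })
  for (i in seq_len(n)) images[[i]]$image$id <- cohort$id[i]

  feats <- lapply(stats::setNames(methods, methods), function(m)
    feature_table(images, method = m, bins = bins))

  tests <- per_feature_tests(cohort, feats)
  global <- global_permutation_test(cohort, feats, n_perm = n_perm,
                                    alpha = alpha, seed = seed)
  primary <- if ("otsu" %in% methods) "otsu" else methods[1]
  selection <- tryCatch(forward_select(cohort, feats[[primary]]),
                        error = function(e) list(selected = character(0)))
  final <- tryCatch(fit_final_model(cohort, feats[[primary]]),
                    error = function(e) NULL)
  tumor <- do.call(rbind, lapply(c("all", "SC", "IC"), function(s) {
    rows <- lapply(c("F40", "F21"), function(f)
      tryCatch(tumor_size_regression(cohort, feats[[primary]], f, s),
               error = function(e) NULL))
    do.call(rbind, rows)
  }))
  # small demonstration cohorts can have sparse high-missingness fields;
  # summarize the variables with data in both groups
  spec <- default_summary_spec()
  ic <- cohort$outcome == "IC"
  ok_var <- vapply(spec$variable, function(v)
    v %in% names(cohort) && sum(!is.na(cohort[[v]][ic])) > 0 &&
      sum(!is.na(cohort[[v]][!ic])) > 0, logical(1))
  summary_tab <- cohort_summary(cohort, spec[ok_var, , drop = FALSE])

  out <- list(cohort = cohort, features = feats, tests = tests,
              global = global, selection = selection["selected"],
              final = final, tumor = tumor, summary = summary_tab,
              manifest = list(n_images = n, seed = seed, methods = methods,
                              bins = bins, n_perm = n_perm, alpha = alpha,
                              package_version =
                                as.character(utils::packageVersion("mammodense"))))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))
    for (m in names(feats))
      utils::write.csv(feats[[m]],
                       file.path(config$out_dir, paste0("features_", m, ".csv")),
                       row.names = FALSE)
    utils::write.csv(tests, file.path(config$out_dir, "per_feature_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(config$out_dir, "cohort_summary.csv"),
                     row.names = FALSE)
    report <- list(global = out$global[c("observed", "p", "n_tests",
                                         "n_excluded", "n_perm", "alpha")],
                   selected = selection$selected, final = final,
                   tumor = tumor, manifest = out$manifest)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

yaml_load_file <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the yaml package", call. = FALSE)
  yaml::read_yaml(path)
}
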