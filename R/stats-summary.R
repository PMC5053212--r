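#' Default variable layout for the cohort characteristics table
#'
#' Names are cohort columns; \code{type} is "mean", "median" or
#' "categorical". Used by \code{\link{cohort_summary}}.
#' @return data.frame with columns \code{variable} and \code{type}
#' @export
default_summary_spec <- function() {
  data.frame(
    variable = c("age_dx", "menopausal", "bmi", "hrt", "oc_use",
                 "parity_status", "births", "age_first_birth",
                 "family_history", "months_to_dx", "pd", "tumor_size",
                 "lymph_node", "grade", "er", "pr"),
    type = c("mean", "categorical", "mean", "categorical", "categorical",
             "categorical", "mean", "mean", "categorical", "median",
             "median", "mean", "categorical", "categorical", "categorical",
             "categorical"),
    stringsAsFactors = FALSE)
}

#' Patient/mammographic/tumor characteristics summary by detection mode
#'
#' For each variable: IC and SC group statistics (mean or median for
#' continuous variables; counts with within-group percentages of
#' non-missing values, rounded to the nearest integer, for categorical
#' ones), a two-sided p-value (Welch t-test for continuous, Pearson
#' chi-square for categorical) and the overall percent missing.
#'
#' @param cohort cohort data.frame with an \code{outcome} column
#' @param spec variable layout, see \code{\link{default_summary_spec}};
#'   variables absent from the cohort are skipped
#' @return data.frame with one row per variable level: \code{variable},
#'   \code{level}, \code{ic_n}, \code{ic_pct} (or \code{ic_stat}),
#'   \code{sc_n}, \code{sc_pct} (or \code{sc_stat}), \code{p},
#'   \code{pct_missing}
#' @export
cohort_summary <- function(cohort, spec = default_summary_spec()) {
  if (any(is.na(cohort$outcome))) stop("outcome must be non-missing", call. = FALSE)
  ic <- cohort$outcome == "IC"
  if (!any(ic) || all(ic)) stop("both IC and SC groups required", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    v <- spec$variable[i]; type <- spec$type[i]
    if (!v %in% names(cohort)) next
    x <- cohort[[v]]
    pct_missing <- 100 * mean(is.na(x))
    xi <- x[ic & !is.na(x)]; xs <- x[!ic & !is.na(x)]
    if (length(xi) == 0 || length(xs) == 0)
      stop(sprintf("variable '%s' entirely missing in one group", v),
           call. = FALSE)
    if (type %in% c("mean", "median")) {
      stat <- if (type == "mean") mean else stats::median
      p <- tryCatch(stats::t.test(xi, xs)$p.value, error = function(e) NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, level = type, ic_n = length(xi),
        ic_stat = stat(xi), ic_pct = NA_real_, sc_n = length(xs),
        sc_stat = stat(xs), sc_pct = NA_real_, p = p,
        pct_missing = pct_missing, stringsAsFactors = FALSE)
    } else {
      levs <- sort(unique(c(xi, xs)))
      tab <- rbind(table(factor(xi, levels = levs)),
                   table(factor(xs, levels = levs)))
      p <- tryCatch(stats::chisq.test(tab, correct = FALSE)$p.value,
                    error = function(e) NA_real_)
      for (lv in levs) {
        ni <- sum(xi == lv); ns <- sum(xs == lv)
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = as.character(lv), ic_n = ni,
          ic_stat = NA_real_, ic_pct = round(100 * ni / length(xi)),
          sc_n = ns, sc_stat = NA_real_,
          sc_pct = round(100 * ns / length(xs)), p = p,
          pct_missing = pct_missing, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
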