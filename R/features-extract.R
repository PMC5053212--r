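# Which feature group computes which identifiers.
FEATURE_GROUPS <- list(
  histogram_features = c("F4", "F5", "F6", "F18", "F27", "F37", "F39"),
  gradient_skewness = "F40",
  shape_features = c("F19", "F20", "F21", "F22", "F26", "F35"),
  projection_features = c("F33", "F34"),
  transform_features = c("F1", "F2", "F3", "F11", "F14", "F16", "F17"),
  gabor_entropy_features = c("F8", "F9", "F10"),
  entropy_filter_feature = "F7",
  cooccurrence_features = c("F12", "F41", "F42"),
  svd_features = c("F24", "F25"))

#' Extract the dense-area feature vector for one image
#'
#' Assembles all feature sub-operations on the tight zero-filled crop of
#' the dense area (\code{\link{dense_patch}}). Deterministic. Features
#' whose value is undefined on the input (zero variance, missing pixel
#' pairs, degenerate patches) are stored as 0 with their flag set; the
#' statistics stage drops flagged values per feature.
#'
#' @param img normalized \code{\link{mammogram}} (or numeric matrix)
#' @param mask logical dense mask
#' @param features subset of \code{\link{FEATURE_NAMES}} to compute
#'   (default all 32); only the needed operator groups are run
#' @return object of class \code{feature_vector}: named numeric vector with
#'   a logical \code{flags} attribute, plus \code{method} and \code{id}
#'   attributes when available
#' @export
extract_features <- function(img, mask, features = FEATURE_NAMES) {
  features <- match.arg(features, FEATURE_NAMES, several.ok = TRUE)
  patch <- dense_patch(img, mask)
  vals <- setNames(rep(0, length(features)), features)
  flags <- setNames(rep(FALSE, length(features)), features)
  for (grp in names(FEATURE_GROUPS)) {
    want <- intersect(FEATURE_GROUPS[[grp]], features)
    if (length(want) == 0L) next
    res <- if (grp == "shape_features") shape_features(patch$mask)
           else do.call(grp, list(patch))
    vals[want] <- res$values[want]
    flags[want] <- res$flags[want]
  }
  structure(vals, flags = flags,
            method = attr(mask, "method"),
            id = if (inherits(img, "mammogram")) img$id else NULL,
            class = "feature_vector")
}

#' Feature table for a set of images
#'
#' Runs segmentation and feature extraction for each image under one
#' thresholding method and binds the results into a data frame (one row per
#' image; feature columns F1...F42 plus matching flag columns).
#'
#' @param images list of preprocessed entries, each a list with
#'   \code{image} (normalized mammogram) and \code{mask} (breast mask)
#' @param method thresholding method passed to \code{\link{dense_mask}}
#' @param features feature subset (default all)
#' @param bins histogram bins for thresholding
#' @return data.frame with columns \code{id}, \code{method}, features and
#'   \code{<feature>_flag} columns
#' @export
feature_table <- function(images, method = "otsu", features = FEATURE_NAMES,
                          bins = 256L) {
  rows <- lapply(images, function(entry) {
    dm <- dense_mask(entry$image, entry$mask, method = method, bins = bins)
    fv <- if (any(dm)) extract_features(entry$image, dm, features = features)
          else structure(setNames(rep(0, length(features)), features),
                         flags = setNames(rep(TRUE, length(features)), features))
    out <- as.list(as.numeric(fv))
    names(out) <- features
    fl <- as.list(attr(fv, "flags"))
    names(fl) <- paste0(features, "_flag")
    c(list(id = entry$image$id, method = method), out, fl)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
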