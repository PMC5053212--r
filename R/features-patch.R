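#' The 32 dense-area feature identifiers
#'
#' Feature numbering retains its historical gaps (F13, F15, F23, ... are
#' absent); there are exactly 32 identifiers.
#' @export
FEATURE_NAMES <- c("F1", "F2", "F3", "F4", "F5", "F6", "F7", "F8", "F9",
                   "F10", "F11", "F12", "F14", "F16", "F17", "F18", "F19",
                   "F20", "F21", "F22", "F24", "F25", "F26", "F27", "F33",
                   "F34", "F35", "F37", "F39", "F40", "F41", "F42")

#' Tight crop of the dense area
#'
#' The canonical input for the texture/transform feature operators: the
#' bounding-box crop of the normalized image with all non-dense pixels set
#' to zero, together with the cropped dense mask.
#'
#' @param img normalized \code{\link{mammogram}} (or numeric matrix)
#' @param mask logical dense mask, same shape as the image
#' @return object of class \code{dense_patch}: list with \code{values} and
#'   \code{mask} matrices
#' @export
dense_patch <- function(img, mask) {
  px <- if (inherits(img, "mammogram")) img$pixels else img
  stopifnot(is.matrix(px), is.logical(mask), all(dim(px) == dim(mask)))
  if (!any(mask)) stop("empty dense mask", call. = FALSE)
  rr <- range(which(rowSums(mask) > 0))
  cr <- range(which(colSums(mask) > 0))
  m <- mask[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  v <- px[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE]
  v[!m] <- 0
  structure(list(values = v, mask = m), class = "dense_patch")
}

# helper: a feature-group result
feat_result <- function(values, flags = NULL) {
  if (is.null(flags)) flags <- setNames(rep(FALSE, length(values)), names(values))
  list(values = values, flags = flags)
}

flagged <- function(names) {
  list(values = setNames(rep(0, length(names)), names),
       flags = setNames(rep(TRUE, length(names)), names))
}
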