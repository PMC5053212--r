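#' Remove nametags and other off-breast artifacts
#'
#' Foreground pixels are those above a low global threshold (default 2% of
#' the intensity range, robust for film digitizations with near-zero
#' background). The breast mask is the largest 8-connected foreground
#' component; everything outside it (nametags, specks) is set to zero.
#'
#' @param img a \code{\link{mammogram}} with integer-scale intensities
#' @param fg_fraction foreground threshold as a fraction of the intensity
#'   range
#' @return list with the cleaned \code{image} and the logical breast
#'   \code{mask}
#' @export
remove_artifacts <- function(img, fg_fraction = 0.02) {
  stopifnot(inherits(img, "mammogram"))
  px <- img$pixels
  fg <- px > fg_fraction * max_intensity(img)
  if (!any(fg)) stop("blank image: no foreground component", call. = FALSE)
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  px[!mask] <- 0
  out <- img
  out$pixels <- px
  list(image = out, mask = mask)
}

#' Normalize intensity between mammograms
#'
#' Rescales breast-pixel intensities so the 1st/99th breast percentiles map
#' to 0/1, clipping to [0, 1]. A monotone map: the ordering of breast-pixel
#' intensities is preserved. Pixels outside the mask stay 0. This reduces
#' contrast differences between films digitized at different exposures.
#'
#' @param img a \code{\link{mammogram}}
#' @param mask logical breast mask
#' @param probs the two anchor percentiles
#' @return the normalized \code{mammogram} (unit-interval floats)
#' @export
normalize_intensity <- function(img, mask, probs = c(0.01, 0.99)) {
  stopifnot(inherits(img, "mammogram"))
  vals <- img$pixels[mask]
  q <- stats::quantile(vals, probs, names = FALSE)
  if (q[2] <= q[1])
    stop("degenerate contrast: breast region is constant", call. = FALSE)
  px <- (img$pixels - q[1]) / (q[2] - q[1])
  px <- pmin(pmax(px, 0), 1)
  px[!mask] <- 0
  out <- img
  out$pixels <- px
  attr(out, "normalized") <- TRUE
  out
}

#' Remove the pectoral muscle from the breast mask
#'
#' The pectoral muscle appears as a bright region in the upper chest-wall
#' corner of an MLO view (the corner is chosen by laterality). Candidate
#' pectoral pixels are the high-intensity pixels of the upper chest-wall
#' quadrant; the 8-connected candidate component touching the corner is
#' taken, a straight line is fitted by least squares to its per-row outer
#' boundary, and everything on the corner side of the line is removed from
#' the mask. If no credible corner region is found the mask is returned
#' unchanged with a warning.
#'
#' @param img normalized \code{\link{mammogram}}
#' @param mask logical breast mask
#' @param level intensity (normalized scale) above which a pixel is
#'   considered pectoral-bright
#' @return the reduced logical mask, with attribute \code{pectoral} holding
#'   the removed region
#' @export
remove_pectoral <- function(img, mask, level = 0.8) {
  stopifnot(inherits(img, "mammogram"))
  px <- img$pixels
  h <- nrow(px); w <- ncol(px)
  mirror <- img$laterality == "right"
  if (mirror) {                       # work in a chest-wall-left frame
    px <- px[, rev(seq_len(w)), drop = FALSE]
    mask <- mask[, rev(seq_len(w)), drop = FALSE]
  }

  quad <- matrix(FALSE, h, w)
  quad[seq_len(floor(h / 2)), seq_len(floor(w / 2))] <- TRUE
  cand <- mask & quad & px > level

  removed <- matrix(FALSE, h, w)
  ok <- FALSE
  if (any(cand)) {
    lab <- EBImage::bwlabel(cand)
    # candidate component attached to the chest-wall border (the pectoral
    # muscle always meets the chest wall); take the topmost such component
    wall_labs <- unique(lab[, seq_len(min(w, 3L))])
    wall_labs <- wall_labs[wall_labs > 0]
    if (length(wall_labs) > 0) {
      top_row <- vapply(wall_labs, function(l)
        min(which(rowSums(lab == l) > 0)), numeric(1))
      comp <- lab == wall_labs[which.min(top_row)]
      # per-row outermost candidate column -> straight boundary fit
      rows <- which(rowSums(comp) > 0)
      if (length(rows) >= 3) {
        edge <- vapply(rows, function(i) max(which(comp[i, ])), integer(1))
        fit <- stats::lm.fit(cbind(1, rows), edge)
        # small outward margin so bright boundary pixels pushed past the
        # fitted line by noise are still removed
        bnd <- fit$coefficients[1] + fit$coefficients[2] * seq_len(h) + 1.5
        colmat <- matrix(seq_len(w), h, w, byrow = TRUE)
        removed <- mask & ((colmat <= pmax(bnd, 0) &
                              matrix(seq_len(h), h, w) <= max(rows) + 1) | comp)
        ok <- sum(removed) > 0
      }
    }
  }
  if (!ok) {
    warning("no pectoral region found; mask returned unchanged",
            call. = FALSE)
    removed <- matrix(FALSE, h, w)
  }
  out <- mask & !removed
  if (mirror) {
    out <- out[, rev(seq_len(w)), drop = FALSE]
    removed <- removed[, rev(seq_len(w)), drop = FALSE]
  }
  attr(out, "pectoral") <- removed
  out
}

#' Full preprocessing pipeline
#'
#' Fixed order: artifact removal, intensity normalization, pectoral-muscle
#' removal. Every output mask is a subset of the input mask and all steps
#' are deterministic.
#'
#' @param img a raw integer-scale \code{\link{mammogram}}
#' @param pectoral logical; attempt pectoral removal
#' @return list with normalized \code{image} and final breast \code{mask}
#'   (pectoral excluded)
#' @export
preprocess_image <- function(img, pectoral = TRUE) {
  st <- remove_artifacts(img)
  norm <- normalize_intensity(st$image, st$mask)
  mask <- st$mask
  if (pectoral)
    mask <- suppressWarnings(remove_pectoral(norm, st$mask))
  list(image = norm, mask = mask)
}
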