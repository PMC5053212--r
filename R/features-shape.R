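# 8-connected labelling: take 4-connected labels (EBImage::bwlabel) and
# union any two labels that touch diagonally.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w])))  # down-left
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs) > 0)
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Holes: 4-connected background components (within the 1-padded bounding
# box) that do not touch the border.
count_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  bg <- EBImage::bwlabel(!pad)
  border <- unique(c(bg[1, ], bg[h + 2L, ], bg[, 1], bg[, w + 2L]))
  length(setdiff(unique(bg[bg > 0]), border))
}

#' Shape features of the dense area (F19, F20, F21, F22, F26, F35)
#'
#' All components of the (possibly disconnected) dense mask are pooled.
#' F19 = number of separate blobs (8-connected components); F20 = solidity,
#' the pixel count over the area of the convex hull of the pixel squares;
#' F21 = eccentricity of the ellipse with the same second central moments
#' as the dense pixel set (with moment eigenvalues l1 >= l2,
#' \code{sqrt(1 - l2/l1)}; 0 for a circle, toward 1 for a line — the ratio
#' of the focal distance to the major axis); F22 = Euler number
#' (components minus holes); F26 = number of holes (low intensity fully
#' surrounded by high intensity); F35 = total perimeter as the count of
#' exposed pixel edges.
#'
#' @param mask logical dense mask (full frame or cropped)
#' @return list with named \code{values} and \code{flags}
#' @export
shape_features <- function(mask) {
  if (!any(mask)) stop("empty dense mask", call. = FALSE)
  lab <- label8(mask)
  n_comp <- max(lab)
  holes <- count_holes(mask)

  idx <- which(mask, arr.ind = TRUE)
  n_px <- nrow(idx)
  # solidity: hull over the 4 corners of each pixel so hull area >= n_px
  corners <- rbind(idx + matrix(c(-0.5, -0.5), n_px, 2, byrow = TRUE),
                   idx + matrix(c(-0.5,  0.5), n_px, 2, byrow = TRUE),
                   idx + matrix(c( 0.5, -0.5), n_px, 2, byrow = TRUE),
                   idx + matrix(c( 0.5,  0.5), n_px, 2, byrow = TRUE))
  ch <- grDevices::chull(corners)
  hx <- corners[ch, 1]; hy <- corners[ch, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  solidity <- if (hull_area > 0) n_px / hull_area else 1

  # moment-based eccentricity, all components pooled
  if (n_px >= 2L) {
    cv <- stats::cov(idx) * (n_px - 1) / n_px
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
  } else ecc <- 0

  # perimeter: exposed 4-neighbor edges (image border counts as exposed)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1), drop = FALSE]
  perim <- sum(core & !pad[1:h, 2:(w + 1)]) + sum(core & !pad[3:(h + 2), 2:(w + 1)]) +
    sum(core & !pad[2:(h + 1), 1:w]) + sum(core & !pad[2:(h + 1), 3:(w + 2)])

  feat_result(c(F19 = n_comp, F20 = min(solidity, 1), F21 = ecc,
                F22 = n_comp - holes, F26 = holes, F35 = perim))
}
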