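#' Mammogram image container
#'
#' A lightweight container for a single-channel mediolateral-oblique (MLO)
#' mammogram raster. On input, pixel values are integers in
#' \code{[0, 2^bit_depth - 1]}; after \code{\link{normalize_intensity}} they
#' are unit-interval floats. The chest wall is assumed to lie along the left
#' image border for \code{laterality = "left"} and along the right border
#' for \code{laterality = "right"}.
#'
#' @param pixels numeric matrix (rows x cols), row-major top-left origin
#' @param bit_depth integer bit depth of the acquisition (default 12)
#' @param laterality "left" or "right"
#' @param id opaque image identifier
#' @return an object of class \code{mammogram}
#' @export
mammogram <- function(pixels, bit_depth = 12L, laterality = c("left", "right"),
                      id = "img") {
  laterality <- match.arg(laterality)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 laterality = laterality, view = "MLO", id = id),
            class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram %s: %d x %d, %d-bit, %s MLO>\n", x$id,
              nrow(x$pixels), ncol(x$pixels), x$bit_depth, x$laterality))
  invisible(x)
}

#' @export
dim.mammogram <- function(x) dim(x$pixels)

max_intensity <- function(img) 2^img$bit_depth - 1

#' Write a mammogram to a 16-bit TIFF or PNG file
#'
#' Integer-scale images are stored as intensity / (2^16 - 1); read back with
#' \code{\link{read_mammogram}}.
#'
#' @param img a \code{mammogram}
#' @param path output path ending in .tif/.tiff or .png
#' @return the path, invisibly
#' @export
write_mammogram <- function(img, path) {
  m <- img$pixels / 65535
  m[m < 0] <- 0; m[m > 1] <- 1
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, target = path)
  } else {
    tiff::writeTIFF(m, where = path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a mammogram written by \code{\link{write_mammogram}}
#' @param path image path
#' @inheritParams mammogram
#' @return a \code{mammogram}
#' @export
read_mammogram <- function(path, bit_depth = 12L, laterality = "left",
                           id = sub("\\.[^.]+$", "", basename(path))) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  mammogram(round(m * 65535), bit_depth = bit_depth,
            laterality = laterality, id = id)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask logical matrix
#' @param path output .png path
#' @return the path, invisibly
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

#' Read a binary mask written by \code{\link{write_mask}}
#' @param path .png path
#' @return logical matrix
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}
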