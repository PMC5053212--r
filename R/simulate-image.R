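#' Intensity layout of the synthetic mammogram phantom
#'
#' Tissue intensity levels as fractions of the maximum representable
#' intensity (\code{2^bit_depth - 1}). The ordering background < fat <
#' dense < pectoral <= nametag is chosen so that Otsu thresholding on the
#' breast region (after pectoral removal) isolates dense tissue.
#'
#' @format named numeric vector with elements \code{background}, \code{fat},
#'   \code{dense}, \code{pectoral}, \code{nametag}
#' @export
sim_intensity_levels <- c(background = 0, fat = 0.35, dense = 0.70,
                          pectoral = 0.92, nametag = 0.98)

#' Parameters for the synthetic mammogram generator
#'
#' The phantom emulates a digitized film MLO mammogram: a half-elliptical
#' breast silhouette attached to the chest-wall border, a pectoral-muscle
#' triangle in the upper chest-wall corner, an off-breast rectangular
#' nametag artifact, and a dense region whose area fraction, elongation and
#' fatty-streak interspersion are controllable. Streaks are low-intensity
#' curvilinear channels carved through the dense region; raising
#' \code{streak_intensity} raises the asymmetry (skewness) of the dense-area
#' gradient-magnitude distribution.
#'
#' @param height,width image size in pixels
#' @param bit_depth acquisition bit depth; intensities span
#'   \code{[0, 2^bit_depth - 1]}
#' @param breast_axes semi-axes (rows, cols) of the silhouette half-ellipse;
#'   default \code{c(0.45 * height, 0.8 * width)}
#' @param pectoral_fraction size of the pectoral corner triangle, in
#'   \code{[0, 0.3]}; the triangle legs are \code{2 * pectoral_fraction}
#'   times the image sides
#' @param dense_fraction target fraction of breast (minus pectoral) pixels
#'   that are dense, in (0, 1)
#' @param dense_eccentricity eccentricity of the dense region's generating
#'   ellipse, in [0, 1)
#' @param streak_intensity amplitude (>= 0) of fatty-streak carving, as a
#'   multiple of the dense-fat intensity contrast
#' @param noise_sd additive Gaussian noise SD in intensity units
#' @param nametag logical; paint a nametag artifact
#' @param laterality chest-wall side convention, "left" or "right"
#' @param seed integer seed for the image's private random stream
#' @return a list of class \code{image_sim_params}
#' @export
image_sim_params <- function(height = 256L, width = 200L, bit_depth = 12L,
                             breast_axes = NULL, pectoral_fraction = 0.18,
                             dense_fraction = 0.2, dense_eccentricity = 0.5,
                             streak_intensity = 0.3, noise_sd = 40,
                             nametag = TRUE, laterality = "left", seed = 1L) {
  if (height <= 0 || width <= 0)
    stop("image dimensions must be positive", call. = FALSE)
  if (is.null(breast_axes)) breast_axes <- c(0.45 * height, 0.8 * width)
  stopifnot_scalar(pectoral_fraction, "pectoral_fraction", 0, 0.3)
  if (!(dense_fraction > 0 && dense_fraction < 1))
    stop("dense_fraction must be in (0, 1)", call. = FALSE)
  if (!(dense_eccentricity >= 0 && dense_eccentricity < 1))
    stop("dense_eccentricity must be in [0, 1)", call. = FALSE)
  stopifnot_scalar(streak_intensity, "streak_intensity", 0)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 bit_depth = as.integer(bit_depth), breast_axes = breast_axes,
                 pectoral_fraction = pectoral_fraction,
                 dense_fraction = dense_fraction,
                 dense_eccentricity = dense_eccentricity,
                 streak_intensity = streak_intensity, noise_sd = noise_sd,
                 nametag = isTRUE(nametag),
                 laterality = match.arg(laterality, c("left", "right")),
                 seed = as.integer(seed)),
            class = "image_sim_params")
}

#' Generate a synthetic mammogram with ground truth
#'
#' Builds the phantom described in \code{\link{image_sim_params}} in a
#' chest-wall-left frame and mirrors it for right laterality. The result is
#' deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param params an \code{\link{image_sim_params}} object
#' @return list with elements \code{image} (a \code{\link{mammogram}}) and
#'   \code{truth} (ground-truth \code{silhouette}, \code{pectoral} and
#'   \code{dense} masks plus the params)
#' @export
generate_breast_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  p <- params
  with_local_seed(p$seed, {
    h <- p$height; w <- p$width
    maxI <- 2^p$bit_depth - 1
    lev <- sim_intensity_levels * maxI

    r <- matrix(seq_len(h), h, w)          # row index
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    a <- p$breast_axes[1]; b <- p$breast_axes[2]
    sil <- ((r - h / 2) / a)^2 + ((cc - 1) / b)^2 <= 1

    # pectoral triangle in the upper chest-wall corner
    if (p$pectoral_fraction > 0) {
      hp <- 2 * p$pectoral_fraction * h
      wp <- 2 * p$pectoral_fraction * w
      pect <- sil & ((r - 1) / hp + (cc - 1) / wp <= 1)
    } else pect <- matrix(FALSE, h, w)

    allowed <- sil & !pect
    n_target <- p$dense_fraction * sum(allowed)

    # dense region: level set of an anisotropic Gaussian, i.e. a rotated
    # ellipse with the requested eccentricity and pixel count
    rho <- sqrt(1 - p$dense_eccentricity^2)  # minor/major axis ratio
    ae <- sqrt(n_target / (pi * rho)); be <- rho * ae
    theta <- runif(1, 0, pi)
    rc <- 0.60 * h; ccen <- 0.33 * w
    dr <- r - rc; dc <- cc - ccen
    u <- cos(theta) * dc + sin(theta) * dr   # ellipse frame
    v <- -sin(theta) * dc + cos(theta) * dr
    ell <- (u / ae)^2 + (v / be)^2 <= 1
    dense <- ell & allowed
    if (sum(dense) < 0.97 * sum(ell) || sum(ell) == 0)
      stop("dense region cannot fit inside the breast silhouette; ",
           "reduce dense_fraction or dense_eccentricity", call. = FALSE)

    img <- matrix(lev[["background"]], h, w)
    img[sil] <- lev[["fat"]]
    img[dense] <- lev[["dense"]]
    img[pect] <- lev[["pectoral"]]

    # fatty streaks: sinusoidal channels in the ellipse frame, carved as
    # Gaussian-profile intensity dips through the dense region
    if (p$streak_intensity > 0) {
      depth <- p$streak_intensity * (lev[["dense"]] - lev[["fat"]])
      # streak count scales with the dense region so the carved walls stay a
      # small, outlier-like fraction of the dense pixels at any image size
      n_streak <- max(1L, min(3L, round(be / 10)))
      v0 <- runif(n_streak, -0.6, 0.6) * be
      phase <- runif(n_streak, 0, 2 * pi)
      freq <- runif(n_streak, 0.8, 1.6)
      sigma_w <- 1.5
      red <- matrix(0, h, w)
      idx <- which(dense)
      for (k in seq_len(n_streak)) {
        vk <- v0[k] + 0.25 * be * sin(2 * pi * freq[k] * u[idx] / ae + phase[k])
        red[idx] <- pmax(red[idx],
                         depth * exp(-((v[idx] - vk) / sigma_w)^2 / 2))
      }
      img <- img - red
    }

    if (p$nametag) {
      tag <- r >= 0.04 * h & r <= 0.16 * h & cc >= 0.72 * w & cc <= 0.94 * w
      tag <- tag & !sil                     # artifact is off-breast
      img[tag] <- lev[["nametag"]]
    }

    if (p$noise_sd > 0) img <- img + rnorm(h * w, 0, p$noise_sd)
    img <- round(pmin(pmax(img, 0), maxI))

    if (p$laterality == "right") {
      flip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
      img <- flip(img); sil <- flip(sil); pect <- flip(pect)
      dense <- flip(dense)
    }

    list(image = mammogram(img, bit_depth = p$bit_depth,
                           laterality = p$laterality,
                           id = sprintf("sim%06d", p$seed)),
         truth = list(silhouette = sil, pectoral = pect, dense = dense,
                      params = p))
  })
}

#' Write a simulated image plus its ground truth to disk
#'
#' Image as 16-bit TIFF, masks as 8-bit PNG, parameters and mask paths in a
#' JSON sidecar.
#'
#' @param sim result of \code{\link{generate_breast_image}}
#' @param dir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
write_simulated_image <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- sim$image$id
  paths <- c(image = file.path(dir, paste0(id, ".tif")),
             dense = file.path(dir, paste0(id, "_dense.png")),
             pectoral = file.path(dir, paste0(id, "_pectoral.png")),
             silhouette = file.path(dir, paste0(id, "_silhouette.png")),
             sidecar = file.path(dir, paste0(id, ".json")))
  write_mammogram(sim$image, paths[["image"]])
  write_mask(sim$truth$dense, paths[["dense"]])
  write_mask(sim$truth$pectoral, paths[["pectoral"]])
  write_mask(sim$truth$silhouette, paths[["silhouette"]])
  side <- c(unclass(sim$truth$params), list(paths = as.list(paths)))
  jsonlite::write_json(side, paths[["sidecar"]], auto_unbox = TRUE)
  invisible(paths)
}
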