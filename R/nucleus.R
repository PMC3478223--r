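#' NucleusImage: an 8-bit nucleus with its segmentation mask
#'
#' The unit record of the pipeline: a grayscale matrix (luminance 0-255,
#' origin top-left, row index = y), a same-shape logical mask marking
#' nuclear pixels, and an isotropic spatial calibration in micrometres per
#' pixel edge. Background pixels never enter any feature computation.
#'
#' @param gray integer matrix, values in `[0, 255]`
#' @param mask logical (or 0/1) matrix, same shape as `gray`
#' @param calibration micrometres per pixel edge, > 0
#' @param patient_id,nucleus_id identifier strings
#' @return object of class `nucleus_image`
#' @export
nucleus_image <- function(gray, mask, calibration = 0.1,
                          patient_id = "p0", nucleus_id = "n0") {
  stopifnot(is.matrix(gray), is.matrix(mask))
  if (!identical(dim(gray), dim(mask))) {
    stop("gray and mask shapes differ: ", paste(dim(gray), collapse = "x"),
         " vs ", paste(dim(mask), collapse = "x"))
  }
  gray <- matrix(as.integer(gray), nrow(gray), ncol(gray))
  if (anyNA(gray) || any(gray < 0L) || any(gray > 255L)) {
    stop("gray values must lie in [0, 255]")
  }
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  if (anyNA(mask)) stop("mask must be binary with no missing values")
  if (sum(mask) < 50L) {
    stop("mask has ", sum(mask), " foreground pixels; at least 50 required")
  }
  if (!is.numeric(calibration) || length(calibration) != 1L || calibration <= 0) {
    stop("calibration must be a positive scalar (um per pixel)")
  }
  structure(
    list(gray = gray, mask = mask, calibration = as.numeric(calibration),
         patient_id = as.character(patient_id),
         nucleus_id = as.character(nucleus_id)),
    class = "nucleus_image"
  )
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat(sprintf(
    "<nucleus_image %s/%s: %dx%d px, %d foreground, %.3g um/px>\n",
    x$patient_id, x$nucleus_id, nrow(x$gray), ncol(x$gray),
    sum(x$mask), x$calibration))
  invisible(x)
}

#' Convert a 24-bit RGB image to 8-bit luminance
#'
#' Rec.601 weights, the standard for legacy 24-bit bitmaps:
#' `gray = round(0.299 R + 0.587 G + 0.114 B)`, clipped to `[0, 255]`.
#'
#' @param rgb integer `h x w x 3` array with channel values 0-255
#' @return integer matrix of luminance values
#' @export
rgb_to_gray <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L) {
    stop("expected a 3-channel RGB array, got dims ",
         paste(dim(rgb), collapse = "x"))
  }
  g <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  matrix(as.integer(pmin(pmax(round(g), 0), 255)), dim(rgb)[1], dim(rgb)[2])
}

#' Load a nucleus image and its mask from disk
#'
#' Reads PGM/PPM files. RGB input is converted to luminance with
#' [rgb_to_gray()]; inputs deeper than 8 bits are rescaled to 0-255 by a
#' linear min-max map then rounded; 8-bit grayscale passes through
#' unchanged. The mask is binarized at threshold 128 (foreground >= 128 on
#' its own maxval-normalized 0-255 scale).
#'
#' @param image_path path to the nucleus image (PGM or PPM)
#' @param mask_path path to the mask image (PGM, 0/255 convention)
#' @param calibration micrometres per pixel edge
#' @param patient_id,nucleus_id identifier strings
#' @return a [nucleus_image()]
#' @export
load_nucleus <- function(image_path, mask_path, calibration = 0.1,
                         patient_id = "p0", nucleus_id = "n0") {
  img <- read_pnm(image_path)
  msk <- read_pnm(mask_path)
  if (length(dim(img)) == 3L) img <- rgb_to_gray(img)
  maxval <- attr(img, "maxval")
  if (!is.null(maxval) && maxval > 255L) {
    rng <- range(img)
    img <- if (rng[2] > rng[1]) {
      round((img - rng[1]) / (rng[2] - rng[1]) * 255)
    } else {
      img * 0L
    }
    img <- matrix(as.integer(img), nrow(img), ncol(img))
  }
  if (length(dim(msk)) == 3L) msk <- rgb_to_gray(msk)
  mmax <- attr(msk, "maxval")
  if (!is.null(mmax) && mmax > 255L) msk <- round(msk / mmax * 255)
  if (!identical(dim(img), dim(msk))) {
    stop("image and mask shapes differ: ", image_path, " vs ", mask_path)
  }
  bin <- msk >= 128
  if (!any(bin)) stop("mask is empty after binarization: ", mask_path)
  nucleus_image(img, bin, calibration, patient_id, nucleus_id)
}

#' Otsu threshold segmentation fallback
#'
#' Convenience global-threshold mask for images lacking an external mask
#' (dark nucleus on bright background). Interactive segmentation quality is
#' not claimed; the validated pipeline path uses supplied masks.
#'
#' @param gray integer matrix 0-255
#' @return logical mask (`TRUE` = nucleus, the darker class)
#' @export
otsu_mask <- function(gray) {
  h <- tabulate(as.integer(gray) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * 0:255)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  t <- which.max(sigma_b) - 1L
  gray <= t
}
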