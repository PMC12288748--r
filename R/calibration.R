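#' Read an RGB image into a [0,1] pixel array
#'
#' Reads an 8- or 16-bit RGB PNG (or TIFF, if the \pkg{tiff} package is
#' available) and returns an H x W x 3 array of values in \[0, 1\]. Alpha
#' channels are dropped; grayscale images are expanded to three channels.
#'
#' @param path Path to a PNG or TIFF file.
#' @return An H x W x 3 numeric array.
#' @export
read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    img <- tiff::readTIFF(path)
  } else {
    img <- png::readPNG(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Construct a calibrated image object
#'
#' Container for a reflectance-scaled RGB pixel grid together with its
#' physical scale and replicate metadata.
#'
#' @param pixels H x W x 3 array of values in \[0, 1\].
#' @param mm_per_pixel Physical size of one pixel in mm (> 0), or `NA` if the
#'   scale has not been estimated yet.
#' @param turtle_id,view,replicate,source Replicate metadata. `view` must be
#'   one of `"top"`, `"left"`, `"right"`, `"front"`, `"back"`; `source` one of
#'   `"museum"`, `"field"`, `"synthetic"`.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, mm_per_pixel = NA_real_,
                             turtle_id = NA_character_, view = "top",
                             replicate = 1L, source = "synthetic") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3L] == 3L)
  view <- match.arg(view, c("top", "left", "right", "front", "back"))
  source <- match.arg(source, c("museum", "field", "synthetic"))
  if (!is.na(mm_per_pixel) && mm_per_pixel <= 0)
    stop("mm_per_pixel must be positive")
  structure(
    list(pixels = pixels, mm_per_pixel = mm_per_pixel,
         meta = list(turtle_id = turtle_id, view = view,
                     replicate = as.integer(replicate), source = source)),
    class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px", d[1L], d[2L]))
  if (!is.na(x$mm_per_pixel))
    cat(sprintf(", %.4g mm/px", x$mm_per_pixel))
  cat(sprintf("\n  turtle %s, %s view, replicate %d (%s)\n",
              x$meta$turtle_id, x$meta$view, x$meta$replicate, x$meta$source))
  invisible(x)
}

#' @export
plot.calibrated_image <- function(x, ...) {
  op <- graphics::par(mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  d <- dim(x$pixels)
  graphics::plot(NA, xlim = c(0, d[2L]), ylim = c(d[1L], 0), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  graphics::rasterImage(x$pixels, 0, d[1L], d[2L], 0, interpolate = FALSE)
  invisible(x)
}

.as_pixels <- function(image) {
  if (inherits(image, "calibrated_image")) image$pixels else image
}

#' Gray-card linear color calibration
#'
#' Scales each RGB channel so that the mean of the 18% reflectance gray card
#' region maps to the calibration target, then clips to \[0, 1\]. This is the
#' standard minimal linear gray-card model: channel gain
#' `target / mean(channel over card ROI)`.
#'
#' @param image H x W x 3 array in \[0, 1\] (raw pixel values), or a
#'   `calibrated_image` (re-calibration is then a no-op up to numerical
#'   tolerance when the same ROI is used).
#' @param card_roi Integer vector `c(row, col, height, width)` of the card
#'   region, 1-based, top-left anchored. Under uneven lighting any uniformly
#'   lit sub-section of the card may be supplied.
#' @param target Reflectance value the card is mapped to; default `0.18`.
#' @param ... Metadata passed to [calibrated_image()].
#' @return A `calibrated_image`.
#' @export
calibrate_gray_card <- function(image, card_roi, target = 0.18, ...) {
  px <- .as_pixels(image)
  d <- dim(px)
  r0 <- card_roi[1L]; c0 <- card_roi[2L]; h <- card_roi[3L]; w <- card_roi[4L]
  if (r0 < 1L || c0 < 1L || h < 1L || w < 1L ||
      r0 + h - 1L > d[1L] || c0 + w - 1L > d[2L])
    stop("card_roi out of image bounds")
  out <- px
  for (ch in 1:3) {
    mu <- mean(px[r0:(r0 + h - 1L), c0:(c0 + w - 1L), ch])
    if (mu <= 0) stop("degenerate card ROI: zero-mean channel")
    out[, , ch] <- pmin(1, pmax(0, px[, , ch] * (target / mu)))
  }
  if (inherits(image, "calibrated_image")) {
    image$pixels <- out
    image
  } else {
    calibrated_image(out, ...)
  }
}

#' Estimate the physical scale from the gray card edge
#'
#' The card has a known physical edge length (50 mm for the standard card);
#' counting the pixels along that edge gives the scale.
#'
#' @param card_edge_pixels Number of pixels along the card edge (> 0).
#' @param edge_mm Physical edge length in mm; default 50.
#' @return Scale in mm per pixel (`edge_mm / card_edge_pixels`).
#' @export
estimate_scale <- function(card_edge_pixels, edge_mm = 50) {
  if (!is.numeric(card_edge_pixels) || card_edge_pixels <= 0)
    stop("card_edge_pixels must be positive")
  edge_mm / card_edge_pixels
}

#' Construct a scute mask object
#'
#' @param mask Logical H x W matrix of scute interior pixels.
#' @param outline Logical H x W matrix of outline pixels; disjoint from mask.
#' @return An object of class `scute_mask`.
#' @export
scute_mask <- function(mask, outline) {
  stopifnot(is.logical(mask), is.logical(outline),
            identical(dim(mask), dim(outline)))
  if (!any(mask)) stop("scute mask is empty")
  if (any(mask & outline)) stop("mask and outline overlap")
  structure(list(mask = mask, outline = outline), class = "scute_mask")
}

#' @export
print.scute_mask <- function(x, ...) {
  cat(sprintf("<scute_mask> %d interior px, %d outline px (%d x %d frame)\n",
              sum(x$mask), sum(x$outline), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}

#' Extract the scute region from its colored outline
#'
#' The scute is hand-outlined in a color not occurring elsewhere in the image
#' (bright green, RGB (0,255,0), by convention). Outline pixels are matched
#' within a per-channel tolerance; the exterior is found by 4-connected flood
#' fill from the image border, and the interior is everything else minus the
#' outline. The interior must be a single non-empty 8-connected component.
#'
#' @param image `calibrated_image` or H x W x 3 array.
#' @param outline_rgb Outline color in \[0, 1\] units; default `c(0, 1, 0)`.
#' @param tolerance Per-channel matching tolerance; default 0 (exact match,
#'   appropriate for digitally drawn outlines).
#' @return A [scute_mask()].
#' @export
extract_scute_mask <- function(image, outline_rgb = c(0, 1, 0),
                               tolerance = 0) {
  px <- .as_pixels(image)
  eps <- tolerance + 1e-9
  outline <- abs(px[, , 1L] - outline_rgb[1L]) <= eps &
    abs(px[, , 2L] - outline_rgb[2L]) <= eps &
    abs(px[, , 3L] - outline_rgb[3L]) <= eps
  if (!any(outline)) stop("no outline found")
  ext <- exterior_region(outline, connectivity = 4L)
  interior <- !ext & !outline
  if (!any(interior)) stop("outline not closed / ambiguous: empty interior")
  lab <- label_matrix(interior, connectivity = 8L)
  if (max(lab) != 1L)
    stop("outline not closed / ambiguous: multiple interior regions")
  scute_mask(interior, outline)
}
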