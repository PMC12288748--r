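#' Configuration of the four-step pattern identification algorithm
#'
#' @param tau Dynamic threshold ratio applied to the scute-mean red-minus-blue
#'   value; default 1.10 (a pixel is pattern when its R - B exceeds 110% of
#'   the scute average).
#' @param min_object_mm2 Minimum connected-object size retained, mm^2;
#'   default 1.
#' @param max_hole_mm2 Holes strictly smaller than this are filled, mm^2;
#'   default 1.
#' @param opening_mm Side of the square structuring element used for the
#'   final morphological opening, mm; default 0.5.
#' @param connectivity Object connectivity, 4 or 8; default 8 (holes always
#'   use the complementary 4-connectivity).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(tau = 1.10, min_object_mm2 = 1.0,
                              max_hole_mm2 = 1.0, opening_mm = 0.5,
                              connectivity = 8L) {
  stopifnot(tau > 0, min_object_mm2 >= 0, max_hole_mm2 >= 0, opening_mm >= 0,
            connectivity %in% c(4L, 8L))
  structure(list(tau = tau, min_object_mm2 = min_object_mm2,
                 max_hole_mm2 = max_hole_mm2, opening_mm = opening_mm,
                 connectivity = as.integer(connectivity)),
            class = "extraction_config")
}

#' Construct a binary pattern object
#'
#' @param pattern Logical H x W matrix of pattern pixels.
#' @param mm_per_pixel Physical scale, mm per pixel (> 0).
#' @param config_used The [extraction_config()] that produced it, if any.
#' @return An object of class `binary_pattern`.
#' @export
binary_pattern <- function(pattern, mm_per_pixel, config_used = NULL) {
  stopifnot(is.logical(pattern), is.matrix(pattern), mm_per_pixel > 0)
  structure(list(pattern = pattern, mm_per_pixel = mm_per_pixel,
                 config_used = config_used),
            class = "binary_pattern")
}

#' @export
print.binary_pattern <- function(x, ...) {
  cat(sprintf("<binary_pattern> %d pattern px in %d x %d frame, %.3g mm/px\n",
              sum(x$pattern), nrow(x$pattern), ncol(x$pattern),
              x$mm_per_pixel))
  invisible(x)
}

#' @export
plot.binary_pattern <- function(x, ...) {
  img <- array(0, c(dim(x$pattern), 3L))
  img[, , 1L][x$pattern] <- 0.9
  img[, , 2L][x$pattern] <- 0.8
  plot(calibrated_image(img, x$mm_per_pixel), ...)
  invisible(x)
}

.mm2_to_px <- function(mm2, mm_per_pixel) round(mm2 * (1 / mm_per_pixel)^2)

#' Step 1: dynamic red-minus-blue thresholding
#'
#' Computes d = R - B at every pixel and marks a scute pixel as pre-pattern
#' when d exceeds `tau` times the scute-average d. The threshold adapts to
#' the overall yellowness of each scute; yellow consists of red and green
#' light and excludes blue, so a large R - B singles out yellow pixels on the
#' dark shell background. If the scute mean is not positive the rule is still
#' applied literally and a warning is raised.
#'
#' @param image `calibrated_image` (its `mm_per_pixel` is carried along) or
#'   an H x W x 3 array (then `mm_per_pixel` must be given).
#' @param mask A [scute_mask()] or logical matrix of scute pixels.
#' @param tau Threshold ratio; default 1.10.
#' @param mm_per_pixel Scale override when `image` is a bare array.
#' @return A [binary_pattern()] of the pre-pattern.
#' @export
yellow_prepattern <- function(image, mask, tau = 1.10, mm_per_pixel = NULL) {
  px <- .as_pixels(image)
  m <- if (inherits(mask, "scute_mask")) mask$mask else mask
  if (!any(m)) stop("empty scute mask")
  if (is.null(mm_per_pixel))
    mm_per_pixel <- if (inherits(image, "calibrated_image")) image$mm_per_pixel else NA_real_
  if (is.na(mm_per_pixel)) stop("mm_per_pixel unknown")
  d <- px[, , 1L] - px[, , 3L]
  mu <- mean(d[m])
  if (mu <= 0)
    warning("scute-average red-minus-blue is not positive; thresholding rule applied literally")
  binary_pattern(m & (d > tau * mu), mm_per_pixel,
                 config_used = extraction_config(tau = tau))
}

#' Step 2: removal of spurious small objects
#'
#' Deletes connected components smaller than `min_mm2` (converted to a pixel
#' count with `round()`, so 1 mm^2 is 25 px at 5 px/mm and 400 px at
#' 20 px/mm). Surviving components all have at least that many pixels; no
#' pixel is ever added.
#'
#' @param bp A [binary_pattern()].
#' @param min_mm2 Size threshold in mm^2; default 1.
#' @param connectivity 4 or 8; default 8.
#' @return A [binary_pattern()].
#' @export
remove_small_objects <- function(bp, min_mm2 = 1.0, connectivity = 8L) {
  stopifnot(inherits(bp, "binary_pattern"))
  min_px <- .mm2_to_px(min_mm2, bp$mm_per_pixel)
  if (min_px <= 1L || !any(bp$pattern)) return(bp)
  lab <- label_matrix(bp$pattern, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  bp$pattern <- matrix(lab %in% keep & lab > 0L, nrow(lab), ncol(lab))
  bp
}

#' Step 3: filling of small holes
#'
#' A hole is a 4-connected background component fully enclosed by pattern
#' pixels (it cannot be reached from the image border without crossing
#' pattern). Holes strictly smaller than `max_hole_mm2` (pixel count via
#' `round()`) are set to pattern; nothing else changes. Holes often arise
#' from glare or scattering making single pixels fail the yellow threshold
#' inside an otherwise solid pattern region.
#'
#' @param bp A [binary_pattern()].
#' @param max_hole_mm2 Hole size threshold in mm^2; default 1.
#' @return A [binary_pattern()].
#' @export
fill_small_holes <- function(bp, max_hole_mm2 = 1.0) {
  stopifnot(inherits(bp, "binary_pattern"))
  if (!any(bp$pattern)) return(bp)
  max_px <- .mm2_to_px(max_hole_mm2, bp$mm_per_pixel)
  if (max_px <= 1L) return(bp)
  ext <- exterior_region(bp$pattern, connectivity = 4L)
  holes <- !bp$pattern & !ext
  if (!any(holes)) return(bp)
  lab <- label_matrix(holes, connectivity = 4L)
  sizes <- tabulate(lab[lab > 0L])
  fill <- which(sizes < max_px)
  bp$pattern <- bp$pattern | (lab > 0L & matrix(lab %in% fill, nrow(lab), ncol(lab)))
  bp
}

#' Step 4: edge smoothing by morphological opening
#'
#' Erodes and then dilates the pattern with a square structuring element of
#' physical side `opening_mm` (0.5 mm by default; at least 1 px). This
#' removes thin protrusions and one-pixel bridges between objects without
#' changing the bulk of each object, and is idempotent.
#'
#' @param bp A [binary_pattern()].
#' @param opening_mm Structuring element side in mm; default 0.5.
#' @return A [binary_pattern()]; always a subset of the input.
#' @export
smooth_edges <- function(bp, opening_mm = 0.5) {
  stopifnot(inherits(bp, "binary_pattern"))
  k <- max(1L, as.integer(round(opening_mm / bp$mm_per_pixel)))
  bp$pattern <- open_square(bp$pattern, k)
  bp
}

#' Full four-step pattern extraction
#'
#' Applies, in order: dynamic red-minus-blue thresholding (Step 1), removal
#' of small objects (Step 2), filling of small enclosed holes (Step 3), and
#' edge smoothing by opening (Step 4). The order is literal; fragments that
#' the opening shrinks below the Step 2 size are not re-filtered.
#'
#' @param image `calibrated_image` or H x W x 3 array.
#' @param mask A [scute_mask()] or logical matrix.
#' @param config An [extraction_config()].
#' @param mm_per_pixel Scale override when `image` is a bare array.
#' @return A [binary_pattern()] with `config_used` attached.
#' @export
extract_pattern <- function(image, mask, config = extraction_config(),
                            mm_per_pixel = NULL) {
  stopifnot(inherits(config, "extraction_config"))
  bp <- yellow_prepattern(image, mask, tau = config$tau,
                          mm_per_pixel = mm_per_pixel)
  bp <- remove_small_objects(bp, config$min_object_mm2, config$connectivity)
  bp <- fill_small_holes(bp, config$max_hole_mm2)
  bp <- smooth_edges(bp, config$opening_mm)
  bp$config_used <- config
  bp
}
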