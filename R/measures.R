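# The 19 pattern measurements.
#
# Measurements that are undefined on an input (empty pattern, empty
# background, degenerate denominators) return the NA sentinel rather than
# aborting; downstream statistics drop sentinels pairwise.

#' Names of the 19 pattern measurements
#'
#' @return Character vector: FA, E, PL, PA, H, S, B, Sy, ED, IC, Ob, OA, RC,
#'   BC, GC, YC, CR, OF, NO.
#' @export
measure_names <- function() {
  c("FA", "E", "PL", "PA", "H", "S", "B", "Sy", "ED", "IC",
    "Ob", "OA", "RC", "BC", "GC", "YC", "CR", "OF", "NO")
}

.pattern_mat <- function(pattern) {
  if (inherits(pattern, "binary_pattern")) pattern$pattern else pattern
}
.mask_mat <- function(mask) {
  if (inherits(mask, "scute_mask")) mask$mask else mask
}

#' Label pattern objects and compute per-object shape descriptors
#'
#' Connected-component labeling of the binary pattern, with per-object pixel
#' count, physical area, perimeter (Moore boundary-tracing polygon length
#' with diagonal steps counted sqrt(2)), eccentricity of the
#' moment-equivalent ellipse, and centroid. Eccentricity uses normalized
#' second central moments with the 1/12 pixel-extent correction, so a single
#' pixel has eccentricity 0 and an elongated one-pixel-wide line approaches 1.
#'
#' @param pattern A [binary_pattern()] or logical matrix.
#' @param connectivity 4 or 8; default 8.
#' @param mm_per_pixel Scale override for a bare matrix input.
#' @return An `object_set` data frame with one row per object: `label`,
#'   `pixel_count`, `area_mm2`, `perimeter_px`, `perimeter_mm`,
#'   `eccentricity`, `centroid_r`, `centroid_c`. Zero rows for an empty
#'   pattern.
#' @export
label_objects <- function(pattern, connectivity = 8L, mm_per_pixel = NULL) {
  m <- .pattern_mat(pattern)
  if (is.null(mm_per_pixel))
    mm_per_pixel <- if (inherits(pattern, "binary_pattern")) pattern$mm_per_pixel else 1
  lab <- label_matrix(m, connectivity)
  n <- max(lab)
  out <- data.frame(label = integer(0), pixel_count = integer(0),
                    area_mm2 = numeric(0), perimeter_px = numeric(0),
                    perimeter_mm = numeric(0), eccentricity = numeric(0),
                    centroid_r = numeric(0), centroid_c = numeric(0))
  if (n == 0L) return(structure(out, class = c("object_set", "data.frame")))
  idx <- which(lab > 0L, arr.ind = TRUE)
  labs <- lab[lab > 0L]
  rows <- lapply(seq_len(n), function(k) {
    co <- idx[labs == k, , drop = FALSE]
    npx <- nrow(co)
    cr <- mean(co[, 1L]); cc <- mean(co[, 2L])
    # normalized second central moments of unit-square pixels
    uxx <- sum((co[, 1L] - cr)^2) / npx + 1 / 12
    uyy <- sum((co[, 2L] - cc)^2) / npx + 1 / 12
    uxy <- sum((co[, 1L] - cr) * (co[, 2L] - cc)) / npx
    common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
    l1 <- (uxx + uyy + common) / 2
    l2 <- (uxx + uyy - common) / 2
    ecc <- if (l1 <= 0) 0 else sqrt(max(0, 1 - l2 / l1))
    per <- trace_perimeter(co)
    data.frame(label = k, pixel_count = npx,
               area_mm2 = npx * mm_per_pixel^2,
               perimeter_px = per, perimeter_mm = per * mm_per_pixel,
               eccentricity = ecc, centroid_r = cr, centroid_c = cc)
  })
  structure(do.call(rbind, rows), class = c("object_set", "data.frame"))
}

#' Fractional area of the pattern
#'
#' Pattern pixel count divided by scute pixel count.
#'
#' @param pattern A [binary_pattern()] or logical matrix.
#' @param mask A [scute_mask()] or logical matrix.
#' @return FA in \[0, 1\].
#' @export
fractional_area <- function(pattern, mask) {
  p <- .pattern_mat(pattern); m <- .mask_mat(mask)
  if (!any(m)) stop("empty scute mask")
  sum(p & m) / sum(m)
}

#' Peak length: characteristic pattern spacing
#'
#' Skeletonizes the pattern within the scute and, separately, the non-pattern
#' within the scute, and returns
#' `2 * scute_px / (pattern_skeleton_px + background_skeleton_px) * mm_per_pixel`.
#' For a striped pattern this recovers the stripe period.
#'
#' @param pattern A [binary_pattern()] or logical matrix.
#' @param mask A [scute_mask()] or logical matrix.
#' @param mm_per_pixel Scale override for a bare matrix input.
#' @return PL in mm, or `NA` when both skeletons are empty.
#' @export
peak_length <- function(pattern, mask, mm_per_pixel = NULL) {
  p <- .pattern_mat(pattern); m <- .mask_mat(mask)
  if (is.null(mm_per_pixel))
    mm_per_pixel <- if (inherits(pattern, "binary_pattern")) pattern$mm_per_pixel else 1
  # crop to the scute bounding box (plus margin): thinning is local, and the
  # frame outside the scute contributes nothing to either skeleton
  bb <- which(m, arr.ind = TRUE)
  rs <- max(1L, min(bb[, 1L]) - 1L):min(nrow(m), max(bb[, 1L]) + 1L)
  cs <- max(1L, min(bb[, 2L]) - 1L):min(ncol(m), max(bb[, 2L]) + 1L)
  p <- p[rs, cs, drop = FALSE]; m <- m[rs, cs, drop = FALSE]
  sk1 <- sum(skeletonize(p & m))
  sk2 <- sum(skeletonize(m & !p))
  if (sk1 + sk2 == 0L) return(NA_real_)
  2 * sum(m) / (sk1 + sk2) * mm_per_pixel
}

#' Perimeter-to-area ratio of the pattern objects
#'
#' Mean object perimeter divided by mean object area, in physical units
#' (1/mm): wide compact objects score low, long thin objects high.
#'
#' @param objects An `object_set` from [label_objects()].
#' @return PA in 1/mm, or `NA` for an empty object set.
#' @export
perimeter_area_ratio <- function(objects) {
  if (nrow(objects) == 0L) return(NA_real_)
  mean(objects$perimeter_mm) / mean(objects$area_mm2)
}

#' Mean hue, saturation and brightness of the pattern pixels
#'
#' Converts pattern pixels from RGB to HSB (hue on \[0, 1\): 0 red, 1/3
#' green, 2/3 blue) and returns the arithmetic means.
#'
#' @param image `calibrated_image` or H x W x 3 array.
#' @param pattern A [binary_pattern()] or logical matrix.
#' @return Named vector `c(H=, S=, B=)`, or all `NA` for an empty pattern.
#' @export
mean_hsb <- function(image, pattern) {
  px <- .as_pixels(image); p <- .pattern_mat(pattern)
  if (!any(p)) return(c(H = NA_real_, S = NA_real_, B = NA_real_))
  hsv <- grDevices::rgb2hsv(rbind(px[, , 1L][p], px[, , 2L][p], px[, , 3L][p]),
                            maxColorValue = 1)
  c(H = mean(hsv[1L, ]), S = mean(hsv[2L, ]), B = mean(hsv[3L, ]))
}

#' Channel contrasts between pattern and non-pattern
#'
#' Differences of channel means over pattern pixels versus non-pattern scute
#' pixels: red (RC), green (GC), blue (BC), yellow (YC, where yellow =
#' min(R, G) per pixel), grayscale intensity (IC, luma weights
#' 0.2989/0.5870/0.1140), and the Euclidean color distance
#' `ED = sqrt(RC^2 + GC^2 + BC^2)`.
#'
#' @param image `calibrated_image` or H x W x 3 array.
#' @param pattern A [binary_pattern()] or logical matrix.
#' @param mask A [scute_mask()] or logical matrix.
#' @return Named vector `c(RC=, GC=, BC=, YC=, IC=, ED=)`; all `NA` when the
#'   pattern or the non-pattern set is empty.
#' @export
channel_contrasts <- function(image, pattern, mask) {
  px <- .as_pixels(image)
  p <- .pattern_mat(pattern) & .mask_mat(mask)
  np <- .mask_mat(mask) & !p
  if (!any(p) || !any(np))
    return(c(RC = NA_real_, GC = NA_real_, BC = NA_real_, YC = NA_real_,
             IC = NA_real_, ED = NA_real_))
  R <- px[, , 1L]; G <- px[, , 2L]; B <- px[, , 3L]
  y <- pmin(R, G)
  gray <- 0.2989 * R + 0.5870 * G + 0.1140 * B
  rc <- mean(R[p]) - mean(R[np])
  gc <- mean(G[p]) - mean(G[np])
  bc <- mean(B[p]) - mean(B[np])
  c(RC = rc, GC = gc, BC = bc,
    YC = mean(y[p]) - mean(y[np]),
    IC = mean(gray[p]) - mean(gray[np]),
    ED = sqrt(rc^2 + gc^2 + bc^2))
}

#' Centrality ratio of the pattern
#'
#' Mean Euclidean distance of pattern pixels to the scute centroid divided by
#' the same mean for non-pattern scute pixels; below 1 for center-heavy
#' patterns.
#'
#' @param pattern A [binary_pattern()] or logical matrix.
#' @param mask A [scute_mask()] or logical matrix.
#' @return CR, or `NA` when the pattern or non-pattern set is empty.
#' @export
centrality_ratio <- function(pattern, mask) {
  p <- .pattern_mat(pattern) & .mask_mat(mask)
  m <- .mask_mat(mask)
  np <- m & !p
  if (!any(p) || !any(np)) return(NA_real_)
  co_m <- which(m, arr.ind = TRUE)
  ctr <- colMeans(co_m)
  dist_to_ctr <- function(co) sqrt((co[, 1L] - ctr[1L])^2 + (co[, 2L] - ctr[2L])^2)
  mean(dist_to_ctr(which(p, arr.ind = TRUE))) /
    mean(dist_to_ctr(which(np, arr.ind = TRUE)))
}

#' Occupation factor: convex-hull coverage of the scute
#'
#' Pixel count of the filled convex hull of all pattern pixels divided by the
#' scute pixel count. Hull pixels outside a non-convex scute still count, so
#' OF can exceed 1 in principle and always satisfies OF >= FA.
#'
#' @param pattern A [binary_pattern()] or logical matrix.
#' @param mask A [scute_mask()] or logical matrix.
#' @return OF, or `NA` for an empty pattern.
#' @export
occupation_factor <- function(pattern, mask) {
  p <- .pattern_mat(pattern); m <- .mask_mat(mask)
  if (!any(m)) stop("empty scute mask")
  if (!any(p)) return(NA_real_)
  hull <- convex_hull_mask(which(p, arr.ind = TRUE), nrow(p), ncol(p))
  sum(hull) / sum(m)
}

#' Normalized offset of the pattern centroid
#'
#' Distance between the pattern centroid and the scute centroid, normalized
#' by the scute radius `sqrt(scute pixel count)`.
#'
#' @param pattern A [binary_pattern()] or logical matrix.
#' @param mask A [scute_mask()] or logical matrix.
#' @return NO, or `NA` for an empty pattern.
#' @export
normalized_offset <- function(pattern, mask) {
  p <- .pattern_mat(pattern); m <- .mask_mat(mask)
  if (!any(m)) stop("empty scute mask")
  if (!any(p)) return(NA_real_)
  cp <- colMeans(which(p, arr.ind = TRUE))
  cm <- colMeans(which(m, arr.ind = TRUE))
  sqrt(sum((cp - cm)^2)) / sqrt(sum(m))
}

#' Compute all 19 pattern measurements
#'
#' @param image `calibrated_image` or H x W x 3 array.
#' @param mask A [scute_mask()] or logical matrix.
#' @param pattern A [binary_pattern()] (or logical matrix with
#'   `mm_per_pixel` supplied).
#' @param grid [symmetry_grid()] for the symmetry search.
#' @param connectivity Object connectivity; default 8.
#' @param mm_per_pixel Scale override for bare-matrix input.
#' @return A `measure_set`: named numeric vector of the 19 measurements with
#'   replicate metadata attached as attributes. Undefined values are `NA`
#'   sentinels; an empty pattern yields FA = 0 and sentinels for all
#'   pattern-conditional measures.
#' @export
measure_all <- function(image, mask, pattern, grid = symmetry_grid(),
                        connectivity = 8L, mm_per_pixel = NULL) {
  px <- .as_pixels(image)
  m <- .mask_mat(mask)
  p <- .pattern_mat(pattern)
  if (is.null(mm_per_pixel))
    mm_per_pixel <- if (inherits(pattern, "binary_pattern")) pattern$mm_per_pixel
                    else if (inherits(image, "calibrated_image")) image$mm_per_pixel
                    else 1
  objs <- label_objects(p, connectivity, mm_per_pixel)
  hsb <- mean_hsb(px, p)
  con <- channel_contrasts(px, p, m)
  out <- c(
    FA = fractional_area(p, m),
    E  = if (nrow(objs)) mean(objs$eccentricity) else NA_real_,
    PL = peak_length(p, m, mm_per_pixel),
    PA = perimeter_area_ratio(objs),
    H  = unname(hsb["H"]), S = unname(hsb["S"]), B = unname(hsb["B"]),
    Sy = symmetry_index(p, grid),
    ED = unname(con["ED"]), IC = unname(con["IC"]),
    Ob = nrow(objs),
    OA = if (nrow(objs)) mean(objs$area_mm2) else NA_real_,
    RC = unname(con["RC"]), BC = unname(con["BC"]), GC = unname(con["GC"]),
    YC = unname(con["YC"]),
    CR = centrality_ratio(p, m),
    OF = occupation_factor(p, m),
    NO = normalized_offset(p, m))
  meta <- if (inherits(image, "calibrated_image")) image$meta else NULL
  structure(out[measure_names()], meta = meta,
            mm_per_pixel = mm_per_pixel, class = "measure_set")
}

#' @export
print.measure_set <- function(x, digits = 4, ...) {
  meta <- attr(x, "meta")
  if (!is.null(meta))
    cat(sprintf("<measure_set> turtle %s, %s view, replicate %d\n",
                meta$turtle_id, meta$view, meta$replicate))
  else cat("<measure_set>\n")
  print(round(unclass(x)[measure_names()], digits))
  invisible(x)
}

#' @export
summary.measure_set <- function(object, ...) {
  v <- unclass(object)
  cat(sprintf("19 pattern measurements (%d defined, %d NA sentinels)\n",
              sum(!is.na(v)), sum(is.na(v))))
  print.measure_set(object, ...)
  invisible(object)
}
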