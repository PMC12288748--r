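# Synthetic scute scenes with exact ground truth.
#
# A scene is a dark scute delimited by a closed bright-green outline, yellow
# pattern objects inside it, and a uniform gray-card patch elsewhere in the
# frame. Geometry is defined in continuous coordinates and rasterized by
# pixel-center inclusion, so every ground-truth count is an exact pixel tally.

# Evaluate with a temporary RNG state so generators do not disturb the
# caller's random stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a pattern object for a synthetic scene
#'
#' @param shape One of `"disc"`, `"stripe"`, `"blob"`.
#' @param center Numeric `c(row, col)` center in pixel coordinates.
#' @param radius_mm Disc/blob radius in mm (discs and blobs).
#' @param width_mm,length_mm Stripe extent in mm: `width_mm` along columns,
#'   `length_mm` along rows.
#' @param rgb Object color, three values in \[0, 1\].
#' @return An `object_spec` list.
#' @export
object_spec <- function(shape = c("disc", "stripe", "blob"), center,
                        radius_mm = NULL, width_mm = NULL, length_mm = NULL,
                        rgb = c(0.80, 0.65, 0.15)) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2L, length(rgb) == 3L,
            all(rgb >= 0), all(rgb <= 1))
  if (shape %in% c("disc", "blob")) stopifnot(is.numeric(radius_mm), radius_mm > 0)
  if (shape == "stripe") stopifnot(is.numeric(width_mm), width_mm > 0,
                                   is.numeric(length_mm), length_mm > 0)
  structure(list(shape = shape, center = as.numeric(center),
                 radius_mm = radius_mm, width_mm = width_mm,
                 length_mm = length_mm, rgb = rgb),
            class = "object_spec")
}

#' Specify a synthetic scute scene
#'
#' @param image_size Integer `c(H, W)` in pixels.
#' @param scute_polygon Two-column matrix of `(row, col)` vertices of the
#'   scute boundary, in pixel coordinates.
#' @param background_rgb Scute/background color, three values in \[0, 1\].
#' @param objects List of [object_spec()]s; all must lie strictly inside the
#'   scute interior.
#' @param card_rect Integer `c(row, col, height, width)` of the gray-card
#'   patch; must not intersect the scute polygon.
#' @param card_rgb Card pixel value (identical in all channels), in (0, 1\].
#' @param mm_per_pixel True physical scale (> 0).
#' @param noise_sd Per-channel additive Gaussian noise sd; default 0.
#' @param seed Integer seed controlling the noise draw.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_size, scute_polygon, background_rgb = c(0.12, 0.10, 0.08),
                       objects = list(), card_rect, card_rgb = 0.36,
                       mm_per_pixel = 0.2, noise_sd = 0, seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 8L),
            is.matrix(scute_polygon), ncol(scute_polygon) == 2L,
            nrow(scute_polygon) >= 3L,
            length(background_rgb) == 3L, all(background_rgb >= 0),
            all(background_rgb <= 1),
            length(card_rect) == 4L, all(card_rect >= 1L),
            length(card_rgb) == 1L, card_rgb > 0, card_rgb <= 1,
            mm_per_pixel > 0, noise_sd >= 0)
  if (card_rect[1L] + card_rect[3L] - 1L > image_size[1L] ||
      card_rect[2L] + card_rect[4L] - 1L > image_size[2L])
    stop("card_rect out of frame")
  # card must not intersect the polygon's bounding box (a fortiori its interior)
  if (card_rect[1L] <= max(scute_polygon[, 1L]) &&
      card_rect[1L] + card_rect[3L] - 1L >= min(scute_polygon[, 1L]) &&
      card_rect[2L] <= max(scute_polygon[, 2L]) &&
      card_rect[2L] + card_rect[4L] - 1L >= min(scute_polygon[, 2L]))
    stop("card_rect intersects the scute region")
  structure(list(image_size = as.integer(image_size),
                 scute_polygon = scute_polygon,
                 background_rgb = background_rgb, objects = objects,
                 card_rect = as.integer(card_rect), card_rgb = card_rgb,
                 mm_per_pixel = mm_per_pixel, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default synthetic study scene
#'
#' A 260 x 640 frame at 5 px/mm (within the 5-20 px/mm range of calibrated
#' field photographs) holding a hexagonal scute about 40 mm across on the
#' left and a true-size 50 x 30 mm gray-card patch on the right, with three
#' well-separated yellow discs and mild sensor noise.
#'
#' @param seed Integer seed for the noise draw.
#' @param objects Optional replacement object list.
#' @param noise_sd Per-channel Gaussian noise sd; default 0.005.
#' @return A [scene_spec()].
#' @export
default_scene_spec <- function(seed = 1L, objects = NULL, noise_sd = 0.005) {
  poly <- cbind(c(30, 30, 130, 230, 230, 130),
                c(90, 210, 290, 210, 90, 10))
  if (is.null(objects)) {
    objects <- list(
      object_spec("disc", center = c(90, 110), radius_mm = 4.0),
      object_spec("disc", center = c(150, 190), radius_mm = 5.0),
      object_spec("disc", center = c(180, 90), radius_mm = 3.0))
  }
  scene_spec(image_size = c(260L, 640L), scute_polygon = poly,
             objects = objects,
             card_rect = c(6L, 370L, 250L, 150L),  # 50 mm x 30 mm at 5 px/mm
             card_rgb = 0.36, mm_per_pixel = 0.2,
             noise_sd = noise_sd, seed = seed)
}

# Rasterize one object spec to a logical matrix.
.rasterize_object <- function(obj, H, W, mm_per_pixel) {
  out <- matrix(FALSE, H, W)
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  if (obj$shape == "disc") {
    rad <- obj$radius_mm / mm_per_pixel
    sel <- (rr - obj$center[1L])^2 + (cc - obj$center[2L])^2 <= rad^2
  } else if (obj$shape == "stripe") {
    hw <- obj$width_mm / mm_per_pixel / 2
    hl <- obj$length_mm / mm_per_pixel / 2
    sel <- abs(cc - obj$center[2L]) <= hw & abs(rr - obj$center[1L]) <= hl
  } else {  # blob: main disc plus two fixed overlapping satellites
    rad <- obj$radius_mm / mm_per_pixel
    sel <- (rr - obj$center[1L])^2 + (cc - obj$center[2L])^2 <= rad^2
    s1 <- c(obj$center[1L] - 0.6 * rad, obj$center[2L] + 0.7 * rad)
    s2 <- c(obj$center[1L] + 0.7 * rad, obj$center[2L] - 0.5 * rad)
    sel <- sel |
      (rr - s1[1L])^2 + (cc - s1[2L])^2 <= (0.6 * rad)^2 |
      (rr - s2[1L])^2 + (cc - s2[2L])^2 <= (0.55 * rad)^2
  }
  out[cbind(rr[sel], cc[sel])] <- TRUE
  out
}

#' Generate a synthetic scute scene with ground truth
#'
#' Rasterizes the scene of a [scene_spec()]: scute fill by pixel-center
#' point-in-polygon inclusion, a 2 px thick exact-color green outline ring
#' just inside the polygon boundary, objects painted inside, the card patch
#' painted uniform, additive Gaussian noise, and the outline and card redrawn
#' exact afterwards. The ground truth records the true object count and
#' pixel areas, the true fractional area over the scute interior, the scale,
#' and the card edge length in pixels implied by a 50 mm card.
#'
#' @param spec A [scene_spec()].
#' @return A `scute_scene` list with elements `image` (H x W x 3 array),
#'   `truth`, and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_size[1L]; W <- spec$image_size[2L]
  rr <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  fill <- matrix(FALSE, H, W)
  fill[cbind(rr, cc)] <- points_in_polygon(rr, cc, spec$scute_polygon[, 1L],
                                           spec$scute_polygon[, 2L])
  if (!any(fill)) stop("scute polygon encloses no pixels")
  interior <- erode_square(erode_square(fill, 3L), 3L)  # 5x5 erosion: 2 px ring
  outline <- fill & !interior
  if (!any(interior)) stop("scute polygon too small for a 2 px outline ring")

  obj_masks <- lapply(spec$objects, .rasterize_object, H = H, W = W,
                      mm_per_pixel = spec$mm_per_pixel)
  for (i in seq_along(obj_masks)) {
    if (any(obj_masks[[i]] & !interior))
      stop(sprintf("object %d overlaps the scute outline or exterior", i))
    if (!any(obj_masks[[i]]))
      stop(sprintf("object %d rasterizes to no pixels", i))
  }

  img <- array(rep(spec$background_rgb, each = H * W), c(H, W, 3L))
  for (i in seq_along(obj_masks)) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[obj_masks[[i]]] <- spec$objects[[i]]$rgb[ch]
      img[, , ch] <- plane
    }
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed,
                     img + array(stats::rnorm(length(img), 0, spec$noise_sd),
                                 dim(img)))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }
  # card and outline painted last so they are exact
  cr <- spec$card_rect
  img[cr[1L]:(cr[1L] + cr[3L] - 1L), cr[2L]:(cr[2L] + cr[4L] - 1L), ] <- spec$card_rgb
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[outline] <- c(0, 1, 0)[ch]
    img[, , ch] <- plane
  }

  pattern_union <- Reduce(`|`, obj_masks, matrix(FALSE, H, W))
  truth <- list(
    n_objects = length(obj_masks),
    object_px = vapply(obj_masks, sum, integer(1L)),
    pattern_px = sum(pattern_union),
    interior_px = sum(interior),
    fractional_area = sum(pattern_union) / sum(interior),
    mm_per_pixel = spec$mm_per_pixel,
    card_edge_px = 50 / spec$mm_per_pixel,
    card_rect = cr,
    interior = interior,
    outline = outline,
    pattern = pattern_union)
  structure(list(image = img, truth = truth, spec = spec),
            class = "scute_scene")
}

#' @export
print.scute_scene <- function(x, ...) {
  cat(sprintf("<scute_scene> %d x %d px, %d object(s), true FA %.4f, %.3g mm/px\n",
              nrow(x$image), ncol(x$image), x$truth$n_objects,
              x$truth$fractional_area, x$truth$mm_per_pixel))
  invisible(x)
}

#' @export
plot.scute_scene <- function(x, ...) {
  plot(calibrated_image(x$image, x$truth$mm_per_pixel), ...)
}

#' Specify replicate-to-replicate acquisition jitter
#'
#' Emulates re-photographing the same scute: a multiplicative illumination
#' gain, a sub-pixel camera translation, and a small rotation. Jitter acts on
#' the scene geometry (polygon vertices and object centers are rotated and
#' shifted in continuous coordinates, then re-rasterized) and on color (gain),
#' with the green outline redrawn exact afterwards, matching a workflow where
#' outlines are drawn after calibration.
#'
#' @param gain_sd Sd of the multiplicative illumination gain (mean 1).
#' @param shift_px_sd Sd of the translation, pixels, each axis.
#' @param rot_deg_sd Sd of the rotation, degrees.
#' @param n_replicates Number of replicate images (>= 2).
#' @param seed Integer seed for the jitter draws.
#' @return A `jitter_spec` list.
#' @export
jitter_spec <- function(gain_sd = 0.05, shift_px_sd = 1.0, rot_deg_sd = 1.0,
                        n_replicates = 2L, seed = 1L) {
  stopifnot(gain_sd >= 0, shift_px_sd >= 0, rot_deg_sd >= 0,
            n_replicates >= 2L)
  structure(list(gain_sd = gain_sd, shift_px_sd = shift_px_sd,
                 rot_deg_sd = rot_deg_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "jitter_spec")
}

#' Generate jittered replicate images of one scene
#'
#' @param spec A [scene_spec()] describing the base scene.
#' @param jitter A [jitter_spec()].
#' @return List of `scute_scene`s of length `jitter$n_replicates`; each
#'   carries its own exact ground truth for the transformed geometry.
#' @export
generate_replicates <- function(spec, jitter) {
  stopifnot(inherits(spec, "scene_spec"), inherits(jitter, "jitter_spec"))
  n <- jitter$n_replicates
  draws <- with_seed(jitter$seed, list(
    gain = stats::rnorm(n, 1, jitter$gain_sd),
    dr = stats::rnorm(n, 0, jitter$shift_px_sd),
    dc = stats::rnorm(n, 0, jitter$shift_px_sd),
    theta = stats::rnorm(n, 0, jitter$rot_deg_sd) * pi / 180))
  ctr <- colMeans(spec$scute_polygon)
  rot_about <- function(pts, theta) {
    d <- sweep(pts, 2L, ctr)
    cbind(ctr[1L] + cos(theta) * d[, 1L] - sin(theta) * d[, 2L],
          ctr[2L] + sin(theta) * d[, 1L] + cos(theta) * d[, 2L])
  }
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$scute_polygon <- rot_about(spec$scute_polygon, draws$theta[i])
    sp$scute_polygon[, 1L] <- sp$scute_polygon[, 1L] + draws$dr[i]
    sp$scute_polygon[, 2L] <- sp$scute_polygon[, 2L] + draws$dc[i]
    sp$objects <- lapply(spec$objects, function(o) {
      nc <- rot_about(rbind(o$center), draws$theta[i])
      o$center <- c(nc[1L, 1L] + draws$dr[i], nc[1L, 2L] + draws$dc[i])
      o
    })
    g <- max(draws$gain[i], 0)
    sp$background_rgb <- pmin(1, spec$background_rgb * g)
    sp$card_rgb <- min(1, spec$card_rgb * g)
    sp$objects <- lapply(sp$objects, function(o) {
      o$rgb <- pmin(1, o$rgb * g); o
    })
    sp$seed <- (spec$seed + 1000L * i) %% .Machine$integer.max
    sc <- generate_scene(sp)
    sc$truth$gain <- draws$gain[i]
    sc$truth$replicate <- i
    sc
  })
}

#' Simulate a citizen-science survey matrix
#'
#' Binary votes drawn independently per (turtle, volunteer, category) with
#' category-specific application probabilities.
#'
#' @param n_turtles,n_volunteers Positive integers.
#' @param category_probs Nine probabilities in \[0, 1\], one per pattern
#'   category.
#' @param seed Integer seed.
#' @return A `survey_matrix`: list with a `votes` array
#'   (turtle x volunteer x category) and the fixed nine category labels.
#' @export
generate_survey <- function(n_turtles, n_volunteers,
                            category_probs = rep(0.3, 9L), seed = 1L) {
  stopifnot(n_turtles >= 1L, n_volunteers >= 1L,
            length(category_probs) == 9L,
            all(category_probs >= 0), all(category_probs <= 1))
  votes <- with_seed(seed, {
    v <- array(0L, c(n_turtles, n_volunteers, 9L))
    for (k in 1:9)
      v[, , k] <- matrix(stats::rbinom(n_turtles * n_volunteers, 1L,
                                       category_probs[k]),
                         n_turtles, n_volunteers)
    v
  })
  structure(list(votes = votes,
                 turtles = sprintf("t%03d", seq_len(n_turtles)),
                 categories = pattern_categories()),
            class = "survey_matrix")
}

#' The nine pattern categories used in the consensus survey
#'
#' @return Character vector of the nine category labels.
#' @export
pattern_categories <- function() {
  c("M-shaped", "Single spotted", "Striated", "Blotchy", "Spotted",
    "Speckled", "Banded", "Patchy", "Starburst")
}
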