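test_that("object labeling matches an independent propagation oracle", {
  set.seed(101)
  for (conn in c(4L, 8L)) {
    for (i in 1:4) {
      m <- rand_pattern(30, 30, 0.3)
      ours <- relabel_first_occurrence(scutepattern:::label_matrix(m, conn))
      oracle <- relabel_first_occurrence(label_oracle(m, conn))
      expect_identical(ours, oracle)
    }
  }
  # two disjoint 3 x 3 squares
  m <- matrix(FALSE, 12, 12); m[2:4, 2:4] <- TRUE; m[8:10, 8:10] <- TRUE
  objs <- label_objects(m, mm_per_pixel = 1)
  expect_equal(nrow(objs), 2L)
  expect_equal(objs$pixel_count, c(9L, 9L))
})

test_that("eccentricity separates discs from lines", {
  H <- 41; rr <- rep(1:H, times = H); cc <- rep(1:H, each = H)
  disc <- matrix((rr - 21)^2 + (cc - 21)^2 <= 15^2, H, H)
  e_disc <- label_objects(disc, mm_per_pixel = 1)$eccentricity
  expect_lt(e_disc, 0.1)
  line <- matrix(FALSE, 10, 40); line[5, 2:39] <- TRUE
  e_line <- label_objects(line, mm_per_pixel = 1)$eccentricity
  expect_gt(e_line, 0.99)
  # single pixel: degenerate moments give 0
  px1 <- matrix(FALSE, 5, 5); px1[3, 3] <- TRUE
  expect_equal(label_objects(px1, mm_per_pixel = 1)$eccentricity, 0)
})

test_that("fractional area and perimeter/area follow their formulas", {
  mask <- matrix(FALSE, 20, 20); mask[3:18, 3:18] <- TRUE   # 256 px
  pat <- matrix(FALSE, 20, 20); pat[5:12, 5:12] <- TRUE     # 64 px
  expect_equal(fractional_area(pat, mask), 0.25)
  expect_equal(fractional_area(mask, mask), 1)
  expect_equal(fractional_area(matrix(FALSE, 20, 20), mask), 0)
  expect_error(fractional_area(pat, matrix(FALSE, 20, 20)), "empty")

  # k x k square at scale s: perimeter 4(k-1) px, PA = 4(k-1) s / (k s)^2
  for (k in c(5, 9)) {
    s <- 0.2
    sq <- matrix(FALSE, 20, 20); sq[3:(2 + k), 3:(2 + k)] <- TRUE
    objs <- label_objects(sq, mm_per_pixel = s)
    expect_equal(objs$perimeter_px, 4 * (k - 1))
    expect_equal(perimeter_area_ratio(objs), 4 * (k - 1) * s / (k * s)^2)
  }
  # two identical objects have the same PA as one
  two <- matrix(FALSE, 30, 30)
  two[2:6, 2:6] <- TRUE; two[20:24, 20:24] <- TRUE
  one <- matrix(FALSE, 30, 30); one[2:6, 2:6] <- TRUE
  expect_equal(perimeter_area_ratio(label_objects(two, mm_per_pixel = 0.5)),
               perimeter_area_ratio(label_objects(one, mm_per_pixel = 0.5)))
  expect_true(is.na(perimeter_area_ratio(label_objects(matrix(FALSE, 5, 5),
                                                       mm_per_pixel = 1))))
})

test_that("peak length recovers the period of striped patterns", {
  # vertical stripes, period 16 px (8 on / 8 off), scale 1 mm/px; the frame
  # is large enough that thinning end-effects stay within the tolerance
  H <- 128; W <- 128
  mask <- matrix(TRUE, H, W)
  pat <- matrix(FALSE, H, W)
  for (c0 in seq(1, W, by = 16)) pat[, c0:(c0 + 7)] <- TRUE
  pl <- peak_length(pat, mask, mm_per_pixel = 1)
  expect_lt(abs(pl - 16), 2)
  # empty pattern still yields a finite value from the background skeleton
  pl0 <- peak_length(matrix(FALSE, H, W), mask, mm_per_pixel = 1)
  expect_true(is.finite(pl0))
})

test_that("mean HSB matches per-pixel conversion", {
  img <- flat_image(10, 10, c(1, 0, 0))
  pat <- matrix(TRUE, 10, 10)
  hsb <- mean_hsb(img, pat)
  expect_equal(unname(hsb["H"]), 0)          # pure red
  gray <- flat_image(10, 10, c(0.4, 0.4, 0.4))
  expect_equal(unname(mean_hsb(gray, pat)["S"]), 0)
  # mixed two-color patch: mean equals the direct per-pixel average
  img2 <- flat_image(10, 10, c(0.8, 0.6, 0.1))
  half <- matrix(FALSE, 10, 10); half[, 1:5] <- TRUE
  img2 <- paint(img2, half, c(0.2, 0.7, 0.3))
  direct <- rowMeans(grDevices::rgb2hsv(
    rbind(img2[, , 1][pat], img2[, , 2][pat], img2[, , 3][pat]),
    maxColorValue = 1))
  expect_equal(unname(mean_hsb(img2, pat)), unname(direct), tolerance = 1e-12)
  expect_true(all(is.na(mean_hsb(img2, matrix(FALSE, 10, 10)))))
})

test_that("channel contrasts reduce to channel means and the ED identity", {
  mask <- matrix(TRUE, 12, 12)
  pat <- matrix(FALSE, 12, 12); pat[3:8, 3:8] <- TRUE
  img <- flat_image(12, 12, c(0.2, 0.3, 0.25))
  img <- paint(img, pat, c(0.7, 0.6, 0.25))
  con <- channel_contrasts(img, pat, mask)
  expect_equal(unname(con["RC"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(con["GC"]), 0.3, tolerance = 1e-12)
  expect_equal(unname(con["BC"]), 0, tolerance = 1e-12)
  expect_equal(unname(con["YC"]), mean(pmin(0.7, 0.6)) - pmin(0.2, 0.3),
               tolerance = 1e-12)
  expect_equal(unname(con["ED"]),
               sqrt(con[["RC"]]^2 + con[["GC"]]^2 + con[["BC"]]^2),
               tolerance = 1e-12)
  # identical pattern and background colors: all six contrasts vanish
  flat <- flat_image(12, 12, c(0.3, 0.3, 0.3))
  expect_true(all(abs(channel_contrasts(flat, pat, mask)) < 1e-12))
  # empty non-pattern: sentinel
  expect_true(all(is.na(channel_contrasts(img, mask, mask))))
})

test_that("centrality, occupation and offset measure pattern geometry", {
  H <- 31; rr <- rep(1:H, times = H); cc <- rep(1:H, each = H)
  mask <- matrix((rr - 16)^2 + (cc - 16)^2 <= 14^2, H, H)
  central <- matrix((rr - 16)^2 + (cc - 16)^2 <= 4^2, H, H)
  expect_lt(centrality_ratio(central, mask), 1)

  # convex solid pattern: hull equals pattern, so OF = FA
  sq_mask <- matrix(FALSE, 20, 20); sq_mask[2:19, 2:19] <- TRUE
  sq <- matrix(FALSE, 20, 20); sq[5:10, 5:10] <- TRUE
  expect_equal(occupation_factor(sq, sq_mask), fractional_area(sq, sq_mask))
  # two distant dots: hull covers the joining segment, OF >> FA
  dots <- matrix(FALSE, 20, 20); dots[10, 3] <- TRUE; dots[10, 18] <- TRUE
  expect_gt(occupation_factor(dots, sq_mask),
            5 * fractional_area(dots, sq_mask))

  # random pattern: hull pixels match the add-a-point hull-area oracle
  set.seed(7)
  p <- rand_pattern(15, 15, 0.15)
  p[3, 3] <- TRUE; p[12, 13] <- TRUE
  hull <- scutepattern:::convex_hull_mask(which(p, arr.ind = TRUE), 15, 15)
  co <- which(p, arr.ind = TRUE)
  for (r in 1:15) for (c in 1:15) {
    expect_equal(hull[r, c], hull_contains_oracle(co, r, c),
                 info = sprintf("pixel (%d,%d)", r, c))
  }

  # normalized offset: centered pattern scores 0; single dot scores d/sqrt(N)
  expect_equal(normalized_offset(central, mask), 0, tolerance = 1e-12)
  dot <- matrix(FALSE, H, H); dot[16, 22] <- TRUE
  expect_equal(normalized_offset(dot, mask), 6 / sqrt(sum(mask)),
               tolerance = 1e-12)
})

test_that("measure_all returns the 19 named measures with sentinels", {
  sp <- default_scene_spec(seed = 41, objects = list(
    object_spec("disc", center = c(100, 100), radius_mm = 4),
    object_spec("disc", center = c(160, 200), radius_mm = 4),
    object_spec("disc", center = c(180, 80), radius_mm = 4)))
  sc <- generate_scene(sp)
  msk <- extract_scute_mask(sc$image)
  pat <- extract_pattern(sc$image, msk, mm_per_pixel = 0.2)
  ms <- measure_all(sc$image, msk, pat,
                    grid = symmetry_grid(angle_range = 20, angle_step = 10,
                                         refine_step = 10))
  expect_identical(names(ms), measure_names())
  expect_equal(length(unclass(ms)), 19L)
  expect_equal(unname(ms["Ob"]), 3)
  expect_equal(unname(ms["OA"]), pi * 4^2, tolerance = 0.05)
  expect_gte(unname(ms["OF"]), unname(ms["FA"]))
  expect_equal(unname(ms["ED"]),
               sqrt(ms[["RC"]]^2 + ms[["GC"]]^2 + ms[["BC"]]^2),
               tolerance = 1e-9)
  # sum of object pixel counts equals total pattern pixels
  objs <- label_objects(pat)
  expect_equal(sum(objs$pixel_count), sum(pat$pattern))

  # empty pattern: FA 0, pattern-conditional measures are sentinels
  empty <- binary_pattern(matrix(FALSE, nrow(msk$mask), ncol(msk$mask)), 0.2)
  ms0 <- measure_all(sc$image, msk, empty)
  expect_equal(unname(ms0["FA"]), 0)
  expect_equal(unname(ms0["Ob"]), 0)
  for (nm in c("E", "PA", "H", "S", "B", "Sy", "ED", "IC", "OA", "RC", "BC",
               "GC", "YC", "CR", "OF", "NO"))
    expect_true(is.na(ms0[[nm]]), info = nm)
})

test_that("all measures are invariant under a 90-degree rotation", {
  sp <- default_scene_spec(seed = 43, objects = list(
    object_spec("disc", center = c(100, 120), radius_mm = 4),
    object_spec("blob", center = c(170, 170), radius_mm = 5)))
  sc <- generate_scene(sp)
  msk <- extract_scute_mask(sc$image)
  pat <- extract_pattern(sc$image, msk, mm_per_pixel = 0.2)
  rot90_mat <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  rot90_img <- function(a) {
    out <- array(0, c(ncol(a), nrow(a), 3))
    for (ch in 1:3) out[, , ch] <- rot90_mat(a[, , ch])
    out
  }
  g <- symmetry_grid(angle_range = 180, angle_step = 15, refine_step = 15)
  m1 <- measure_all(sc$image, msk$mask, pat, grid = g, mm_per_pixel = 0.2)
  m2 <- measure_all(rot90_img(sc$image), rot90_mat(msk$mask),
                    binary_pattern(rot90_mat(pat$pattern), 0.2),
                    grid = g, mm_per_pixel = 0.2)
  exact <- setdiff(measure_names(), c("PL", "PA", "E", "Sy"))
  expect_equal(unclass(m1)[exact], unclass(m2)[exact], tolerance = 1e-9)
  # discretized operators are only near-invariant: thinning is anisotropic
  # (PL), boundary tracing can differ at corners (PA), and the symmetry
  # search rounds rotated coordinates with parity-dependent ties (Sy)
  expect_equal(m1[["PL"]], m2[["PL"]], tolerance = 0.1)
  expect_equal(m1[["PA"]], m2[["PA"]], tolerance = 0.01)
  expect_equal(m1[["E"]], m2[["E"]], tolerance = 1e-6)
  expect_equal(m1[["Sy"]], m2[["Sy"]], tolerance = 0.01)
})

test_that("labeling count agrees with EBImage on shared conventions", {
  skip_if_not_installed("EBImage")
  set.seed(55)
  for (i in 1:3) {
    m <- rand_pattern(25, 25, 0.3)
    ours <- max(scutepattern:::label_matrix(m, 4L))
    eb <- max(EBImage::bwlabel(m))  # EBImage labels 4-connected components
    expect_equal(ours, eb)
  }
})
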