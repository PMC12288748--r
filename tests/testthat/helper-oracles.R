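# Independent oracles and fixture builders shared across the test files.

# Exhaustive symmetry search: same discretization as symmetry_index (the
# grid is part of the definition) but overlap counted by naive set
# membership per (angle, translation), no FFT.
sym_oracle <- function(m, grid) {
  A <- which(m, arr.ind = TRUE); colnames(A) <- NULL
  B <- cbind(A[, 1], -A[, 2])
  tr <- grid$trans_range
  if (is.null(tr)) {
    bb <- c(diff(range(A[, 1])), diff(range(A[, 2]))) + 1
    tr <- ceiling(0.25 * max(bb))
  }
  offs <- scutepattern:::translation_offsets(tr, grid$trans_step)
  angles <- sort(unique(c(0, seq(-grid$angle_range, grid$angle_range,
                                 by = grid$angle_step))))
  cA <- round(colMeans(A))
  keyA <- paste(A[, 1], A[, 2])
  best <- 0
  for (th in angles) {
    Br <- scutepattern:::rotate_round_coords(B, th)
    bs <- cA - round(colMeans(Br))
    for (k in seq_len(nrow(offs))) {
      kk <- paste(Br[, 1] + bs[1] + offs[k, 1], Br[, 2] + bs[2] + offs[k, 2])
      best <- max(best, sum(kk %in% keyA))
    }
  }
  best / nrow(A)
}

# Connected-component labeling by iterative minimum-label propagation
# (a different algorithm from the package's seeded BFS).
label_oracle <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  lab[mask] <- which(mask)
  shift_int <- function(m, dr, dc) {
    out <- matrix(0L, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    new <- lab
    for (s in shifts) {
      nb <- shift_int(lab, s[1], s[2])
      upd <- mask & nb > 0L & (new == 0L | nb < new)
      new[upd] <- nb[upd]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# Canonical relabeling (first-occurrence order) so partitions can be compared.
relabel_first_occurrence <- function(lab) {
  out <- lab
  v <- lab[lab > 0L]
  map <- stats::setNames(seq_along(unique(v)), unique(v))
  out[lab > 0L] <- map[as.character(v)]
  out
}

# Convex-hull membership oracle: a pixel center is in the hull iff adding it
# leaves the hull area unchanged (shoelace on chull vertices).
hull_area <- function(coords) {
  u <- unique(coords)
  if (nrow(u) < 3L) return(0)
  hv <- grDevices::chull(u[, 2], u[, 1])
  p <- u[hv, , drop = FALSE]
  x <- p[, 2]; y <- p[, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

hull_contains_oracle <- function(coords, r, c) {
  base <- hull_area(coords)
  abs(hull_area(rbind(coords, c(r, c))) - base) < 1e-9
}

# Random sparse binary pattern.
rand_pattern <- function(H, W, p = 0.2) {
  matrix(stats::runif(H * W) < p, H, W)
}

# Deterministic random multi-disc scene honoring the recovery constraints:
# discs 3-5 mm radius, pairwise gaps well beyond twice the opening element,
# everything strictly inside the scute interior.
make_recovery_scene <- function(i) {
  for (attempt in 1:50) {
    sp <- tryCatch({
      objects <- scutepattern:::with_seed(100000L + 1000L * i + attempt, {
        k <- sample(2:4, 1)
        reps <- 0
        repeat {
          ctr_r <- stats::runif(k, 70, 190)
          ctr_c <- stats::runif(k, 60, 240)
          rad <- stats::runif(k, 3, 5)
          rad_px <- rad / 0.2
          ok <- TRUE
          if (k > 1) {
            dd <- as.matrix(stats::dist(cbind(ctr_r, ctr_c)))
            for (a in 1:(k - 1)) for (b in (a + 1):k)
              if (dd[a, b] < rad_px[a] + rad_px[b] + 12) ok <- FALSE
          }
          reps <- reps + 1
          if (ok || reps > 200) break
        }
        if (!ok) stop("no placement")
        lapply(seq_len(k), function(j)
          object_spec("disc", center = c(ctr_r[j], ctr_c[j]),
                      radius_mm = rad[j]))
      })
      spec <- default_scene_spec(seed = 7L * i + attempt, objects = objects)
      generate_scene(spec)  # errors if a disc leaves the interior
      spec
    }, error = function(e) NULL)
    if (!is.null(sp)) return(sp)
  }
  stop("could not build a valid recovery scene")
}

# Radial-gradient disc whose super-threshold fractional area is analytic:
# d(r) = d0 (1 - r/Rd) over a disc of radius Rd gives mean d0/3, so the
# pixels above tau * mean are exactly r < Rd (1 - tau/3) and
# FA(tau) = (1 - tau/3)^2.
radial_gradient_fixture <- function(H = 500, Rd = 240, d0 = 0.5) {
  ctr <- c(H / 2, H / 2)
  rr <- rep(1:H, times = H); cc <- rep(1:H, each = H)
  rad <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
  mask <- matrix(rad <= Rd, H, H)
  img <- array(0.1, c(H, H, 3))
  Rch <- matrix(0.1, H, H)
  Rch[mask] <- 0.1 + d0 * (1 - rad[mask] / Rd)
  img[, , 1] <- Rch
  list(image = img, mask = mask, mm_per_pixel = 0.5,
       fa_closed = function(tau) (1 - tau / 3)^2)
}

# Tiny uniform test image helpers.
flat_image <- function(H, W, rgb) {
  array(rep(rgb, each = H * W), c(H, W, 3))
}

paint <- function(img, mask, rgb) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}
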