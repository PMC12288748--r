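# Internal binary-image primitives.
#
# All operate on logical H x W matrices indexed [row, col], pixel centers at
# integer coordinates. Everything outside the image frame is background.

# Shift matrix content by (dr, dc); vacated cells get `fill`.
shift_mat <- function(m, dr, dc, fill = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Neighbor linear indices of `idx` (vector), clipped at the frame.
.neighbor_idx <- function(idx, H, W, connectivity = 4L) {
  r <- (idx - 1L) %% H + 1L
  up <- idx[r > 1L] - 1L
  dn <- idx[r < H] + 1L
  lf <- idx[idx > H] - H
  rt <- idx[idx <= H * (W - 1L)] + H
  out <- c(up, dn, lf, rt)
  if (connectivity == 8L) {
    ul <- idx[r > 1L & idx > H] - 1L - H
    dl <- idx[r < H & idx > H] + 1L - H
    ur <- idx[r > 1L & idx <= H * (W - 1L)] - 1L + H
    dr <- idx[r < H & idx <= H * (W - 1L)] + 1L + H
    out <- c(out, ul, dl, ur, dr)
  }
  out
}

# Region reachable from `seeds` through TRUE cells of `open`.
flood_fill <- function(open, seeds, connectivity = 4L) {
  H <- nrow(open); W <- ncol(open)
  visited <- matrix(FALSE, H, W)
  frontier <- seeds[open[seeds] & !visited[seeds]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nb <- unique(.neighbor_idx(frontier, H, W, connectivity))
    nb <- nb[open[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# Exterior: cells connected to the image border without crossing `blocked`.
exterior_region <- function(blocked, connectivity = 4L) {
  H <- nrow(blocked); W <- ncol(blocked)
  border <- unique(c(
    seq_len(H),                         # first column
    seq_len(H) + H * (W - 1L),          # last column
    1L + H * (seq_len(W) - 1L),         # first row
    H + H * (seq_len(W) - 1L)           # last row
  ))
  flood_fill(!blocked, border, connectivity)
}

# Connected-component labeling; returns integer matrix, 0 = background.
label_matrix <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  todo <- which(mask)
  cur <- 0L
  for (s in todo) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      nb <- unique(.neighbor_idx(frontier, H, W, connectivity))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

# Erosion / dilation by a k x k square structuring element. The anchor is at
# floor((k-1)/2); an opening (erode then dilate with the reflected element)
# equals the union of all k x k placements fully inside pattern and frame,
# so the result does not depend on the anchor convention.
erode_square <- function(m, k) {
  if (k <= 1L) return(m)
  a <- (k - 1L) %/% 2L
  offs <- 0:(k - 1L) - a
  out <- m
  for (i in offs) for (j in offs) {
    if (i == 0L && j == 0L) next
    out <- out & shift_mat(m, -i, -j, fill = FALSE)
  }
  out
}

dilate_square <- function(m, k) {
  if (k <= 1L) return(m)
  a <- (k - 1L) %/% 2L
  offs <- 0:(k - 1L) - a
  out <- m
  for (i in offs) for (j in offs) {
    if (i == 0L && j == 0L) next
    out <- out | shift_mat(m, i, j, fill = FALSE)
  }
  out
}

open_square <- function(m, k) dilate_square(erode_square(m, k), k)

# Zhang-Suen thinning to a unit-width skeleton.
skeletonize <- function(m) {
  m <- m * 1L
  sub_pass <- function(m, first) {
    P2 <- shift_mat(m == 1L, 1L, 0L) * 1L   # north neighbor value
    P3 <- shift_mat(m == 1L, 1L, -1L) * 1L  # north-east
    P4 <- shift_mat(m == 1L, 0L, -1L) * 1L  # east
    P5 <- shift_mat(m == 1L, -1L, -1L) * 1L # south-east
    P6 <- shift_mat(m == 1L, -1L, 0L) * 1L  # south
    P7 <- shift_mat(m == 1L, -1L, 1L) * 1L  # south-west
    P8 <- shift_mat(m == 1L, 0L, 1L) * 1L   # west
    P9 <- shift_mat(m == 1L, 1L, 1L) * 1L   # north-west
    B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
    A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) +
      (P4 == 0L & P5 == 1L) + (P5 == 0L & P6 == 1L) +
      (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
      (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
    if (first) {
      cond <- P2 * P4 * P6 == 0L & P4 * P6 * P8 == 0L
    } else {
      cond <- P2 * P4 * P8 == 0L & P2 * P6 * P8 == 0L
    }
    del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
    m[del] <- 0L
    list(m = m, changed = any(del))
  }
  repeat {
    s1 <- sub_pass(m, TRUE)
    s2 <- sub_pass(s1$m, FALSE)
    m <- s2$m
    if (!s1$changed && !s2$changed) break
  }
  m == 1L
}

# Moore-neighbor boundary tracing of one 8-connected object given as a
# coordinate matrix (r, c). Returns the closed-tour length with diagonal
# steps counted sqrt(2). Isolated pixels have length 0.
trace_perimeter <- function(coords) {
  n <- nrow(coords)
  if (n == 1L) return(0)
  rmin <- min(coords[, 1L]); cmin <- min(coords[, 2L])
  H <- max(coords[, 1L]) - rmin + 3L
  W <- max(coords[, 2L]) - cmin + 3L
  m <- matrix(FALSE, H, W)
  m[cbind(coords[, 1L] - rmin + 2L, coords[, 2L] - cmin + 2L)] <- TRUE
  # clockwise Moore neighborhood starting north
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  step_len <- sqrt(dr^2 + dc^2)
  # start at uppermost-then-leftmost pixel; its west and north are background
  ord <- order(coords[, 1L], coords[, 2L])
  cur <- c(coords[ord[1L], 1L] - rmin + 2L, coords[ord[1L], 2L] - cmin + 2L)
  start <- cur
  # backtrack initially to the west (direction index 7)
  back_dir <- 7L
  total <- 0
  second <- NULL
  steps <- 0L
  repeat {
    # scan clockwise starting just after the backtrack direction
    found <- NA_integer_
    for (s in 1:8) {
      d <- (back_dir + s - 1L) %% 8L + 1L
      nr <- cur[1L] + dr[d]; nc <- cur[2L] + dc[d]
      if (m[nr, nc]) { found <- d; break }
    }
    if (is.na(found)) return(0)  # unreachable for n > 1 within one 8-component
    nxt <- c(cur[1L] + dr[found], cur[2L] + dc[found])
    if (is.null(second)) {
      second <- nxt
    } else if (steps > 0L && all(cur == start) && all(nxt == second)) {
      break  # the tour is repeating its initial move: closed
    }
    total <- total + step_len[found]
    steps <- steps + 1L
    cur <- nxt
    back_dir <- (found + 3L) %% 8L + 1L  # direction back to the previous pixel
    if (steps > 4L * H * W) break        # safety net, never expected
  }
  total
}

# Filled convex hull of a pixel coordinate set, as a logical H x W matrix.
# A pixel belongs to the hull if its center is inside or on the hull polygon.
convex_hull_mask <- function(coords, H, W) {
  out <- matrix(FALSE, H, W)
  if (nrow(coords) == 0L) return(out)
  u <- unique(coords)
  segment_raster <- function(p1, p2) {
    n <- max(2L, 4L * (max(abs(p2 - p1)) + 1L))
    t <- seq(0, 1, length.out = n)
    unique(cbind(round(p1[1L] + t * (p2[1L] - p1[1L])),
                 round(p1[2L] + t * (p2[2L] - p1[2L]))))
  }
  degenerate <- function(pts) {
    # pixels along the segment joining the extreme points of a collinear set
    d <- sqrt(rowSums(sweep(pts, 2L, pts[1L, ])^2))
    i <- which.max(d)
    d2 <- sqrt(rowSums(sweep(pts, 2L, pts[i, ])^2))
    j <- which.max(d2)
    segment_raster(pts[i, ], pts[j, ])
  }
  if (nrow(u) <= 2L) {
    out[if (nrow(u) == 1L) u else degenerate(u)] <- TRUE
    return(out)
  }
  hv <- grDevices::chull(u[, 2L], u[, 1L])  # x = col, y = row
  poly <- u[hv, , drop = FALSE]
  nv <- nrow(poly)
  if (nv <= 2L) {  # collinear set: hull is the segment through the pixels
    out[degenerate(u)] <- TRUE
    return(out)
  }
  rr <- min(u[, 1L]):max(u[, 1L])
  cc <- min(u[, 2L]):max(u[, 2L])
  pr <- rep(rr, times = length(cc))
  pc <- rep(cc, each = length(rr))
  eps <- 1e-9
  pos <- rep(TRUE, length(pr))
  neg <- rep(TRUE, length(pr))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (poly[j, 1L] - poly[i, 1L]) * (pc - poly[i, 2L]) -
      (poly[j, 2L] - poly[i, 2L]) * (pr - poly[i, 1L])
    pos <- pos & cross >= -eps
    neg <- neg & cross <= eps
  }
  inside <- pos | neg
  out[cbind(pr[inside], pc[inside])] <- TRUE
  out
}

# Even-odd point-in-polygon test for pixel centers (vectorized pnpoly).
points_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(pr)
  nv <- length(vr)
  inside <- rep(FALSE, n)
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr)) &
      (pc < (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
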