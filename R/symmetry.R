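# Mirror-symmetry index via brute-force rigid-transform search.
#
# The pattern pixel set A is mirrored left-right to A'; the index is the
# maximum of |A intersect T(A')| / |A| over a discretized set of rigid
# transformations T (rotation about the mirrored set's centroid followed by
# an integer translation). Because the search covers rotations and
# translations of the mirror copy, the result does not depend on the initial
# mirror axis choice.

#' Discretization of the rigid-transform symmetry search
#'
#' @param angle_range Half-width of the rotation search, degrees;
#'   default 180 (all orientations).
#' @param angle_step Coarse rotation step, degrees; default 5.
#' @param refine_step Fine step used in a second pass around the best coarse
#'   angle; default 1. Set equal to `angle_step` to disable refinement.
#' @param trans_range Half-width of the translation search in px around the
#'   centroid-aligned position; `NULL` (default) uses 25% of the larger
#'   pattern bounding-box side.
#' @param trans_step Translation step in px; default 1.
#' @param downsample Integer block-reduction factor applied to patterns
#'   before the search; default 1 (none). A factor of 2 trades at most about
#'   0.02 of index accuracy for a four-fold smaller search.
#' @return A `symmetry_grid` list.
#' @export
symmetry_grid <- function(angle_range = 180, angle_step = 5, refine_step = 1,
                          trans_range = NULL, trans_step = 1L,
                          downsample = 1L) {
  stopifnot(angle_range >= 0, angle_step > 0, refine_step > 0,
            is.null(trans_range) || trans_range >= 0, trans_step > 0,
            downsample >= 1L)
  structure(list(angle_range = angle_range, angle_step = angle_step,
                 refine_step = refine_step, trans_range = trans_range,
                 trans_step = as.integer(trans_step),
                 downsample = as.integer(downsample)),
            class = "symmetry_grid")
}

# Rotate integer pixel coordinates about the set centroid, round to pixels,
# deduplicate. Shared by the search and by any exhaustive re-check: the
# discretization is part of the index definition.
rotate_round_coords <- function(coords, theta_deg) {
  th <- theta_deg * pi / 180
  ctr <- colMeans(coords)
  d1 <- coords[, 1L] - ctr[1L]
  d2 <- coords[, 2L] - ctr[2L]
  out <- cbind(round(ctr[1L] + cos(th) * d1 - sin(th) * d2),
               round(ctr[2L] + sin(th) * d1 + cos(th) * d2))
  unique(out)
}

# Candidate translations: integer offsets added to the rotated mirror copy
# after aligning rounded centroids, spanning +/- trans_range at trans_step.
translation_offsets <- function(trans_range, trans_step) {
  s <- seq(0L, as.integer(trans_range), by = as.integer(trans_step))
  v <- sort(unique(c(-s, s)))
  cbind(rep(v, times = length(v)), rep(v, each = length(v)))
}

.block_reduce <- function(m, f) {
  if (f <= 1L) return(m)
  H <- nrow(m); W <- ncol(m)
  Hc <- ceiling(H / f); Wc <- ceiling(W / f)
  out <- matrix(FALSE, Hc, Wc)
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx)) {
    out[cbind((idx[, 1L] - 1L) %/% f + 1L, (idx[, 2L] - 1L) %/% f + 1L)] <- TRUE
  }
  out
}

# Best overlap count over all integer translations for a fixed rotated copy,
# computed for every offset at once by FFT cross-correlation, then restricted
# to the candidate offsets. Exact: counts are integers recovered by rounding.
.best_overlap_fft <- function(A_idx, B_idx, offsets, base_shift) {
  # place both sets in a common frame large enough that differences are unique
  all_r <- c(A_idx[, 1L], B_idx[, 1L] + base_shift[1L])
  all_c <- c(A_idx[, 2L], B_idx[, 2L] + base_shift[2L])
  r0 <- min(all_r); c0 <- min(all_c)
  eR <- max(all_r) - r0 + 1L
  eC <- max(all_c) - c0 + 1L
  S1 <- 2L * eR + 1L
  S2 <- 2L * eC + 1L
  MA <- matrix(0, S1, S2)
  MB <- matrix(0, S1, S2)
  MA[cbind(A_idx[, 1L] - r0 + 1L, A_idx[, 2L] - c0 + 1L)] <- 1
  MB[cbind(B_idx[, 1L] + base_shift[1L] - r0 + 1L,
           B_idx[, 2L] + base_shift[2L] - c0 + 1L)] <- 1
  # C[t] = sum_p MA(p) * MB(p - t), t modulo (S1, S2). Restricting offsets to
  # |t| <= extent keeps the modular lookup alias-free; larger offsets cannot
  # beat the maximum since their true overlap is zero.
  C <- Re(stats::fft(stats::fft(MA) * Conj(stats::fft(MB)), inverse = TRUE)) /
    (S1 * S2)
  keep <- abs(offsets[, 1L]) <= eR & abs(offsets[, 2L]) <= eC
  offsets <- offsets[keep, , drop = FALSE]
  tr <- offsets[, 1L] %% S1
  tc <- offsets[, 2L] %% S2
  max(round(C[cbind(tr + 1L, tc + 1L)]))
}

#' Mirror-symmetry index of a binary pattern
#'
#' Searches a discretized set of rigid transformations (rotations of the
#' left-right mirror copy about its centroid, each followed by integer
#' translations around the centroid-aligned position) for the placement
#' maximizing pixel overlap with the original pattern, and returns that
#' overlap divided by the pattern pixel count (or by the union size when
#' `normalization = "union"`). A perfectly mirror-symmetric pattern scores 1.
#'
#' @param pattern A [binary_pattern()] or logical matrix.
#' @param grid A [symmetry_grid()].
#' @param normalization `"pattern"` (default; overlap / |A|, where the mirror
#'   copy has the same cardinality as A) or `"union"`.
#' @return The symmetry index in (0, 1\], or `NA` for an empty pattern.
#' @export
symmetry_index <- function(pattern, grid = symmetry_grid(),
                           normalization = c("pattern", "union")) {
  normalization <- match.arg(normalization)
  m <- if (inherits(pattern, "binary_pattern")) pattern$pattern else pattern
  if (!any(m)) return(NA_real_)
  if (grid$downsample > 1L && sum(m) > 1e4) {
    m <- .block_reduce(m, grid$downsample)
  }
  A <- which(m, arr.ind = TRUE)
  colnames(A) <- NULL
  B <- cbind(A[, 1L], -A[, 2L])  # left-right mirror
  trans_range <- grid$trans_range
  if (is.null(trans_range)) {
    bb <- c(diff(range(A[, 1L])), diff(range(A[, 2L]))) + 1
    trans_range <- ceiling(0.25 * max(bb))
  }
  offsets <- translation_offsets(trans_range, grid$trans_step)
  angles <- sort(unique(c(0, seq(-grid$angle_range, grid$angle_range,
                                 by = grid$angle_step))))
  cA <- round(colMeans(A))
  eval_angle <- function(th) {
    Br <- rotate_round_coords(B, th)
    base_shift <- cA - round(colMeans(Br))
    c(.best_overlap_fft(A, Br, offsets, base_shift), nrow(Br))
  }
  ov <- vapply(angles, eval_angle, numeric(2L))
  best_i <- which.max(ov[1L, ])
  best <- ov[1L, best_i]
  best_nB <- ov[2L, best_i]
  if (grid$refine_step < grid$angle_step) {
    fine <- seq(angles[best_i] - grid$angle_step,
                angles[best_i] + grid$angle_step, by = grid$refine_step)
    fine <- setdiff(fine, angles)
    if (length(fine)) {
      ovf <- vapply(fine, eval_angle, numeric(2L))
      fi <- which.max(ovf[1L, ])
      if (ovf[1L, fi] > best) {
        best <- ovf[1L, fi]
        best_nB <- ovf[2L, fi]
      }
    }
  }
  denom <- if (normalization == "pattern") nrow(A) else nrow(A) + best_nB - best
  best / denom
}
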