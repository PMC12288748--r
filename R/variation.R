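# Measurement-noise and between-individual variation analysis.
#
# A measure table is a long data frame with columns turtle_id, view,
# replicate, source, measure, value; sentinel values are NA and are dropped
# groupwise before each statistic.

.check_measure_table <- function(table) {
  need <- c("turtle_id", "view", "replicate", "measure", "value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("measure table lacks columns: ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Pairwise-difference coefficient of variation
#'
#' For two replicate measurements the relative variability is the absolute
#' difference divided by the pair mean; with only two values this is a more
#' faithful dispersion measure than the (downward-biased) two-point standard
#' deviation, and equals `sqrt(2)` times the standard CV of the pair.
#'
#' @param x1,x2 The two replicate values.
#' @return `|x1 - x2| / mean(x1, x2)`, or `NA` when the mean is zero.
#' @export
cv_pairwise <- function(x1, x2) {
  mu <- (x1 + x2) / 2
  ifelse(mu == 0, NA_real_, abs(x1 - x2) / mu)
}

#' Standard coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric vector with at least two non-missing values.
#' @return sd/mean, or `NA` for fewer than two values or a zero mean.
#' @export
cv_standard <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  mu <- mean(values)
  if (mu == 0) return(NA_real_)
  stats::sd(values) / mu
}

#' Within-individual (replicate) CV per measure and view
#'
#' For every (turtle, view, measure) group the replicate CV is the pairwise
#' CV for duplicates and the standard CV for three or more replicates; groups
#' with fewer than two replicates are skipped. Group CVs are averaged over
#' turtles per (measure, view), and per measure over the five views.
#'
#' With `normalization = "population"` the pairwise absolute difference (or
#' replicate sd) is instead divided by the mean of the measure across all
#' individuals for that viewpoint, an alternative normalization for
#' replicate noise relative to the population scale.
#'
#' @param table Long measure table (see above).
#' @param normalization `"pair"` (default) or `"population"`.
#' @return A data frame per (measure, view) with `within_cv` and `n_turtles`,
#'   plus attribute `"by_measure"`: per-measure mean and sd across views.
#' @export
within_individual_cv <- function(table, normalization = c("pair", "population")) {
  normalization <- match.arg(normalization)
  .check_measure_table(table)
  table <- table[!is.na(table$value), , drop = FALSE]
  rows <- list()
  for (ms in unique(table$measure)) {
    for (vw in unique(table$view)) {
      sub <- table[table$measure == ms & table$view == vw, , drop = FALSE]
      if (!nrow(sub)) next
      pop_mu <- mean(sub$value)
      cvs <- vapply(split(sub$value, sub$turtle_id), function(v) {
        if (length(v) < 2L) return(NA_real_)
        if (normalization == "pair") {
          if (length(v) == 2L) cv_pairwise(v[1L], v[2L]) else cv_standard(v)
        } else {
          if (pop_mu == 0) return(NA_real_)
          if (length(v) == 2L) abs(v[1L] - v[2L]) / pop_mu
          else stats::sd(v) / pop_mu
        }
      }, numeric(1L))
      cvs <- cvs[!is.na(cvs)]
      if (!length(cvs)) next
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, view = vw, within_cv = mean(cvs),
        n_turtles = length(cvs))
    }
  }
  if (!length(rows)) return(NULL)  # no group with >= 2 replicates
  out <- do.call(rbind, rows)
  by_measure <- do.call(rbind, lapply(split(out, out$measure), function(d)
    data.frame(measure = d$measure[1L], mean_cv = mean(d$within_cv),
               sd_cv = if (nrow(d) > 1L) stats::sd(d$within_cv) else NA_real_,
               n_views = nrow(d))))
  rownames(by_measure) <- NULL
  attr(out, "by_measure") <- by_measure
  out
}

#' Across-individual CV per measure and view
#'
#' Each turtle's value is the mean of its replicates; the across-individual
#' CV is sd/mean of those per-turtle values over all turtles, per
#' (measure, view), then view-averaged per measure.
#'
#' @param table Long measure table.
#' @return A data frame per (measure, view) with `across_cv` and `n_turtles`,
#'   plus attribute `"by_measure"` as in [within_individual_cv()].
#' @export
across_individual_cv <- function(table) {
  .check_measure_table(table)
  table <- table[!is.na(table$value), , drop = FALSE]
  rows <- list()
  for (ms in unique(table$measure)) {
    for (vw in unique(table$view)) {
      sub <- table[table$measure == ms & table$view == vw, , drop = FALSE]
      if (!nrow(sub)) next
      per_turtle <- vapply(split(sub$value, sub$turtle_id), mean, numeric(1L))
      if (length(per_turtle) < 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, view = vw, across_cv = cv_standard(per_turtle),
        n_turtles = length(per_turtle))
    }
  }
  if (!length(rows)) return(NULL)  # fewer than two turtles everywhere
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$across_cv), , drop = FALSE]
  if (!nrow(out)) return(NULL)
  by_measure <- do.call(rbind, lapply(split(out, out$measure), function(d)
    data.frame(measure = d$measure[1L], mean_cv = mean(d$across_cv),
               sd_cv = if (nrow(d) > 1L) stats::sd(d$across_cv) else NA_real_,
               n_views = nrow(d))))
  rownames(by_measure) <- NULL
  attr(out, "by_measure") <- by_measure
  out
}

#' Noise ratio: within-individual relative to across-individual variation
#'
#' The view-averaged within CV divided by the view-averaged across CV per
#' measure; a ratio near 1 means the apparent between-individual variation is
#' mostly replicate noise. Measures whose *within* CV exceeds the
#' substantial-variation criterion (10% by default) are flagged.
#'
#' @param within Output of [within_individual_cv()].
#' @param across Output of [across_individual_cv()].
#' @param flag_threshold Substantial-variation CV criterion; default 0.10.
#' @return Data frame per measure: `within_cv`, `across_cv`, `noise_ratio`,
#'   `substantial_within`.
#' @export
noise_ratio <- function(within, across, flag_threshold = 0.10) {
  w <- attr(within, "by_measure")
  a <- attr(across, "by_measure")
  if (is.null(w)) w <- within
  if (is.null(a)) a <- across
  m <- merge(w[, c("measure", "mean_cv")], a[, c("measure", "mean_cv")],
             by = "measure", suffixes = c("_within", "_across"))
  ratio <- ifelse(m$mean_cv_across > 0,
                  m$mean_cv_within / m$mean_cv_across, NA_real_)
  data.frame(measure = m$measure,
             within_cv = m$mean_cv_within,
             across_cv = m$mean_cv_across,
             noise_ratio = ratio,
             substantial_within = m$mean_cv_within > flag_threshold,
             substantial_ratio = !is.na(ratio) & ratio > flag_threshold)
}

#' Sensitivity of fractional area to the extraction threshold
#'
#' Re-runs the full extraction at the baseline threshold ratio and each test
#' ratio, and summarizes, per view and test ratio, the mean fractional area,
#' the percent change of that mean relative to baseline, and the mean
#' pairwise CV between baseline and test FA per image. Lowering the
#' threshold admits more pixels, so percent changes are positive below the
#' baseline and negative above it.
#'
#' @param scutes List of records, each a list with elements `image`
#'   (`calibrated_image` or array), `mask`, `view`, optionally `turtle_id`
#'   and `mm_per_pixel`.
#' @param taus Test threshold ratios; default `c(0.90, 1.05, 1.15, 1.30)`.
#' @param baseline Baseline ratio; default 1.10.
#' @param config Base [extraction_config()]; its `tau` is overridden.
#' @return Data frame per (view, tau): `mean_fa`, `pct_change`, `cv`, `n`.
#' @export
threshold_sensitivity <- function(scutes, taus = c(0.90, 1.05, 1.15, 1.30),
                                  baseline = 1.10,
                                  config = extraction_config()) {
  stopifnot(length(scutes) >= 1L)
  all_taus <- sort(unique(c(taus, baseline)))
  fa <- lapply(scutes, function(sc) {
    mmpp <- sc$mm_per_pixel
    if (is.null(mmpp) && inherits(sc$image, "calibrated_image"))
      mmpp <- sc$image$mm_per_pixel
    vapply(all_taus, function(tv) {
      cfg <- config; cfg$tau <- tv
      fractional_area(extract_pattern(sc$image, sc$mask, cfg,
                                      mm_per_pixel = mmpp), sc$mask)
    }, numeric(1L))
  })
  views <- vapply(scutes, function(sc) {
    if (is.null(sc$view)) "top" else sc$view
  }, character(1L))
  rows <- list()
  for (vw in unique(views)) {
    famat <- do.call(rbind, fa[views == vw])
    colnames(famat) <- sprintf("%.6g", all_taus)
    base_col <- match(sprintf("%.6g", baseline), colnames(famat))
    base_mean <- mean(famat[, base_col])
    for (tv in taus) {
      tc <- match(sprintf("%.6g", tv), colnames(famat))
      mu <- mean(famat[, tc])
      pct <- if (base_mean == 0) NA_real_ else (mu - base_mean) / base_mean * 100
      cvs <- cv_pairwise(famat[, base_col], famat[, tc])
      rows[[length(rows) + 1L]] <- data.frame(
        view = vw, tau = tv, baseline = baseline, mean_fa = mu,
        pct_change = pct, cv = mean(cvs, na.rm = TRUE), n = nrow(famat))
    }
  }
  do.call(rbind, rows)
}

# Feltz-Miller asymptotic test for equality of two CVs.
.feltz_miller <- function(x, y) {
  nx <- length(x); ny <- length(y)
  cx <- stats::sd(x) / mean(x); cy <- stats::sd(y) / mean(y)
  dx <- nx - 1L; dy <- ny - 1L
  cp <- (dx * cx + dy * cy) / (dx + dy)
  num <- (cx - cy)^2
  den <- cp^2 * (0.5 + cp^2) * (1 / dx + 1 / dy)
  stat <- num / den
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  list(statistic = stat, p.value = p)
}

#' Group comparison of measures with multiplicity control
#'
#' Per (measure, view), using one value per turtle (replicate mean),
#' compares the two groups defined by `group_col` with a t-test on means
#' (Welch by default), an F-test on variances, and a CV-difference test
#' (by default an F-test on values standardized by their group means;
#' alternatively the Feltz-Miller asymptotic CV test). Within each
#' (test, view) family the p-values across measures are adjusted by the
#' Benjamini-Hochberg procedure.
#'
#' @param table Long measure table with a `source` (or other grouping)
#'   column taking exactly two levels among the tested rows.
#' @param group_col Grouping column name; default `"source"`.
#' @param t_var_equal Use the pooled-variance t-test; default `FALSE` (Welch).
#' @param cv_test `"scaled_f"` (default) or `"feltz_miller"`.
#' @return Data frame per (measure, view): group sizes, the three test
#'   statistics, raw and BH-adjusted p-values.
#' @export
group_comparison <- function(table, group_col = "source",
                             t_var_equal = FALSE,
                             cv_test = c("scaled_f", "feltz_miller")) {
  cv_test <- match.arg(cv_test)
  .check_measure_table(table)
  if (!group_col %in% names(table)) stop("missing grouping column: ", group_col)
  table <- table[!is.na(table$value), , drop = FALSE]
  lv <- sort(unique(table[[group_col]]))
  if (length(lv) != 2L) stop("grouping column must have exactly two levels")
  rows <- list()
  for (ms in unique(table$measure)) {
    for (vw in unique(table$view)) {
      sub <- table[table$measure == ms & table$view == vw, , drop = FALSE]
      per <- lapply(lv, function(g) {
        s <- sub[sub[[group_col]] == g, , drop = FALSE]
        vapply(split(s$value, s$turtle_id), mean, numeric(1L))
      })
      n1 <- length(per[[1L]]); n2 <- length(per[[2L]])
      if (n1 < 2L || n2 < 2L) next
      if (stats::sd(per[[1L]]) == 0 && stats::sd(per[[2L]]) == 0) next
      tt <- stats::t.test(per[[1L]], per[[2L]], var.equal = t_var_equal)
      ft <- stats::var.test(per[[1L]], per[[2L]])
      cv <- if (cv_test == "scaled_f") {
        if (mean(per[[1L]]) == 0 || mean(per[[2L]]) == 0) NULL
        else stats::var.test(per[[1L]] / mean(per[[1L]]),
                             per[[2L]] / mean(per[[2L]]))
      } else {
        if (mean(per[[1L]]) == 0 || mean(per[[2L]]) == 0) NULL
        else .feltz_miller(per[[1L]], per[[2L]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, view = vw, n1 = n1, n2 = n2,
        t_stat = unname(tt$statistic), t_p = tt$p.value,
        f_stat = unname(ft$statistic), f_p = ft$p.value,
        cv_stat = if (is.null(cv)) NA_real_ else unname(cv$statistic),
        cv_p = if (is.null(cv)) NA_real_ else cv$p.value)
    }
  }
  if (!length(rows)) stop("no (measure, view) cell has two groups with >= 2 turtles")
  out <- do.call(rbind, rows)
  out$t_p_adj <- NA_real_; out$f_p_adj <- NA_real_; out$cv_p_adj <- NA_real_
  for (vw in unique(out$view)) {
    i <- out$view == vw
    out$t_p_adj[i] <- stats::p.adjust(out$t_p[i], method = "BH")
    out$f_p_adj[i] <- stats::p.adjust(out$f_p[i], method = "BH")
    out$cv_p_adj[i] <- stats::p.adjust(out$cv_p[i], method = "BH")
  }
  attr(out, "cv_test") <- cv_test
  attr(out, "t_test") <- if (t_var_equal) "pooled" else "welch"
  out
}
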