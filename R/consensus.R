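# Citizen-science consensus scoring and correlation with pattern measures.

#' Majority-vote consensus proportion for one category
#'
#' The proportion of the more frequent binary assignment among the
#' volunteers: `max(#0, #1) / n`, from 0.5 (maximally split; exact ties give
#' exactly 0.5) to 1 (unanimous). Six '0' votes and four '1' votes give 0.6.
#'
#' @param votes Vector of 0/1 votes (logical or numeric).
#' @return Consensus proportion in \[0.5, 1\].
#' @export
category_consensus <- function(votes) {
  votes <- votes[!is.na(votes)]
  if (!length(votes)) stop("empty vote list")
  if (!all(votes %in% c(0, 1))) stop("votes must be binary 0/1")
  n1 <- sum(votes == 1)
  max(n1, length(votes) - n1) / length(votes)
}

#' Overall consensus score for one turtle
#'
#' Arithmetic mean of the nine per-category consensus proportions; 0.5 for
#' complete disagreement on every category, 1 for complete agreement.
#'
#' @param votes Volunteer x category binary matrix with nine columns (one
#'   per pattern category).
#' @return Overall consensus in \[0.5, 1\].
#' @export
overall_consensus <- function(votes) {
  votes <- as.matrix(votes)
  if (ncol(votes) != 9L)
    stop("expected all nine category columns, got ", ncol(votes))
  mean(apply(votes, 2L, category_consensus))
}

#' Read a consensus survey from CSV
#'
#' Accepts either the long dialect (columns `turtle_id`, `volunteer`,
#' `category`, `vote`) or the wide dialect (`turtle_id` plus one binary
#' column per `volunteer:category` pair named `v<k>:<category>` or
#' `<volunteer>_<category>`). Blank or missing cells are read as 0
#' ("category does not apply"); their count is reported in a message.
#'
#' @param path CSV file path.
#' @return A `survey_matrix` (see [generate_survey()]).
#' @export
read_survey <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cats <- pattern_categories()
  if (all(c("turtle_id", "volunteer", "category", "vote") %in% names(df))) {
    turtles <- unique(df$turtle_id)
    vols <- unique(df$volunteer)
    votes <- array(0L, c(length(turtles), length(vols), 9L))
    ci <- match(df$category, cats)
    if (anyNA(ci)) stop("unknown category label(s): ",
                        paste(unique(df$category[is.na(ci)]), collapse = ", "))
    n_blank <- sum(is.na(df$vote))
    v <- ifelse(is.na(df$vote), 0L, as.integer(df$vote))
    votes[cbind(match(df$turtle_id, turtles), match(df$volunteer, vols), ci)] <- v
  } else {
    if (!"turtle_id" %in% names(df)) stop("survey CSV lacks turtle_id")
    turtles <- df$turtle_id
    vc <- setdiff(names(df), "turtle_id")
    split_col <- function(nm) {
      parts <- strsplit(nm, "[:_]")[[1L]]
      cat_lab <- paste(parts[-1L], collapse = " ")
      c(parts[1L], cat_lab)
    }
    meta <- t(vapply(vc, split_col, character(2L)))
    ci <- match(meta[, 2L], cats)
    if (anyNA(ci)) {
      # allow category-only match ignoring case and separators
      norm <- function(x) tolower(gsub("[^a-z]", "", tolower(x)))
      ci <- match(norm(meta[, 2L]), norm(cats))
    }
    if (anyNA(ci)) stop("cannot map wide survey columns onto the nine categories")
    vols <- unique(meta[, 1L])
    votes <- array(0L, c(length(turtles), length(vols), 9L))
    n_blank <- 0L
    for (j in seq_along(vc)) {
      v <- df[[vc[j]]]
      n_blank <- n_blank + sum(is.na(v) | v == "")
      v <- ifelse(is.na(v) | v == "", 0L, as.integer(v))
      votes[, match(meta[j, 1L], vols), ci[j]] <- v
    }
  }
  if (n_blank > 0L)
    message(n_blank, " blank survey cell(s) read as 0 (category does not apply)")
  structure(list(votes = votes, turtles = as.character(turtles),
                 categories = cats),
            class = "survey_matrix")
}

#' Consensus scores for every turtle and category
#'
#' Per turtle: the nine category consensus proportions and their mean (the
#' overall consensus score). Per category: the mean consensus across
#' turtles. Also reports distribution summaries of the overall scores. Any
#' volunteer assigning more than four categories to one turtle triggers a
#' warning (the scoring remains well defined).
#'
#' @param survey A `survey_matrix`.
#' @param low_cut,high_cut Cut points for the "low/high consensus" counts in
#'   the summary; defaults 0.70 and 0.80.
#' @return A `consensus_result`: list with `per_turtle` (data frame),
#'   `per_category` (named means), and `summary`.
#' @export
consensus_table <- function(survey, low_cut = 0.70, high_cut = 0.80) {
  stopifnot(inherits(survey, "survey_matrix"))
  v <- survey$votes
  nt <- dim(v)[1L]
  over4 <- sum(apply(v, c(1L, 2L), sum) > 4L)
  if (over4 > 0L)
    warning(over4, " (turtle, volunteer) response(s) select more than four categories")
  per_cat <- matrix(NA_real_, nt, 9L,
                    dimnames = list(survey$turtles, survey$categories))
  nv <- dim(v)[2L]
  for (i in seq_len(nt)) {
    vm <- matrix(v[i, , ], nv, 9L)
    per_cat[i, ] <- apply(vm, 2L, category_consensus)
  }
  overall <- rowMeans(per_cat)
  per_turtle <- data.frame(turtle_id = survey$turtles, per_cat,
                           overall = overall, check.names = FALSE,
                           row.names = NULL)
  structure(list(
    per_turtle = per_turtle,
    per_category = colMeans(per_cat),
    summary = list(mean = mean(overall), sd = stats::sd(overall),
                   min = min(overall), max = max(overall),
                   n_turtles = nt,
                   n_below_low = sum(overall < low_cut),
                   n_above_high = sum(overall > high_cut),
                   low_cut = low_cut, high_cut = high_cut)),
    class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<consensus_result> %d turtles; overall consensus mean %.3f (sd %.3f), range %.3f-%.3f\n",
    s$n_turtles, s$mean, s$sd, s$min, s$max))
  cat(sprintf("  %d turtle(s) below %.2f, %d above %.2f\n",
              s$n_below_low, s$low_cut, s$n_above_high, s$high_cut))
  cat("  per-category mean consensus:\n")
  print(round(x$per_category, 3))
  invisible(x)
}

#' Correlate pattern measurements with consensus scores
#'
#' For each of the 19 measurements (averaged over the top-view replicates
#' per turtle), computes the Pearson correlation with the overall consensus
#' score, the raw and BH-adjusted p-values across the 19 tests, and a
#' Cook's-distance screen from the univariate linear regression of consensus
#' on the measurement (any observation with distance > 1 indicates a single
#' influential individual).
#'
#' @param consensus A `consensus_result`.
#' @param measures Long measure table; only `view == "top"` rows are used.
#' @param view Viewpoint whose images enter the correlation; default "top".
#' @return Data frame per measure: `r`, `p`, `p_adj`, `n`, `max_cooks`,
#'   `influential`.
#' @export
correlate_measures <- function(consensus, measures, view = "top") {
  stopifnot(inherits(consensus, "consensus_result"))
  .check_measure_table(measures)
  sub <- measures[measures$view == view & !is.na(measures$value), , drop = FALSE]
  sc <- stats::setNames(consensus$per_turtle$overall,
                        consensus$per_turtle$turtle_id)
  rows <- list()
  for (ms in unique(sub$measure)) {
    d <- sub[sub$measure == ms, , drop = FALSE]
    per_turtle <- vapply(split(d$value, d$turtle_id), mean, numeric(1L))
    shared <- intersect(names(per_turtle), names(sc))
    if (length(shared) < 3L) next
    x <- per_turtle[shared]; y <- sc[shared]
    if (stats::sd(x) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, r = NA_real_, p = NA_real_, n = length(shared),
        max_cooks = NA_real_, influential = NA)
      next
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    cd <- stats::cooks.distance(stats::lm(y ~ x))
    cd[!is.finite(cd)] <- 0  # exact fits have zero residual variance
    rows[[length(rows) + 1L]] <- data.frame(
      measure = ms, r = unname(ct$estimate), p = ct$p.value,
      n = length(shared), max_cooks = max(cd), influential = any(cd > 1))
  }
  if (!length(rows)) stop("fewer than 3 turtles shared between measures and consensus")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("measure", "r", "p", "p_adj", "n", "max_cooks", "influential")]
}
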