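test_that("category consensus is the majority proportion", {
  expect_equal(category_consensus(c(rep(0, 6), rep(1, 4))), 0.6)
  expect_equal(category_consensus(rep(1, 12)), 1)
  expect_equal(category_consensus(c(rep(0, 5), rep(1, 5))), 0.5)  # tie
  expect_error(category_consensus(numeric(0)), "empty")
  expect_error(category_consensus(c(0, 2)), "binary")
  # relabeling 0 <-> 1 leaves the consensus unchanged
  set.seed(2)
  v <- rbinom(31, 1, 0.3)
  expect_equal(category_consensus(v), category_consensus(1 - v))
})

test_that("overall consensus is the mean of the nine category proportions", {
  un <- matrix(1, nrow = 10, ncol = 9)
  expect_equal(overall_consensus(un), 1)
  tied <- matrix(rep(c(0, 1), each = 5), nrow = 10, ncol = 9)
  expect_equal(overall_consensus(tied), 0.5)
  expect_error(overall_consensus(matrix(0, 5, 4)), "nine")
  # random voting at p = 0.5 gives a score slightly above 0.5 (finite n)
  set.seed(11)
  scores <- replicate(1000, overall_consensus(matrix(rbinom(31 * 9, 1, 0.5),
                                                     31, 9)))
  expect_gt(mean(scores), 0.5)
  expect_lt(mean(scores), 0.62)
  expect_lt(abs(mean(scores) - (0.5 + mean(abs(rbinom(1e5, 31, 0.5) - 15.5)) / 31)),
            0.01)
})

test_that("a volunteer copying the majority never lowers any consensus", {
  set.seed(31)
  votes <- matrix(rbinom(21 * 9, 1, 0.4), 21, 9)
  base <- apply(votes, 2, category_consensus)
  copier <- as.integer(colMeans(votes) >= 0.5)
  grown <- rbind(votes, copier)
  expect_true(all(apply(grown, 2, category_consensus) >= base - 1e-12))
})

test_that("consensus_table summarizes turtles, categories and cut points", {
  sv <- generate_survey(30, 31, c(0.9, 0.1, 0.3, 0.5, 0.2, 0.7, 0.4, 0.6, 0.5),
                        seed = 77)
  ct <- suppressWarnings(consensus_table(sv))  # >4-category picks expected
  expect_equal(nrow(ct$per_turtle), 30L)
  expect_true(all(ct$per_turtle$overall >= 0.5 & ct$per_turtle$overall <= 1))
  expect_equal(ct$summary$mean, mean(ct$per_turtle$overall))
  expect_equal(ct$summary$n_below_low, sum(ct$per_turtle$overall < 0.7))
  # single-turtle survey: summary equals that turtle's score
  sv1 <- generate_survey(1, 15, rep(0.4, 9), seed = 3)
  ct1 <- suppressWarnings(consensus_table(sv1))
  expect_equal(ct1$summary$mean, ct1$per_turtle$overall[1])
  expect_equal(ct1$summary$sd, NA_real_, tolerance = 1e-12)
})

test_that("over-four-category responses warn but still score", {
  votes <- array(0L, c(2, 3, 9))
  votes[1, 1, 1:6] <- 1L   # one volunteer ticks six categories
  sv <- structure(list(votes = votes, turtles = c("a", "b"),
                       categories = pattern_categories()),
                  class = "survey_matrix")
  expect_warning(ct <- consensus_table(sv), "more than four")
  expect_equal(nrow(ct$per_turtle), 2L)
})

test_that("survey CSVs are parsed in both dialects", {
  sv <- generate_survey(4, 5, rep(0.5, 9), seed = 9)
  # long dialect
  long <- expand.grid(volunteer = sprintf("v%d", 1:5),
                      turtle_id = sv$turtles,
                      category = sv$categories, stringsAsFactors = FALSE)
  long$vote <- mapply(function(t, v, k)
    sv$votes[match(t, sv$turtles), match(v, sprintf("v%d", 1:5)),
             match(k, sv$categories)],
    long$turtle_id, long$volunteer, long$category)
  f1 <- tempfile(fileext = ".csv")
  utils::write.csv(long, f1, row.names = FALSE)
  sv1 <- read_survey(f1)
  expect_equal(suppressWarnings(consensus_table(sv1))$per_turtle$overall,
               suppressWarnings(consensus_table(sv))$per_turtle$overall)
  # wide dialect, with blanks read as 0
  wide <- data.frame(turtle_id = sv$turtles)
  for (v in 1:5) for (k in 1:9)
    wide[[sprintf("v%d:%s", v, sv$categories[k])]] <- sv$votes[, v, k]
  wide[1, 2] <- NA
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(wide, f2, row.names = FALSE)
  expect_message(sv2 <- read_survey(f2), "blank")
  v_changed <- sv$votes; v_changed[1, 1, 1] <- 0L
  expect_identical(sv2$votes, v_changed)
  unlink(c(f1, f2))
})

test_that("measure-consensus correlation matches direct computation", {
  sv <- generate_survey(25, 31, rep(0.4, 9), seed = 21)
  ct <- suppressWarnings(consensus_table(sv))
  # a measure equal to the consensus itself: r = 1, nobody influential
  tb <- data.frame(turtle_id = rep(ct$per_turtle$turtle_id, each = 2),
                   view = "top", replicate = rep(1:2, 25), source = "field",
                   measure = "FA",
                   value = rep(ct$per_turtle$overall, each = 2))
  res <- correlate_measures(ct, tb)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_false(res$influential)
  # duplicated measure columns give identical correlations; r matches the
  # covariance formula to near machine precision
  set.seed(8)
  x <- rnorm(25)
  tb2 <- rbind(
    data.frame(turtle_id = ct$per_turtle$turtle_id, view = "top",
               replicate = 1, source = "field", measure = "FA", value = x),
    data.frame(turtle_id = ct$per_turtle$turtle_id, view = "top",
               replicate = 1, source = "field", measure = "OF", value = x))
  res2 <- correlate_measures(ct, tb2)
  expect_equal(res2$r[1], res2$r[2], tolerance = 1e-15)
  y <- ct$per_turtle$overall
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$r[1], r_direct, tolerance = 1e-12)
  # constant measure: sentinel
  tb3 <- tb2[tb2$measure == "FA", ]; tb3$value <- 1
  expect_true(is.na(correlate_measures(ct, tb3)$r))
})

test_that("an independent measure rarely clears |r| = 0.27 at n = 53", {
  sv <- generate_survey(53, 31, rep(0.4, 9), seed = 41)
  ct <- suppressWarnings(consensus_table(sv))
  set.seed(42)
  n_big <- 0
  for (r in 1:500) {
    tb <- data.frame(turtle_id = ct$per_turtle$turtle_id, view = "top",
                     replicate = 1, source = "field", measure = "FA",
                     value = rnorm(53))
    n_big <- n_big + (abs(correlate_measures(ct, tb)$r) > 0.27)
  }
  expect_lt(n_big / 500, 0.10)  # nominal ~5% at the 0.05 critical value
})
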