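make_table <- function(values) {
  # values: named list turtle -> replicate vector; one measure, one view
  do.call(rbind, lapply(names(values), function(t)
    data.frame(turtle_id = t, view = "top",
               replicate = seq_along(values[[t]]), source = "field",
               measure = "FA", value = values[[t]])))
}

test_that("pairwise and standard CV obey their formulas and identity", {
  expect_equal(cv_pairwise(10, 12), 2 / 11)
  expect_equal(cv_pairwise(7, 7), 0)
  expect_true(is.na(cv_pairwise(1, -1)))
  expect_equal(cv_standard(c(1, 2, 3)), 0.5)
  expect_equal(cv_standard(c(4, 4, 4, 4)), 0)
  expect_true(is.na(cv_standard(c(5))))
  set.seed(3)
  x1 <- runif(1000, 1, 10); x2 <- runif(1000, 1, 10)
  expect_equal(cv_pairwise(x1, x2),
               sqrt(2) * vapply(seq_along(x1),
                                function(i) cv_standard(c(x1[i], x2[i])),
                                numeric(1)),
               tolerance = 1e-12)
})

test_that("within-individual CV aggregates replicates as specified", {
  # jitter-free duplicates: all within CVs are zero
  t0 <- make_table(list(a = c(5, 5), b = c(2, 2)))
  w0 <- within_individual_cv(t0)
  expect_equal(w0$within_cv, 0)
  # hand-computed two-turtle case: (10,12) -> 2/11, (20,20) -> 0, mean 1/11
  t1 <- make_table(list(a = c(10, 12), b = c(20, 20)))
  w1 <- within_individual_cv(t1)
  expect_equal(w1$within_cv, (2 / 11) / 2)
  expect_equal(w1$n_turtles, 2L)
  # triplicates use the standard CV
  t2 <- make_table(list(a = c(1, 2, 3)))
  expect_equal(within_individual_cv(t2)$within_cv, 0.5)
  # population normalization divides by the per-view mean over all turtles
  w1p <- within_individual_cv(t1, normalization = "population")
  pop_mu <- mean(c(10, 12, 20, 20))
  expect_equal(w1p$within_cv, mean(c(2 / pop_mu, 0)))
  # single-replicate groups are skipped
  t3 <- make_table(list(a = c(10, 12), b = 7))
  expect_equal(within_individual_cv(t3)$n_turtles, 1L)
})

test_that("across-individual CV uses replicate means per turtle", {
  t1 <- make_table(list(a = c(1, 1), b = c(3, 3)))
  a1 <- across_individual_cv(t1)
  expect_equal(a1$across_cv, sqrt(2) / 2)  # sd(c(1,3))/mean = sqrt(2)/2
  t2 <- make_table(list(a = c(4, 6), b = c(5, 5), c = c(5, 5)))
  a2 <- across_individual_cv(t2)
  expect_equal(a2$across_cv, 0)  # all per-turtle means equal 5
})

test_that("noise ratio flags substantial variation at the 10% criterion", {
  t1 <- make_table(list(a = c(10, 11.5), b = c(30, 31), c = c(19, 20)))
  w <- within_individual_cv(t1); a <- across_individual_cv(t1)
  nr <- noise_ratio(w, a)
  expect_equal(nr$noise_ratio, nr$within_cv / nr$across_cv)
  # direct numbers: within 0.15 / across 0.60 -> 0.25
  w2 <- data.frame(measure = "FA", mean_cv = 0.15)
  a2 <- data.frame(measure = "FA", mean_cv = 0.60)
  nr2 <- noise_ratio(w2, a2)
  expect_equal(nr2$noise_ratio, 0.25)
  expect_true(nr2$substantial_within)
  expect_true(nr2$substantial_ratio)
  nr3 <- noise_ratio(data.frame(measure = "FA", mean_cv = 0),
                     data.frame(measure = "FA", mean_cv = 0.5))
  expect_equal(nr3$noise_ratio, 0)
})

test_that("replicate noise dominating the design drives the ratio to 1", {
  # identical turtles, noisy replicates: across variation is pure noise
  set.seed(91)
  vals <- lapply(1:40, function(i) 10 + rnorm(2, 0, 1))
  names(vals) <- sprintf("t%02d", 1:40)
  tb <- make_table(vals)
  nr <- noise_ratio(within_individual_cv(tb), across_individual_cv(tb))
  # pairwise CV of N(10,1) pairs ~ sqrt(2)*sd/mu; across CV of pair means
  # ~ sd/(mu*sqrt(2)): the ratio concentrates near 2
  expect_gt(nr$noise_ratio, 1)
})

test_that("all CV outputs are scale invariant", {
  t1 <- make_table(list(a = c(10, 12), b = c(20, 22), c = c(18, 19)))
  t2 <- t1; t2$value <- t2$value * 37.5
  expect_equal(within_individual_cv(t1)$within_cv,
               within_individual_cv(t2)$within_cv, tolerance = 1e-12)
  expect_equal(across_individual_cv(t1)$across_cv,
               across_individual_cv(t2)$across_cv, tolerance = 1e-12)
})

test_that("threshold sensitivity is zero at baseline and signed correctly", {
  fx <- radial_gradient_fixture(H = 160, Rd = 70)
  rec <- list(list(image = fx$image, mask = fx$mask,
                   mm_per_pixel = fx$mm_per_pixel, view = "top"))
  tab0 <- threshold_sensitivity(rec, taus = 1.10, baseline = 1.10)
  expect_equal(tab0$pct_change, 0)
  expect_equal(tab0$cv, 0)
  tab <- threshold_sensitivity(rec, taus = c(0.95, 1.25), baseline = 1.10)
  expect_gt(tab$pct_change[tab$tau == 0.95], 0)
  expect_lt(tab$pct_change[tab$tau == 1.25], 0)
})

test_that("group comparison runs the three test families with BH control", {
  set.seed(17)
  mk_group <- function(ids, source, f) {
    do.call(rbind, lapply(ids, function(i)
      data.frame(turtle_id = sprintf("%s%02d", source, i), view = "top",
                 replicate = 1:2, source = source, measure = "FA",
                 value = f())))
  }
  # identical distributions: no rejections expected at alpha 0.05
  tb <- rbind(mk_group(1:20, "museum", function() rnorm(2, 10, 1)),
              mk_group(1:20, "field", function() rnorm(2, 10, 1)))
  res <- group_comparison(tb)
  expect_true(all(c("t_p_adj", "f_p_adj", "cv_p_adj") %in% names(res)))
  expect_gt(res$t_p, 0.001)

  # equal means, 4x variance: the F-test rejects far more than the t-test
  nrej <- c(t = 0, f = 0)
  for (r in 1:200) {
    tb2 <- rbind(mk_group(1:40, "museum", function() rnorm(2, 10, 1)),
                 mk_group(1:10, "field", function() rnorm(2, 10, 2)))
    res2 <- group_comparison(tb2)
    nrej["t"] <- nrej["t"] + (res2$t_p < 0.05)
    nrej["f"] <- nrej["f"] + (res2$f_p < 0.05)
  }
  expect_gt(nrej[["f"]], 3 * nrej[["t"]])
  expect_gt(nrej[["f"]], 100)
})

test_that("Benjamini-Hochberg adjustment matches the step-up closed form", {
  p <- seq(0.01, 0.19, by = 0.01)
  direct <- function(p) {
    n <- length(p); o <- order(p); ro <- order(o)
    adj <- pmin(1, cummin((n / (n:1)) * p[o][n:1])[n:1])
    adj[ro]
  }
  expect_equal(stats::p.adjust(p, "BH"), direct(p), tolerance = 1e-15)
  set.seed(5)
  q <- runif(19)
  adj <- stats::p.adjust(q, "BH")
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(q)]) >= -1e-15))  # monotone in raw p
})
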