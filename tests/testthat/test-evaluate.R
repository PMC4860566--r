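test_that("confusion counts partition the VOI", {
  set.seed(41)
  d <- c(8, 6, 10)
  voi <- array(runif(prod(d)) < 0.4, d)
  truth <- voi & array(runif(prod(d)) < 0.3, d)
  pred <- voi & array(runif(prod(d)) < 0.3, d)
  cc <- confusion(pred, truth, voi)
  expect_equal(sum(cc), sum(voi))
  expect_equal(unname(cc[["fp"]] + cc[["tp"]]), sum(pred & voi))
  # perfect prediction has no errors
  cc2 <- confusion(truth, truth, voi)
  expect_equal(unname(cc2[c("fp", "fn")]), c(0L, 0L))
  # empty prediction turns all truth into false negatives
  cc3 <- confusion(array(FALSE, d), truth, voi)
  expect_equal(unname(cc3[["fn"]]), sum(truth))
  expect_equal(unname(cc3[["tp"]]), 0L)
  expect_error(confusion(pred, truth[1:4, , ], voi), "shapes")
})

test_that("SEN/SPE/BAR follow their definitions, including printed table rows", {
  m <- sen_spe_bar(50, 10, 90, 50)
  expect_equal(unname(m[["sen"]]), 50)
  # BAR is always the mean of SEN and SPE: printed row and printed cohort means
  expect_equal((94.81 + 86.73) / 2, 90.77)
  expect_equal((85.69 + 85.91) / 2, 85.80)
  perfect <- sen_spe_bar(10, 0, 100, 0)
  expect_equal(unname(perfect[["bar"]]), 100)
  # undefined SEN on an all-negative eye is NA, SPE still reported
  normal <- sen_spe_bar(0, 3, 97, 0)
  expect_true(is.na(normal[["sen"]]))
  expect_equal(unname(normal[["spe"]]), 97)
  expect_true(is.na(normal[["bar"]]))
  expect_error(sen_spe_bar(0, 0, 0, 0), "denominators")
  # property: BAR equals the mean wherever both are defined
  set.seed(42)
  for (i in 1:20) {
    cc <- rpois(4, 30) + 1
    mm <- sen_spe_bar(cc[1], cc[2], cc[3], cc[4])
    expect_equal(unname(mm[["bar"]]), (mm[["sen"]] + mm[["spe"]]) / 2)
  }
})

test_that("cohort statistics use the t-based 95% interval", {
  s <- cohort_stats(c(0, 2))
  expect_equal(s$mean, 1)
  z <- cohort_stats(rep(3, 5))
  expect_equal(z$ci, c(3, 3))
  expect_error(cohort_stats(1), "at least 2")
  # coverage: the CI from 20 standard-normal draws covers 0 about 95% of the time
  set.seed(43)
  hits <- vapply(1:1000, function(i) {
    ci <- cohort_stats(rnorm(20))$ci
    ci[1] <= 0 && ci[2] >= 0
  }, TRUE)
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})

test_that("correlation inference matches its contracts", {
  x <- 1:10
  expect_equal(correlation_with_ci(x, 2 * x + 1)$r, 1)
  set.seed(44)
  a <- rnorm(1000); b <- rnorm(1000)
  r <- correlation_with_ci(a, b)
  expect_lt(abs(r$r), 0.1)
  expect_equal(correlation_with_ci(a, b)$r, correlation_with_ci(b, a)$r)
  expect_error(correlation_with_ci(a[1:3], b[1:3]), "at least 4")
  expect_error(correlation_with_ci(rep(1, 10), rnorm(10)), "variance")
})

test_that("Bland-Altman limits behave as mean +/- 1.96 sd of the differences", {
  x <- c(1, 2, 3, 4)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$lower, ba$upper)
  ba2 <- bland_altman(x + 0.5, x)
  expect_equal(ba2$mean_diff, 0.5)
  expect_equal(c(ba2$lower, ba2$upper), c(0.5, 0.5))
  set.seed(45)
  a <- rnorm(2000); b <- a + rnorm(2000)
  ba3 <- bland_altman(a, b)
  inside <- mean(ba3$table$diff >= ba3$lower & ba3$table$diff <= ba3$upper)
  expect_gt(inside, 0.93)
  expect_lt(inside, 0.97)
  expect_equal(names(ba3$table), c("mean", "diff"))
})

test_that("the two-sample t-test is pooled, symmetric, and detects separation", {
  g <- c(1, 2, 3)
  tt <- two_sample_ttest(g, g)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  set.seed(46)
  a <- rnorm(4, 0, 0.001); b <- 1 + rnorm(4, 0, 0.001)
  expect_lt(two_sample_ttest(a, b)$p, 1e-3)
  t1 <- two_sample_ttest(a, b); t2 <- two_sample_ttest(b, a)
  expect_equal(t1$t, -t2$t)
  expect_equal(t1$p, t2$p)
  # matches the classical pooled-variance computation
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(t1$t, unname(ref$statistic))
  expect_error(two_sample_ttest(1, c(1, 2)), "at least 2")
})

test_that("eval_report aggregates per-eye rows into cohort summaries", {
  mk <- function(id, group, tp, fp, tn, fn, dv, tv)
    list(id = id, group = group, tp = tp, fp = fp, tn = tn, fn = fn,
         detected_volume = dv, truth_volume = tv, ez_volume = 0.5)
  eyes <- list(mk("t1", "trauma", 90, 5, 900, 10, 0.11, 0.10),
               mk("t2", "trauma", 80, 8, 890, 20, 0.09, 0.10),
               mk("t3", "trauma", 70, 2, 910, 30, 0.05, 0.06),
               mk("t4", "trauma", 95, 9, 880, 5, 0.14, 0.13),
               mk("n1", "normal", 0, 3, 997, 0, 0.002, 0),
               mk("n2", "normal", 0, 1, 999, 0, 0.001, 0))
  rep <- eval_report(eyes)
  expect_s3_class(rep, "ez_eval_report")
  expect_equal(nrow(rep$per_eye), 6L)
  expect_true(is.na(rep$per_eye$sen[5]))
  expect_equal(rep$summaries$trauma_bar$mean,
               mean(rep$per_eye$bar[1:4]))
  expect_true(abs(rep$summaries$volume_correlation$r) <= 1)
  expect_true(rep$summaries$group_ttest$p < 0.05)
  expect_length(rep$summaries$normal_spe$ci, 2L)
})

test_that("agreement plots are written for trauma cohorts", {
  mk <- function(id, group, dv, tv)
    list(id = id, group = group, tp = 10, fp = 1, tn = 100, fn = 2,
         detected_volume = dv, truth_volume = tv, ez_volume = 0.5)
  rep <- eval_report(list(mk("t1", "trauma", 0.11, 0.10),
                          mk("t2", "trauma", 0.09, 0.10),
                          mk("t3", "trauma", 0.05, 0.06),
                          mk("t4", "trauma", 0.14, 0.13)))
  out <- file.path(tempdir(), "ez-plots")
  paths <- plot_report(rep, out)
  expect_true(all(file.exists(file.path(out, c("volume_scatter.png",
                                               "bland_altman.png")))))
})
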