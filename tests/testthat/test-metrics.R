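test_that("error metrics follow their formulas and rmse dominates mae", {
  expect_equal(unname(error_metrics(1:5 / 10, 1:5 / 10)), c(0, 0))
  em <- error_metrics(rep(0.5, 4), rep(0.4, 4))
  expect_equal(unname(em), c(0.1, 0.1))
  set.seed(1)
  y <- runif(10); yh <- runif(10)
  em <- error_metrics(y, yh)
  expect_equal(unname(em["mae"]), sum(abs(y - yh)) / 10, tolerance = 1e-12)
  expect_equal(unname(em["rmse"]), sqrt(sum((y - yh)^2) / 10),
               tolerance = 1e-12)
  for (i in 1:20) {
    y <- runif(8); yh <- runif(8)
    em <- error_metrics(y, yh)
    expect_gte(em["rmse"], em["mae"] - 1e-12)
  }
  expect_error(error_metrics(numeric(0), numeric(0)), "empty")
})

test_that("PDA follows its dimension-averaged formula", {
  Y <- matrix(runif(35), 7)
  expect_equal(pda(Y, Y), 1)
  expect_equal(pda(matrix(0.5, 6, 5), matrix(0.6, 6, 5)), 0.9)
  set.seed(2)
  Y <- matrix(runif(35), 7); Yh <- matrix(runif(35), 7)
  want <- 0
  for (p in 1:5) {
    s <- 0
    for (i in 1:7) s <- s + abs(Y[i, p] - Yh[i, p])
    want <- want + (1 - s / 7)
  }
  expect_equal(pda(Y, Yh), want / 5, tolerance = 1e-12)
  expect_error(pda(Y * 2, Yh), "\\[0, 1\\]")
})

test_that("PCI measures self-consistency of predictions only", {
  set.seed(3)
  Yp <- matrix(runif(25, 0, 0.6), 5)
  expect_equal(pci(rowMeans(Yp), Yp), 1)
  expect_equal(pci(rowMeans(Yp) + 0.2, Yp), 0.8, tolerance = 1e-9)
  yh <- runif(5)
  want <- 1 - mean(abs(yh - rowMeans(Yp)))
  expect_equal(pci(yh, Yp), want, tolerance = 1e-12)
})

test_that("PCE combines its components with the stated weights", {
  expect_equal(unname(pce(1, 1, 0)["pce"]), 1)
  expect_equal(unname(pce(0.5, 0.5, 0.5)["pce"]), 0.5)
  got <- pce(0.8, 0.6, 0.25)
  expect_equal(unname(got["pce"]), 0.4 * 0.8 + 0.3 * 0.6 + 0.3 * 0.75,
               tolerance = 1e-12)
  # rmse_norm caps at 1
  expect_equal(unname(pce(1, 1, 3)["rmse_norm"]), 1)
  expect_error(pce(1, 1, 0, weights = c(0.5, 0.5, 0.5)), "sum to 1")
  # monotonicity
  expect_gt(pce(0.9, 0.6, 0.2)["pce"], pce(0.8, 0.6, 0.2)["pce"])
  expect_lt(pce(0.8, 0.6, 0.3)["pce"], pce(0.8, 0.6, 0.2)["pce"])
})

test_that("PDA and PCI shift by at most a uniform prediction offset", {
  set.seed(4)
  for (i in 1:10) {
    Y <- matrix(runif(30, 0.2, 0.8), 6)
    Yh <- matrix(runif(30, 0.2, 0.8), 6)
    delta <- 0.05
    expect_lte(abs(pda(Y, Yh) - pda(Y, Yh + delta)), delta + 1e-12)
    expect_lte(abs(pci(rowMeans(Yh), Yh + delta) - pci(rowMeans(Yh), Yh)),
               delta + 1e-12)
  }
})

test_that("consistency violation rate counts threshold exceedances", {
  Yp <- matrix(runif(20), 4)
  consistent <- list(wellbeing = rowMeans(Yp), perma = Yp)
  expect_equal(consistency_violation_rate(consistent, 0), 0)
  off <- list(wellbeing = rep(0.7, 4), perma = matrix(0.5, 4, 5))
  expect_equal(consistency_violation_rate(off, 0.1), 1)
  set.seed(5)
  b <- list(wellbeing = runif(50), perma = matrix(runif(250), 50))
  dev <- abs(b$wellbeing - rowMeans(b$perma))
  expect_equal(consistency_violation_rate(b, 0.1), mean(dev > 0.1))
  expect_error(consistency_violation_rate(b, -0.1), "nonnegative")
})

test_that("paired t-test reproduces the textbook example", {
  a <- c(0.2, 0.35, 0.5, 0.6, 0.75)
  b <- a - c(0.1, 0.2, 0.3, 0.4, 0.5)
  tt <- paired_ttest(a, b)
  expect_equal(tt$t_stat, 4.242641, tolerance = 1e-6)
  expect_equal(tt$df, 4L)
  expect_equal(tt$p_value, 0.01323, tolerance = 1e-3)
  expect_equal(tt$mean_diff, 0.3)
  expect_equal(tt$sd_diff, 0.1581139, tolerance = 1e-6)
  # independent oracle: stats::t.test
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(tt$t_stat, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("paired t-test is antisymmetric and handles degeneracy", {
  set.seed(6)
  a <- runif(12); b <- runif(12)
  t1 <- paired_ttest(a, b)
  t2 <- paired_ttest(b, a)
  expect_equal(t1$t_stat, -t2$t_stat)
  expect_equal(t1$p_value, t2$p_value)
  # identical errors
  ti <- paired_ttest(a, a)
  expect_equal(ti$t_stat, 0)
  expect_equal(ti$p_value, 1)
  expect_true(ti$degenerate)
  # symmetric differences cancel
  ts <- paired_ttest(c(1, 0), c(0, 1))
  expect_equal(ts$t_stat, 0)
  expect_equal(ts$p_value, 1)
  # constant nonzero difference (identical d_i, so s_d is exactly zero)
  tc <- paired_ttest(rep(0.3, 12), rep(0.25, 12))
  expect_equal(tc$p_value, 0)
  expect_true(tc$degenerate)
  expect_error(paired_ttest(a, a[1:5]), "aligned")
  expect_error(paired_ttest(1, 2), "at least 2")
})

test_that("evaluate_predictions composes the per-metric oracles", {
  set.seed(7)
  n <- 40
  labels <- list(wellbeing = runif(n), perma = matrix(runif(5 * n), n))
  # perfect consistent predictions
  perfect <- list(wellbeing = rowMeans(labels$perma), perma = labels$perma)
  rp <- evaluate_predictions(perfect,
                             list(wellbeing = rowMeans(labels$perma),
                                  perma = labels$perma))
  expect_equal(rp$mae, 0); expect_equal(rp$rmse, 0)
  expect_equal(rp$pda, 1); expect_equal(rp$pci, 1); expect_equal(rp$pce, 1)
  expect_equal(rp$consistency_violation_rate, 0)
  # random bundle: every field matches its own metric
  bundle <- list(wellbeing = runif(n), perma = matrix(runif(5 * n), n))
  r <- evaluate_predictions(bundle, labels)
  em <- error_metrics(labels$wellbeing, bundle$wellbeing)
  expect_equal(r$mae, unname(em["mae"]))
  expect_equal(r$rmse, unname(em["rmse"]))
  expect_equal(r$pda, pda(labels$perma, bundle$perma))
  expect_equal(r$pci, pci(bundle$wellbeing, bundle$perma))
  expect_equal(r$pce,
               unname(pce(r$pda, r$pci, r$rmse)["pce"]), tolerance = 1e-12)
  # a single stratum reproduces the unstratified numbers
  rs <- evaluate_predictions(bundle, labels, strata = rep("all", n))
  expect_equal(rs$strata$all$mae, r$mae)
  expect_equal(rs$strata$all$pce, r$pce)
})

test_that("compare_models produces a sorted pairwise table", {
  set.seed(8)
  e_best <- abs(rnorm(50, 0, 0.05))
  e_worse <- e_best + 0.05
  e_third <- abs(rnorm(50, 0, 0.2))
  cm <- compare_models(list(good = e_best, bad = e_worse, ugly = e_third))
  expect_equal(cm$models$model[1], "good")
  expect_equal(nrow(cm$pairs), 3L)
  gb <- cm$pairs[cm$pairs$model_a == "good" & cm$pairs$model_b == "bad", ]
  expect_lt(gb$p_value, 0.001)
  expect_lt(gb$mean_diff, 0)
  # model against itself is degenerate with p = 1
  self <- paired_ttest(e_best, e_best)
  expect_equal(self$p_value, 1)
  # holm adjustment only appends a column
  cmh <- compare_models(list(a = e_best, b = e_worse), adjust = "holm")
  expect_true("p_adjusted" %in% names(cmh$pairs))
  expect_error(compare_models(list(a = e_best)), "at least 2")
  expect_error(compare_models(list(a = e_best, b = e_worse[1:10])),
               "aligned")
})
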