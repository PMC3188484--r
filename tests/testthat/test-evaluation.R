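test_that("2AFC classification picks the stronger side, ties by seeded coin", {
  trials <- tibble::tibble(psi_left = c(10, 2, 5), psi_right = c(5, 8, 5),
                           target_side = c("left", "left", "right"))
  out <- classify_2afc(trials, seed = 9)
  expect_identical(out$choice[1:2], c("left", "right"))
  expect_equal(out$confidence, c(5, 6, 0))
  expect_identical(out$correct[1:2], c(TRUE, FALSE))
  out2 <- classify_2afc(trials, seed = 9)
  expect_identical(out$choice, out2$choice)  # tie break reproducible
  expect_identical(out$correct, out$choice == out$target_side)
})

test_that("ROC reproduces known areas and rejects one-class input", {
  sep <- tibble::tibble(signal = c(3, 4, 5, -1, -2, -3),
                        target_side = rep(c("left", "right"), each = 3))
  expect_equal(attr(roc_curve(sep), "auc"), 1)

  mixed <- tibble::tibble(signal = c(1, 3, 2, 4),
                          target_side = c("left", "left", "right", "right"))
  expect_equal(attr(roc_curve(mixed, thresholds = "data"), "auc"), 0.25)

  only <- tibble::tibble(signal = 1:3, target_side = "left")
  expect_error(roc_curve(only), "undefined ROC")

  set.seed(40)
  null <- tibble::tibble(signal = rnorm(2000),
                         target_side = rep(c("left", "right"), 1000))
  expect_lt(abs(attr(roc_curve(null), "auc") - 0.5), 0.05)
})

test_that("trapezoid AUC agrees with the Mann-Whitney pair probability", {
  set.seed(41)
  for (rep in 1:20) {
    s_left <- round(rnorm(30, mean = 0.4), 1)   # rounding induces ties
    s_right <- round(rnorm(30), 1)
    trials <- tibble::tibble(signal = c(s_left, s_right),
                             target_side = rep(c("left", "right"), each = 30))
    oracle <- mw_auc(s_left, s_right)
    expect_lt(abs(attr(roc_curve(trials, thresholds = "data"), "auc") -
                    oracle), 1e-9)
    expect_lt(abs(attr(roc_curve(trials, n_thresholds = 100), "auc") -
                    oracle), 0.01)
    # invariance under a strictly monotone transform
    trials2 <- dplyr::mutate(trials, signal = atan(signal) * 3 + 1)
    expect_lt(abs(attr(roc_curve(trials2, thresholds = "data"), "auc") -
                    oracle), 1e-9)
  }
})

test_that("binomial error bars follow the closed form", {
  expect_equal(binomial_error(0.5, 100), 0.05)
  expect_equal(binomial_error(c(0, 1), 50), c(0, 0))
  expect_equal(binomial_error(0.9, 1000), sqrt(0.9 * 0.1 / 1000))
})

test_that("the psychometric form is chance-anchored and recoverable", {
  expect_equal(psychometric_fun(1, tau = 1.5, asymptote = 0.95, onset = 1),
               0.5)
  expect_equal(psychometric_fun(0.2, tau = 2, asymptote = 0.9, onset = 1),
               0.5)
  expect_equal(psychometric_fun(Inf, tau = 2, asymptote = 0.9), 0.9)

  x <- seq(1, 9, by = 0.5)
  y <- psychometric_fun(x, tau = 1.5, asymptote = 0.95, onset = 1)
  fit <- fit_psychometric(x, y, asymptote = 0.95, onset = 1)
  expect_lt(abs(fit$tau - 1.5), 1e-6)
  expect_true(fit$converged)
  expect_equal(predict(fit, 1), 0.5)
  expect_equal(predict(fit, 1e9), 0.95, tolerance = 1e-6)

  # free asymptote fit on clean data
  fit2 <- fit_psychometric(x, y, asymptote = NULL, onset = 1)
  expect_lt(abs(fit2$asymptote - 0.95), 1e-3)
  expect_lt(abs(fit2$tau - 1.5), 0.05)

  # chance-level data cannot identify tau
  flat <- fit_psychometric(1:6, rep(0.5, 6), asymptote = 0.5)
  expect_false(flat$converged)
  expect_identical(flat$tau, Inf)
})

test_that("tidy and glance return the documented tibbles", {
  x <- 0:6
  y <- psychometric_fun(x, 2, 0.9)
  fit <- fit_psychometric(x, y, asymptote = 0.9)
  td <- tidy(fit)
  expect_identical(td$term, c("tau", "asymptote", "onset"))
  gl <- glance(fit)
  expect_identical(names(gl),
                   c("tau", "asymptote", "onset", "sigma", "n", "converged"))

  trials <- tibble::tibble(signal = c(1, 3, 2, 4),
                           target_side = c("left", "left", "right", "right"))
  roc <- roc_curve(trials)
  expect_identical(names(tidy(roc)), c("threshold", "fpr", "tpr"))
  expect_identical(glance(roc)$auc, attr(roc, "auc"))
  expect_identical(auc(roc), attr(roc, "auc"))
})
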