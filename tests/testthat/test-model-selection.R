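mk_seq <- function(rss) {
  models <- lapply(seq_along(rss), function(k) {
    structure(list(k = k, change_indices = seq_len(k - 1L),
                   segment_means = numeric(k), rss = rss[k]),
              class = "segmentation_model")
  })
  structure(list(models = models, d = length(rss) + 5L, kmax = length(rss)),
            class = "segmentation_sequence")
}

test_that("complexity path hull breakpoints are the rss differences", {
  path <- model_complexity_path(mk_seq(c(10, 2, 1.9)))
  expect_equal(path$k, c(3, 2, 1))
  expect_equal(path$lambda_lo, c(0, 0.1, 8))
  expect_equal(path$lambda_hi, c(0.1, 8, Inf))
})

test_that("a constant signal selects one segment for every penalty", {
  path <- model_complexity_path(mk_seq(c(0, 0, 0, 0)))
  expect_equal(path$k, 1)  # ties always resolve to fewer segments
  expect_equal(path$lambda_lo, 0)
})

test_that("path selection matches direct argmin on a penalty grid", {
  set.seed(31)
  y <- rnorm(30) + rep(c(0, 2, -1), each = 10)
  fit <- fit_models(y, 8)
  rss <- vapply(fit$models, `[[`, numeric(1), "rss")
  path <- model_complexity_path(fit)
  for (lambda in exp(seq(log(1e-4), log(100), length.out = 200))) {
    expect_equal(annotseg:::select_at_penalty(path, lambda),
                 oracle_select_k(rss, lambda))
  }
})

test_that("penalty targets are the widest zero-error log-lambda interval", {
  sim <- simulate_profile(120, changes = c(40, 80), means = c(0, 1.2, 0),
                          noise_sd = 0.1, seed = 32)
  pr <- sim$profile$chromosomes[[1]]
  fit <- fit_models(pr$logratio, 10)
  anns <- annotations_from_truth(sim$truth, seed = 33)$breakpoint
  ex <- make_example(fit, pr$start, pr$logratio, anns)
  expect_false(is.null(ex))
  expect_equal(unname(ex$features),
               c(1, log(fit$d), log(robust_scale(pr$logratio))))
  expect_true(ex$lo < ex$hi)
  # a fine grid of penalties confirms zero error strictly inside the
  # target and nonzero error just outside each finite endpoint
  path <- model_complexity_path(fit)
  err_at <- function(loglam) {
    k <- annotseg:::select_at_penalty(path, exp(loglam))
    annotation_error(fit$models[[k]], pr$start, anns)
  }
  inside <- seq(max(ex$lo, -10) + 1e-3, min(ex$hi, 10) - 1e-3, length.out = 50)
  expect_true(all(vapply(inside, err_at, integer(1)) == 0L))
  if (is.finite(ex$lo)) expect_gt(err_at(ex$lo - 1e-3), 0L)
  if (is.finite(ex$hi)) expect_gt(err_at(ex$hi + 1e-3), 0L)
})

test_that("a fully consistent chromosome yields an unbounded target", {
  sim <- simulate_profile(50, noise_sd = 0.1, seed = 34)  # no true changes
  pr <- sim$profile$chromosomes[[1]]
  fit <- fit_models(pr$logratio, 3)
  # only one uninformative region consistent with every model
  anns <- data.frame(chrom = "chr1", start = 0, end = 1, label = "0breakpoints")
  ex <- make_example(fit, pr$start, pr$logratio, anns)
  expect_equal(ex$lo, -Inf)
  expect_equal(ex$hi, Inf)
})

test_that("chromosomes with no zero-error penalty yield no example", {
  sim <- simulate_profile(100, changes = seq(10, 90, by = 10),
                          means = rep(c(0, 1), length.out = 10),
                          noise_sd = 0.05, seed = 35)
  pr <- sim$profile$chromosomes[[1]]
  anns <- annotations_from_truth(sim$truth, seed = 36)$breakpoint
  one <- anns[anns$label == "1breakpoint", ]
  fit <- fit_models(pr$logratio, 5)  # cannot carry 9 breakpoints
  expect_null(make_example(fit, pr$start, pr$logratio, one))
})

mk_example <- function(features, lo, hi) {
  structure(list(features = features, lo = lo, hi = hi),
            class = "penalty_example")
}

test_that("interval regression achieves zero loss on feasible targets", {
  # two overlapping finite targets sharing a common point
  exs <- list(
    mk_example(c(1, log(100), log(0.2)), 0, 4),
    mk_example(c(1, log(500), log(0.4)), 2, 6)
  )
  reg <- fit_interval_regression(exs)
  for (e in exs) {
    f <- sum(reg$weights * e$features)
    expect_gt(f, e$lo)
    expect_lt(f, e$hi)
  }

  # targets constructed around a known linear predictor are all satisfied
  set.seed(37)
  w_true <- c(2, 0.5, 1.8)
  exs <- lapply(1:12, function(i) {
    x <- c(1, log(sample(50:2000, 1)), log(runif(1, 0.05, 0.5)))
    f <- sum(w_true * x)
    mk_example(x, f - 2, f + 2)
  })
  reg <- fit_interval_regression(exs)
  pred <- vapply(exs, function(e) sum(reg$weights * e$features), numeric(1))
  lo <- vapply(exs, `[[`, numeric(1), "lo")
  hi <- vapply(exs, `[[`, numeric(1), "hi")
  expect_true(all(pred > lo & pred < hi))
  # training is deterministic: refitting reproduces identical weights
  expect_identical(reg$weights, fit_interval_regression(exs)$weights)

  expect_error(fit_interval_regression(exs[1]), "at least 2")
})

test_that("predicted k follows the penalized argmin, with the BIC fallback", {
  seq3 <- mk_seq(c(10, 2, 1.9))
  set.seed(38)
  y <- rnorm(20)
  # lambda-hat = 1 lands in the k = 2 piece of the path
  reg <- structure(list(weights = c(0, 0, 0), margin = 1, trained_on = 2),
                   class = "interval_regression")
  expect_equal(predict_segments(reg, seq3, seq(0, by = 10, length.out = 20), y), 2L)
  # a huge penalty always selects one segment
  reg$weights <- c(50, 0, 0)
  expect_equal(predict_segments(reg, seq3, seq(0, by = 10, length.out = 20), y), 1L)
  # fallback penalty equals s^2 log d evaluated on the path
  khat <- predict_segments(NULL, seq3, seq(0, by = 10, length.out = 20), y)
  lam <- robust_scale(y)^2 * log(seq3$d)
  expect_equal(khat, oracle_select_k(c(10, 2, 1.9), lam))
})

test_that("displayed model is the consistent k closest to k-hat, ties down", {
  sim <- simulate_profile(150, changes = c(50, 100), means = c(0, 1, 0),
                          noise_sd = 0.08, seed = 39)
  pr <- sim$profile$chromosomes[[1]]
  fit <- fit_models(pr$logratio, 8)
  anns <- annotations_from_truth(sim$truth, seed = 40)$breakpoint
  cons <- consistent_models(fit, pr$start, anns)
  dm <- select_displayed(fit, pr$start, pr$logratio, anns)
  expect_equal(dm$algorithm, "pruneddp")
  expect_equal(dm$model$k, cons[which.min(abs(cons - dm$k_hat))])
  expect_equal(annotation_error(dm$model, pr$start, anns), 0L)
  # the tie rule itself: equidistant consistent counts resolve downward
  expect_equal(c(3L, 5L)[which.min(abs(c(3L, 5L) - 4L))], 3L)
})

test_that("regression round-trips through its key-value serialization", {
  exs <- list(
    mk_example(c(1, log(100), log(0.2)), 0, 4),
    mk_example(c(1, log(500), log(0.4)), 2, 6)
  )
  reg <- fit_interval_regression(exs)
  path <- tempfile()
  write_regression(reg, path)
  back <- read_regression(path)
  expect_equal(back$weights, reg$weights)
  expect_equal(back$margin, reg$margin)
  expect_equal(back$trained_on, reg$trained_on)
})
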