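test_that("linear SVM recovers the analytic two-point solution", {
  # symmetric 1-D problem: support vectors at +/-1, boundary at 0, w = 1
  fit <- train_linear_svm(matrix(c(1, 3, -1, -3)), c(1, 1, -1, -1))
  expect_equal(unname(fit$w), 1, tolerance = 1e-6)
  expect_equal(fit$b, 0, tolerance = 1e-6)
  expect_gt(predict(fit, matrix(2), type = "decision"), 0)
  expect_lt(predict(fit, matrix(-2), type = "decision"), 0)
  expect_equal(predict(fit, matrix(c(2, -2))), c(1, -1))

  # orientation must not depend on which class comes first in the data
  flip <- train_linear_svm(matrix(c(-1, -3, 1, 3)), c(-1, -1, 1, 1))
  expect_equal(unname(flip$w), 1, tolerance = 1e-6)

  expect_error(train_linear_svm(matrix(1:3), c(1, 1, 1)), "Both classes")
})

test_that("duplicated training rows leave separable decisions unchanged", {
  set.seed(10)
  X <- rbind(matrix(rnorm(20, mean = 3), 10, 2),
             matrix(rnorm(20, mean = -3), 10, 2))
  y <- rep(c(1, -1), each = 10)
  probe <- matrix(rnorm(60), 30, 2)
  f1 <- predict(train_linear_svm(X, y), probe)
  f2 <- predict(train_linear_svm(rbind(X, X), c(y, y)), probe)
  expect_identical(f1, f2)
})

test_that("scaling all features by a positive constant preserves predictions", {
  set.seed(11)
  X <- rbind(matrix(rnorm(16, 2), 8, 2), matrix(rnorm(16, -2), 8, 2))
  y <- rep(c(1, -1), each = 8)
  probe <- matrix(rnorm(40), 20, 2)
  p1 <- predict(train_linear_svm(X, y), probe)
  p2 <- predict(train_linear_svm(X * 7, y), probe * 7)
  expect_identical(p1, p2)
})

test_that("leave-pair-out folds match hand-enumerated 1-D fixtures", {
  # 2 per class: folds train on {3, -3}-style pairs, boundary at midpoints
  ss <- make_sample_set(matrix(c(1, 3, -1, -3)), c(1, 1, -1, -1))
  res <- leave_pair_out_cv(ss)
  expect_equal(res$n_folds, 2)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$accuracy, lopo_oracle_1d(c(1, 3, -1, -3), c(1, 1, -1, -1)))

  # fixtures up to 6 samples, including imperfectly separable folds
  fixtures <- list(
    list(x = c(2, 4, 6, -2, -4, -6), l = c(1, 1, 1, -1, -1, -1)),
    list(x = c(1.5, 30, 3, -1.5, -3, -30), l = c(1, 1, 1, -1, -1, -1)),
    list(x = c(2, 4, 6, -2, -4, -30), l = c(1, 1, 1, -1, -1, -1)),
    list(x = c(2, 4, -2, -4), l = c(1, 1, -1, -1))
  )
  for (f in fixtures) {
    got <- leave_pair_out_cv(make_sample_set(matrix(f$x), f$l))$accuracy
    expect_equal(got, lopo_oracle_1d(f$x, f$l))
  }
})

test_that("well-separated clusters decode perfectly; accuracy is quantized", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40, 10), 20, 2), matrix(rnorm(40, -10), 20, 2))
  ss <- make_sample_set(X, rep(c(1, -1), each = 20))
  res <- leave_pair_out_cv(ss)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_folds, 20)

  # accuracy always lives on the 1/(2 n_folds) lattice
  set.seed(13)
  noisy <- make_sample_set(matrix(rnorm(24), 12, 2), rep(c(1, -1), 6))
  acc <- leave_pair_out_cv(noisy)$accuracy
  expect_equal(acc * 12, round(acc * 12))

  unbal <- make_sample_set(matrix(rnorm(3)), c(1, 1, -1))
  expect_error(leave_pair_out_cv(unbal), "balanced")
})

test_that("permuted labels decode at chance on average", {
  set.seed(14)
  X <- matrix(rnorm(36 * 5), 36, 5)
  accs <- vapply(1:200, function(i) {
    labels <- sample(rep(c(1, -1), 18))
    leave_pair_out_cv(make_sample_set(X, labels))$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.02)
})

test_that("random pairing is seeded and reproducible", {
  set.seed(15)
  X <- matrix(rnorm(24 * 3), 24, 3)
  ss <- make_sample_set(X, rep(c(1, -1), 12))
  a <- leave_pair_out_cv(ss, pairing = "random", seed = 3)
  b <- leave_pair_out_cv(ss, pairing = "random", seed = 3)
  expect_identical(a, b)
})

test_that("decode_all is a deterministic map over cells with gap reporting", {
  sets <- list()
  set.seed(16)
  for (i in 1:3) {
    sets[[i]] <- make_sample_set(matrix(rnorm(16), 8, 2), rep(c(1, -1), 4),
                                 classification = paste0("c", i))
  }
  tbl <- tibble::tibble(samples = sets)
  out1 <- decode_all(tbl)
  out2 <- decode_all(tbl)
  expect_identical(out1, out2)
  expect_equal(nrow(out1), 3)
  expect_equal(out1$accuracy[1],
               leave_pair_out_cv(sets[[1]])$accuracy)

  # an unbalanced cell is skipped and reported, not fatal
  sets[[4]] <- make_sample_set(matrix(rnorm(3)), c(1, 1, -1),
                               classification = "broken")
  expect_message(out3 <- decode_all(tibble::tibble(samples = sets)),
                 "Skipping")
  expect_equal(nrow(out3), 3)
  expect_equal(attr(out3, "gaps")$classification, "broken")
})

test_that("independent QP solver agrees on the decision function", {
  skip_if_not_installed("kernlab")
  set.seed(17)
  X <- rbind(matrix(rnorm(30, 1.5), 15, 2), matrix(rnorm(30, -1.5), 15, 2))
  y <- rep(c(1, -1), each = 15)
  fit <- train_linear_svm(X, y, C = 1)
  kfit <- kernlab::ksvm(X, factor(y), kernel = "vanilladot", C = 1,
                        scaled = FALSE, kpar = list())
  probe <- matrix(rnorm(40), 20, 2)
  mine <- predict(fit, probe)
  theirs <- as.numeric(as.character(kernlab::predict(kfit, probe)))
  expect_equal(mine, theirs)
})
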