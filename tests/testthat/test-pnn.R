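test_that("pnn stores exemplars verbatim and validates input", {
  f <- gauss_features(10, 3, delta = 2, seed = 51)
  model <- pnn(f, sigma = 1.5)
  expect_equal(nrow(model$exemplars), 20)
  expect_error(pnn(f, sigma = 0), "positive")
  expect_error(pnn(f, sigma = -1), "positive")
  expect_error(pnn(f[f$group == 1, ], sigma = 1), "both classes")
})

test_that("small sigma gives nearest-exemplar classification", {
  f <- gauss_features(15, 2, delta = 3, seed = 52)
  model <- pnn(f, sigma = 1e-4)
  # query very near known exemplars of each class
  q0 <- f[2, ]; q0$f1 <- q0$f1 + 1e-6
  q1 <- f[25, ]; q1$f2 <- q1$f2 + 1e-6
  expect_identical(predict(model, q0)$.pred_class, 0L)
  expect_identical(predict(model, q1)$.pred_class, 1L)
  # exact nearest-exemplar rule on random queries
  set.seed(52)
  q <- tibble::tibble(f1 = rnorm(20, 1.5, 2), f2 = rnorm(20, 1.5, 2))
  pred <- predict(model, q)$.pred_class
  xs <- model$exemplars
  qs <- sweep(sweep(as.matrix(q), 2, model$center), 2, model$scale, "/")
  nn <- apply(qs, 1, function(v)
    model$labels[which.min(colSums((t(xs) - v)^2))])
  expect_identical(pred, as.integer(nn))
})

test_that("an exact tie resolves to class 0", {
  f <- tibble::tibble(subject_id = c("a", "b"), group = c(0L, 1L),
                      f1 = c(-1, 1))
  model <- pnn(f, sigma = 1, standardize = FALSE)
  pred <- predict(model, tibble::tibble(f1 = 0))
  expect_equal(pred$.pred_0, 0.5)
  expect_identical(pred$.pred_class, 0L)
})

test_that("predictions are invariant to duplicating every exemplar", {
  f <- gauss_features(12, 3, delta = 1, seed = 53)
  doubled <- dplyr::bind_rows(f, dplyr::mutate(f, subject_id = paste0(subject_id, "b")))
  q <- tibble::tibble(f1 = rnorm(10), f2 = rnorm(10), f3 = rnorm(10))
  p1 <- predict(pnn(f, sigma = 0.8, standardize = FALSE), q)
  p2 <- predict(pnn(doubled, sigma = 0.8, standardize = FALSE), q)
  expect_equal(p1$.pred_1, p2$.pred_1, tolerance = 1e-12)
})

test_that("large sigma drives class scores together", {
  f <- gauss_features(10, 2, delta = 4, seed = 54)
  q <- tibble::tibble(f1 = 2, f2 = 2)
  p <- predict(pnn(f, sigma = 1e6), q)
  expect_equal(p$.pred_0, 0.5, tolerance = 1e-6)
})

test_that("well-separated clusters are classified almost perfectly", {
  train <- gauss_features(50, 3, delta = 4, seed = 55)
  test <- gauss_features(50, 3, delta = 4, seed = 56)
  model <- pnn(train, sigma = 1.5)
  pred <- predict(model, test)
  expect_gte(mean(pred$.pred_class == test$group), 0.95)
})

test_that("dimension mismatch and missing columns raise errors", {
  f <- gauss_features(8, 3, seed = 57)
  model <- pnn(f, sigma = 1)
  expect_error(predict(model, tibble::tibble(f1 = 1, f2 = 2)), "f3")
  expect_error(predict(model, c(1, 2)), "dimension mismatch")
})

test_that("tune_sigma scans the default 20-candidate grid and breaks ties down", {
  f <- gauss_features(15, 2, delta = 3, seed = 58)
  s <- tune_sigma(f, seed = 3)
  expect_length(attr(s, "accuracy"), 20)
  expect_true(s %in% seq(0.1, 2, by = 0.1))
  expect_identical(as.numeric(tune_sigma(f, sigma_grid = 0.7, seed = 3)), 0.7)
  # separable data: every sigma perfect -> tie -> smallest candidate
  well <- gauss_features(15, 2, delta = 8, seed = 59)
  expect_equal(as.numeric(tune_sigma(well, seed = 3)), 0.1)
})

test_that("holdout_split is stratified, exact and reproducible", {
  f <- gauss_features(50, 2, seed = 60)
  f$group <- rep(c(0L, 1L), c(43, 57))  # unbalance it
  sp <- holdout_split(f, c("0" = 9, "1" = 11), seed = 17)
  expect_equal(sum(sp$train$group == 0), 34)
  expect_equal(sum(sp$test$group == 0), 9)
  expect_equal(sum(sp$train$group == 1), 46)
  expect_equal(sum(sp$test$group == 1), 11)
  sp2 <- holdout_split(f, c("0" = 9, "1" = 11), seed = 17)
  expect_identical(sp$test$subject_id, sp2$test$subject_id)
  all_train <- holdout_split(f, c("0" = 0, "1" = 0), seed = 1)
  expect_equal(nrow(all_train$train), nrow(f))
  expect_error(holdout_split(f, c("0" = 99, "1" = 0), seed = 1), "99")
})

test_that("cross_validate partitions subjects into near-equal folds", {
  f <- gauss_features(49, 2, delta = 4, seed = 61)
  # 98 subjects, 10 folds -> folds of 10 or 9
  cv <- cross_validate(f, n_folds = 10, sigma = 1.5, seed = 9)
  expect_equal(sum(cv$n_test), 98)
  expect_true(all(cv$n_test %in% c(9, 10)))
  expect_equal(attr(cv, "mean"), mean(cv$accuracy), tolerance = 1e-12)
  expect_equal(attr(cv, "std"), sd(cv$accuracy), tolerance = 1e-12)
  expect_gte(attr(cv, "mean"), 95)
  cv2 <- cross_validate(f, n_folds = 10, sigma = 1.5, seed = 9)
  expect_identical(cv$accuracy, cv2$accuracy)
  expect_error(cross_validate(f[1:12, ], n_folds = 10, sigma = 1), "folds")
})

test_that("seeded helpers leave the caller's RNG stream untouched", {
  f <- gauss_features(20, 2, delta = 3, seed = 62)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(cross_validate(f, n_folds = 5, sigma = 1, seed = 3))
  expect_identical(rnorm(1), before)
})
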