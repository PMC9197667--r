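# Probabilistic neural network: a Parzen-window Bayes classifier with
# four conceptual layers (input, pattern, summation, decision) and no
# iterative weight training — the pattern layer holds the training
# exemplars verbatim, one Gaussian kernel exp(-||x - w_k||^2 / (2 sigma^2))
# per exemplar, and the summation layer averages kernels per class.
#
# Numerical detail: kernels are evaluated with a common shift of the
# smallest squared distance before exponentiation. The shift cancels in the
# class-posterior normalization but keeps the sigma -> 0 limit equal to
# nearest-exemplar classification instead of a 0/0 tie.

feature_xy <- function(features) {
  stopifnot(is.data.frame(features))
  cols <- setdiff(names(features), c("subject_id", "group"))
  list(x = as.matrix(features[, cols, drop = FALSE]),
       y = as.integer(features$group),
       cols = cols)
}

#' Fit a probabilistic neural network
#'
#' Stores the training exemplars and labels; there is no weight training.
#' Feature columns are z-scored with the training statistics (and the same
#' transform is applied at prediction time) so that one smoothing factor
#' sigma is meaningful across features. Class kernel sums are normalized by
#' class size (uniform priors) by default, appropriate when group sizes are
#' unbalanced by sampling rather than by prevalence.
#'
#' @param features A `feature_matrix` tibble (columns `subject_id`, `group`,
#'   then numeric features), or any data frame shaped that way.
#' @param sigma Smoothing factor of the Gaussian kernels (> 0).
#' @param prior `"uniform"` (default) or `"proportional"` to class counts.
#' @param standardize Z-score feature columns with training statistics
#'   (default `TRUE`).
#' @return A `pnn` model object.
#' @export
pnn <- function(features, sigma = 1.5, prior = c("uniform", "proportional"),
                standardize = TRUE) {
  prior <- match.arg(prior)
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0)
    abort("sigma must be a single positive number")
  d <- feature_xy(features)
  if (length(unique(d$y)) < 2)
    abort("training data must contain both classes")
  if (anyNA(d$x)) abort("missing values in features")
  center <- if (standardize) colMeans(d$x) else rep(0, ncol(d$x))
  scale <- if (standardize) apply(d$x, 2, sd) else rep(1, ncol(d$x))
  scale[scale == 0] <- 1
  out <- list(exemplars = sweep(sweep(d$x, 2, center), 2, scale, "/"),
              labels = d$y, sigma = sigma, prior = prior,
              center = center, scale = scale, feature_names = d$cols)
  class(out) <- "pnn"
  out
}

#' @export
print.pnn <- function(x, ...) {
  cat("<pnn> ", nrow(x$exemplars), " pattern units (",
      sum(x$labels == 0), "/", sum(x$labels == 1), " per class), ",
      length(x$feature_names), " input features, sigma = ", x$sigma,
      ", ", x$prior, " priors\n", sep = "")
  invisible(x)
}

#' @method glance pnn
#' @export
glance.pnn <- function(x, ...) {
  tibble(n_exemplars = nrow(x$exemplars), n_features = length(x$feature_names),
         sigma = x$sigma, prior = x$prior)
}

#' Predict classes with a PNN
#'
#' Decision layer: argmax of the class-normalized kernel sums; an exact tie
#' resolves deterministically to class 0. Per-class scores (posterior
#' probabilities) are returned for audit.
#'
#' @param object A `pnn` model.
#' @param new_data Data frame with the model's feature columns (extra
#'   columns such as `subject_id`/`group` are ignored).
#' @param ... Unused.
#' @return Tibble with `.pred_class` (integer 0/1), `.pred_0`, `.pred_1`.
#' @export
predict.pnn <- function(object, new_data, ...) {
  if (is.data.frame(new_data)) {
    missing <- setdiff(object$feature_names, names(new_data))
    if (length(missing) > 0)
      abort(paste0("new_data lacks feature column(s): ",
                   paste(missing, collapse = ", ")))
    x <- as.matrix(new_data[, object$feature_names, drop = FALSE])
  } else {
    nf <- length(object$feature_names)
    if (length(new_data) %% nf != 0) abort("feature dimension mismatch")
    x <- matrix(new_data, ncol = nf, byrow = TRUE)
  }
  if (ncol(x) != length(object$feature_names))
    abort("feature dimension mismatch")
  x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")

  w <- switch(object$prior,
              uniform = 1 / pmax(table(factor(object$labels, c(0, 1))), 1),
              proportional = rep(1 / length(object$labels), 2))
  n <- nrow(x)
  p0 <- p1 <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(object$exemplars, 2, x[i, ])^2)
    k <- exp(-(d2 - min(d2)) / (2 * object$sigma^2))  # shift cancels below
    s0 <- w[[1]] * sum(k[object$labels == 0])
    s1 <- w[[2]] * sum(k[object$labels == 1])
    tot <- s0 + s1
    p0[i] <- s0 / tot; p1[i] <- s1 / tot
  }
  tibble(.pred_class = as.integer(p1 > p0), .pred_0 = p0, .pred_1 = p1)
}

# Stratified fold assignment: within each class, shuffle then deal into
# folds round-robin, so fold sizes differ by at most one per class.
make_folds <- function(y, n_folds, seed) {
  if (n_folds < 2) abort("n_folds must be >= 2")
  cnt <- table(factor(y, c(0, 1)))
  if (any(cnt < n_folds))
    abort(paste0("smallest class has ", min(cnt), " subjects; use at most ",
                 min(cnt), " folds"))
  rng <- local_rng(seed)
  fold <- integer(length(y))
  ptr <- 0L  # global rotation keeps overall fold sizes within one subject
  for (cls in c(0L, 1L)) {
    idx <- sample(which(y == cls))
    fold[idx] <- (ptr + seq_along(idx) - 1L) %% n_folds + 1L
    ptr <- ptr + length(idx)
  }
  fold
}

# Accuracy (%) of PNN over pre-assigned folds at a fixed sigma.
fold_accuracies <- function(features, fold, sigma, prior = "uniform") {
  vapply(sort(unique(fold)), function(f) {
    train <- features[fold != f, , drop = FALSE]
    test <- features[fold == f, , drop = FALSE]
    model <- pnn(train, sigma = sigma, prior = prior)
    pred <- predict(model, test)
    100 * mean(pred$.pred_class == test$group)
  }, numeric(1))
}

#' Tune the smoothing factor
#'
#' Stratified cross-validated accuracy on the training features for every
#' candidate sigma; returns the maximizer, ties resolving to the smaller
#' sigma. The default grid is 0.1 to 2 in steps of 0.1.
#'
#' @param features A `feature_matrix`-shaped data frame.
#' @param sigma_grid Candidate smoothing factors (positive).
#' @param n_folds Folds of the internal cross-validation (default 10,
#'   reduced automatically if a class is smaller).
#' @param seed Seed for the fold assignment.
#' @param prior Passed to [pnn()].
#' @return The selected sigma; attribute `accuracy` holds the per-candidate
#'   mean accuracies.
#' @export
tune_sigma <- function(features, sigma_grid = seq(0.1, 2, by = 0.1),
                       n_folds = 10, seed = 1, prior = "uniform") {
  if (length(sigma_grid) == 0 || any(sigma_grid <= 0))
    abort("sigma_grid must be nonempty and positive")
  y <- as.integer(features$group)
  n_folds <- min(n_folds, min(table(factor(y, c(0, 1)))))
  fold <- make_folds(y, n_folds, seed)
  acc <- vapply(sigma_grid,
                function(s) mean(fold_accuracies(features, fold, s, prior)),
                numeric(1))
  best <- sigma_grid[order(-acc, sigma_grid)][1]
  attr(best, "accuracy") <- setNames(acc, sigma_grid)
  best
}

#' Stratified holdout split
#'
#' Randomly holds out a fixed number of subjects per class for testing,
#' reproducibly given the seed.
#'
#' @param features A `feature_matrix`-shaped data frame.
#' @param n_test Named numeric, test-set sizes per class, e.g.
#'   `c("0" = 9, "1" = 11)`.
#' @param seed Seed for the random selection.
#' @return List with `train` and `test` tibbles (row order preserved
#'   within each part).
#' @export
holdout_split <- function(features, n_test, seed = 1) {
  y <- as.integer(features$group)
  cnt <- table(factor(y, c(0, 1)))
  for (cls in c("0", "1")) {
    nt <- n_test[[cls]] %||% 0
    if (nt < 0 || nt > cnt[[cls]])
      abort(paste0("requested ", nt, " test subjects from class ", cls,
                   " of size ", cnt[[cls]]))
  }
  rng <- local_rng(seed)
  test_idx <- integer(0)
  for (cls in c(0L, 1L)) {
    nt <- n_test[[as.character(cls)]] %||% 0
    if (nt > 0) test_idx <- c(test_idx, sample(which(y == cls), nt))
  }
  test_idx <- sort(test_idx)
  list(train = features[setdiff(seq_along(y), test_idx), , drop = FALSE],
       test = features[test_idx, , drop = FALSE])
}

#' N-fold cross-validated PNN accuracy
#'
#' Stratified, shuffled folds (seeded); each fold is held out in turn while
#' the PNN is fit on the rest. With `sigma = NULL` the smoothing factor is
#' tuned within each training fold by an internal stratified
#' cross-validation, so the held-out fold never influences the tuning.
#'
#' @param features A `feature_matrix`-shaped data frame.
#' @param n_folds Number of folds N (default 10).
#' @param sigma Fixed smoothing factor, or `NULL` to tune per fold.
#' @param seed Seed controlling fold assignment (and tuning folds).
#' @param sigma_grid Candidate grid when tuning (default 0.1..2 step 0.1).
#' @param prior Passed to [pnn()].
#' @return A `pnn_cv` report: tibble of per-fold `n_test` and `accuracy`
#'   (%), with attributes `mean`, `std`, `n_folds`, `seed`, `sigma`.
#' @export
cross_validate <- function(features, n_folds = 10, sigma = 1.5, seed = 1,
                           sigma_grid = seq(0.1, 2, by = 0.1),
                           prior = "uniform") {
  y <- as.integer(features$group)
  fold <- make_folds(y, n_folds, seed)
  sigmas <- numeric(n_folds)
  acc <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    train <- features[fold != f, , drop = FALSE]
    test <- features[fold == f, , drop = FALSE]
    s <- if (is.null(sigma))
      tune_sigma(train, sigma_grid, n_folds = 5, seed = seed + f,
                 prior = prior)
    else sigma
    sigmas[f] <- s
    model <- pnn(train, sigma = s, prior = prior)
    pred <- predict(model, test)
    acc[f] <- 100 * mean(pred$.pred_class == test$group)
  }
  fold_sizes <- tabulate(fold, n_folds)
  out <- tibble(fold = seq_len(n_folds), n_test = fold_sizes,
                sigma = sigmas, accuracy = acc)
  attr(out, "mean") <- mean(acc)
  attr(out, "std") <- sd(acc)
  attr(out, "n_folds") <- n_folds
  attr(out, "seed") <- seed
  attr(out, "sigma") <- if (is.null(sigma)) NA_real_ else sigma
  class(out) <- c("pnn_cv", class(out))
  out
}

#' @export
print.pnn_cv <- function(x, ...) {
  cat("<pnn_cv> ", attr(x, "n_folds"), "-fold accuracy: ",
      sprintf("%.2f%% +/- %.2f%%", attr(x, "mean"), attr(x, "std")),
      " (seed ", attr(x, "seed"), ")\n", sep = "")
  NextMethod()
}

#' @method tidy pnn_cv
#' @export
tidy.pnn_cv <- function(x, ...) as_tibble(x)

#' @method glance pnn_cv
#' @export
glance.pnn_cv <- function(x, ...) {
  tibble(mean_accuracy = attr(x, "mean"), std_accuracy = attr(x, "std"),
         n_folds = attr(x, "n_folds"), seed = attr(x, "seed"))
}

#' @method autoplot pnn_cv
#' @export
autoplot.pnn_cv <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "mean"),
                        linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "accuracy (%)",
                  title = sprintf("%d-fold cross-validation: %.2f%% ± %.2f%%",
                                  attr(object, "n_folds"), attr(object, "mean"),
                                  attr(object, "std")))
}
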