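# Two-group statistics for a single region's entropy values:
# Welch t-test (p-value) and ROC/AUC (sensitivity index).
#
# Orientation convention used throughout: group 1 (excellent) is the
# positive class and higher entropy scores toward "excellent", i.e.
# AUC = P(score_1 > score_0) + 0.5 * P(tie). AUC is never folded: values
# below 0.5 are reported as-is and labeled "below-chance".

#' Two-sample t-test between groups
#'
#' Welch's unequal-variance t-test by default (group sizes in this setting
#' are typically unbalanced and variance equality unverified); set
#' `var_equal = TRUE` for the pooled-variance test. Wraps [stats::t.test()].
#'
#' @param a,b Numeric vectors (group 0 and group 1), each of length >= 2.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return One-row tibble: `t_statistic`, `df`, `p_value`, `n0`, `n1`,
#'   `mean0`, `mean1`, `computable`. When a group is too small or both
#'   groups are constant the result is flagged `computable = FALSE` with
#'   `NA` statistics rather than an error.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  base <- tibble(t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                 n0 = length(a), n1 = length(b),
                 mean0 = if (length(a)) mean(a) else NA_real_,
                 mean1 = if (length(b)) mean(b) else NA_real_,
                 computable = FALSE)
  if (length(a) < 2 || length(b) < 2) return(base)
  tt <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) return(base)
  base$t_statistic <- unname(tt$statistic)
  base$df <- unname(tt$parameter)
  base$p_value <- tt$p.value
  base$computable <- TRUE
  base
}

# Tie-corrected Mann-Whitney AUC via midranks; fast enough for the inner
# loop of the parameter grid. scores1 = positive class.
auc_rank <- function(scores0, scores1) {
  n0 <- length(scores0); n1 <- length(scores1)
  rk <- rank(c(scores0, scores1))
  u1 <- sum(rk[(n0 + 1):(n0 + n1)]) - n1 * (n1 + 1) / 2
  u1 / (n0 * n1)
}

#' ROC curve and AUC for a two-group score
#'
#' Positive class is group 1 (excellent); higher scores count toward the
#' positive class. The AUC equals the tie-corrected Mann-Whitney statistic
#' U / (n0 * n1) = P(excellent score > poor score) + 0.5 P(tie), and also
#' the trapezoidal area under the returned curve. No folding is applied:
#' an AUC below 0.5 is reported as-is.
#'
#' @param scores0 Scores of group 0 (poor), nonempty.
#' @param scores1 Scores of group 1 (excellent), nonempty.
#' @return A `roc_result`: list with `auc`, `curve` (tibble of `fpr`, `tpr`
#'   ordered from (0,0) to (1,1)), `n0`, `n1` and the orientation note.
#' @export
roc_auc <- function(scores0, scores1) {
  scores0 <- scores0[!is.na(scores0)]; scores1 <- scores1[!is.na(scores1)]
  if (length(scores0) == 0 || length(scores1) == 0)
    abort("both groups must contain at least one score")
  n0 <- length(scores0); n1 <- length(scores1)
  # thresholds descending; ties grouped so the curve is a step/diagonal path
  thr <- sort(unique(c(scores0, scores1)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores1 >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores0 >= t) / n0, numeric(1))
  curve <- tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- bind_rows(curve, tibble(fpr = 1, tpr = 1))
  out <- list(auc = auc_rank(scores0, scores1), curve = curve,
              n0 = n0, n1 = n1,
              orientation = "higher score => positive class (group 1, excellent)")
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", format(x$auc, digits = 4),
      " (", auc_band(x$auc), "), n0 = ", x$n0, ", n1 = ", x$n1, "\n",
      "  ", x$orientation, "\n", sep = "")
  invisible(x)
}

#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, band = auc_band(x$auc), n0 = x$n0, n1 = x$n1)
}

#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc))
}

#' Qualitative band of an AUC value
#'
#' The conventional five-level reading of AUC: 0.50-0.59 poor, 0.60-0.69
#' bad, 0.70-0.79 medium, 0.80-0.89 good, 0.90-1 excellent. Values below
#' 0.50 (possible because AUC is not folded) are labeled "below-chance".
#'
#' @param auc Numeric vector of AUC values in \[0, 1\].
#' @return Character vector of band labels.
#' @export
#' @examples
#' auc_band(c(0.492, 0.683, 0.90))
auc_band <- function(auc) {
  if (any(is.na(auc)) || any(auc < 0) || any(auc > 1))
    abort("AUC values must lie in [0, 1]")
  as.character(cut(auc, breaks = c(0, 0.5, 0.6, 0.7, 0.8, 0.9, 1 + 1e-9),
                   labels = c("below-chance", "poor", "bad", "medium",
                              "good", "excellent"),
                   right = FALSE))
}
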