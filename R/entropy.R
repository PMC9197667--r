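# Sample entropy and multiscale entropy.
#
# Conventions (stated once, used everywhere):
#   - the similarity factor r is in SD units: each regional series is
#     z-scored ONCE at scale 1 and never re-normalized per scale, so the
#     cross-scale "complexity loss" interpretation is preserved;
#   - Chebyshev template distance, strict matches d < r, self-matches
#     excluded, and m-matches restricted to templates extendable to m+1
#     so that C^{m+1}/C^m is a proper conditional probability;
#   - zero match counts yield an undefined (NA) entropy, never +/-Inf.

#' Coarse-grain a time series
#'
#' Replaces non-overlapping blocks of `tau` consecutive samples by their
#' mean; the trailing `length(x) %% tau` remainder points are discarded.
#' `tau = 1` returns the series unchanged.
#'
#' @param x Numeric vector.
#' @param tau Scale factor (positive integer, at most `length(x)`).
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
#' @examples
#' coarse_grain(1:6, 2)  # 1.5 3.5 5.5
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (length(tau) != 1 || is.na(tau) || tau < 1)
    abort("tau must be a positive integer")
  if (tau > length(x))
    abort(paste0("tau (", tau, ") exceeds series length (", length(x), ")"))
  if (tau == 1) return(as.numeric(x))
  L <- length(x) %/% tau
  colMeans(matrix(x[seq_len(L * tau)], nrow = tau))
}

#' Sample entropy of a series
#'
#' SampEn(m, r) = -ln( C^{m+1}(r) / C^m(r) ), the negative log of the
#' conditional probability that template pairs matching for m points
#' (Chebyshev distance < r, self-matches excluded) also match for m + 1.
#' Low values indicate a regular signal. The input is used as given: for
#' r in SD units, pass a z-scored series (see [mse()], which normalizes
#' once at scale 1).
#'
#' @param y Numeric series (no missing values).
#' @param m Embedding dimension (positive integer).
#' @param r Similarity factor (tolerance), > 0, in the units of `y`.
#' @return Sample entropy, or `NA` when no template pair matches at
#'   dimension m (or m + 1), in which case the estimate is undefined.
#' @export
#' @examples
#' sample_entropy(rep(3, 10), m = 1, r = 0.2)  # 0: every template matches
sample_entropy <- function(y, m = 1, r = 0.5) {
  vals <- sample_entropy_multi(y, m, r)
  vals$entropy[1]
}

# Vectorized-in-r workhorse: one pass over template pairs for a whole
# r grid. Returns a plain list (hot path; no tibble overhead):
# list(r, entropy, defined, A, B).
sample_entropy_multi <- function(y, m, r) {
  m <- as.integer(m)
  if (length(m) != 1 || is.na(m) || m < 1) abort("m must be a positive integer")
  if (anyNA(y)) abort("missing values in series")
  if (length(y) - m < 2)
    abort(paste0("series too short for m = ", m,
                 ": need at least m + 2 = ", m + 2, " points"))
  cnt <- sampen_counts(as.numeric(y), m, as.numeric(r))
  defined <- cnt$A > 0 & cnt$B > 0
  ent <- ifelse(defined, -log(cnt$A / cnt$B), NA_real_)
  list(r = as.numeric(r), entropy = ent, defined = defined,
       A = cnt$A, B = cnt$B)
}

#' Multiscale entropy curve
#'
#' Z-scores the series once (scale 1, population SD), then computes
#' sample entropy of the coarse-grained series at each scale factor in
#' `tau`. The series is deliberately not re-normalized per scale, so the
#' decline of entropy with scale reflects genuine loss of variance and
#' irregularity under averaging. A warning (not an error) is emitted when
#' a coarse series is shorter than `10 * m` points, the usual guidance
#' below which sample entropy becomes unreliable.
#'
#' @param x Numeric series.
#' @param m Embedding dimension.
#' @param r Similarity factor in SD units of the original series.
#' @param tau Integer vector of scale factors (default 1:6).
#' @return An `mse_curve` tibble with columns `tau`, `entropy`, `defined`,
#'   and attributes `m` and `r`.
#' @export
mse <- function(x, m = 1, r = 0.5, tau = 1:6) {
  tau <- as.integer(tau)
  if (any(tau < 1)) abort("all scale factors must be >= 1")
  Lmin <- length(x) %/% max(tau)
  if (Lmin - m < 2)
    abort(paste0("series too short: floor(N / max(tau)) - m must be >= 2, got ",
                 Lmin - m))
  z <- zscore_series(x)
  short <- tau[(length(x) %/% tau) < 10 * m]
  if (length(short) > 0)
    warn(paste0("coarse series shorter than 10*m = ", 10 * m,
                " points at scale(s) ", paste(short, collapse = ", "),
                "; entropy estimates may be unreliable"))
  vals <- vapply(tau, function(tv) {
    se <- sample_entropy_multi(coarse_grain(z, tv), m, r)
    c(se$entropy[1], se$defined[1])
  }, numeric(2))
  out <- tibble(tau = tau, entropy = vals[1, ], defined = as.logical(vals[2, ]))
  attr(out, "m") <- m
  attr(out, "r") <- r
  class(out) <- c("mse_curve", class(out))
  out
}

#' @method autoplot mse_curve
#' @export
autoplot.mse_curve <- function(object, ...) {
  ggplot2::ggplot(object[object$defined, ],
                  ggplot2::aes(x = .data$tau, y = .data$entropy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(object$tau)) +
    ggplot2::labs(x = "scale factor τ", y = "sample entropy",
                  title = sprintf("Multiscale entropy (m = %d, r = %.2f)",
                                  attr(object, "m"), attr(object, "r")))
}

#' Per-subject, per-region entropy table for a cohort
#'
#' Computes sample entropy for every subject, region and combination of the
#' parameter grids, z-scoring each regional series once at scale 1. This is
#' the batch entry point behind the optimization grid; all tolerances in
#' `r` are counted in a single pass over template pairs per (series, m,
#' tau), which makes the dense default grid affordable.
#'
#' @param cohort A [study_cohort()].
#' @param m Integer vector of embedding dimensions (default `1:2`).
#' @param r Numeric vector of similarity factors in SD units
#'   (default `seq(0.05, 0.60, by = 0.05)`).
#' @param tau Integer vector of scale factors (default `1:6`).
#' @param warn_short Emit the short-series warning once if any coarse
#'   length falls below `10 * m` (default `TRUE`).
#' @return Long tibble: `subject_id`, `group`, `region`, `m`, `r`, `tau`,
#'   `entropy`, `defined`.
#' @export
cohort_entropy <- function(cohort, m = 1:2, r = seq(0.05, 0.60, by = 0.05),
                           tau = 1:6, warn_short = TRUE) {
  stopifnot(inherits(cohort, "study_cohort"))
  m <- as.integer(m); tau <- as.integer(tau)
  ntp <- attr(cohort, "n_timepoints")
  if (warn_short) {
    for (mv in m) {
      short <- tau[(ntp %/% tau) < 10 * mv]
      if (length(short) > 0)
        warn(paste0("coarse series shorter than 10*m = ", 10 * mv,
                    " points at scale(s) ", paste(short, collapse = ", "),
                    " for m = ", mv))
    }
  }
  labels <- region_labels(cohort)
  nr <- length(r)
  combos <- expand.grid(tau = tau, m = m)  # tau varies fastest
  ncomb <- nrow(combos)
  block <- ncomb * nr                      # rows per (subject, region)
  nreg <- length(labels)
  nsub <- nrow(cohort)
  total <- nsub * nreg * block
  ent <- numeric(total); def <- logical(total)
  pos <- 0L
  for (i in seq_len(nsub)) {
    mat <- cohort$series[[i]]
    for (g in seq_len(nreg)) {
      z <- zscore_series(mat[g, ])
      for (ci in seq_len(ncomb)) {
        y <- coarse_grain(z, combos$tau[ci])
        se <- sample_entropy_multi(y, combos$m[ci], r)
        idx <- pos + seq_len(nr)
        ent[idx] <- se$entropy; def[idx] <- se$defined
        pos <- pos + nr
      }
    }
  }
  tibble(
    subject_id = rep(cohort$subject_id, each = nreg * block),
    group = rep(cohort$group, each = nreg * block),
    region = rep(rep(labels, each = block), times = nsub),
    m = rep(rep(combos$m, each = nr), times = nsub * nreg),
    r = rep(r, times = nsub * nreg * ncomb),
    tau = rep(rep(combos$tau, each = nr), times = nsub * nreg),
    entropy = ent, defined = def)
}
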