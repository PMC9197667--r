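# Independent brute-force oracles. These enumerate explicitly and stay
# deliberately naive; they share only the counting convention with the
# implementation (templates i = 1..L-m, pairs i < j, Chebyshev distance,
# strict d < r), not any code.

# Sample entropy by exhaustive template-pair enumeration.
oracle_sampen <- function(y, m, r) {
  L <- length(y)
  nt <- L - m
  if (nt < 2) stop("oracle: series too short")
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(y[i:(i + m - 1)] - y[j:(j + m - 1)]))
      if (dm < r) {
        B <- B + 1L
        if (max(dm, abs(y[i + m] - y[j + m])) < r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# Coarse-graining by explicit block loop.
oracle_coarse <- function(x, tau) {
  L <- length(x) %/% tau
  vapply(seq_len(L), function(j) mean(x[((j - 1) * tau + 1):(j * tau)]),
         numeric(1))
}

# AUC by exhaustive pair counting (ties count one half).
oracle_auc <- function(s0, s1) {
  tot <- 0
  for (a in s0) for (b in s1) tot <- tot + (b > a) + 0.5 * (b == a)
  tot / (length(s0) * length(s1))
}

# Welch t-test from the textbook formulas, no stats:: shortcuts beyond
# the t distribution function itself.
oracle_welch <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- sum((a - mean(a))^2) / (n1 - 1)
  v2 <- sum((b - mean(b))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Small planted cohort used by several files: cheap but with a real
# group difference in the first `n_planted` regions.
toy_cohort <- function(n = 10, n_regions = 6, n_planted = 2, seed = 42,
                       delta_phi = 0.5) {
  generate_cohort(n0 = n, n1 = n, n_regions = n_regions,
                  planted_regions = seq_len(n_planted),
                  n_timepoints = 120, phi_base = 0.2, delta_phi = delta_phi,
                  seed = seed)
}

# Feature tibble of two Gaussian clusters separated by `delta` in every
# dimension (class 0 at 0, class 1 at delta).
gauss_features <- function(n_per_class = 30, n_features = 3, delta = 2,
                           sd = 1, seed = 1) {
  set.seed(seed)
  x0 <- matrix(rnorm(n_per_class * n_features, 0, sd), n_per_class)
  x1 <- matrix(rnorm(n_per_class * n_features, delta, sd), n_per_class)
  out <- tibble::as_tibble(as.data.frame(rbind(x0, x1)),
                           .name_repair = "minimal")
  names(out) <- paste0("f", seq_len(n_features))
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(2 * n_per_class)),
                   group = rep(c(0L, 1L), each = n_per_class)),
    out)
}
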