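# Synthetic two-group cohorts with planted, scale-localized complexity
# differences.
#
# Each regional series is a stationary AR(1) process
#   x_t = phi * x_{t-1} + eps_t,  eps ~ N(0, noise_sd^2).
# Background regions use phi = phi_base in both groups. In the planted
# regions of group 0 (poor) the coefficient is raised to
# phi_base + delta_phi: stronger autocorrelation means a more regular
# signal and hence lower sample entropy — the "complexity loss" direction
# in which poorer physiological status shows reduced signal complexity.
# A burn-in is discarded so initial-condition transients cannot bias the
# entropy estimates.

#' Generate a synthetic two-group cohort
#'
#' Defaults emulate a resting-state BOLD study: 43 poor + 55 excellent
#' subjects, 90 AAL-labeled regions of 175 time points each, with nine
#' planted regions whose temporal regularity differs between groups.
#'
#' @param n0,n1 Subjects in group 0 (poor) and group 1 (excellent).
#' @param n_regions Regions per subject (default 90; AAL labels are used
#'   when it is exactly 90, otherwise `R001`, `R002`, ...).
#' @param n_timepoints Time points per series (default 175).
#' @param planted_regions Indices of regions with a planted group
#'   difference (default: nine default-mode-network-adjacent AAL regions).
#' @param phi_base Background AR(1) coefficient (default 0.2, a weakly
#'   autocorrelated band-passed signal).
#' @param delta_phi Extra AR(1) regularity in planted regions of group 0
#'   (default 0.5). `delta_phi = 0` yields a null cohort.
#' @param noise_sd Innovation standard deviation (default 1; entropy is
#'   computed on z-scored series, so this is a free scale).
#' @param seed Seed; the cohort is reproducible byte-identically given it.
#' @param burn_in Initial samples discarded per series (default 500).
#' @return A [study_cohort()]; attribute `planted_regions` records the
#'   planted region labels.
#' @export
generate_cohort <- function(n0 = 43, n1 = 55, n_regions = 90,
                            n_timepoints = 175,
                            planted_regions = c(23, 35, 38, 44, 46, 74, 82, 88, 89),
                            phi_base = 0.2, delta_phi = 0.5, noise_sd = 1,
                            seed = 1, burn_in = 500) {
  if (abs(phi_base) >= 1 || abs(phi_base + delta_phi) >= 1)
    abort("non-stationary configuration: need |phi| < 1 for both groups")
  if (length(planted_regions) > 0 &&
      (min(planted_regions) < 1 || max(planted_regions) > n_regions))
    abort("planted_regions must be indices in 1..n_regions")
  if (n0 < 1 || n1 < 1) abort("both groups need at least one subject")
  labels <- if (n_regions == 90) aal90_labels()
            else sprintf("R%03d", seq_len(n_regions))
  rng <- local_rng(seed)

  make_subject <- function(group) {
    phi <- rep(phi_base, n_regions)
    if (group == 0) phi[planted_regions] <- phi_base + delta_phi
    total <- burn_in + n_timepoints
    mat <- matrix(0, n_regions, n_timepoints, dimnames = list(labels, NULL))
    for (g in seq_len(n_regions)) {
      x <- stats::filter(rnorm(total, sd = noise_sd), phi[g],
                         method = "recursive")
      mat[g, ] <- as.numeric(x)[(burn_in + 1):total]
    }
    mat
  }

  groups <- c(rep(0L, n0), rep(1L, n1))
  ids <- sprintf("S%03d", seq_along(groups))
  series <- lapply(groups, make_subject)
  cohort <- study_cohort(ids, groups, series)
  attr(cohort, "planted_regions") <- labels[planted_regions]
  attr(cohort, "seed") <- seed
  cohort
}

#' Planted regions of a synthetic cohort
#' @param cohort A cohort produced by [generate_cohort()].
#' @return Character vector of planted region labels (empty for cohorts
#'   read from disk).
#' @export
planted_regions <- function(cohort) {
  attr(cohort, "planted_regions") %||% character(0)
}
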