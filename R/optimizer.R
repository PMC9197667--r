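# Grid search over (m, r, tau) and the sequential selection of optimal
# entropy parameters, biomarker regions and feature vectors.
#
# Selection logic, in the order the analysis runs:
#   1. m: the embedding dimension whose mean significant-region count over
#      all (r, tau) cells is largest (tie -> smaller m);
#   2. robust r band: the r values with >= min_regions significant regions
#      at EVERY scale factor;
#   3. tau, then r: by the mean AUC over significant regions per cell,
#      which formalizes "pick the cell where the sensitive regions
#      discriminate best" without singling out one exemplar region.
# The whole optimization is a pure function of (cohort, grids, alpha).

# Rank AUC over defined values of one cell (group 1 = positive class).
cell_auc <- function(values, groups, defined) {
  v <- values[defined]; g <- groups[defined]
  if (!any(g == 0) || !any(g == 1)) return(NA_real_)
  auc_rank(v[g == 0], v[g == 1])
}

# Centered second moment of a subset; NA-free by construction.
cell_var <- function(v) if (length(v) < 2) NA_real_ else stats::var(v)

#' Run the (m, r, tau) optimization grid
#'
#' For every combination of embedding dimension, similarity factor, scale
#' factor and region: per-subject sample entropy (z-scored once at scale 1),
#' then a Welch two-sample t-test and the Mann-Whitney AUC between the two
#' groups. Subjects with undefined entropy in a cell are excluded from that
#' cell's statistics and counted in `n_excluded`. Deterministic given the
#' cohort and grids. Defaults are the usual ranges for short BOLD series:
#' m in 1..2, r = 0.05..0.60 step 0.05, tau = 1..6.
#'
#' @param cohort A [study_cohort()] containing both groups, or a long
#'   entropy table as produced by [cohort_entropy()] (columns `subject_id`,
#'   `group`, `region`, `m`, `r`, `tau`, `entropy`, `defined`), in which
#'   case the entropies are not recomputed and the grids are inferred —
#'   useful for label permutations and for resuming from a saved table.
#' @param m,r,tau Parameter grids (see [cohort_entropy()]); ignored when
#'   `cohort` is already an entropy table.
#' @param p_adjust Optional multiple-testing correction across regions
#'   within each (m, r, tau) cell, passed to [stats::p.adjust()]
#'   (e.g. `"BH"`). Default `"none"`: uncorrected per-region p-values.
#' @return An `entropy_grid` tibble with one row per (m, r, tau, region):
#'   `n0`, `n1`, `mean0`, `mean1`, `t_statistic`, `df`, `p_value`, `auc`,
#'   `n_excluded`; attributes record the grids.
#' @export
entropy_grid <- function(cohort, m = 1:2, r = seq(0.05, 0.60, by = 0.05),
                         tau = 1:6, p_adjust = "none") {
  if (inherits(cohort, "study_cohort")) {
    if (length(m) == 0 || length(r) == 0 || length(tau) == 0)
      abort("all parameter grids must be nonempty")
    if (length(unique(cohort$group)) < 2 || min(table(cohort$group)) < 2)
      abort("cohort must contain at least 2 subjects in each group")
    ent <- cohort_entropy(cohort, m = m, r = r, tau = tau)
    regions <- region_labels(cohort)
    n_subjects <- nrow(cohort)
  } else if (is.data.frame(cohort) &&
             all(c("subject_id", "group", "region", "m", "r", "tau",
                   "entropy", "defined") %in% names(cohort))) {
    ent <- cohort
    m <- sort(unique(ent$m)); r <- sort(unique(ent$r))
    tau <- sort(unique(ent$tau))
    regions <- unique(ent$region)
    n_subjects <- length(unique(ent$subject_id))
    subj_groups <- distinct(ent, .data$subject_id, .data$group)$group
    if (length(unique(subj_groups)) < 2 || min(table(subj_groups)) < 2)
      abort("entropy table must contain at least 2 subjects in each group")
  } else {
    abort("cohort must be a study_cohort or a cohort_entropy() table")
  }
  cells <- ent |>
    group_by(.data$m, .data$r, .data$tau, .data$region) |>
    summarize(
      n_excluded = sum(!.data$defined),
      n0 = sum(.data$defined & .data$group == 0L),
      n1 = sum(.data$defined & .data$group == 1L),
      mean0 = ifelse(.data$n0 > 0,
                     mean(.data$entropy[.data$defined & .data$group == 0L]),
                     NA_real_),
      mean1 = ifelse(.data$n1 > 0,
                     mean(.data$entropy[.data$defined & .data$group == 1L]),
                     NA_real_),
      var0 = cell_var(.data$entropy[.data$defined & .data$group == 0L]),
      var1 = cell_var(.data$entropy[.data$defined & .data$group == 1L]),
      auc = cell_auc(.data$entropy, .data$group, .data$defined),
      .groups = "drop") |>
    # Welch t statistic, Welch-Satterthwaite df and two-sided p, vectorized
    # over cells; matches stats::t.test(var.equal = FALSE)
    mutate(se0 = .data$var0 / .data$n0, se1 = .data$var1 / .data$n1,
           t_statistic = ifelse(.data$se0 + .data$se1 > 0,
                                (.data$mean0 - .data$mean1) /
                                  sqrt(.data$se0 + .data$se1), NA_real_),
           df = (.data$se0 + .data$se1)^2 /
             (.data$se0^2 / (.data$n0 - 1) + .data$se1^2 / (.data$n1 - 1)),
           p_value = 2 * pt(-abs(.data$t_statistic), .data$df)) |>
    select(-"se0", -"se1", -"var0", -"var1") |>
    select("m", "r", "tau", "region", "n0", "n1", "n_excluded",
           "mean0", "mean1", "t_statistic", "df", "p_value", "auc")
  if (p_adjust != "none") {
    cells <- cells |>
      group_by(.data$m, .data$r, .data$tau) |>
      mutate(p_value = stats::p.adjust(.data$p_value, method = p_adjust)) |>
      ungroup()
  }
  attr(cells, "m_grid") <- as.integer(m)
  attr(cells, "r_grid") <- as.numeric(r)
  attr(cells, "tau_grid") <- as.integer(tau)
  attr(cells, "region_labels") <- regions
  attr(cells, "n_subjects") <- n_subjects
  class(cells) <- c("entropy_grid", class(cells))
  cells
}

#' @export
print.entropy_grid <- function(x, ...) {
  cat("<entropy_grid> ", nrow(x), " cells: m in {",
      paste(attr(x, "m_grid"), collapse = ","), "}, ",
      length(attr(x, "r_grid")), " r values, ",
      length(attr(x, "tau_grid")), " scale factors, ",
      length(attr(x, "region_labels")), " regions\n", sep = "")
  NextMethod()
}

#' @method tidy entropy_grid
#' @export
tidy.entropy_grid <- function(x, ...) as_tibble(x)

#' Count significant regions per grid cell
#'
#' @param grid An [entropy_grid()].
#' @param m Restrict to these embedding dimensions (default: all in grid).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with `m`, `r`, `tau`, `n_significant`.
#' @export
count_significant <- function(grid, m = NULL, alpha = 0.05) {
  tab <- as_tibble(grid)
  if (!is.null(m)) tab <- tab[tab$m %in% m, ]
  tab |>
    group_by(.data$m, .data$r, .data$tau) |>
    summarize(n_significant = sum(.data$p_value < alpha, na.rm = TRUE),
              .groups = "drop")
}

#' @method autoplot entropy_grid
#' @export
autoplot.entropy_grid <- function(object, alpha = 0.05, ...) {
  counts <- count_significant(object, alpha = alpha)
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$tau),
                                       y = factor(.data$r),
                                       fill = .data$n_significant)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$m), labeller = ggplot2::label_both) +
    ggplot2::labs(x = "scale factor τ", y = "similarity factor r",
                  fill = sprintf("regions\np < %.2g", alpha))
}

#' Select the embedding dimension
#'
#' Picks the m whose mean count of significant regions over all (r, tau)
#' cells is largest; ties resolve to the smaller m (cheaper templates,
#' milder length requirements).
#'
#' @inheritParams count_significant
#' @return The selected m (integer).
#' @export
select_m <- function(grid, alpha = 0.05) {
  means <- count_significant(grid, alpha = alpha) |>
    group_by(.data$m) |>
    summarize(mean_significant = mean(.data$n_significant), .groups = "drop") |>
    arrange(dplyr::desc(.data$mean_significant), .data$m)
  as.integer(means$m[1])
}

#' Robust band of similarity factors
#'
#' The r values for which at least `min_regions` regions are significant at
#' every scale factor in the grid — tolerances that "work at all scales".
#' If no r qualifies, falls back (with a warning) to the single r with the
#' best worst-case (over tau) count.
#'
#' @inheritParams count_significant
#' @param m Embedding dimension to condition on.
#' @param min_regions Minimum significant-region count required at every
#'   scale (default 1).
#' @return Numeric vector of r grid values (the band).
#' @export
robust_r_band <- function(grid, m, alpha = 0.05, min_regions = 1) {
  worst <- count_significant(grid, m = m, alpha = alpha) |>
    group_by(.data$r) |>
    summarize(worst_case = min(.data$n_significant), .groups = "drop") |>
    arrange(.data$r)
  band <- worst$r[worst$worst_case >= min_regions]
  if (length(band) == 0) {
    fb <- worst$r[which.max(worst$worst_case)]
    warn(paste0("no similarity factor reaches ", min_regions,
                " significant region(s) at every scale; falling back to r = ",
                fb, " (best worst-case count ", max(worst$worst_case), ")"))
    band <- fb
  }
  band
}

#' Select the scale factor and similarity factor
#'
#' Scores each (r, tau) cell by the mean AUC over its significant regions
#' (p < alpha); tau is chosen as the scale whose best in-band score is
#' maximal, then r as the in-band argmax at that tau. Ties resolve to the
#' smaller tau, then to the r nearest the band midpoint. The selection
#' trace (score table and per-step winners) is recorded so the choice can
#' be replayed.
#'
#' @inheritParams robust_r_band
#' @param band Numeric vector of candidate r values (see [robust_r_band()]).
#' @return An `mse_params` object: list with `m`, `r`, `tau` and
#'   `selection_trace`.
#' @export
select_tau_r <- function(grid, m, band, alpha = 0.05) {
  if (length(band) == 0) abort("empty r band")
  tab <- as_tibble(grid)
  scores <- tab[tab$m == m & tab$r %in% band, ] |>
    group_by(.data$r, .data$tau) |>
    summarize(score = if (any(.data$p_value < alpha, na.rm = TRUE))
                mean(.data$auc[!is.na(.data$p_value) & .data$p_value < alpha])
              else NA_real_,
              n_significant = sum(.data$p_value < alpha, na.rm = TRUE),
              .groups = "drop")
  if (all(is.na(scores$score)))
    abort(paste0("no significant region in any (r, tau) cell of the band at ",
                 "alpha = ", alpha, "; widen the parameter grids or the band"))
  by_tau <- scores |>
    group_by(.data$tau) |>
    summarize(best = suppressWarnings(max(.data$score, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(best = ifelse(is.finite(.data$best), .data$best, NA_real_)) |>
    arrange(dplyr::desc(.data$best), .data$tau)
  tau_star <- by_tau$tau[1]
  at_tau <- scores[scores$tau == tau_star & !is.na(scores$score), ]
  mid <- (min(band) + max(band)) / 2
  at_tau <- at_tau[order(-at_tau$score, abs(at_tau$r - mid), at_tau$r), ]
  r_star <- at_tau$r[1]
  out <- list(m = as.integer(m), r = r_star, tau = as.integer(tau_star),
              selection_trace = list(band = band, alpha = alpha,
                                     scores = scores, by_tau = by_tau,
                                     tau_selected = tau_star,
                                     r_selected = r_star))
  class(out) <- "mse_params"
  out
}

#' Sequential parameter optimization
#'
#' Runs the full selection sequence on a computed grid: embedding dimension
#' by mean significant-region count, robust r band, then (tau, r) by mean
#' AUC over significant regions. `method = "joint"` instead takes the
#' single (m, r, tau) cell with the maximal score, ignoring the band — a
#' sensitivity check on the sequential procedure.
#'
#' @inheritParams robust_r_band
#' @param method `"sequential"` (default) or `"joint"`.
#' @return An `mse_params` object with the full `selection_trace`.
#' @export
optimize_params <- function(grid, alpha = 0.05, min_regions = 1,
                            method = c("sequential", "joint")) {
  method <- match.arg(method)
  if (length(attr(grid, "m_grid")) < 1) abort("grid covers no m")
  if (method == "joint") {
    tab <- as_tibble(grid) |>
      group_by(.data$m, .data$r, .data$tau) |>
      summarize(score = if (any(.data$p_value < alpha, na.rm = TRUE))
                  mean(.data$auc[!is.na(.data$p_value) & .data$p_value < alpha])
                else NA_real_, .groups = "drop") |>
      arrange(dplyr::desc(.data$score), .data$m, .data$tau, .data$r)
    if (all(is.na(tab$score)))
      abort("no significant region in any grid cell; widen the grids")
    out <- list(m = as.integer(tab$m[1]), r = tab$r[1],
                tau = as.integer(tab$tau[1]),
                selection_trace = list(method = "joint", alpha = alpha,
                                       scores = tab))
    class(out) <- "mse_params"
    return(out)
  }
  m_star <- select_m(grid, alpha = alpha)
  band <- robust_r_band(grid, m = m_star, alpha = alpha,
                        min_regions = min_regions)
  params <- select_tau_r(grid, m = m_star, band = band, alpha = alpha)
  params$selection_trace$method <- "sequential"
  params$selection_trace$m_counts <-
    count_significant(grid, alpha = alpha) |>
    group_by(.data$m) |>
    summarize(mean_significant = mean(.data$n_significant), .groups = "drop")
  params$selection_trace$m_selected <- m_star
  params
}

#' @export
print.mse_params <- function(x, ...) {
  cat("<mse_params> m = ", x$m, ", r = ", format(x$r), ", tau = ", x$tau,
      "\n", sep = "")
  invisible(x)
}

#' @method tidy mse_params
#' @export
tidy.mse_params <- function(x, ...) x$selection_trace$scores

#' @method glance mse_params
#' @export
glance.mse_params <- function(x, ...) {
  tibble(m = x$m, r = x$r, tau = x$tau,
         band_lo = min(x$selection_trace$band %||% x$r),
         band_hi = max(x$selection_trace$band %||% x$r))
}

#' Select biomarker regions at the optimal parameters
#'
#' Regions whose entropy differs significantly between groups (p < alpha)
#' at the selected (m, r, tau), sorted by ascending p-value.
#'
#' @inheritParams robust_r_band
#' @param params An `mse_params` object (must lie on the grid).
#' @return A `biomarker_set` tibble: `region`, `p_value`, `auc`, `band`,
#'   `mean0`, `mean1`; attribute `params`.
#' @export
select_biomarkers <- function(grid, params, alpha = 0.05) {
  tab <- as_tibble(grid)
  cell <- tab[tab$m == params$m & tab$tau == params$tau &
                abs(tab$r - params$r) < 1e-12, ]
  if (nrow(cell) == 0)
    abort("params do not lie on the computed grid")
  hits <- cell[!is.na(cell$p_value) & cell$p_value < alpha, ]
  if (nrow(hits) == 0) {
    near <- cell[order(cell$p_value), c("region", "p_value", "auc")]
    msg <- paste0("no region significant at alpha = ", alpha,
                  " for (m, r, tau) = (", params$m, ", ", params$r, ", ",
                  params$tau, "); nearest misses:\n",
                  paste(utils::capture.output(print(head(near, 5))),
                        collapse = "\n"))
    abort(msg)
  }
  out <- hits[order(hits$p_value),
              c("region", "p_value", "auc", "mean0", "mean1", "n0", "n1")]
  out$band <- auc_band(out$auc)
  attr(out, "params") <- params
  class(out) <- c("biomarker_set", class(out))
  out
}

#' Build the per-subject feature matrix
#'
#' One row per subject, one column per biomarker region (in biomarker
#' order), entries the subject's sample entropy at the optimal parameters.
#' Subjects with any undefined feature are dropped and recorded in the
#' `dropped` attribute.
#'
#' @param cohort A [study_cohort()].
#' @param params An `mse_params` object.
#' @param biomarkers A `biomarker_set` (nonempty).
#' @return A `feature_matrix` tibble: `subject_id`, `group`, then one
#'   numeric column per biomarker region; attributes `params`, `regions`,
#'   `dropped`.
#' @export
build_features <- function(cohort, params, biomarkers) {
  regions <- if (is.data.frame(biomarkers)) biomarkers$region else biomarkers
  if (length(regions) == 0) abort("biomarker set is empty")
  labels <- region_labels(cohort)
  missing <- setdiff(regions, labels)
  if (length(missing) > 0)
    abort(paste0("regions not in cohort: ", paste(missing, collapse = ", ")))

  sub <- cohort
  sub$series <- lapply(cohort$series,
                       function(mat) mat[regions, , drop = FALSE])
  attr(sub, "region_labels") <- regions
  ent <- cohort_entropy(sub, m = params$m, r = params$r, tau = params$tau,
                        warn_short = FALSE)
  bad <- unique(ent$subject_id[!ent$defined])
  if (length(bad) > 0)
    warn(paste0("dropping subject(s) with undefined entropy features: ",
                paste(bad, collapse = ", ")))
  keep <- !(ent$subject_id %in% bad)
  wide <- tidyr::pivot_wider(ent[keep, c("subject_id", "group", "region",
                                         "entropy")],
                             names_from = "region", values_from = "entropy")
  wide <- wide[match(setdiff(cohort$subject_id, bad), wide$subject_id),
               c("subject_id", "group", regions)]
  attr(wide, "params") <- params
  attr(wide, "regions") <- regions
  attr(wide, "dropped") <- bad
  class(wide) <- c("feature_matrix", class(wide))
  wide
}
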