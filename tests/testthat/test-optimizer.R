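# Construct a minimal entropy_grid by hand, to test the selection rules on
# exactly controlled p/AUC surfaces.
fake_grid <- function(cells) {
  if (!"n0" %in% names(cells)) cells$n0 <- 10L
  if (!"n1" %in% names(cells)) cells$n1 <- 10L
  cells$n_excluded <- 0L
  cells$mean0 <- 1; cells$mean1 <- 1.2
  cells$t_statistic <- -1; cells$df <- 18
  attr(cells, "m_grid") <- sort(unique(cells$m))
  attr(cells, "r_grid") <- sort(unique(cells$r))
  attr(cells, "tau_grid") <- sort(unique(cells$tau))
  attr(cells, "region_labels") <- unique(cells$region)
  class(cells) <- c("entropy_grid", class(cells))
  cells
}
`%||%` <- function(a, b) if (is.null(a)) b else a

grid_frame <- function(m, r, tau, regions) {
  tidyr::expand_grid(m = m, r = r, tau = tau, region = regions)
}

test_that("entropy_grid is complete and deterministic", {
  coh <- toy_cohort(n = 6, n_regions = 4, seed = 31)
  g1 <- entropy_grid(coh, m = 1:2, r = c(0.3, 0.5), tau = 1:3)
  expect_equal(nrow(g1), 2 * 2 * 3 * 4)
  expect_equal(dplyr::n_distinct(g1$region), 4)
  g2 <- entropy_grid(coh, m = 1:2, r = c(0.3, 0.5), tau = 1:3)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
})

test_that("grid cell statistics equal the standalone test functions", {
  coh <- toy_cohort(n = 8, n_regions = 3, seed = 32)
  ent <- cohort_entropy(coh, m = 1, r = c(0.4, 0.5), tau = 1:2,
                        warn_short = FALSE)
  g <- entropy_grid(ent)
  for (k in seq_len(nrow(g))) {
    row <- g[k, ]
    sub <- ent[ent$m == row$m & ent$r == row$r & ent$tau == row$tau &
                 ent$region == row$region & ent$defined, ]
    tt <- welch_t_test(sub$entropy[sub$group == 0],
                       sub$entropy[sub$group == 1])
    expect_equal(row$t_statistic, tt$t_statistic, tolerance = 1e-8)
    expect_equal(row$p_value, tt$p_value, tolerance = 1e-8)
    expect_equal(row$auc, roc_auc(sub$entropy[sub$group == 0],
                                  sub$entropy[sub$group == 1])$auc,
                 tolerance = 1e-12)
  }
})

test_that("a planted region separates while a noise region does not", {
  coh <- generate_cohort(n0 = 20, n1 = 20, n_regions = 2,
                         planted_regions = 1, n_timepoints = 150,
                         phi_base = 0.2, delta_phi = 0.55, seed = 33)
  g <- entropy_grid(coh, m = 1, r = 0.5, tau = 1)
  planted <- g[g$region == region_labels(coh)[1], ]
  noise <- g[g$region == region_labels(coh)[2], ]
  expect_lt(planted$p_value, 0.01)
  expect_gt(noise$p_value, 0.05)
})

test_that("count_significant respects alpha bounds", {
  cells <- grid_frame(1:2, c(0.3, 0.5), 1:2, c("A", "B", "C"))
  cells$p_value <- 0.5
  cells$auc <- 0.6
  g <- fake_grid(cells)
  expect_true(all(count_significant(g, alpha = 0.04)$n_significant == 0))
  expect_true(all(count_significant(g, alpha = 1)$n_significant == 3))
})

test_that("select_m prefers the dominant m and breaks ties downward", {
  cells <- grid_frame(1:2, c(0.3, 0.5), 1:2, c("A", "B"))
  cells$p_value <- ifelse(cells$m == 1, 0.01, 0.5)
  cells$auc <- 0.7
  expect_identical(select_m(fake_grid(cells)), 1L)
  cells$p_value <- ifelse(cells$m == 2, 0.01, 0.5)
  expect_identical(select_m(fake_grid(cells)), 2L)
  cells$p_value <- 0.01  # exact tie
  expect_identical(select_m(fake_grid(cells)), 1L)
})

test_that("robust_r_band keeps r values significant at every scale", {
  cells <- grid_frame(1, c(0.35, 0.40, 0.45, 0.50, 0.55, 0.60), 1:4,
                      c("A", "B"))
  cells$auc <- 0.7
  # significant at all scales only for r in {0.45, 0.5, 0.55}
  cells$p_value <- ifelse(cells$r %in% c(0.45, 0.50, 0.55), 0.01,
                          ifelse(cells$tau <= 2, 0.01, 0.8))
  band <- robust_r_band(fake_grid(cells), m = 1)
  expect_equal(band, c(0.45, 0.5, 0.55))
})

test_that("empty robust band falls back to best worst-case r with a warning", {
  cells <- grid_frame(1, c(0.3, 0.4, 0.5), 1:3, c("A", "B"))
  cells$auc <- 0.7
  # only r = 0.4 keeps one region significant at every scale; nobody
  # reaches the requested two regions
  cells$p_value <- ifelse(cells$r == 0.4 & cells$region == "A", 0.01,
                          ifelse(cells$tau <= 2, 0.01, 0.9))
  expect_warning(
    band <- robust_r_band(fake_grid(cells), m = 1, min_regions = 2),
    "falling back")
  expect_equal(band, 0.4)
})

test_that("select_tau_r maximizes mean AUC of significant regions with tie rules", {
  cells <- grid_frame(1, c(0.4, 0.5, 0.6), 1:5, c("A", "B", "C"))
  cells$p_value <- 0.01
  cells$auc <- 0.6
  cells$auc[cells$tau == 4 & cells$r == 0.5] <- 0.9  # unique peak
  opt <- select_tau_r(fake_grid(cells), m = 1, band = c(0.4, 0.5, 0.6))
  expect_identical(opt$tau, 4L)
  expect_equal(opt$r, 0.5)

  cells$auc <- 0.6
  cells$auc[cells$tau %in% c(3, 5)] <- 0.8  # tie across tau -> smaller
  opt <- select_tau_r(fake_grid(cells), m = 1, band = c(0.4, 0.5, 0.6))
  expect_identical(opt$tau, 3L)
  expect_equal(opt$r, 0.5)  # tie across r -> nearest band midpoint
})

test_that("selection trace replay reproduces the choice", {
  coh <- toy_cohort(n = 10, n_regions = 5, n_planted = 3, seed = 35)
  g <- entropy_grid(coh, m = 1:2, r = seq(0.3, 0.6, 0.1), tau = 1:3)
  opt <- optimize_params(g)
  tr <- opt$selection_trace
  best_tau <- tr$by_tau$tau[which.max(tr$by_tau$best)]
  at_tau <- tr$scores[tr$scores$tau == best_tau & !is.na(tr$scores$score), ]
  mid <- (min(tr$band) + max(tr$band)) / 2
  at_tau <- at_tau[order(-at_tau$score, abs(at_tau$r - mid), at_tau$r), ]
  expect_identical(opt$tau, as.integer(best_tau))
  expect_equal(opt$r, at_tau$r[1])
})

test_that("select_biomarkers returns sorted significant regions or errors", {
  coh <- toy_cohort(n = 12, n_regions = 6, n_planted = 2, seed = 36)
  g <- entropy_grid(coh, m = 1, r = 0.5, tau = 1:2)
  opt <- list(m = 1L, r = 0.5, tau = 1L)
  bm <- select_biomarkers(g, opt)
  expect_true(all(diff(bm$p_value) >= 0))
  expect_true(all(bm$p_value < 0.05))
  expect_error(select_biomarkers(g, opt, alpha = 0), "nearest misses")
  expect_error(select_biomarkers(g, list(m = 1L, r = 0.9, tau = 1L)),
               "do not lie")
})

test_that("identical groups produce no biomarkers, with diagnostics", {
  coh <- toy_cohort(n = 8, n_regions = 4, seed = 37, delta_phi = 0)
  g <- entropy_grid(coh, m = 1, r = 0.5, tau = 1)
  expect_error(select_biomarkers(g, list(m = 1L, r = 0.5, tau = 1L),
                                 alpha = 1e-6), "nearest misses")
})

test_that("build_features keeps subject order and biomarker column order", {
  coh <- toy_cohort(n = 10, n_regions = 5, n_planted = 3, seed = 38)
  g <- entropy_grid(coh, m = 1, r = 0.5, tau = 1:2)
  opt <- list(m = 1L, r = 0.5, tau = 1L)
  bm <- select_biomarkers(g, opt, alpha = 0.2)
  f <- build_features(coh, opt, bm)
  expect_identical(names(f), c("subject_id", "group", bm$region))
  expect_identical(f$subject_id, coh$subject_id)
  expect_false(anyNA(f))
  # single biomarker -> n x 1 feature block
  f1 <- build_features(coh, opt, bm[1, ])
  expect_identical(names(f1), c("subject_id", "group", bm$region[1]))
  expect_equal(nrow(f1), nrow(coh))
})
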