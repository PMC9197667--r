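test_that("zscore_series matches the closed form and is idempotent", {
  z <- zscore_series(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(zscore_series(z), z, tolerance = 1e-12)
})

test_that("zscore_series flags zero-variance input instead of erroring", {
  z <- zscore_series(c(5, 5, 5))
  expect_equal(as.numeric(z), c(0, 0, 0))
  expect_true(attr(z, "degenerate"))
  expect_error(zscore_series(5), "at least 2")
})

test_that("cohort construction validates shapes, labels and groups", {
  mk <- function(lab = paste0("R", 1:3), ncol = 10) {
    matrix(rnorm(length(lab) * ncol), length(lab), ncol,
           dimnames = list(lab, NULL))
  }
  set.seed(1)
  expect_s3_class(study_cohort(c("a", "b"), c(0, 1), list(mk(), mk())),
                  "study_cohort")
  expect_error(study_cohort(c("a", "b"), c(0, 2), list(mk(), mk())), "b")
  expect_error(study_cohort(c("a", "b"), c(0, 1),
                            list(mk(), mk(paste0("R", 1:4)))), "\\bb\\b")
  bad <- mk(); bad[2, 3] <- NA
  expect_error(study_cohort(c("a", "b"), c(0, 1), list(mk(), bad)), "missing")
})

test_that("write_cohort / read_manifest round-trips bit-identically in order", {
  coh <- toy_cohort(n = 2, n_regions = 4, seed = 7)
  dir <- withr::local_tempdir()
  mpath <- write_cohort(coh, dir)
  back <- read_manifest(mpath)
  expect_identical(back$subject_id, coh$subject_id)
  expect_identical(back$group, coh$group)
  expect_identical(region_labels(back), region_labels(coh))
  for (i in seq_len(nrow(coh)))
    expect_identical(back$series[[i]], coh$series[[i]])
})

test_that("read_manifest rejects missing files and bad groups by name", {
  coh <- toy_cohort(n = 2, n_regions = 3, seed = 8)
  dir <- withr::local_tempdir()
  mpath <- write_cohort(coh, dir)
  man <- readr::read_csv(mpath, show_col_types = FALSE)
  man$group[2] <- 2
  readr::write_csv(man, mpath)
  expect_error(read_manifest(mpath), man$subject_id[2])
  man$group[2] <- 1
  man$matrix_path[1] <- "nope.tsv"
  readr::write_csv(man, mpath)
  expect_error(read_manifest(mpath), "not found")
})

test_that("read_manifest maps textual group labels when asked", {
  coh <- toy_cohort(n = 2, n_regions = 3, seed = 9)
  dir <- withr::local_tempdir()
  mpath <- write_cohort(coh, dir)
  man <- readr::read_csv(mpath, show_col_types = FALSE)
  man$group <- ifelse(man$group == 0, "poor", "excellent")
  readr::write_csv(man, mpath)
  expect_error(read_manifest(mpath), "non-binary")
  back <- read_manifest(mpath, group_map = c(poor = 0, excellent = 1))
  expect_identical(back$group, coh$group)
})

test_that("comma-delimited matrices are auto-detected", {
  mat <- matrix(rnorm(12), 3, 4, dimnames = list(c("A", "B", "C"), NULL))
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = ","),
    character(1)), p)
  back <- read_region_matrix(p)
  expect_equal(back, mat, tolerance = 1e-15)
})

test_that("reports round-trip losslessly through the matching reader", {
  d <- withr::local_tempdir()
  tab <- tibble::tibble(region = c("x", "y"),
                        p_value = c(1 / 3, pi * 1e-7),
                        auc = c(0.123456789012345, 1 - 1e-15))
  write_report(tab, file.path(d, "t.tsv"))
  back <- read_report(file.path(d, "t.tsv"))
  expect_identical(back$p_value, tab$p_value)
  expect_identical(back$auc, tab$auc)

  rec <- list(params = list(m = 1L, r = 0.45, tau = 5L),
              fold_accuracies = c(80, 88.24, 100 / 3),
              mean = mean(c(80, 88.24, 100 / 3)))
  write_report(rec, file.path(d, "r.json"))
  back <- read_report(file.path(d, "r.json"))
  expect_identical(back$fold_accuracies, rec$fold_accuracies)
  expect_identical(back$mean, rec$mean)
  expect_identical(back$params$r, 0.45)
})
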