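# Cohort container and plain-text I/O.
#
# A study cohort is a tibble with one row per subject:
#   subject_id <chr>, group <int 0/1>, series <list of region x time matrices>
# plus attributes region_labels and n_timepoints. Matrices are validated
# eagerly at construction; the pipeline never silently drops a subject.

#' Construct a study cohort
#'
#' Bundles per-subject region-by-time matrices with binary group labels
#' (0 = poor, 1 = excellent) into a validated tibble with a `series`
#' list-column. All matrices must share the same region labels (row names),
#' region order and number of time points, and contain no missing values.
#'
#' @param subject_id Character vector of unique subject identifiers.
#' @param group Integer vector of 0/1 group labels (0 = poor, 1 = excellent).
#' @param series List of numeric matrices, regions in rows (row names are the
#'   region labels) and time points in columns.
#' @return A `study_cohort` tibble with attributes `region_labels` and
#'   `n_timepoints`.
#' @export
study_cohort <- function(subject_id, group, series) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id))
    abort("duplicate subject_id values in cohort")
  if (length(group) != length(subject_id) || length(series) != length(subject_id))
    abort("subject_id, group and series must have equal length")
  if (!all(group %in% c(0, 1)))
    abort(paste0("group labels must be 0 or 1; offending subjects: ",
                 paste(subject_id[!group %in% c(0, 1)], collapse = ", ")))
  if (length(series) == 0) abort("cohort must contain at least one subject")

  ref <- series[[1]]
  if (is.null(rownames(ref)))
    abort(paste0("matrix of subject ", subject_id[1], " has no region labels"))
  labels <- rownames(ref)
  ntp <- ncol(ref)
  for (i in seq_along(series)) {
    mat <- series[[i]]
    if (!is.matrix(mat) || !is.numeric(mat))
      abort(paste0("subject ", subject_id[i], ": series is not a numeric matrix"))
    if (nrow(mat) != length(labels) || ncol(mat) != ntp)
      abort(paste0("subject ", subject_id[i], ": matrix is ", nrow(mat), "x",
                   ncol(mat), ", expected ", length(labels), "x", ntp))
    if (!identical(rownames(mat), labels))
      abort(paste0("subject ", subject_id[i],
                   ": region labels differ from the first subject's"))
    if (anyNA(mat))
      abort(paste0("subject ", subject_id[i], ": matrix contains missing values"))
  }

  out <- tibble(subject_id = subject_id,
                group = as.integer(group),
                series = series)
  attr(out, "region_labels") <- labels
  attr(out, "n_timepoints") <- ntp
  class(out) <- c("study_cohort", class(out))
  out
}

#' @export
print.study_cohort <- function(x, ...) {
  cat("<study_cohort> ", nrow(x), " subjects (",
      sum(x$group == 0), " poor / ", sum(x$group == 1), " excellent), ",
      length(region_labels(x)), " regions x ", attr(x, "n_timepoints"),
      " time points\n", sep = "")
  NextMethod()
}

#' Region labels of a cohort
#' @param cohort A `study_cohort`.
#' @return Character vector of region labels.
#' @export
region_labels <- function(cohort) attr(cohort, "region_labels")

#' Read a subject manifest and all regional matrices
#'
#' The manifest is a CSV with header `subject_id,group,matrix_path`;
#' `matrix_path` entries are resolved relative to the manifest's directory
#' unless absolute. Each matrix file is delimited text with one row per
#' region: a leading region-label field followed by the time points; the
#' delimiter (tab or comma) is auto-detected. Region labels are taken from
#' the first subject and enforced on all others. Subjects are returned in
#' manifest order.
#'
#' @param path Path to the manifest CSV.
#' @param group_map Optional named vector mapping textual group labels to
#'   0/1, e.g. `c(poor = 0, excellent = 1)`. By default groups must already
#'   be coded 0/1.
#' @return A [study_cohort()].
#' @export
read_manifest <- function(path, group_map = NULL) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  man <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("subject_id", "group", "matrix_path")
  if (!all(need %in% names(man)))
    abort(paste0("manifest must have columns ", paste(need, collapse = ", ")))

  grp <- man$group
  if (!is.null(group_map)) {
    mapped <- unname(group_map[grp])
    grp <- ifelse(is.na(mapped), suppressWarnings(as.numeric(grp)), mapped)
  } else {
    grp <- suppressWarnings(as.numeric(grp))
  }
  bad <- is.na(grp) | !(grp %in% c(0, 1))
  if (any(bad))
    abort(paste0("non-binary group label for subject(s): ",
                 paste(man$subject_id[bad], collapse = ", ")))

  base <- dirname(path)
  series <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$matrix_path[i]
    if (!file.exists(p)) p <- file.path(base, man$matrix_path[i])
    if (!file.exists(p))
      abort(paste0("matrix file not found for subject ", man$subject_id[i],
                   ": ", man$matrix_path[i]))
    read_region_matrix(p)
  })
  study_cohort(man$subject_id, grp, series)
}

#' Read one region-by-time matrix
#'
#' Delimited text, one row per region: leading region-label field, then the
#' time points; no header line. Tab or comma delimiter auto-detected.
#'
#' @param path Path to the matrix file.
#' @return Numeric matrix with region labels as row names.
#' @export
read_region_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  # base parser: correctly rounded doubles, so written matrices round-trip
  # bit-identically
  tab <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  mat <- matrix(suppressWarnings(as.numeric(as.matrix(tab[, -1, drop = FALSE]))),
                nrow = nrow(tab),
                dimnames = list(tab[[1]], NULL))
  if (anyNA(mat)) abort(paste0("missing or non-numeric values in ", path))
  mat
}

#' Write a cohort to disk in manifest + matrix form
#'
#' Writes `manifest.csv` plus one tab-delimited matrix file per subject
#' (`<subject_id>.tsv`), in the formats read back by [read_manifest()].
#'
#' @param cohort A `study_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$subject_id, ".tsv"))
  for (i in seq_len(nrow(cohort))) {
    mat <- cohort$series[[i]]
    lines <- vapply(seq_len(nrow(mat)), function(g)
      paste(c(rownames(mat)[g], sprintf("%.17g", mat[g, ])), collapse = "\t"),
      character(1))
    writeLines(lines, paths[i])
  }
  man <- tibble(subject_id = cohort$subject_id, group = cohort$group,
                matrix_path = basename(paths))
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(man, mpath, progress = FALSE)
  invisible(mpath)
}

#' Z-score a time series (population convention)
#'
#' Centers and scales to mean 0 and standard deviation 1 using the
#' population divisor `n`. A zero-variance input cannot be scaled: it is
#' returned as all zeros with attribute `degenerate = TRUE`, which keeps a
#' constant series exactly constant for the entropy computation (all
#' templates match, sample entropy 0).
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector of the same length; attribute `degenerate` is set
#'   to `TRUE` for zero-variance input.
#' @export
zscore_series <- function(x) {
  if (length(x) < 2) abort("need at least 2 points to z-score")
  if (anyNA(x)) abort("missing values in series")
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (x - mu) / s
}

#' Write a result as structured text
#'
#' Data frames go to TSV (full double precision, shortest round-trip
#' representation); any other result is serialized as JSON. Numeric fields
#' survive a round trip through [read_report()] bit-identically.
#'
#' @param result A data frame or a list-like result object.
#' @param path Output path; the extension (`.tsv` or `.json`) selects the
#'   reader on the way back.
#' @return Invisibly, `path`.
#' @export
write_report <- function(result, path) {
  if (is.data.frame(result)) {
    # 17 significant digits: doubles survive the round trip bit-identically
    out <- dplyr::mutate(as_tibble(result), across(
      dplyr::where(is.double), \(x) sprintf("%.17g", x)))
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", na = "null")
  }
  invisible(path)
}

#' Read a report written by [write_report()]
#' @param path Path to a `.tsv` or `.json` report.
#' @return A tibble (TSV) or list (JSON).
#' @export
read_report <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # base parser for the same bit-exactness as read_region_matrix
    as_tibble(utils::read.delim(path, check.names = FALSE))
  }
}
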