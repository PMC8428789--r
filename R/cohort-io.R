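# Reading, validating and writing longitudinal radiomics tables, and
# densifying three annual readings to five half-yearly intervals with a
# natural cubic spline.

.COHORT_REQUIRED <- c("nodule_id", "time_index")

.validate_cohort <- function(data, source = "cohort") {
  missing <- setdiff(c(.COHORT_REQUIRED, feature_names()), names(data))
  if (length(missing) > 0) {
    stop(source, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in feature_names()) {
    bad <- which(!is.finite(data[[f]]))
    if (length(bad) > 0) {
      stop(source, ": non-finite value in `", f, "` at row ", bad[1], ".",
           call. = FALSE)
    }
  }
  bad_se <- which(data$sum_entropy <= 0)
  if (length(bad_se) > 0) {
    stop(source, ": `sum_entropy` must be > 0 (its logarithm enters the ",
         "benign/malignant likelihood); violated at row ", bad_se[1], ".",
         call. = FALSE)
  }
  dup <- duplicated(data[, c("nodule_id", "time_index")])
  if (any(dup)) {
    stop(source, ": duplicated (nodule_id, time_index) at row ",
         which(dup)[1], ".", call. = FALSE)
  }
  invisible(data)
}

#' Read a longitudinal radiomics cohort
#'
#' Reads an RFC-4180 CSV in long format: one row per nodule and screening,
#' columns `nodule_id`, `time_index`, the seven features of
#' [feature_names()], and optionally `truth_label`. Rows are sorted by
#' `(nodule_id, time_index)`. Schema violations, non-numeric feature cells,
#' duplicated time points, non-finite values and non-positive sum entropy
#' are rejected with errors naming the offending column or row.
#'
#' @param path CSV file path.
#' @return A tibble; an empty (header-only) file yields an empty cohort.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  spec <- readr::cols(
    nodule_id = readr::col_character(),
    time_index = readr::col_double(),
    .default = readr::col_double()
  )
  if ("truth_label" %in% names(utils::read.csv(path, nrows = 0))) {
    spec$cols$truth_label <- readr::col_character()
  }
  data <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                           progress = FALSE))
  probs <- readr::problems(data)
  if (nrow(probs) > 0) {
    stop("parse error in ", path, ": row ", probs$row[1], ", column `",
         probs$col[1], "`: expected ", probs$expected[1], ", got ",
         probs$actual[1], ".", call. = FALSE)
  }
  if (nrow(data) == 0) {
    missing <- setdiff(c(.COHORT_REQUIRED, feature_names()), names(data))
    if (length(missing) > 0) {
      stop(path, " is missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(tibble::as_tibble(data))
  }
  .validate_cohort(data, source = path)
  data <- dplyr::arrange(data, .data$nodule_id, .data$time_index)
  # per-nodule indices must be contiguous from 1 after sorting
  bad <- data |>
    dplyr::summarise(
      ok = all(.data$time_index == seq_len(dplyr::n())),
      .by = "nodule_id"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop(path, ": time_index must be contiguous from 1 for every nodule; ",
         "violated for ", bad$nodule_id[1], ".", call. = FALSE)
  }
  data
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort tibble (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  .validate_cohort(tibble::as_tibble(cohort))
  readr::write_csv(cohort, path, progress = FALSE)
  invisible(path)
}

#' Densify an annual trajectory to five half-yearly intervals
#'
#' Fits, per feature, a natural cubic spline (zero second derivative at the
#' ends) through the three annual readings and evaluates it at the two
#' midpoints, giving readings at years 0, 0.5, 1, 1.5, 2 re-indexed
#' `time_index = 1..5`. The three original observations are preserved
#' bitwise. A trajectory that already has five points passes through
#' unchanged; any other length is an error.
#'
#' Spline values below zero for positive-domain features are floored at
#' 1e-9 (sum entropy, small area emphasis) or 0 (LDHGLE, cluster prominence,
#' strength), and sphericity / small area emphasis are capped at 1, each
#' with a warning, so downstream likelihood domains stay valid.
#'
#' @param trajectory Single-nodule tibble with 3 (or 5) rows, `time_index`
#'   and the seven feature columns.
#' @return A five-row tibble with contiguous `time_index = 1..5`.
#' @export
#' @examples
#' traj <- dplyr::bind_cols(
#'   tibble::tibble(nodule_id = "n1", time_index = 1:3),
#'   features_for_state(c(0.1, 0.3, 0.6), synthetic_config(feature_noise_sd = 0))
#' )
#' densify_trajectory(traj)
densify_trajectory <- function(trajectory) {
  trajectory <- tibble::as_tibble(trajectory)
  if ("nodule_id" %in% names(trajectory) &&
      length(unique(trajectory$nodule_id)) > 1L) {
    stop("densify_trajectory() expects a single nodule; use ",
         "densify_cohort() for a table of several.", call. = FALSE)
  }
  if ("time_index" %in% names(trajectory)) {
    trajectory <- dplyr::arrange(trajectory, .data$time_index)
  }
  if (nrow(trajectory) == 5L) {
    return(trajectory)
  }
  if (nrow(trajectory) != 3L) {
    stop("densification expects exactly 3 annual readings (or 5 already ",
         "half-yearly ones); got ", nrow(trajectory), ".", call. = FALSE)
  }
  out <- trajectory[c(1L, 1L, 2L, 2L, 3L), , drop = FALSE]
  out$time_index <- 1:5
  clipped <- character(0)
  for (f in feature_names()) {
    y <- trajectory[[f]]
    mid <- stats::spline(x = 1:3, y = y, method = "natural",
                         xout = c(1.5, 2.5))$y
    lo <- switch(f, sum_entropy = , small_area_emphasis = 1e-9,
                 ldhgle = , cluster_prominence = , strength = 0, -Inf)
    hi <- switch(f, sphericity = , small_area_emphasis = 1, Inf)
    fixed <- pmin(pmax(mid, lo), hi)
    if (any(fixed != mid)) clipped <- c(clipped, f)
    vals <- out[[f]]
    vals[c(2L, 4L)] <- fixed
    out[[f]] <- vals
  }
  if (length(clipped) > 0) {
    warning("interpolated value(s) outside the feature domain clipped for: ",
            paste(unique(clipped), collapse = ", "), call. = FALSE)
  }
  out
}

#' Densify every annual trajectory of a cohort
#'
#' Applies [densify_trajectory()] per nodule; five-point nodules pass
#' through.
#'
#' @param cohort Long-format cohort tibble.
#' @return The densified cohort tibble.
#' @export
densify_cohort <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot("nodule_id" %in% names(cohort))
  cohort |>
    dplyr::group_split(.data$nodule_id) |>
    purrr::map(densify_trajectory) |>
    dplyr::bind_rows()
}
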