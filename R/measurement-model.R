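# Polynomial measurement functions: expected feature values as an M-th order
# polynomial in the latent malignancy score, fit per feature by ordinary
# least squares from (state, feature) training pairs.

#' Fit the polynomial measurement model
#'
#' Fits, for each of the seven radiomic features, an ordinary least-squares
#' polynomial of the feature value on the latent malignancy state,
#' `z_q = sum_{m=0..M} p_qm * u^m`. Fits are feature-wise independent and use
#' a QR (orthogonal-decomposition) solve via [stats::lm()], which is well
#' conditioned on \[0, 1\] at the orders used here. The residual standard
#' deviation per feature is stored as the feature's measurement-noise scale.
#'
#' @param pairs Data frame of training pairs: a `state` column (scores in
#'   \[0, 1\]) plus the seven feature columns of [feature_names()].
#' @param order Polynomial order M (integer >= 1). The default 3 is the
#'   order at which multi-class diagnosis performs best; see the vignette.
#' @return An object of class `"measurement_model"`: list with `order`,
#'   `coeffs` (named list of length-(M+1) coefficient vectors, constant term
#'   first), `noise_sd` (named numeric) and `n_train`.
#' @export
#' @examples
#' pairs <- generate_training_pairs(200, synthetic_config(feature_noise_sd = 0),
#'                                  seed = 1)
#' m <- fit_measurement_model(pairs, order = 3)
#' glance(m)
fit_measurement_model <- function(pairs, order = 3) {
  pairs <- tibble::as_tibble(pairs)
  if (!("state" %in% names(pairs))) {
    stop("`pairs` must contain a `state` column.", call. = FALSE)
  }
  missing <- setdiff(feature_names(), names(pairs))
  if (length(missing) > 0) {
    stop("`pairs` is missing feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order)) {
    stop("`order` must be an integer >= 1.", call. = FALSE)
  }
  order <- as.integer(order)
  u <- pairs$state
  .check_state(u)
  n_distinct <- length(unique(u))
  if (n_distinct < order + 1L) {
    stop("rank deficiency: polynomial order ", order, " needs at least ",
         order + 1L, " distinct states, got ", n_distinct, ".",
         call. = FALSE)
  }
  X <- outer(u, 0:order, `^`)  # Vandermonde; lm.fit solves by QR
  coeffs <- list()
  noise_sd <- numeric(0)
  for (feat in feature_names()) {
    fit <- stats::lm.fit(X, pairs[[feat]])
    beta <- unname(fit$coefficients)
    if (any(!is.finite(beta))) {
      stop("rank deficiency while fitting feature `", feat, "`.",
           call. = FALSE)
    }
    df <- length(u) - (order + 1L)
    coeffs[[feat]] <- beta
    noise_sd[[feat]] <-
      if (df > 0) sqrt(sum(fit$residuals^2) / df) else 0
  }
  structure(
    list(order = order, coeffs = coeffs, noise_sd = noise_sd,
         n_train = length(u)),
    class = "measurement_model"
  )
}

#' Predict expected (noise-free) feature values at given states
#'
#' Evaluates each feature's fitted measurement polynomial at the supplied
#' malignancy scores.
#'
#' @param model A [fit_measurement_model()] object.
#' @param u Diagnostic scores in \[0, 1\] (vectorized).
#' @return A tibble with one row per state and the seven feature columns.
#' @export
predict_features <- function(model, u) {
  stopifnot(inherits(model, "measurement_model"))
  .check_state(u)
  powers <- outer(u, 0:model$order, `^`)
  out <- lapply(model$coeffs, function(beta) drop(powers %*% beta))
  tibble::as_tibble(out)
}

#' @export
print.measurement_model <- function(x, ...) {
  cat("<measurement_model> order", x$order, "fit on", x$n_train, "pairs\n")
  for (feat in names(x$coeffs)) {
    cat(sprintf("  %-20s [%s]  sd %.4g\n", feat,
                paste(signif(x$coeffs[[feat]], 5), collapse = ", "),
                x$noise_sd[[feat]]))
  }
  invisible(x)
}

#' Tidy a measurement model
#'
#' @param x A `measurement_model`.
#' @param ... Unused.
#' @return A tibble with one row per feature and polynomial degree:
#'   columns `feature`, `degree`, `estimate`.
#' @method tidy measurement_model
#' @export
tidy.measurement_model <- function(x, ...) {
  purrr::map_dfr(names(x$coeffs), function(feat) {
    tibble::tibble(feature = feat, degree = 0:x$order,
                   estimate = x$coeffs[[feat]])
  })
}

#' @rdname tidy.measurement_model
#' @return For `glance()`: a one-row tibble with `order`, `n_train` and the
#'   mean residual standard deviation across features.
#' @method glance measurement_model
#' @export
glance.measurement_model <- function(x, ...) {
  tibble::tibble(order = x$order, n_train = x$n_train,
                 n_features = length(x$coeffs),
                 mean_noise_sd = mean(x$noise_sd))
}

#' Serialize a measurement model to JSON
#'
#' The JSON document stores the order, per-feature coefficient arrays and
#' per-feature residual standard deviations at full precision (`digits = NA`),
#' so a write/read round trip is bit-faithful.
#'
#' @param model A `measurement_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurement_model <- function(model, path) {
  stopifnot(inherits(model, "measurement_model"))
  doc <- list(order = model$order, coeffs = model$coeffs,
              noise_sd = as.list(model$noise_sd), n_train = model$n_train)
  # I(17): 17 significant digits, enough for a bit-faithful double round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_measurement_model
#' @export
read_measurement_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("order", "coeffs", "noise_sd")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0) {
    stop("measurement-model JSON is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(
    list(order = as.integer(doc$order),
         coeffs = lapply(doc$coeffs, as.numeric),
         noise_sd = unlist(doc$noise_sd),
         n_train = if (is.null(doc$n_train)) NA_integer_
                   else as.integer(doc$n_train)),
    class = "measurement_model"
  )
}
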