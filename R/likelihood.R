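# Published diagnostic likelihood polynomials and the threshold-gated
# combined likelihood used by the particle filter.

# Benign/malignant likelihood: quartic in SVR plus a log term in sum entropy.
.EQ_BM <- c(a = 0.7478, b = 2.2268, c = -5.5856, d = 3.6318,
            e = -0.73065, f = 1.2814e-02)

# Stage likelihood: linear in sphericity, LDHGLE, cluster prominence,
# small area emphasis and strength.
.EQ_STAGE <- c(intercept = 1.2, sphericity = -1.1348, ldhgle = -7.4597e-07,
               cluster_prominence = 3.0780e-08, small_area_emphasis = 0.3917,
               strength = -0.00361)

# Score ranges mapping a posterior diagnostic score to a class.
.SCORE_EARLY <- 0.51
.SCORE_ADVANCED <- 0.70
.SCORE_CAP <- 0.90

.CLASS_LEVELS <- c("benign", "early_stage", "advanced_stage")

#' Radiomic feature names used throughout the package
#'
#' Fixed lower-snake identifiers for the seven diagnostic radiomic features,
#' in the order surface-volume ratio, sum entropy, sphericity, large
#' dependence high gray level emphasis, cluster prominence, small area
#' emphasis, strength.
#'
#' @return Character vector of length 7.
#' @export
#' @examples
#' feature_names()
feature_names <- function() {
  c("svr", "sum_entropy", "sphericity", "ldhgle", "cluster_prominence",
    "small_area_emphasis", "strength")
}

#' Class labels for nodule diagnosis
#'
#' @return Character vector of the three diagnosis classes, in score order.
#' @export
class_levels <- function() .CLASS_LEVELS

#' Benign/malignant diagnostic likelihood
#'
#' Evaluates the published quartic-plus-log likelihood of malignancy from the
#' surface-volume ratio and the sum entropy of a nodule:
#' `a + b*z1 + c*z1^2 + d*z1^3 + e*z1^4 + f*log(z2)` with
#' a = 0.7478, b = 2.2268, c = -5.5856, d = 3.6318, e = -0.73065,
#' f = 1.2814e-02. Scores below 0.51 indicate a benign nodule.
#'
#' @param svr Surface-volume ratio values (numeric).
#' @param sum_entropy Sum entropy values (numeric, strictly positive: the
#'   formula takes their natural logarithm).
#' @return Numeric likelihood scores, vectorized over the inputs.
#' @export
#' @examples
#' likelihood_benign_malignant(0, 1)    # constant term only
#' likelihood_benign_malignant(0.5, 1)
likelihood_benign_malignant <- function(svr, sum_entropy) {
  if (!is.numeric(svr) || !is.numeric(sum_entropy)) {
    stop("`svr` and `sum_entropy` must be numeric.", call. = FALSE)
  }
  if (any(!is.finite(svr)) || any(!is.finite(sum_entropy))) {
    stop("non-finite feature value passed to the benign/malignant likelihood.",
         call. = FALSE)
  }
  if (any(sum_entropy <= 0)) {
    stop("`sum_entropy` must be > 0: the likelihood takes log(sum_entropy).",
         call. = FALSE)
  }
  k <- .EQ_BM
  k[["a"]] + k[["b"]] * svr + k[["c"]] * svr^2 + k[["d"]] * svr^3 +
    k[["e"]] * svr^4 + k[["f"]] * log(sum_entropy)
}

#' Cancer-stage diagnostic likelihood
#'
#' Evaluates the published linear stage likelihood
#' `1.2 - 1.1348*sphericity - 7.4597e-07*ldhgle + 3.0780e-08*cluster_prominence
#' + 0.3917*small_area_emphasis - 0.00361*strength`.
#' Values in \[0.51, 0.70) indicate early-stage and \[0.70, 0.90\]
#' advanced-stage cancer. The LDHGLE and cluster-prominence coefficients are
#' negligibly small and can be dropped via `drop_small_terms`.
#'
#' @param sphericity,ldhgle,cluster_prominence,small_area_emphasis,strength
#'   Feature values (numeric, finite).
#' @param drop_small_terms If `TRUE`, omit the LDHGLE and cluster-prominence
#'   terms. Default `FALSE` (full formula).
#' @return Numeric likelihood scores, vectorized over the inputs.
#' @export
#' @examples
#' likelihood_stage(0.5, 0, 0, 0, 0)
likelihood_stage <- function(sphericity, ldhgle, cluster_prominence,
                             small_area_emphasis, strength,
                             drop_small_terms = FALSE) {
  vals <- list(sphericity, ldhgle, cluster_prominence, small_area_emphasis,
               strength)
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    stop("stage-likelihood features must be numeric.", call. = FALSE)
  }
  if (!all(vapply(vals, function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite feature value passed to the stage likelihood.",
         call. = FALSE)
  }
  k <- .EQ_STAGE
  out <- k[["intercept"]] + k[["sphericity"]] * sphericity +
    k[["small_area_emphasis"]] * small_area_emphasis +
    k[["strength"]] * strength
  if (!drop_small_terms) {
    out <- out + k[["ldhgle"]] * ldhgle +
      k[["cluster_prominence"]] * cluster_prominence
  }
  out
}

#' Likelihood configuration
#'
#' Bundles the malignancy gate thresholds and options for
#' [combined_likelihood()]. A nodule observation is routed to the stage
#' likelihood when its SVR and sum entropy are both at or above the
#' thresholds `Ta` and `Tb`; otherwise to the benign/malignant likelihood.
#'
#' The default thresholds are calibrated against the synthetic feature
#' generator: `Ta` is the SVR at which the benign/malignant likelihood
#' crosses the 0.51 class boundary along the generator's feature curve
#' (approximately -0.0895) and `Tb` is the generator's sum entropy at that
#' same boundary (2.02). See `vignette("nodule-particle-filter")`.
#'
#' @param Ta SVR malignancy threshold.
#' @param Tb Sum-entropy malignancy threshold.
#' @param drop_small_terms Passed to [likelihood_stage()].
#' @param mixed_gate Branch used when exactly one of the two gate features is
#'   above its threshold. The default `"benign"` is the conservative choice.
#' @return A list of class `"likelihood_config"`.
#' @export
likelihood_config <- function(Ta = NULL, Tb = NULL, drop_small_terms = FALSE,
                              mixed_gate = c("benign", "stage")) {
  mixed_gate <- match.arg(mixed_gate)
  defaults <- .default_thresholds()
  if (is.null(Ta)) Ta <- defaults[["Ta"]]
  if (is.null(Tb)) Tb <- defaults[["Tb"]]
  if (!is.finite(Ta) || !is.finite(Tb)) {
    stop("thresholds `Ta` and `Tb` must be finite.", call. = FALSE)
  }
  structure(
    list(Ta = Ta, Tb = Tb, drop_small_terms = isTRUE(drop_small_terms),
         mixed_gate = mixed_gate),
    class = "likelihood_config"
  )
}

#' @export
print.likelihood_config <- function(x, ...) {
  cat("<likelihood_config>\n")
  cat(sprintf("  Ta (SVR gate):          % .6f\n", x$Ta))
  cat(sprintf("  Tb (sum-entropy gate):  % .6f\n", x$Tb))
  cat(sprintf("  drop_small_terms:       %s\n", x$drop_small_terms))
  cat(sprintf("  mixed_gate branch:      %s\n", x$mixed_gate))
  invisible(x)
}

#' Combined multi-class likelihood
#'
#' Threshold-gated combination of the benign/malignant and stage likelihoods.
#' Observations with SVR >= `Ta` and sum entropy >= `Tb` (both at or above
#' their malignancy thresholds) are scored with the stage likelihood; all
#' others with the benign/malignant likelihood. The gate depends only on SVR
#' and sum entropy.
#'
#' @param data A data frame with the seven feature columns named as in
#'   [feature_names()].
#' @param cfg A [likelihood_config()].
#' @return The input as a tibble with two added columns: `.likelihood` (the
#'   combined score) and `.branch` (`"benign"` or `"stage"`).
#' @export
#' @examples
#' z <- tibble::tibble(svr = c(-0.2, 0.1), sum_entropy = c(1, 2.5),
#'                     sphericity = 0.45, ldhgle = 0, cluster_prominence = 0,
#'                     small_area_emphasis = 0.9, strength = c(250, 150))
#' combined_likelihood(z, likelihood_config())
combined_likelihood <- function(data, cfg = likelihood_config()) {
  stopifnot(inherits(cfg, "likelihood_config"))
  data <- tibble::as_tibble(data)
  missing <- setdiff(feature_names(), names(data))
  if (length(missing) > 0) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lik <- .combined_likelihood_vec(
    svr = data$svr, sum_entropy = data$sum_entropy,
    sphericity = data$sphericity, ldhgle = data$ldhgle,
    cluster_prominence = data$cluster_prominence,
    small_area_emphasis = data$small_area_emphasis,
    strength = data$strength, cfg = cfg
  )
  data$.likelihood <- lik$value
  data$.branch <- lik$branch
  data
}

# Vectorized kernel shared by combined_likelihood(), the particle filter and
# the grid oracle. Returns value + branch without tibble overhead.
.combined_likelihood_vec <- function(svr, sum_entropy, sphericity, ldhgle,
                                     cluster_prominence, small_area_emphasis,
                                     strength, cfg) {
  stage_gate <- (svr >= cfg$Ta) & (sum_entropy >= cfg$Tb)
  if (cfg$mixed_gate == "stage") {
    stage_gate <- (svr >= cfg$Ta) | (sum_entropy >= cfg$Tb)
  }
  value <- numeric(length(svr))
  if (any(!stage_gate)) {
    i <- !stage_gate
    value[i] <- likelihood_benign_malignant(svr[i], sum_entropy[i])
  }
  if (any(stage_gate)) {
    i <- stage_gate
    value[i] <- likelihood_stage(sphericity[i], ldhgle[i],
                                 cluster_prominence[i],
                                 small_area_emphasis[i], strength[i],
                                 drop_small_terms = cfg$drop_small_terms)
  }
  list(value = value, branch = ifelse(stage_gate, "stage", "benign"))
}

#' Map a posterior diagnostic score to a class label
#'
#' Scores below 0.51 are benign, scores in \[0.51, 0.70) early-stage cancer
#' and scores at or above 0.70 advanced-stage cancer. Scores above 0.90 fall
#' outside the published advanced range and are clamped into
#' `advanced_stage` with a warning.
#'
#' @param score Numeric posterior diagnostic scores (finite).
#' @return A factor with levels `benign`, `early_stage`, `advanced_stage`.
#' @export
#' @examples
#' classify_score(c(0.30, 0.60, 0.80))
classify_score <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score))) {
    stop("`score` must be finite numeric.", call. = FALSE)
  }
  if (any(score > .SCORE_CAP)) {
    warning("score(s) above ", .SCORE_CAP,
            " fall outside the published advanced-stage range; ",
            "clamped into advanced_stage.", call. = FALSE)
  }
  labels <- ifelse(score < .SCORE_EARLY, .CLASS_LEVELS[1L],
                   ifelse(score < .SCORE_ADVANCED, .CLASS_LEVELS[2L],
                          .CLASS_LEVELS[3L]))
  factor(labels, levels = .CLASS_LEVELS)
}
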