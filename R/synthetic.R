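# Synthetic cohort generator.
#
# Ground-truth malignancy-score paths and class-consistent feature
# trajectories are built by inverting the published likelihood polynomials,
# so that the combined likelihood of a noise-free feature vector equals the
# generating score exactly. The whole pipeline is therefore testable without
# access to the restricted screening-trial imaging data.
#
# Feature curves as a function of the true score u in [0, 1]:
#   sum_entropy(u) = 1 + 2u                  (crosses the gate at u = 0.51)
#   svr(u)         = ascending-branch inverse of the benign/malignant quartic
#                    for u < 0.51; C1 linear continuation above
#   sphericity     = 0.45, small_area_emphasis = 0.9, ldhgle = cp = 0
#   strength(u)    = closed-form solve of the stage likelihood, linear in u
# With these choices the benign branch reproduces u for u < 0.51 and the
# stage branch reproduces u for u >= 0.51; all curves except svr are exactly
# representable by the cubic measurement polynomial.

.GEN_SE_BASE <- 1
.GEN_SE_SLOPE <- 2
.GEN_SPLIT <- 0.51
.GEN_SPHERICITY <- 0.45
.GEN_SAE <- 0.9
.GEN_SVR_BRACKET <- c(-0.8, 0.261)  # ascending branch of the quartic

.gen_sum_entropy <- function(u) .GEN_SE_BASE + .GEN_SE_SLOPE * u

# strength(u): 1.2 - 1.1348*sph + 0.3917*sae - 0.00361*strength = u
.gen_strength <- function(u) {
  k <- .EQ_STAGE
  (k[["intercept"]] + k[["sphericity"]] * .GEN_SPHERICITY +
     k[["small_area_emphasis"]] * .GEN_SAE - u) / (-k[["strength"]])
}

# Quartic part of the benign/malignant likelihood (no log term).
.bm_quartic <- function(z) {
  k <- .EQ_BM
  k[["a"]] + k[["b"]] * z + k[["c"]] * z^2 + k[["d"]] * z^3 + k[["e"]] * z^4
}

.bm_quartic_deriv <- function(z) {
  k <- .EQ_BM
  k[["b"]] + 2 * k[["c"]] * z + 3 * k[["d"]] * z^2 + 4 * k[["e"]] * z^3
}

# Inverse of the benign/malignant likelihood along the generator curve:
# solve Q(z) = u - f*log(sum_entropy(u)) on the ascending bracket.
.gen_svr_benign <- function(u) {
  f <- .EQ_BM[["f"]]
  vapply(u, function(ui) {
    target <- ui - f * log(.gen_sum_entropy(ui))
    lo <- .GEN_SVR_BRACKET[1]
    hi <- .GEN_SVR_BRACKET[2]
    flo <- .bm_quartic(lo) - target
    fhi <- .bm_quartic(hi) - target
    if (flo * fhi > 0) {
      stop("score ", format(ui), " is outside the solvable range of the ",
           "SVR bracket [", lo, ", ", hi, "].", call. = FALSE)
    }
    stats::uniroot(function(z) .bm_quartic(z) - target, c(lo, hi),
                   tol = 1e-13)$root
  }, numeric(1))
}

# Boundary constants of the piecewise svr curve, computed once per session.
.gen_svr_boundary <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      z0 <- .gen_svr_benign(.GEN_SPLIT)
      # d svr / d u at the boundary from the implicit equation
      f <- .EQ_BM[["f"]]
      s0 <- (1 - f * .GEN_SE_SLOPE / .gen_sum_entropy(.GEN_SPLIT)) /
        .bm_quartic_deriv(z0)
      cache <<- c(z0 = z0, s0 = s0)
    }
    cache
  }
})

.gen_svr <- function(u) {
  b <- .gen_svr_boundary()
  out <- numeric(length(u))
  low <- u < .GEN_SPLIT
  if (any(low)) out[low] <- .gen_svr_benign(u[low])
  if (any(!low)) out[!low] <- b[["z0"]] + b[["s0"]] * (u[!low] - .GEN_SPLIT)
  out
}

# Default gate thresholds: the generator's feature values at the class
# boundary u = 0.51. Used by likelihood_config().
.default_thresholds <- function() {
  c(Ta = unname(.gen_svr_boundary()[["z0"]]),
    Tb = .gen_sum_entropy(.GEN_SPLIT))
}

#' Synthetic-cohort configuration
#'
#' Cohort sizes, noise scales and per-class target ranges for the final
#' malignancy score. The class ranges are insets of the published score
#' ranges (benign < 0.51, early \[0.51, 0.70), advanced \[0.70, 0.90\]) so
#' that measurement noise does not straddle a class boundary.
#'
#' @param n_benign,n_early,n_advanced Nodules per class.
#' @param state_noise_sd Process-noise standard deviation applied as jitter
#'   around the mean score path (score units).
#' @param feature_noise_sd Measurement-noise standard deviation added
#'   independently to every generated feature value.
#' @param benign_range,early_range,advanced_range Target intervals for the
#'   final true score per class; must be ordered and disjoint.
#' @param k_intervals Number of screening intervals per trajectory.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_benign = 20, n_early = 20, n_advanced = 20,
                             state_noise_sd = 0.01, feature_noise_sd = 0.01,
                             benign_range = c(0.05, 0.45),
                             early_range = c(0.52, 0.68),
                             advanced_range = c(0.72, 0.88),
                             k_intervals = 5) {
  sizes <- c(n_benign, n_early, n_advanced)
  if (any(sizes < 0) || any(sizes != round(sizes))) {
    stop("cohort sizes must be nonnegative integers.", call. = FALSE)
  }
  if (state_noise_sd < 0 || feature_noise_sd < 0) {
    stop("noise standard deviations must be >= 0.", call. = FALSE)
  }
  ranges <- list(benign = benign_range, early = early_range,
                 advanced = advanced_range)
  for (r in ranges) {
    if (length(r) != 2L || r[1] > r[2]) {
      stop("class ranges must be length-2 increasing intervals.",
           call. = FALSE)
    }
  }
  if (!(benign_range[2] < early_range[1] && early_range[2] < advanced_range[1])) {
    stop("class ranges must be disjoint and ordered ",
         "(benign < early < advanced).", call. = FALSE)
  }
  if (k_intervals < 2) stop("`k_intervals` must be >= 2.", call. = FALSE)
  structure(
    list(n_benign = as.integer(n_benign), n_early = as.integer(n_early),
         n_advanced = as.integer(n_advanced),
         state_noise_sd = state_noise_sd,
         feature_noise_sd = feature_noise_sd,
         benign_range = benign_range, early_range = early_range,
         advanced_range = advanced_range,
         k_intervals = as.integer(k_intervals)),
    class = "synthetic_config"
  )
}

#' Ground-truth malignancy-score path for one nodule
#'
#' Benign targets (final score below 0.51) give a flat-low mean path at the
#' target; malignant targets give a monotone linear ramp from a small initial
#' score (0.05) to the target over the `k` intervals, emulating progression.
#' Gaussian jitter of sd `state_noise_sd` is added and the path is clipped to
#' \[0, 1\].
#'
#' @param target Final true score in \[0, 1\].
#' @param k Number of screening intervals.
#' @param state_noise_sd Jitter standard deviation.
#' @return Numeric vector of `k` scores in \[0, 1\].
#' @export
#' @examples
#' generate_state_path(0.8, k = 5, state_noise_sd = 0)
generate_state_path <- function(target, k = 5, state_noise_sd = 0) {
  .check_state(target, "target")
  stopifnot(length(target) == 1L, k >= 2)
  mean_path <- if (target < .GEN_SPLIT) {
    rep(target, k)
  } else {
    seq(min(0.05, target), target, length.out = k)
  }
  if (state_noise_sd > 0) {
    pmin(pmax(mean_path + stats::rnorm(k, sd = state_noise_sd), 0), 1)
  } else {
    mean_path
  }
}

#' Class-consistent feature vectors for given malignancy scores
#'
#' Inverts the published likelihood polynomials so that, without noise, the
#' combined likelihood of the generated features equals the generating score
#' to within the root-solve tolerance (1e-10 or better): scores below 0.51
#' are reproduced through the benign/malignant branch (SVR solved from the
#' quartic, sub-threshold sum entropy), scores at or above 0.51 through the
#' stage branch (strength solved in closed form, supra-threshold SVR and sum
#' entropy). Gaussian noise of sd `feature_noise_sd` is then added to every
#' feature and values are clipped back to their domains (sum entropy and
#' small area emphasis strictly positive, sphericity and small area emphasis
#' at most 1, nonnegative texture features).
#'
#' @param u Malignancy scores in \[0, 1\] (vectorized).
#' @param cfg A [synthetic_config()]; only the noise scale is used.
#' @return Tibble with one row per score and the seven feature columns.
#' @export
#' @examples
#' z <- features_for_state(c(0.3, 0.6), synthetic_config(feature_noise_sd = 0))
#' combined_likelihood(z, likelihood_config())$.likelihood
features_for_state <- function(u, cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .check_state(u, "target score")
  out <- tibble::tibble(
    svr = .gen_svr(u),
    sum_entropy = .gen_sum_entropy(u),
    sphericity = rep(.GEN_SPHERICITY, length(u)),
    ldhgle = rep(0, length(u)),
    cluster_prominence = rep(0, length(u)),
    small_area_emphasis = rep(.GEN_SAE, length(u)),
    strength = .gen_strength(u)
  )
  if (cfg$feature_noise_sd > 0) {
    n <- length(u)
    sd <- cfg$feature_noise_sd
    out$svr <- out$svr + stats::rnorm(n, sd = sd)
    out$sum_entropy <- pmax(out$sum_entropy + stats::rnorm(n, sd = sd), 1e-9)
    out$sphericity <- pmin(pmax(out$sphericity + stats::rnorm(n, sd = sd), 0), 1)
    out$ldhgle <- pmax(out$ldhgle + stats::rnorm(n, sd = sd), 0)
    out$cluster_prominence <-
      pmax(out$cluster_prominence + stats::rnorm(n, sd = sd), 0)
    out$small_area_emphasis <-
      pmin(pmax(out$small_area_emphasis + stats::rnorm(n, sd = sd), 1e-9), 1)
    out$strength <- pmax(out$strength + stats::rnorm(n, sd = sd), 0)
  }
  out
}

#' Generate a synthetic screening cohort
#'
#' Draws, for every nodule, a final-score target uniformly inside its class
#' range, builds the ground-truth score path and emits noisy feature vectors
#' per screening interval.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `"synthetic_cohort"` with two tibbles:
#'   `cohort` (long format: `nodule_id`, `time_index`, features,
#'   `truth_label`) and `truth` (`nodule_id`, `truth_label`, plus
#'   `true_state_k1` ... `true_state_kK`).
#' @export
#' @examples
#' gen <- generate_cohort(synthetic_config(2, 2, 2), seed = 7)
#' dplyr::count(gen$cohort, truth_label)
generate_cohort <- function(cfg = synthetic_config(), seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  classes <- tibble::tibble(
    truth_label = rep(class_levels(),
                      times = c(cfg$n_benign, cfg$n_early, cfg$n_advanced)),
    range_lo = rep(c(cfg$benign_range[1], cfg$early_range[1],
                     cfg$advanced_range[1]),
                   times = c(cfg$n_benign, cfg$n_early, cfg$n_advanced)),
    range_hi = rep(c(cfg$benign_range[2], cfg$early_range[2],
                     cfg$advanced_range[2]),
                   times = c(cfg$n_benign, cfg$n_early, cfg$n_advanced))
  )
  n <- nrow(classes)
  if (n == 0L) {
    empty <- tibble::tibble(nodule_id = character(0),
                            time_index = integer(0))
    for (f in feature_names()) empty[[f]] <- numeric(0)
    empty$truth_label <- character(0)
    truth <- tibble::tibble(nodule_id = character(0),
                            truth_label = character(0))
    for (k in seq_len(cfg$k_intervals)) {
      truth[[paste0("true_state_k", k)]] <- numeric(0)
    }
    return(structure(list(cohort = empty, truth = truth, config = cfg),
                     class = "synthetic_cohort"))
  }
  classes$nodule_id <- sprintf("nod%03d", seq_len(n))
  K <- cfg$k_intervals
  withr::with_seed(.derive_seed(seed, 1L), {
    classes$target <- stats::runif(n, classes$range_lo, classes$range_hi)
    paths <- lapply(classes$target, generate_state_path, k = K,
                    state_noise_sd = cfg$state_noise_sd)
    cohort <- purrr::map_dfr(seq_len(n), function(i) {
      feats <- features_for_state(paths[[i]], cfg)
      dplyr::bind_cols(
        tibble::tibble(nodule_id = classes$nodule_id[i],
                       time_index = seq_len(K)),
        feats,
        tibble::tibble(truth_label = classes$truth_label[i])
      )
    })
  })
  truth <- tibble::tibble(nodule_id = classes$nodule_id,
                          truth_label = classes$truth_label)
  states <- do.call(rbind, paths)
  colnames(states) <- paste0("true_state_k", seq_len(K))
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(states))
  structure(list(cohort = cohort, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$truth), "nodules x",
      x$config$k_intervals, "intervals\n")
  print(table(x$truth$truth_label))
  invisible(x)
}

#' Generate (state, feature) training pairs for the measurement model
#'
#' States are uniform on \[0, 1\]; features come from [features_for_state()]
#' with the configured measurement noise.
#'
#' @param n Number of pairs (>= 1).
#' @param cfg A [synthetic_config()].
#' @param seed Integer seed.
#' @return Tibble with a `state` column and the seven feature columns,
#'   suitable as input to [fit_measurement_model()].
#' @export
generate_training_pairs <- function(n, cfg = synthetic_config(), seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count.", call. = FALSE)
  }
  withr::with_seed(.derive_seed(seed, 2L), {
    u <- stats::runif(as.integer(n))
    dplyr::bind_cols(tibble::tibble(state = u), features_for_state(u, cfg))
  })
}

# Deterministic sub-seed derivation; keeps results below 2^31.
.derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %%
               2147483629)
}
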