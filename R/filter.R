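# Sequential importance resampling (bootstrap) particle filter over the
# latent malignancy score, plus a deterministic grid-Bayes reference filter.
#
# One filtering sweep over the K screening intervals:
#   k = 1:  particles from the uniform initial prior, then weighting
#   k >= 2: propagate every particle through the transition kernel
#   weight:  Gaussian kernel on the difference between the combined
#            likelihood of the predicted features at the particle state and
#            the combined likelihood of the observed features
#   resample (systematic) when the effective sample size falls below the
#            configured fraction of Ns; the default always resamples
# Sweeps are repeated with fresh randomness until the posterior-mean
# sequence stabilizes (mean squared change <= xi) or max_outer_iters.

#' Particle filter configuration
#'
#' @param n_particles Number of particles Ns (default 4000).
#' @param alpha Transition-kernel parameter; see [transition_density()].
#'   The kernel shape is published but its scale is not. The default 1 makes
#'   the kernel the plain exponential law in the absolute score change;
#'   smaller values increasingly favour "no change" and make the posterior
#'   lag fast progressions (see the vignette).
#' @param sigma_w Width of the Gaussian weighting kernel on the likelihood
#'   discrepancy (default 0.05, in likelihood-score units).
#' @param ess_fraction Resampling trigger, as a fraction of `n_particles` in
#'   (0, 1\]. The default 1 resamples at every interval, matching the
#'   published algorithm; smaller values give ESS-triggered resampling.
#' @param xi Convergence threshold on the mean squared change of the
#'   posterior-mean sequence between outer iterations (default 1e-4).
#' @param max_outer_iters Cap on outer iterations (default 50).
#' @param k_intervals Number of screening intervals K (default 5).
#' @param order Measurement-polynomial order the model must have.
#' @param seed Master seed used by [run_filter()] and [run_cohort()].
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(n_particles = 4000, alpha = 1, sigma_w = 0.05,
                          ess_fraction = 1, xi = 1e-4, max_outer_iters = 50,
                          k_intervals = 5, order = 3, seed = 1) {
  if (n_particles < 2) stop("`n_particles` must be >= 2.", call. = FALSE)
  .check_alpha(alpha)
  if (sigma_w <= 0) stop("`sigma_w` must be > 0.", call. = FALSE)
  if (ess_fraction <= 0 || ess_fraction > 1) {
    stop("`ess_fraction` must be in (0, 1].", call. = FALSE)
  }
  if (xi <= 0) stop("`xi` must be > 0.", call. = FALSE)
  if (max_outer_iters < 1) stop("`max_outer_iters` must be >= 1.", call. = FALSE)
  if (k_intervals < 2) stop("`k_intervals` must be >= 2.", call. = FALSE)
  structure(
    list(n_particles = as.integer(n_particles), alpha = alpha,
         sigma_w = sigma_w, ess_fraction = ess_fraction, xi = xi,
         max_outer_iters = as.integer(max_outer_iters),
         k_intervals = as.integer(k_intervals), order = as.integer(order),
         seed = as.integer(seed)),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  for (f in names(x)) cat(sprintf("  %-16s %s\n", f, format(x[[f]])))
  invisible(x)
}

.check_particles <- function(particles) {
  if (!is.data.frame(particles) ||
      !all(c("state", "weight") %in% names(particles))) {
    stop("particles must be a data frame with `state` and `weight` columns.",
         call. = FALSE)
  }
  if (nrow(particles) < 2L) stop("need at least 2 particles.", call. = FALSE)
  .check_state(particles$state)
  invisible(particles)
}

#' Update particle weights against one observation
#'
#' For each particle, the measurement model predicts noise-free features at
#' the particle's state; the combined likelihood of those predicted features
#' is compared with the combined likelihood of the observed features. The
#' closeness of the two likelihood values sets the weight: the unnormalized
#' weight is `prior_weight * exp(-(L_pred - L_obs)^2 / (2 * sigma_w^2))`,
#' then weights are normalized to sum to one. Both likelihood evaluations
#' apply the threshold gate to their own feature vector.
#'
#' If every unnormalized weight underflows to zero, the weights are reset to
#' uniform with a warning rather than aborting the run.
#'
#' @param particles Tibble with `state` and `weight` columns.
#' @param observed One-row data frame with the seven feature columns.
#' @param model A [fit_measurement_model()] object.
#' @param lik_cfg A [likelihood_config()].
#' @param sigma_w Weighting-kernel width.
#' @return The particle tibble with normalized updated weights.
#' @export
compute_weights <- function(particles, observed, model, lik_cfg, sigma_w) {
  .check_particles(particles)
  observed <- tibble::as_tibble(observed)
  stopifnot(nrow(observed) == 1L)
  l_obs <- combined_likelihood(observed, lik_cfg)$.likelihood
  .update_weights(particles, l_obs, model, lik_cfg, sigma_w)
}

# Internal update against a precomputed observed likelihood value.
.update_weights <- function(particles, l_obs, model, lik_cfg, sigma_w) {
  pred <- predict_features(model, particles$state)
  l_pred <- .combined_likelihood_vec(
    pred$svr, pred$sum_entropy, pred$sphericity, pred$ldhgle,
    pred$cluster_prominence, pred$small_area_emphasis, pred$strength,
    cfg = lik_cfg
  )$value
  w <- particles$weight * exp(-(l_pred - l_obs)^2 / (2 * sigma_w^2))
  total <- sum(w)
  if (!is.finite(total) || total <= 0) {
    warning("degenerate particle weights (all underflowed); ",
            "reset to uniform.", call. = FALSE)
    w <- rep(1 / nrow(particles), nrow(particles))
  } else {
    w <- w / total
  }
  particles$weight <- w
  particles
}

#' Effective sample size of a weighted particle set
#'
#' `1 / sum(w_i^2)` for normalized weights: Ns for uniform weights, 1 when a
#' single particle carries all mass.
#'
#' @param particles Tibble with normalized `weight` column.
#' @return Scalar in \[1, Ns\].
#' @export
effective_sample_size <- function(particles) {
  .check_particles(particles)
  1 / sum(particles$weight^2)
}

#' Systematic resampling
#'
#' Draws Ns ancestors with a single uniform offset against the stratified
#' cumulative weight thresholds, so each particle's expected copy count is
#' `Ns * w_i` and realized counts differ from expectation by less than one.
#' Output weights are uniform `1/Ns`.
#'
#' @param particles Tibble with normalized weights.
#' @param n Number of draws (defaults to the particle count).
#' @return Resampled particle tibble of `n` rows with uniform weights.
#' @export
systematic_resample <- function(particles, n = nrow(particles)) {
  .check_particles(particles)
  ns <- as.integer(n)
  u <- (stats::runif(1) + 0:(ns - 1)) / ns
  ancestors <- findInterval(u, cumsum(particles$weight)) + 1L
  ancestors[ancestors > nrow(particles)] <- nrow(particles)  # cumsum rounding
  tibble::tibble(state = particles$state[ancestors],
                 weight = rep(1 / ns, ns))
}

#' Posterior mean estimate (PME) of a particle set
#'
#' The weighted mean of the particle states: the weighted-sample form of the
#' posterior expectation of the malignancy score.
#'
#' @param particles Tibble with normalized weights.
#' @return Scalar score in \[0, 1\].
#' @export
posterior_mean <- function(particles) {
  .check_particles(particles)
  sum(particles$weight * particles$state)
}

#' Outer-iteration convergence criterion
#'
#' The mean squared change of the per-interval posterior-mean sequence
#' between two consecutive outer iterations, compared against the threshold:
#' `sum((new - prev)^2) / K <= xi` (boundary inclusive).
#'
#' @param prev,new Numeric PME sequences of equal length K.
#' @param xi Positive threshold.
#' @return Logical.
#' @export
check_convergence <- function(prev, new, xi) {
  if (length(prev) != length(new)) {
    stop("PME sequences have different lengths (", length(prev), " vs ",
         length(new), ").", call. = FALSE)
  }
  stopifnot(xi > 0)
  mean((new - prev)^2) <= xi
}

# One filtering sweep over the K observed likelihood values; returns the PME
# and pre-resampling ESS per interval. Uses the ambient RNG state.
.filter_sweep <- function(l_obs, model, lik_cfg, cfg) {
  ns <- cfg$n_particles
  K <- length(l_obs)
  pme <- numeric(K)
  ess <- numeric(K)
  particles <- tibble::tibble(state = stats::runif(ns),
                              weight = rep(1 / ns, ns))
  for (k in seq_len(K)) {
    if (k > 1L) {
      particles$state <- .propagate_states(particles$state, cfg$alpha)
    }
    particles <- .update_weights(particles, l_obs[k], model, lik_cfg,
                                 cfg$sigma_w)
    ess[k] <- effective_sample_size(particles)
    pme[k] <- posterior_mean(particles)
    if (ess[k] <= cfg$ess_fraction * ns) {
      particles <- systematic_resample(particles)
    }
  }
  list(pme = pme, ess = ess)
}

#' Run the particle filter on one nodule trajectory
#'
#' Estimates the posterior mean of the malignancy score at every screening
#' interval, repeats the filtering sweep with fresh randomness until the PME
#' sequence stabilizes (see [check_convergence()]), and classifies the
#' nodule from the final-interval PME. Each outer iteration draws from a
#' deterministic sub-stream of the master seed, so results are reproducible
#' bitwise for a fixed configuration.
#'
#' @param trajectory Data frame for a single nodule: `time_index` plus the
#'   seven feature columns, with exactly `cfg$k_intervals` rows.
#' @param model A [fit_measurement_model()] object of matching order.
#' @param lik_cfg A [likelihood_config()].
#' @param cfg A [filter_config()].
#' @return An object of class `"nodule_diagnosis"`: list with `nodule_id`,
#'   `pme` (K posterior means), `final_score`, `label`, `converged`,
#'   `outer_iterations`, `ess` (K-vector from the final iteration), and the
#'   configurations used.
#' @export
#' @examples
#' cfg0 <- synthetic_config(feature_noise_sd = 0)
#' model <- fit_measurement_model(generate_training_pairs(400, cfg0, seed = 2))
#' traj <- dplyr::bind_cols(tibble::tibble(time_index = 1:5),
#'                          features_for_state(rep(0.3, 5), cfg0))
#' fit <- run_filter(traj, model, cfg = filter_config(n_particles = 500))
#' glance(fit)
run_filter <- function(trajectory, model, lik_cfg = likelihood_config(),
                       cfg = filter_config()) {
  stopifnot(inherits(model, "measurement_model"),
            inherits(cfg, "filter_config"))
  trajectory <- tibble::as_tibble(trajectory)
  if (nrow(trajectory) != cfg$k_intervals) {
    stop("trajectory has ", nrow(trajectory), " intervals but the filter ",
         "expects K = ", cfg$k_intervals, ".", call. = FALSE)
  }
  if (model$order != cfg$order) {
    stop("measurement model order (", model$order, ") does not match ",
         "`cfg$order` (", cfg$order, ").", call. = FALSE)
  }
  if ("time_index" %in% names(trajectory)) {
    trajectory <- dplyr::arrange(trajectory, .data$time_index)
  }
  l_obs <- combined_likelihood(trajectory, lik_cfg)$.likelihood
  nodule_id <- if ("nodule_id" %in% names(trajectory)) {
    as.character(trajectory$nodule_id[1])
  } else {
    NA_character_
  }

  pme_prev <- NULL
  converged <- FALSE
  sweep <- NULL
  iters <- 0L
  for (iter in seq_len(cfg$max_outer_iters)) {
    iters <- iter
    sweep <- withr::with_seed(
      .derive_seed(cfg$seed, 100L + iter),
      .filter_sweep(l_obs, model, lik_cfg, cfg)
    )
    if (!is.null(pme_prev) &&
        check_convergence(pme_prev, sweep$pme, cfg$xi)) {
      converged <- TRUE
      break
    }
    pme_prev <- sweep$pme
  }
  final <- sweep$pme[cfg$k_intervals]
  structure(
    list(nodule_id = nodule_id, pme = sweep$pme, final_score = final,
         label = suppressWarnings(classify_score(final)),
         converged = converged, outer_iterations = iters,
         ess = sweep$ess, filter_config = cfg, likelihood_config = lik_cfg),
    class = "nodule_diagnosis"
  )
}

#' @export
print.nodule_diagnosis <- function(x, ...) {
  cat("<nodule_diagnosis>",
      if (!is.na(x$nodule_id)) x$nodule_id else "", "\n")
  cat("  PME: ", paste(sprintf("%.3f", x$pme), collapse = " -> "), "\n")
  cat(sprintf("  final score %.4f -> %s (%s after %d outer iteration%s)\n",
              x$final_score, as.character(x$label),
              if (x$converged) "converged" else "NOT converged",
              x$outer_iterations, if (x$outer_iterations == 1) "" else "s"))
  invisible(x)
}

#' Tidy per-interval results of a nodule diagnosis
#'
#' @param x A `nodule_diagnosis`.
#' @param ... Unused.
#' @return A tibble with `interval`, `pme` and `ess` columns.
#' @method tidy nodule_diagnosis
#' @export
tidy.nodule_diagnosis <- function(x, ...) {
  tibble::tibble(interval = seq_along(x$pme), pme = x$pme, ess = x$ess)
}

#' @rdname tidy.nodule_diagnosis
#' @return For `glance()`: a one-row tibble with the nodule id, final score,
#'   label, convergence flag and outer-iteration count.
#' @method glance nodule_diagnosis
#' @export
glance.nodule_diagnosis <- function(x, ...) {
  tibble::tibble(nodule_id = x$nodule_id, final_score = x$final_score,
                 label = x$label, converged = x$converged,
                 outer_iterations = x$outer_iterations)
}

#' Run the particle filter over a cohort
#'
#' Applies [run_filter()] to every nodule of a long-format cohort table.
#' Three-point (annual) trajectories are densified to five half-yearly
#' intervals first; five-point trajectories pass through unchanged. Each
#' nodule gets a deterministic seed derived from the master seed, and
#' per-nodule failures (for example a trajectory of unusable length) do not
#' abort the batch: failed nodules are collected in the `"failures"`
#' attribute of the result.
#'
#' @param cohort Long-format cohort tibble (see [read_cohort()]).
#' @param model,lik_cfg,cfg As in [run_filter()]; `cfg$seed` is the master
#'   seed.
#' @return A tibble with one row per diagnosed nodule: `nodule_id`,
#'   `pme_k1` ... `pme_kK`, `final_score`, `label`, `converged`,
#'   `outer_iterations`; failures in `attr(, "failures")`.
#' @export
run_cohort <- function(cohort, model, lik_cfg = likelihood_config(),
                       cfg = filter_config()) {
  cohort <- tibble::as_tibble(cohort)
  stopifnot("nodule_id" %in% names(cohort))
  ids <- unique(cohort$nodule_id)
  failures <- list()
  rows <- list()
  for (i in seq_along(ids)) {
    traj <- cohort[cohort$nodule_id == ids[i], , drop = FALSE]
    res <- tryCatch({
      if (nrow(traj) == 3L) traj <- densify_trajectory(traj)
      nod_cfg <- cfg
      nod_cfg$seed <- .derive_seed(cfg$seed, 1000L + i)
      run_filter(traj, model, lik_cfg, nod_cfg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(nodule_id = ids[i], error = conditionMessage(res))
    } else {
      pme <- as.list(res$pme)
      names(pme) <- paste0("pme_k", seq_along(res$pme))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(nodule_id = ids[i]),
        tibble::as_tibble(pme),
        tibble::tibble(final_score = res$final_score,
                       label = as.character(res$label),
                       converged = res$converged,
                       outer_iterations = res$outer_iterations)
      )
    }
  }
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble()
  attr(out, "failures") <-
    if (length(failures) > 0) dplyr::bind_rows(failures) else NULL
  out
}

#' Deterministic grid-Bayes reference filter
#'
#' Exact Bayes recursion on a uniform discretization of the score domain:
#' the transition kernel becomes a column-normalized matrix, the update
#' multiplies by the same Gaussian likelihood-discrepancy kernel as
#' [compute_weights()], and the normalizing constant is computed by
#' summation. Fully deterministic; serves as the reference the particle
#' filter is checked against.
#'
#' @param trajectory Single-nodule trajectory, as in [run_filter()].
#' @param model,lik_cfg,cfg As in [run_filter()] (no randomness is used).
#' @param n_grid Number of grid points (>= 101; default 1001).
#' @return Numeric vector of K per-interval posterior-mean scores.
#' @export
grid_posterior <- function(trajectory, model, lik_cfg = likelihood_config(),
                           cfg = filter_config(), n_grid = 1001) {
  stopifnot(inherits(model, "measurement_model"),
            inherits(cfg, "filter_config"))
  if (n_grid < 101) stop("`n_grid` must be >= 101.", call. = FALSE)
  trajectory <- tibble::as_tibble(trajectory)
  if (nrow(trajectory) != cfg$k_intervals) {
    stop("trajectory has ", nrow(trajectory), " intervals but the filter ",
         "expects K = ", cfg$k_intervals, ".", call. = FALSE)
  }
  if ("time_index" %in% names(trajectory)) {
    trajectory <- dplyr::arrange(trajectory, .data$time_index)
  }
  l_obs <- combined_likelihood(trajectory, lik_cfg)$.likelihood

  u <- seq(0, 1, length.out = n_grid)
  pred <- predict_features(model, u)
  g <- .combined_likelihood_vec(
    pred$svr, pred$sum_entropy, pred$sphericity, pred$ldhgle,
    pred$cluster_prominence, pred$small_area_emphasis, pred$strength,
    cfg = lik_cfg
  )$value

  trans <- exp(-abs(outer(u, u, `-`))^cfg$alpha / cfg$alpha)
  trans <- sweep(trans, 2L, colSums(trans), `/`)  # columns: from-state

  p <- rep(1 / n_grid, n_grid)
  pme <- numeric(cfg$k_intervals)
  for (k in seq_len(cfg$k_intervals)) {
    if (k > 1L) p <- drop(trans %*% p)
    p <- p * exp(-(g - l_obs[k])^2 / (2 * cfg$sigma_w^2))
    total <- sum(p)
    if (!is.finite(total) || total <= 0) {
      p <- rep(1 / n_grid, n_grid)  # mirror the particle-filter reset
    } else {
      p <- p / total
    }
    pme[k] <- sum(u * p)
  }
  pme
}
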