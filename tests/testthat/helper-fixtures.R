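# Shared fixtures, built once per test run.

# Noise-free generator settings: the deterministic backbone most tests use.
noisefree_config <- function() {
  synthetic_config(state_noise_sd = 0, feature_noise_sd = 0)
}

# Measurement model fit on noise-free training pairs (cached: the benign
# branch of the generator root-solves per state).
cached_model <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      pairs <- generate_training_pairs(500, noisefree_config(), seed = 424)
      model <<- fit_measurement_model(pairs, order = 3)
    }
    model
  }
})

# Small particle count for unit tests; acceptance tests use the full 4000.
quick_filter_config <- function(...) {
  filter_config(n_particles = 1000, ...)
}

# Single-nodule trajectory observed exactly on the generator curves.
make_trajectory <- function(states, id = "nod001") {
  dplyr::bind_cols(
    tibble::tibble(nodule_id = id, time_index = seq_along(states)),
    features_for_state(states, noisefree_config())
  )
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")

# Hand-built measurement model whose predicted features always satisfy the
# stage gate and whose stage likelihood is exactly the identity in the
# state: constants everywhere except a linear strength curve solving
# 1.2 - 1.1348*0.45 + 0.3917*0.9 - 0.00361*strength(u) = u.
identity_model <- function() {
  a <- (1.2 - 1.1348 * 0.45 + 0.3917 * 0.9) / 0.00361
  zero <- c(0, 0, 0, 0)
  structure(
    list(order = 3L,
         coeffs = list(svr = c(0.15, 0, 0, 0),
                       sum_entropy = c(2.5, 0, 0, 0),
                       sphericity = c(0.45, 0, 0, 0),
                       ldhgle = zero, cluster_prominence = zero,
                       small_area_emphasis = c(0.9, 0, 0, 0),
                       strength = c(a, -1 / 0.00361, 0, 0)),
         noise_sd = stats::setNames(rep(0, 7), feature_names()),
         n_train = 0L),
    class = "measurement_model"
  )
}
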