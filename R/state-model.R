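# Latent malignancy state: transition prior and sampling.
#
# The state is a diagnostic score u in [0, 1]. Its screening-to-screening
# evolution follows an exponential-type kernel in the absolute score change,
# exp(-|u_k - u_{k-1}|^alpha / alpha), restricted to the unit interval.

.check_state <- function(u, what = "state") {
  if (!is.numeric(u) || any(!is.finite(u))) {
    stop("invalid ", what, ": values must be finite numeric.", call. = FALSE)
  }
  if (any(u < 0 | u > 1)) {
    stop("invalid ", what, ": diagnostic scores must lie in [0, 1].",
         call. = FALSE)
  }
  invisible(u)
}

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single positive finite number.", call. = FALSE)
  }
  invisible(alpha)
}

#' State transition density
#'
#' Unnormalized density of the malignancy-score transition kernel,
#' `exp(-|u - u_prev|^alpha / alpha)`. The kernel is symmetric in its two
#' state arguments and attains its maximum value 1 when the score does not
#' change; `alpha` controls the spread of plausible score changes between
#' consecutive screenings.
#'
#' @param u,u_prev Diagnostic scores in \[0, 1\] (vectorized).
#' @param alpha Positive kernel shape/scale parameter.
#' @return Nonnegative unnormalized density values.
#' @export
#' @examples
#' transition_density(0.4, 0.4, alpha = 1)   # 1
#' transition_density(0.9, 0.4, alpha = 1)   # exp(-0.5)
transition_density <- function(u, u_prev, alpha) {
  .check_state(u)
  .check_state(u_prev, "previous state")
  .check_alpha(alpha)
  exp(-abs(u - u_prev)^alpha / alpha)
}

#' Sample from the state transition kernel
#'
#' Draws states distributed proportional to [transition_density()] around
#' `u_prev`, restricted to \[0, 1\].
#'
#' Sampling uses an exact transform rather than naive rejection against a
#' uniform envelope: if `S ~ Gamma(shape = 1/alpha, rate = 1/alpha)` then
#' `S^(1/alpha)` has density proportional to `exp(-t^alpha / alpha)` on
#' `t >= 0`. A random sign gives the signed score change and draws leaving
#' \[0, 1\] are rejected, which truncates (not clips) the kernel to the state
#' domain. This stays efficient for small `alpha`, where the kernel is
#' heavy-tailed and a uniform-envelope sampler would almost always reject.
#'
#' @param u_prev Previous diagnostic score (scalar in \[0, 1\]).
#' @param alpha Positive kernel parameter.
#' @param n Number of samples (>= 1).
#' @return Numeric vector of `n` scores in \[0, 1\]. Deterministic for a
#'   fixed RNG state.
#' @export
#' @examples
#' set.seed(1)
#' sample_transition(0.5, alpha = 0.5, n = 5)
sample_transition <- function(u_prev, alpha, n) {
  .check_state(u_prev, "previous state")
  stopifnot(length(u_prev) == 1L)
  .check_alpha(alpha)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a positive count.", call. = FALSE)
  }
  .propagate_states(rep.int(u_prev, as.integer(n)), alpha)
}

# Propagate a vector of particle states one screening interval forward:
# one independent transition draw per input state. Vectorized rejection of
# out-of-domain moves; deterministic given the RNG state.
.propagate_states <- function(states, alpha, max_rounds = 10000L) {
  out <- states
  todo <- seq_along(states)
  shape <- 1 / alpha
  for (round in seq_len(max_rounds)) {
    m <- length(todo)
    if (m == 0L) {
      return(out)
    }
    s <- stats::rgamma(m, shape = shape, rate = shape)
    step <- s^shape  # |du| = S^(1/alpha)
    sgn <- ifelse(stats::runif(m) < 0.5, -1, 1)
    cand <- states[todo] + sgn * step
    ok <- cand >= 0 & cand <= 1
    out[todo[ok]] <- cand[ok]
    todo <- todo[!ok]
  }
  stop("transition sampling failed to accept after ", max_rounds,
       " rounds; check `alpha`.", call. = FALSE)
}
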