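#' Infection-thinned offspring pmf
#'
#' Law of `X * I` for one individual in state `theta`: mass
#' `1 - alpha + alpha * P_0` at 0 and `alpha * P_r` at `r >= 1`.
#'
#' @param state an [env_state].
#' @return a [sized_pmf] with zero tail mass.
#' @export
thinned_offspring_pmf <- function(state) {
  stopifnot(inherits(state, "env_state"))
  p <- state$alpha * state$offspring
  p[1L] <- p[1L] + (1 - state$alpha)
  sized_pmf(p)
}

#' Exact one-step transition law
#'
#' The law of `Z_{n+1}` given `Z_n = i` in environment state `theta`:
#' a mixture over the participation count `k ~ Q(theta; i, .)` of the k-fold
#' convolution of the thinned offspring pmf.  The convolution replaces the
#' enumeration over all participant offspring/indicator configurations
#' summing to `j`; the two are mathematically identical, and the enumeration
#' survives as a test oracle on tiny instances.
#'
#' @param state an [env_state].
#' @param i current population size (`i = 0` gives a point mass at 0).
#' @param J_max truncation cap (default 4096); lost mass is tracked in
#'   `tail_mass`.
#' @return a [sized_pmf] over next-generation sizes.
#' @export
one_step_pmf <- function(state, i, J_max = 4096L) {
  stopifnot(inherits(state, "env_state"), i >= 0, i == as.integer(i))
  if (i == 0) return(sized_pmf(1))
  q <- kernel_pmf(state$control, i)
  thin <- thinned_offspring_pmf(state)
  cap <- as.integer(J_max) + 1L
  K <- length(q) - 1L
  pw <- conv_powers_upto(thin$probs, K, cap)
  out <- numeric(cap)
  tail <- 0
  for (k in 0:K) {
    if (q[k + 1L] == 0) next
    v <- pw[[k + 1L]]
    lv <- length(v)
    out[seq_len(lv)] <- out[seq_len(lv)] + q[k + 1L] * v
    tail <- tail + q[k + 1L] * max(1 - sum(v), 0)
  }
  last <- max(which(out > 0), 1L)
  sized_pmf(out[seq_len(last)], min(tail, 1))
}

#' Conditional mean of the next generation
#'
#' `E(Z_{n+1} | Z_n = i, theta) = i * m * alpha * eps(theta, i)`; equals the
#' mean of [one_step_pmf()] up to truncation.
#'
#' @param state an [env_state].
#' @param i current size (`>= 0`).
#' @return non-negative numeric.
#' @export
conditional_mean <- function(state, i) {
  stopifnot(i >= 0)
  if (i == 0) return(0)
  sm <- state_summaries(state)
  i * sm$m * sm$alpha * sm$eps_of_k(i)
}

#' Conditional variance of the next generation
#'
#' `Var(Z_{n+1} | Z_n = i, theta) = i * eps(theta, i) * Var(XI) +
#' m^2 alpha^2 delta2(theta, i)`.
#'
#' @inheritParams conditional_mean
#' @return non-negative numeric.
#' @export
conditional_variance <- function(state, i) {
  stopifnot(i >= 0)
  if (i == 0) return(0)
  sm <- state_summaries(state)
  i * sm$eps_of_k(i) * sm$var_xi_product +
    sm$m^2 * sm$alpha^2 * sm$delta2_of_k(i)
}

#' Exact quenched distribution propagation
#'
#' Pushes the point mass at `N0` through the exact one-step law along a fixed
#' environment sequence, giving the quenched law of `Z_0..Z_n`.  The reported
#' `tail_mass` is a valid upper bound on probability lost to truncation and
#' is nondecreasing in the generation.
#'
#' @param law an [env_law].
#' @param env_sequence integer state indices for generations `0..n-1`.
#' @param N0 initial size (`>= 1`).
#' @param J_max truncation cap (default 4096).
#' @return list of [sized_pmf]s of length `length(env_sequence) + 1`.
#' @export
propagate_distribution <- function(law, env_sequence, N0, J_max = 4096L) {
  stopifnot(inherits(law, "env_law"), N0 >= 1, N0 == as.integer(N0))
  cap <- as.integer(J_max) + 1L
  if (N0 >= cap) stop("propagate_distribution: N0 exceeds J_max; raise J_max")
  cur <- numeric(N0 + 1L); cur[N0 + 1L] <- 1
  tail <- 0
  out <- vector("list", length(env_sequence) + 1L)
  out[[1L]] <- sized_pmf(cur, tail)
  for (t in seq_along(env_sequence)) {
    state <- law$states[[env_sequence[t]]]
    thin <- thinned_offspring_pmf(state)
    # participation support over all sizes present this generation
    sizes <- which(cur > 0) - 1L
    Kmax <- if (length(sizes)) max(vapply(sizes, function(i)
      kernel_max_support(state$control, i), numeric(1))) else 0L
    if (Kmax >= 8 * cap)
      stop("propagate_distribution: control support overflows cap; raise J_max")
    pw <- conv_powers_upto(thin$probs, as.integer(Kmax), cap)
    nxt <- numeric(cap)
    for (i in sizes) {
      wi <- cur[i + 1L]
      q <- kernel_pmf(state$control, i)
      for (k in seq_along(q) - 1L) {
        if (q[k + 1L] == 0) next
        v <- pw[[k + 1L]]
        lv <- length(v)
        nxt[seq_len(lv)] <- nxt[seq_len(lv)] + wi * q[k + 1L] * v
      }
    }
    tail <- tail + max(1 - tail - sum(nxt), 0)
    last <- max(which(nxt > 0), 1L)
    out[[t + 1L]] <- sized_pmf(nxt[seq_len(last)], min(tail, 1))
    cur <- nxt
  }
  out
}
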