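#' Wilson score confidence interval for a binomial frequency
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return named vector `c(estimate, lower, upper, half_width)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(estimate = p, lower = max(centre - hw, 0),
    upper = min(centre + hw, 1), half_width = hw)
}

#' Certain-extinction criterion
#'
#' Evaluates, exactly over the finite environment law, the annealed
#' criterion `E[log(eta(theta) * N0 * alpha(theta) * m(theta))]`.  If the
#' expectation is `<= 0` and the strict-monotonicity hypothesis (checked by
#' [check_monotonicity()]) holds for every state, the process dies out with
#' probability one.  A positive expectation leaves the criterion silent
#' (`"criterion_positive"`); an infinite dominating ratio `eta` makes it
#' inapplicable.
#'
#' Note that the initial size `N0` enters the criterion multiplicatively
#' inside the logarithm, so the conclusion can change with `N0`; the report
#' flags the `N0` at which the sign flips.
#'
#' @param law an [env_law].
#' @param N0 initial size (`>= 1`).
#' @param grid_size grid for the monotonicity certificate (default 1e4).
#' @return an object of class `extinction_criterion_report` with fields
#'   `per_state_term`, `expectation`, `monotonicity_ok`, `conclusion`,
#'   `N0_sign_change`.
#' @export
extinction_criterion <- function(law, N0, grid_size = 1e4) {
  stopifnot(inherits(law, "env_law"), N0 >= 1)
  sms <- law_summaries(law)
  eta <- vapply(sms, `[[`, numeric(1), "eta")
  if (any(!is.finite(eta))) {
    rep <- list(per_state_term = rep(NA_real_, length(sms)),
                expectation = NA_real_, monotonicity_ok = NULL,
                conclusion = "theorem_inapplicable",
                reason = "eta = +Inf for some state", N0 = N0,
                labels = law$labels)
    class(rep) <- "extinction_criterion_report"
    return(rep)
  }
  terms <- vapply(sms, function(s) log(s$eta * N0 * s$alpha * s$m), numeric(1))
  expectation <- sum(law$probs * terms)
  mono <- vapply(seq_along(law$states), function(i)
    check_monotonicity(law$states[[i]], N0, grid_size = grid_size)$increasing,
    logical(1))
  conclusion <- if (expectation <= 0 && all(mono)) "certain_extinction"
                else if (expectation <= 0) "theorem_inapplicable"
                else "criterion_positive"
  # N0 appears as + log(N0): the per-law base term is E[log(eta alpha m)]
  base <- expectation - log(N0)
  n0_flip <- if (base < 0) ceiling(exp(-base) - 1e-12) else 1
  structure(list(per_state_term = terms, expectation = expectation,
                 monotonicity_ok = mono, conclusion = conclusion,
                 reason = "", N0 = N0, N0_sign_change = n0_flip,
                 labels = law$labels),
            class = "extinction_criterion_report")
}

#' @export
print.extinction_criterion_report <- function(x, ...) {
  cat("<extinction_criterion_report> N0 =", x$N0, "\n")
  for (i in seq_along(x$per_state_term))
    cat(sprintf("  %-10s log(eta N0 alpha m) = %+.6f  monotonicity %s\n",
                x$labels[i], x$per_state_term[i],
                if (length(x$monotonicity_ok)) x$monotonicity_ok[i] else NA))
  cat(sprintf("  expectation %+.6f -> %s\n", x$expectation, x$conclusion))
  if (nzchar(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Strict-monotonicity certificate for the extinction theorem
#'
#' Numerically certifies, on a uniform grid of `(0, 1)` completed by the
#' limit `eta * N0 * alpha * f'(1)` at `s -> 1`, that
#' `g(s) = (1 - (1 - alpha + alpha f(s))^(eta N0)) / (1 - s)` is strictly
#' increasing.  A finite grid check is a numerical certificate, not a
#' symbolic proof.
#'
#' @param state an [env_state].
#' @param N0 initial size.
#' @param eta override for the dominating ratio (default: from
#'   [state_summaries()]).
#' @param grid_size number of grid points (`>= 3`, default 1e4).
#' @return list with `increasing` (logical), `min_slope`, `g_at_0`,
#'   `g_at_1` (the limit).
#' @export
check_monotonicity <- function(state, N0, eta = NULL, grid_size = 1e4) {
  stopifnot(grid_size >= 3)
  sm <- state_summaries(state)
  if (is.null(eta)) eta <- sm$eta
  if (!is.finite(eta)) stop("check_monotonicity: eta must be finite")
  e <- eta * N0
  s <- seq(0, 1, length.out = grid_size + 1L)
  s <- s[-length(s)]
  g <- (1 - thinned_pgf(state, s)^e) / (1 - s)
  g1 <- e * sm$alpha * sm$m  # limit s -> 1 by l'Hopital
  gv <- c(g, g1)
  slopes <- diff(gv)
  list(increasing = all(slopes > 1e-12), min_slope = min(slopes),
       g_at_0 = gv[1L], g_at_1 = g1)
}

#' Lower-bound iteration for the quenched extinction probability
#'
#' Iterates the nested generating-function bound: with per-generation maps
#' `h_j(s) = (1 - alpha_j + alpha_j f_j(s))^(eta_j)` applied innermost-first
#' at `s = 0` and the outermost exponent `eta_0 * N0`, the iterates `mu_n`
#' are nondecreasing in `[0, 1]` and their limit is a lower bound for the
#' quenched extinction probability `q(xi)`.
#'
#' The exponents may be non-integral; real powers are used.  A constant
#' environment sequence is detected and iterated forward in O(n); a varying
#' sequence is recomputed backward for each prefix.  Critical cases converge
#' slowly and are reported unconverged rather than extrapolated.
#'
#' @param law an [env_law].
#' @param env_sequence integer state indices, innermost generations last.
#' @param N0 initial size.
#' @param n maximum number of iterates (`<= length(env_sequence)`).
#' @param eta_override optional numeric vector of per-state dominating
#'   ratios replacing the minimal deterministic choice.
#' @param tol fixed-point stopping tolerance (default 1e-12).
#' @return an object of class `mu_iteration` with fields `mu` (the computed
#'   iterates), `converged`, `limit_estimate`.
#' @export
iterate_mu <- function(law, env_sequence, N0, n = length(env_sequence),
                       eta_override = NULL, tol = 1e-12) {
  stopifnot(inherits(law, "env_law"), N0 >= 1, n >= 1,
            n <= length(env_sequence))
  sms <- law_summaries(law)
  eta <- if (is.null(eta_override))
    vapply(sms, `[[`, numeric(1), "eta") else eta_override
  if (any(!is.finite(eta[unique(env_sequence[seq_len(n)])])))
    stop("iterate_mu: eta must be finite for all states in the sequence")
  alpha <- vapply(law$states, `[[`, numeric(1), "alpha")
  fval <- function(i, s) offspring_pgf(law$states[[i]], s)
  hmap <- function(i, s, expo) (1 - alpha[i] + alpha[i] * fval(i, s))^expo
  idx <- env_sequence[seq_len(n)]
  constant <- length(unique(idx)) == 1L
  mu <- numeric(0)
  if (constant) {
    i <- idx[1L]
    t <- 0
    for (k in seq_len(n)) {
      base <- 1 - alpha[i] + alpha[i] * fval(i, t)
      mu_k <- base^(eta[i] * N0)
      t <- base^eta[i]
      mu <- c(mu, mu_k)
      if (k >= 2 && abs(mu[k] - mu[k - 1L]) < tol) break
    }
  } else {
    mu_prefix <- function(k) { # backward composition over xi_0..xi_{k-1}
      t <- 0
      if (k >= 2) for (j in k:2) t <- hmap(idx[j], t, eta[idx[j]])
      hmap(idx[1L], t, eta[idx[1L]] * N0)
    }
    for (k in seq_len(n)) {
      mu <- c(mu, mu_prefix(k))
      if (k >= 2 && abs(mu[k] - mu[k - 1L]) < tol) break
    }
  }
  kdone <- length(mu)
  converged <- kdone >= 2 && abs(mu[kdone] - mu[kdone - 1L]) < tol
  structure(list(mu = mu, converged = converged,
                 limit_estimate = mu[kdone], n_iter = kdone,
                 env_sequence = idx, eta = eta, N0 = N0, tol = tol),
            class = "mu_iteration")
}

#' @export
print.mu_iteration <- function(x, ...) {
  cat("<mu_iteration>", x$n_iter, "iterate(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat(sprintf("  limit estimate (lower bound for q): %.10g\n",
              x$limit_estimate))
  invisible(x)
}

#' Monte Carlo extinction probability
#'
#' Frequency of extinction by generation `n_max` over independent
#' replicates, with a Wilson score interval.  A finite horizon makes this an
#' under-estimate of the true extinction probability.
#'
#' @param law an [env_law].
#' @param N0 initial size.
#' @param n_max horizon.
#' @param reps number of replicates (`>= 100`).
#' @param seed optional integer seed.
#' @param conf confidence level for the Wilson interval.
#' @return list with `estimate`, `ci` (Wilson interval), `reps`, `n_max`,
#'   `n_extinct`, `seed`.
#' @export
mc_extinction_probability <- function(law, N0, n_max, reps, seed = NULL,
                                      conf = 0.95) {
  stopifnot(reps >= 100)
  ens <- run_ensemble(law, N0, n_max, reps, seed, mode = "compound")
  x <- sum(!is.na(ens$extinct_at))
  ci <- wilson_ci(x, reps, conf)
  list(estimate = ci[["estimate"]], ci = ci, reps = reps, n_max = n_max,
       n_extinct = x, seed = seed)
}
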