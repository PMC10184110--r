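#' Environment states and environment laws
#'
#' An `env_state` bundles the per-environment primitives of the process: the
#' offspring pmf `P_r(theta)`, the infection-survival probability
#' `alpha(theta)` (an individual escapes or recovers from infection with this
#' probability, and only then reproduces), and the control kernel giving the
#' law of the participation count `phi(k)`.  An `env_law` is a finite i.i.d.
#' environment distribution over such states.
#'
#' @param label short unique name for the state.
#' @param offspring numeric vector, `offspring[r + 1]` = probability of `r`
#'   offspring; finite support, sums to 1 (drift above 1e-9 is an error).
#' @param alpha survival probability in `(0, 1]`; `alpha = 1` is admitted as
#'   the classical no-infection reduction and flagged by
#'   [validate_assumptions()].
#' @param control a [control_kernels] object (default identity).
#' @return `env_state()` returns an object of class `env_state`.
#' @export
env_state <- function(label, offspring, alpha, control = kernel_identity()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  offspring <- check_prob_vec(offspring, sprintf("offspring pmf of %s", label))
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1)
  stopifnot(inherits(control, "control_kernel"))
  structure(list(label = label, offspring = offspring, alpha = alpha,
                 control = control),
            class = "env_state")
}

#' @rdname env_state
#' @param states list of `env_state` objects with unique labels.
#' @param probs sampling probabilities of the states (i.i.d. across
#'   generations); must sum to 1.
#' @return `env_law()` returns an object of class `env_law`.
#' @export
env_law <- function(states, probs = NULL) {
  if (inherits(states, "env_state")) states <- list(states)
  stopifnot(length(states) >= 1L,
            all(vapply(states, inherits, logical(1), "env_state")))
  labels <- vapply(states, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("env_law: state labels must be unique")
  if (is.null(probs)) probs <- rep(1 / length(states), length(states))
  probs <- check_prob_vec(probs, "environment probabilities")
  if (length(probs) != length(states))
    stop("env_law: probs and states lengths differ")
  structure(list(states = states, probs = probs, labels = labels),
            class = "env_law")
}

#' @export
print.env_state <- function(x, ...) {
  cat("<env_state>", x$label, "\n")
  supp <- which(x$offspring > 0) - 1L
  cat("  offspring:", paste(sprintf("P(%d)=%g", supp, x$offspring[supp + 1L]),
                            collapse = ", "), "\n")
  cat("  alpha:", x$alpha, " control:", x$control$kind, "\n")
  invisible(x)
}

#' @export
print.env_law <- function(x, ...) {
  cat("<env_law> with", length(x$states), "state(s)\n")
  for (i in seq_along(x$states))
    cat(sprintf("  [%d] %-10s prob %.4g  (alpha %.4g, control %s)\n",
                i, x$labels[i], x$probs[i], x$states[[i]]$alpha,
                x$states[[i]]$control$kind))
  invisible(x)
}

#' Offspring probability generating function
#'
#' `f_theta(s) = sum_r P_r(theta) s^r` for `s` in `[0, 1]`.
#'
#' @param state an [env_state].
#' @param s numeric vector in `[0, 1]`.
#' @return pgf values; nondecreasing and convex in `s` with `f(1) = 1`.
#' @export
offspring_pgf <- function(state, s) {
  stopifnot(inherits(state, "env_state"))
  if (any(s < 0 | s > 1)) stop("offspring_pgf: s must lie in [0, 1]")
  r <- seq_along(state$offspring) - 1
  vapply(s, function(si) sum(state$offspring * si^r), numeric(1))
}

#' Thinned offspring pgf
#'
#' The pgf of the product `X * I` of the offspring count and the Bernoulli
#' survival indicator: `1 - alpha + alpha * f_theta(s)`.
#'
#' @inheritParams offspring_pgf
#' @return pgf values of the infection-thinned offspring law.
#' @export
thinned_pgf <- function(state, s) {
  1 - state$alpha + state$alpha * offspring_pgf(state, s)
}

#' Scalar summaries of one environment state
#'
#' Computes the moment and participation-rate summaries every limit theorem
#' uses: offspring mean `m` and second moment `m2`, the thinned-offspring
#' variance `Var(X I) = m2 * alpha - (m * alpha)^2`, the participation rate
#' `eps(k) = E[phi(k)] / k` with its supremum `eps_sup` and infimum
#' `eps_inf` over `k >= 1`, the control variance `delta2(k) = Var(phi(k))`
#' with supremum `delta2_sup` (possibly `Inf`), and the minimal deterministic
#' dominating ratio `eta = sup_k max-support(phi(k)) / k` (possibly `Inf`).
#'
#' Closed forms are used for the built-in kernel families; tabulated kernels
#' are scanned numerically over `k <= K_analysis` and the results flagged as
#' numeric.
#'
#' @param state an [env_state].
#' @param K_analysis horizon for numeric scans over `k` (default 512).
#' @return an object of class `state_summaries`; `eps_of_k` and
#'   `delta2_of_k` are vectorised functions of `k >= 1`.
#' @export
state_summaries <- function(state, K_analysis = 512L) {
  stopifnot(inherits(state, "env_state"))
  r <- seq_along(state$offspring) - 1
  m <- sum(r * state$offspring)
  m2 <- sum(r^2 * state$offspring)
  a <- state$alpha
  ker <- state$control
  eps_of_k <- function(k) kernel_eps_k(ker, k)
  delta2_of_k <- function(k) kernel_delta2_k(ker, k)
  numeric_flag <- FALSE
  if (ker$kind == "identity") {
    eps_sup <- 1; eps_inf <- 1; d2_sup <- 0; eta <- 1
  } else if (ker$kind == "binomial_thinning") {
    eps_sup <- ker$p; eps_inf <- ker$p
    d2_sup <- if (ker$p < 1) Inf else 0
    eta <- 1
  } else if (ker$kind == "random_emigration") {
    # eps(k) = 1 - E[min(E, k)]/k is nondecreasing: inf at k = 1, sup -> 1
    eps_inf <- kernel_eps_k(ker, 1L)
    eps_sup <- 1
    emax <- length(ker$removals) - 1L
    kk <- seq_len(max(emax, 1L))
    d2_sup <- max(kernel_delta2_k(ker, kk))
    eta <- 1
  } else if (ker$kind == "random_immigration") {
    # eps(k) = 1 + E[M]/k is nonincreasing: sup at k = 1, inf -> 1
    eps_sup <- kernel_eps_k(ker, 1L)
    eps_inf <- 1
    d2_sup <- kernel_delta2_k(ker, 1L)
    eta <- 1 + (max(which(ker$additions > 0)) - 1L)
  } else { # tabulated: numeric scan over k <= K_analysis
    K <- as.integer(K_analysis)
    if (length(ker$tab) < K)
      stop(sprintf(
        "tabulated kernel lacks pmfs for k = %d..%d (K_analysis = %d)",
        length(ker$tab) + 1L, K, K))
    kk <- seq_len(K)
    ev <- kernel_eps_k(ker, kk)
    eps_sup <- max(ev); eps_inf <- min(ev)
    d2_sup <- max(kernel_delta2_k(ker, kk))
    eta <- max(vapply(kk, function(k) kernel_max_support(ker, k) / k,
                      numeric(1)))
    numeric_flag <- TRUE
  }
  probe <- seq_len(min(K_analysis, 256L))
  eps_probe <- eps_of_k(probe)
  structure(list(
    label = state$label,
    m = m, m2 = m2, alpha = a,
    var_xi_product = m2 * a - (m * a)^2,
    eps_of_k = eps_of_k, delta2_of_k = delta2_of_k,
    eps_sup = eps_sup, eps_inf = eps_inf,
    delta2_sup = d2_sup, eta = eta,
    eps_nondecreasing = all(diff(eps_probe) >= -1e-12),
    numeric_over_K = numeric_flag, K_analysis = as.integer(K_analysis)),
    class = "state_summaries")
}

#' @export
print.state_summaries <- function(x, ...) {
  cat("<state_summaries>", x$label, "\n")
  cat(sprintf("  m = %.6g, m2 = %.6g, alpha = %.6g, Var(XI) = %.6g\n",
              x$m, x$m2, x$alpha, x$var_xi_product))
  cat(sprintf("  eps: inf %.6g, sup %.6g (%s); delta2_sup %.6g; eta %.6g\n",
              x$eps_inf, x$eps_sup,
              if (x$eps_nondecreasing) "nondecreasing in k" else "not monotone",
              x$delta2_sup, x$eta))
  if (x$numeric_over_K)
    cat("  (numeric over k <=", x$K_analysis, ")\n")
  invisible(x)
}

#' Check the standing non-triviality assumptions
#'
#' For each state, checks (A1) `0 < P_0 + P_1 < 1` and
#' `0 < Q(theta; k, k) < 1` for `k >= 1`, and (A2) `0 < alpha < 1`.
#' Violations of the classical reduction kind (identity control, `alpha = 1`)
#' are reported as warnings, never errors, because those reductions are the
#' test oracles linking the model to classical branching processes.
#'
#' @param law an [env_law].
#' @param probe_k sizes at which `Q(k, k)` is probed (default `1:20`).
#' @return data frame with one row per state and check, columns
#'   `state`, `check`, `status` (`"pass"`/`"warn"`), `note`.
#' @export
validate_assumptions <- function(law, probe_k = 1:20) {
  stopifnot(inherits(law, "env_law"))
  rows <- list()
  add <- function(state, check, status, note)
    rows[[length(rows) + 1L]] <<- data.frame(
      state = state, check = check, status = status, note = note,
      stringsAsFactors = FALSE)
  for (st in law$states) {
    p01 <- sum(st$offspring[seq_len(min(2L, length(st$offspring)))])
    if (p01 > 0 && p01 < 1) add(st$label, "A1_offspring", "pass", "")
    else add(st$label, "A1_offspring", "warn",
             sprintf("P0 + P1 = %g not in (0,1): degenerate growth", p01))
    qkk <- vapply(probe_k, function(k) kernel_pmf(st$control, k)[k + 1L],
                  numeric(1))
    if (all(qkk > 0 & qkk < 1)) add(st$label, "A1_control", "pass", "")
    else add(st$label, "A1_control", "warn",
             "Q(k,k) hits {0,1}: reduction case (e.g. identity control)")
    if (st$alpha < 1) add(st$label, "A2_alpha", "pass", "")
    else add(st$label, "A2_alpha", "warn",
             "alpha = 1: reduction to the infection-free controlled model")
  }
  do.call(rbind, rows)
}

#' Sample an i.i.d. environment sequence
#'
#' @param law an [env_law].
#' @param n sequence length (`>= 0`).
#' @param seed optional integer seed; recorded as attribute `"seed"`.
#' @return integer vector of state indices (1-based into `law$states`).
#' @export
sample_environment_sequence <- function(law, n, seed = NULL) {
  stopifnot(inherits(law, "env_law"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- if (n == 0) integer(0)
         else sample.int(length(law$states), n, replace = TRUE,
                         prob = law$probs)
  attr(idx, "seed") <- seed
  idx
}

# cached summaries for all states of a law
law_summaries <- function(law, K_analysis = 512L) {
  lapply(law$states, state_summaries, K_analysis = K_analysis)
}
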