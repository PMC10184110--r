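#' Normalizing factor paths
#'
#' The supremum and infimum normalizers along a fixed environment sequence:
#' `S_n = N0 * prod_{k<n} m alpha eps (xi_k)` and `I_n` likewise with
#' `eps_1`.  Both are accumulated in log space.
#'
#' @param law an [env_law].
#' @param env_sequence integer state indices for generations `0..n-1`.
#' @param N0 initial size.
#' @return list of class `normalizer_path` with `log_S`, `log_I` (length
#'   `n + 1`, starting at `log N0`) and `env_indices`.
#' @export
normalizers <- function(law, env_sequence, N0) {
  stopifnot(inherits(law, "env_law"), N0 >= 1)
  sms <- law_summaries(law)
  eps_inf <- vapply(sms, `[[`, numeric(1), "eps_inf")
  if (any(eps_inf[unique(env_sequence)] == 0))
    stop("normalizers: eps_1 = 0 for some state; I_n identically 0 and ",
         "W-bar undefined")
  lg_sup <- vapply(sms, function(s) log(s$m * s$alpha * s$eps_sup), numeric(1))
  lg_inf <- vapply(sms, function(s) log(s$m * s$alpha * s$eps_inf), numeric(1))
  structure(list(
    log_S = log(N0) + c(0, cumsum(lg_sup[env_sequence])),
    log_I = log(N0) + c(0, cumsum(lg_inf[env_sequence])),
    env_indices = env_sequence, N0 = N0),
    class = "normalizer_path")
}

#' Normalized processes along a trajectory
#'
#' `W-hat_n = Z_n / S_n` and `W-bar_n = Z_n / I_n`, computed by log-space
#' subtraction; exact zeros after extinction propagate as exact zeros.
#'
#' @param law an [env_law].
#' @param trajectory a `cbre_trajectory` from [simulate_path()].
#' @return list of class `normalized_path` with `W_hat`, `W_bar` and the
#'   underlying `normalizer_path`.
#' @export
normalized_path <- function(law, trajectory) {
  stopifnot(inherits(trajectory, "cbre_trajectory"))
  nz <- normalizers(law, trajectory$env_indices, trajectory$N0)
  Z <- trajectory$Z
  W_hat <- ifelse(Z == 0, 0, exp(log(Z) - nz$log_S))
  W_bar <- ifelse(Z == 0, 0, exp(log(Z) - nz$log_I))
  structure(list(W_hat = W_hat, W_bar = W_bar, normalizers = nz),
            class = "normalized_path")
}

#' One-step supermartingale ratio of the sup-normalized process
#'
#' `E(W-hat_{n+1} | F_n) / W-hat_n = eps(theta, i) / eps(theta) <= 1`.  The
#' closed form is cross-checked against the mean of the exact one-step law.
#'
#' @param state an [env_state].
#' @param i current size (`>= 1`; `i = 0` is extinct and returns 1 with a
#'   flag).
#' @param check cross-check against [one_step_pmf()] (default TRUE).
#' @return the ratio, with attribute `"extinct"` when `i = 0`.
#' @export
supermartingale_ratio <- function(state, i, check = TRUE) {
  sm <- state_summaries(state)
  if (i == 0) return(structure(1, extinct = TRUE))
  ratio <- sm$eps_of_k(i) / sm$eps_sup
  if (check) {
    mu <- pmf_mean(one_step_pmf(state, i, J_max = ceiling(64 + 8 * i)))
    ref <- mu / (i * sm$m * sm$alpha * sm$eps_sup)
    if (abs(ratio - ref) > 1e-9)
      stop(sprintf("supermartingale ratio mismatch: %.12g vs kernel %.12g",
                   ratio, ref))
  }
  ratio
}

#' One-step submartingale ratio of the inf-normalized process
#'
#' `E(W-bar_{n+1} | F_n) / W-bar_n = eps(theta, i) / eps_1(theta) >= 1`.
#'
#' @inheritParams supermartingale_ratio
#' @return the ratio (`>= 1`).
#' @export
submartingale_ratio <- function(state, i, check = TRUE) {
  sm <- state_summaries(state)
  if (sm$eps_inf == 0) stop("submartingale_ratio: eps_1 = 0")
  if (i == 0) return(structure(1, extinct = TRUE))
  ratio <- sm$eps_of_k(i) / sm$eps_inf
  if (check) {
    mu <- pmf_mean(one_step_pmf(state, i, J_max = ceiling(64 + 8 * i)))
    ref <- mu / (i * sm$m * sm$alpha * sm$eps_inf)
    if (abs(ratio - ref) > 1e-9)
      stop("submartingale ratio disagrees with the exact one-step law")
  }
  ratio
}

#' Monte Carlo check of the mean identity for the sup-normalized process
#'
#' The exact identity `E(W-hat_{n+1}) = 1 - sum_{k<=n} E(W-hat_k *
#' eps_{Z_k}(xi_k) / eps(xi_k))` is estimated by simulation: the per-path
#' statistic `W-hat_{n+1} + sum_k W-hat_k (eps - eps(., Z_k))/eps` has mean
#' exactly 1.
#'
#' @param law an [env_law].
#' @param N0 initial size.
#' @param n identity horizon (the sum runs over `k = 0..n`).
#' @param reps replicates.
#' @param seed optional integer seed.
#' @return list with `estimate`, `se`, `deviation` (estimate - 1),
#'   `z` (deviation / se), and the components.
#' @export
mean_identity_check <- function(law, N0, n, reps, seed = NULL) {
  # supercritical paths can pass 1e9 well within n = 20 generations; the
  # aggregated sampler is size-free, so a loose cap keeps the identity exact
  ens <- run_ensemble(law, N0, n + 1L, reps, seed, mode = "compound",
                      cap = 1e15)
  stat <- ens$final_Z
  What_final <- ifelse(stat == 0, 0, exp(log(stat) - ens$final_logS))
  per_path <- What_final + ens$identity_csum
  est <- mean(per_path)
  se <- stats::sd(per_path) / sqrt(reps)
  list(estimate = est, se = se, deviation = est - 1,
       z = (est - 1) / se,
       mean_What = mean(What_final),
       mean_correction = mean(ens$identity_csum),
       reps = reps, n = n, seed = seed)
}

# exact annealed moments over the finite i.i.d. law:
# E[ S_i^{-p} g(xi_i) ] = N0^{-p} * E[(m a eps)^{-p}]^i * E[g]
law_expect <- function(law, f) {
  sum(law$probs * vapply(seq_along(law$states), f, numeric(1)))
}

#' Second-moment bound for the sup-normalized process
#'
#' The recursive bound `E(W-hat_{n+1}^2) <= 1 +
#' sum_{i<=n} E[m2 / (S_i alpha eps m^2)] + sum_{i<=n} E[delta2 /
#' (S_i^2 eps^2)]`, computed exactly over the finite environment law using
#' the independence of `S_i` and `xi_i`.
#'
#' @param law an [env_law].
#' @param N0 initial size.
#' @param n horizon (the bound applies to `E(W-hat_{n+1}^2)`).
#' @return list with `bound`, per-index `terms_m2`, `terms_delta2`, and
#'   `finite` (FALSE when `delta2_sup = Inf` for a reachable state, in which
#'   case the bound does not apply).
#' @export
l2_bound <- function(law, N0, n) {
  sms <- law_summaries(law)
  d2 <- vapply(sms, `[[`, numeric(1), "delta2_sup")
  if (any(!is.finite(d2) & law$probs > 0))
    return(list(bound = Inf, finite = FALSE,
                reason = "delta2_sup = Inf; second-moment bound inapplicable"))
  c1 <- law_expect(law, function(i) {
    s <- sms[[i]]; 1 / (s$m * s$alpha * s$eps_sup) })
  c2 <- law_expect(law, function(i) {
    s <- sms[[i]]; 1 / (s$m * s$alpha * s$eps_sup)^2 })
  g1 <- law_expect(law, function(i) {
    s <- sms[[i]]; s$m2 / (s$m^2 * s$alpha * s$eps_sup) })
  g2 <- law_expect(law, function(i) {
    s <- sms[[i]]; s$delta2_sup / s$eps_sup^2 })
  i <- 0:n
  terms_m2 <- (1 / N0) * c1^i * g1
  terms_d2 <- (1 / N0^2) * c2^i * g2
  list(bound = 1 + sum(terms_m2) + sum(terms_d2),
       terms_m2 = terms_m2, terms_delta2 = terms_d2, finite = TRUE)
}

# ratio-test verdict on a nonnegative term sequence
series_verdict <- function(terms, window = 10L) {
  terms <- terms[is.finite(terms)]
  if (!length(terms)) return("diverging")
  nz <- terms[terms > 0]
  if (length(nz) < 2L) return("converged-to-finite")
  k <- min(window, length(nz) - 1L)
  r <- utils::tail(nz, k + 1L)
  ratios <- r[-1L] / r[-length(r)]
  if (max(ratios) < 0.999) "converged-to-finite"
  else if (min(ratios) > 1.001) "diverging"
  # terms bounded away from zero with ratio ~ 1: divergence is certain
  else if (min(r) > 1e-8 && min(ratios) > 0.999) "diverging"
  else "inconclusive"
}

new_condition_report <- function(id, terms, partial, verdict, note = "") {
  structure(list(id = id, terms = terms, partial = partial,
                 verdict = verdict, note = note),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("<condition_report> %-18s %s", x$id, x$verdict))
  if (length(x$partial))
    cat(sprintf("  (last partial %.6g)", utils::tail(x$partial, 1L)))
  cat("\n")
  if (nzchar(x$note)) cat("  ", x$note, "\n")
  invisible(x)
}

#' Hypothesis series of the convergence theorems
#'
#' Computes partial sums/products of the sufficient conditions for the
#' normalized processes to converge: the two second-moment series (L2
#' boundedness / L1 convergence of the sup-normalized process), the three
#' square-rooted series behind L2 convergence, and the expected product
#' `E[prod eps/eps_1]` behind the submartingale limit.  Expectations over
#' the environment are computed exactly for the finite i.i.d. law; the
#' verdict is a ratio test over the last computed terms and is a numerical
#' certificate, not a proof.
#'
#' @param law an [env_law].
#' @param N0 initial size.
#' @param n_terms number of series terms (default 60).
#' @return list of [print.condition_report()] objects, named
#'   `l2_m2`, `l2_delta2`, `l2conv_eps`, `l2conv_m2`, `l2conv_delta2`,
#'   `submg_product`.
#' @export
series_conditions <- function(law, N0, n_terms = 60L) {
  sms <- law_summaries(law)
  lb <- l2_bound(law, N0, n_terms)
  out <- list()
  if (lb$finite) {
    out$l2_m2 <- new_condition_report(
      "l2_m2", lb$terms_m2, cumsum(lb$terms_m2),
      series_verdict(lb$terms_m2))
    out$l2_delta2 <- new_condition_report(
      "l2_delta2", lb$terms_delta2, cumsum(lb$terms_delta2),
      series_verdict(lb$terms_delta2))
    s_m2 <- sqrt(cumsum(lb$terms_m2))
    s_d2 <- sqrt(cumsum(lb$terms_delta2))
    out$l2conv_m2 <- new_condition_report(
      "l2conv_m2", s_m2, cumsum(s_m2), series_verdict(s_m2))
    out$l2conv_delta2 <- new_condition_report(
      "l2conv_delta2", s_d2, cumsum(s_d2), series_verdict(s_d2))
  } else {
    out$l2_m2 <- new_condition_report("l2_m2", numeric(0), numeric(0),
                                      "diverging", lb$reason)
    out$l2_delta2 <- new_condition_report("l2_delta2", numeric(0), numeric(0),
                                          "diverging", lb$reason)
    out$l2conv_m2 <- new_condition_report("l2conv_m2", numeric(0), numeric(0),
                                          "diverging", lb$reason)
    out$l2conv_delta2 <- new_condition_report("l2conv_delta2", numeric(0),
                                              numeric(0), "diverging",
                                              lb$reason)
  }
  gap <- sqrt(law_expect(law, function(i) {
    s <- sms[[i]]; ((s$eps_sup - s$eps_inf) / s$eps_sup)^2 }))
  gap_terms <- rep(gap, n_terms)
  out$l2conv_eps <- new_condition_report(
    "l2conv_eps", gap_terms, cumsum(gap_terms),
    if (gap == 0) "converged-to-finite" else "diverging",
    "constant per-index term: finite iff eps = eps_1 a.s.")
  if (any(vapply(sms, `[[`, numeric(1), "eps_inf") == 0)) {
    out$submg_product <- new_condition_report(
      "submg_product", numeric(0), numeric(0), "diverging",
      "eps_1 = 0: inf-normalized process undefined")
  } else {
    rho <- law_expect(law, function(i) {
      s <- sms[[i]]; s$eps_sup / s$eps_inf })
    prods <- rho^(seq_len(n_terms))
    out$submg_product <- new_condition_report(
      "submg_product", prods, prods,
      if (rho <= 1 + 1e-12) "converged-to-finite" else "diverging",
      sprintf("E[eps/eps_1] = %.6g per factor", rho))
  }
  out
}

#' Default envelope of a rate sequence over k >= 1
#'
#' Builds the envelope the nondegeneracy and L1 conditions need from a
#' sequence `a_1..a_K`: the function `x * envelope(x)` is the lower convex
#' hull (for a nondecreasing sequence, `require = "convex"`) or the upper
#' concave hull (for a nonincreasing sequence, `require = "concave"`) of the
#' points `(j, j * a_j)`, extended linearly beyond `K` with the last hull
#' slope and set to the constant `a_1` on `(0, 1]`.  This construction makes
#' `x * envelope(x)` convex (resp. concave) with the required bounding
#' directions at the integers; both properties are still verified
#' numerically on a grid and reported in `shape_ok`.
#'
#' @param a_k numeric sequence `a_1..a_K` (the participation rates
#'   `eps(theta, k)` or the deviation statistics `r_k`).
#' @param require `"convex"` or `"concave"` for `x * envelope(x)`.
#' @return list with `fn` (vectorised envelope function), `shape_ok`, `K`.
#' @export
envelope_interp <- function(a_k, require = c("convex", "concave")) {
  require <- match.arg(require)
  K <- length(a_k)
  stopifnot(K >= 2L)
  px <- as.numeric(seq_len(K))
  py <- px * a_k
  # monotone-chain hull of (j, j * a_j): lower for convex, upper for concave
  sgn <- if (require == "convex") 1 else -1
  hx <- numeric(0); hy <- numeric(0)
  for (i in seq_len(K)) {
    while (length(hx) >= 2L) {
      n <- length(hx)
      cross <- (hx[n] - hx[n - 1L]) * (py[i] - hy[n - 1L]) -
               (hy[n] - hy[n - 1L]) * (px[i] - hx[n - 1L])
      if (sgn * cross <= 0) { hx <- hx[-n]; hy <- hy[-n] } else break
    }
    hx <- c(hx, px[i]); hy <- c(hy, py[i])
  }
  slope_last <- if (length(hx) >= 2L)
    (hy[length(hy)] - hy[length(hy) - 1L]) /
    (hx[length(hx)] - hx[length(hx) - 1L]) else a_k[1L]
  fn <- function(x) {
    y <- numeric(length(x))
    y[x <= 1] <- a_k[1L]
    hi <- x >= K
    y[hi] <- (hy[length(hy)] + slope_last * (x[hi] - K)) / x[hi]
    mid <- x > 1 & x < K
    if (any(mid)) {
      yh <- stats::approx(hx, hy, xout = x[mid])$y
      y[mid] <- yh / x[mid]
    }
    y
  }
  xs <- seq(0.05, K + 5, by = 0.05)
  star <- xs * fn(xs)
  d2 <- diff(diff(star))
  bound_ok <- if (require == "convex") all(fn(px) <= a_k + 1e-9)
              else all(fn(px) >= a_k - 1e-9)
  shape_ok <- bound_ok &&
    if (require == "convex") all(d2 >= -1e-7) else all(d2 <= 1e-7)
  list(fn = fn, shape_ok = shape_ok, K = K)
}

#' Nondegeneracy condition for the sup-normalized limit
#'
#' When `eps(theta, k)` is nondecreasing in `k` for every state, evaluates
#' partial products of `E[prod_i envelope_{xi_i}(N0 prod_{j<i} m alpha
#' eps_1) / eps(xi_i)]`; if they stabilize above 0 the limit of the
#' sup-normalized process is nondegenerate at zero with positive
#' probability.  Exact for a single-state law; Monte Carlo over environment
#' sequences otherwise.
#'
#' @param law an [env_law].
#' @param N0 initial size.
#' @param n_terms number of product factors (default 80).
#' @param envelope optional list of per-state envelope functions replacing
#'   the default interpolation of `eps(theta, k)`.
#' @param K_env interpolation horizon for the default envelopes.
#' @param mc_sequences Monte Carlo environment sequences for multi-state
#'   laws (default 200).
#' @param seed optional integer seed for the Monte Carlo branch.
#' @return a `condition_report` whose `partial` holds the partial products;
#'   verdict `"positive"` when they stabilize above 0, `"inconclusive"`
#'   when they decay toward 0, `"theorem_inapplicable"` when a state's
#'   `eps(theta, .)` is not nondecreasing or an envelope fails its shape
#'   check.
#' @export
nondegeneracy_condition <- function(law, N0, n_terms = 80L, envelope = NULL,
                                    K_env = 256L, mc_sequences = 200L,
                                    seed = NULL) {
  sms <- law_summaries(law)
  if (!all(vapply(sms, `[[`, logical(1), "eps_nondecreasing")))
    return(new_condition_report(
      "nondegeneracy", numeric(0), numeric(0), "theorem_inapplicable",
      "eps(theta, k) not nondecreasing in k for some state"))
  if (is.null(envelope)) {
    envelope <- lapply(sms, function(s)
      envelope_interp(s$eps_of_k(seq_len(K_env)), "convex"))
    if (!all(vapply(envelope, `[[`, logical(1), "shape_ok")))
      return(new_condition_report(
        "nondegeneracy", numeric(0), numeric(0), "theorem_inapplicable",
        "default envelope failed the convexity check of x * envelope(x)"))
    envelope <- lapply(envelope, `[[`, "fn")
  }
  lg_inf <- vapply(sms, function(s) log(s$m * s$alpha * s$eps_inf), numeric(1))
  eps_sup <- vapply(sms, `[[`, numeric(1), "eps_sup")
  factor_path <- function(idx) {
    args <- N0 * exp(c(0, cumsum(lg_inf[idx]))[seq_along(idx)])
    vapply(seq_along(idx), function(i)
      envelope[[idx[i]]](args[i]) / eps_sup[idx[i]], numeric(1))
  }
  if (length(law$states) == 1L) {
    partial <- cumprod(factor_path(rep(1L, n_terms)))
  } else {
    if (!is.null(seed)) set.seed(seed)
    mats <- replicate(mc_sequences, {
      idx <- sample.int(length(law$states), n_terms, replace = TRUE,
                        prob = law$probs)
      cumprod(factor_path(idx))
    })
    partial <- rowMeans(mats)
  }
  last <- utils::tail(partial, 1L)
  tail10 <- utils::tail(partial, 10L)
  stable <- max(tail10) - min(tail10) < 1e-3 * max(last, 1e-12) + 1e-9
  verdict <- if (last > 1e-6 && stable) "positive" else "inconclusive"
  new_condition_report("nondegeneracy", NULL, partial, verdict,
                       sprintf("limit of partial products ~ %.6g", last))
}

#' Mean absolute deviation statistic of the inf-normalized increments
#'
#' `r_k(theta) = k^{-1} E| Z' - k eps_1 m alpha |` computed exactly from the
#' one-step law at size `k`, together with a nonincreasingness probe over a
#' `k` grid (the L1-convergence condition requires `r_k` nonincreasing).
#'
#' @param state an [env_state].
#' @param k size (`>= 1`).
#' @param J_max truncation cap (default: enough for exact support, else
#'   4096).
#' @return the value of `r_k`.
#' @export
r_statistic <- function(state, k, J_max = NULL) {
  stopifnot(k >= 1)
  sm <- state_summaries(state)
  if (is.null(J_max)) {
    rmax <- length(state$offspring) - 1L
    J_max <- max(64L, 2L * rmax * (kernel_max_support(state$control, k) + 1L))
  }
  pmf <- one_step_pmf(state, k, J_max)
  if (pmf$tail_mass > 1e-6)
    stop("r_statistic: truncation tail above 1e-6; raise J_max")
  centre <- k * sm$eps_inf * sm$m * sm$alpha
  j <- seq_along(pmf$probs) - 1
  sum(abs(j - centre) * pmf$probs) / k
}

#' Realized partial sums of the survival-series diagnostic
#'
#' Along one trajectory, the per-generation partial sums of
#' `sum_k (1 - eps(xi_k, Z_k) / eps(xi_k))`; on the event that the
#' sup-normalized limit is positive this series is finite almost surely.
#' Terms after extinction are dropped and flagged.
#'
#' @param law an [env_law].
#' @param trajectory a `cbre_trajectory`.
#' @return list with `partial_sums`, `terms`, `truncated_at_extinction`.
#' @export
surviving_path_condition <- function(law, trajectory) {
  sms <- law_summaries(law)
  n <- length(trajectory$env_indices)
  terms <- numeric(0)
  for (k in seq_len(n)) {
    Zk <- trajectory$Z[k]
    if (Zk == 0) break
    s <- sms[[trajectory$env_indices[k]]]
    terms <- c(terms, 1 - s$eps_of_k(Zk) / s$eps_sup)
  }
  list(partial_sums = cumsum(terms), terms = terms,
       truncated_at_extinction = !is.na(trajectory$extinct_at))
}

#' L1-convergence condition for the inf-normalized process
#'
#' Evaluates the series `sum_n E[prod_{k<n} eps/eps_1 *
#' psi_{xi_n}(N0 prod_{i<n} m alpha eps_1) / (m alpha eps_1)(xi_n)]` with a
#' nonincreasing envelope `psi` of the `r_k` statistic (default: the
#' interpolation built by [envelope_interp()] from exact `r_k` values).
#' Exact for single-state laws, Monte Carlo otherwise.
#'
#' @inheritParams nondegeneracy_condition
#' @param psi optional list of per-state envelope functions.
#' @param K_env interpolation horizon for the default `psi` (exact `r_k` is
#'   computed for `k = 1..K_env`, so keep it moderate).
#' @return a `condition_report` for the series.
#' @export
l1_condition <- function(law, N0, n_terms = 40L, psi = NULL, K_env = 32L,
                         mc_sequences = 200L, seed = NULL) {
  sms <- law_summaries(law)
  if (any(vapply(sms, `[[`, numeric(1), "eps_inf") == 0))
    return(new_condition_report("l1_series", numeric(0), numeric(0),
                                "diverging", "eps_1 = 0"))
  if (is.null(psi)) {
    rks <- lapply(law$states, function(st)
      vapply(seq_len(K_env), function(k) r_statistic(st, k), numeric(1)))
    noninc <- vapply(rks, function(r) all(diff(r) <= 1e-9), logical(1))
    if (!all(noninc))
      return(new_condition_report(
        "l1_series", numeric(0), numeric(0), "theorem_inapplicable",
        "r_k not nonincreasing over the probe grid for some state"))
    env <- lapply(rks, envelope_interp, require = "concave")
    if (!all(vapply(env, `[[`, logical(1), "shape_ok")))
      return(new_condition_report(
        "l1_series", numeric(0), numeric(0), "inconclusive",
        "default psi failed the concavity check of x * psi(x)"))
    psi <- lapply(env, `[[`, "fn")
  }
  rho_i <- vapply(sms, function(s) s$eps_sup / s$eps_inf, numeric(1))
  lg_inf <- vapply(sms, function(s) log(s$m * s$alpha * s$eps_inf), numeric(1))
  g_inf <- exp(lg_inf)
  term_path <- function(idx) {
    n <- length(idx)
    prods <- c(1, cumprod(rho_i[idx]))[seq_len(n)]
    args <- N0 * exp(c(0, cumsum(lg_inf[idx]))[seq_len(n)])
    vapply(seq_len(n), function(t)
      prods[t] * psi[[idx[t]]](args[t]) / g_inf[idx[t]], numeric(1))
  }
  if (length(law$states) == 1L) {
    terms <- term_path(rep(1L, n_terms))
  } else {
    if (!is.null(seed)) set.seed(seed)
    mats <- replicate(mc_sequences, term_path(
      sample.int(length(law$states), n_terms, replace = TRUE,
                 prob = law$probs)))
    terms <- rowMeans(mats)
  }
  new_condition_report("l1_series", terms, cumsum(terms),
                       series_verdict(terms))
}
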