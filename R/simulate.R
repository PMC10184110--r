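# Monte Carlo engine.  Sampling is generation-major and vectorised across
# replicates: within a generation, replicates sharing an environment state
# are advanced together.  A sum of s i.i.d. offspring counts is drawn by
# sequential conditional binomials over the offspring categories (the
# multinomial decomposition), so the cost per generation is O(number of
# offspring categories), independent of the population sizes.

# binomial sampler valid for sizes beyond .Machine$integer.max: exact
# rbinom below 2^30, rounded/clamped Gaussian above (relative error < 1e-4
# at those sizes)
rbinom_big <- function(n, size, prob) {
  out <- numeric(n)
  big <- size > 2^30
  if (any(!big))
    out[!big] <- stats::rbinom(sum(!big), size[!big], prob)
  if (any(big)) {
    mu <- size[big] * prob
    sd <- sqrt(size[big] * prob * (1 - prob))
    out[big] <- pmin(pmax(round(stats::rnorm(sum(big), mu, sd)), 0),
                     size[big])
  }
  out
}

# totals of `sizes[j]` i.i.d. draws from mass vector pmf over 0..R,
# plus the count of draws equal to 0 (needed for survivor bookkeeping)
multinom_totals <- function(sizes, pmf) {
  n <- length(sizes)
  rem <- sizes
  prem <- 1
  tot <- numeric(n)
  c0 <- numeric(n)
  for (r in seq_along(pmf) - 1L) {
    pr <- pmf[r + 1L]
    if (pr <= 0) next
    cr <- if (prem - pr <= 1e-12) rem
          else rbinom_big(n, rem, min(pr / prem, 1))
    if (r == 0L) c0 <- cr else tot <- tot + r * cr
    rem <- rem - cr
    prem <- prem - pr
    if (prem <= 1e-12) break
  }
  list(tot = tot, c0 = c0)
}

# one reproduction step for a vector of sizes all in the same state
mc_step <- function(state, Z, mode) {
  phi <- kernel_draw(state$control, Z)
  n <- length(Z)
  if (mode == "compound") {
    surv <- rbinom_big(n, phi, state$alpha)
    Z1 <- multinom_totals(surv, state$offspring)$tot
  } else { # per_individual: phi thinned draws, survivors recovered from the
    # zero class (an individual contributing 0 either died of infection or
    # survived with zero offspring)
    thin <- thinned_offspring_pmf(state)$probs
    mt <- multinom_totals(phi, thin)
    Z1 <- mt$tot
    p0 <- state$offspring[1L]
    pz <- thin[1L]
    psurv0 <- if (pz > 0) state$alpha * p0 / pz else 0
    surv <- (phi - mt$c0) + rbinom_big(n, mt$c0, psurv0)
  }
  list(Z1 = Z1, phi = phi, surv = surv)
}

#' Simulate one trajectory of the process
#'
#' Draws a single path of `(xi_n, Z_n, phi_n(Z_n), survivors)` from a given
#' environment law.  Two sampling modes are provided and are equal in
#' distribution: `"per_individual"` draws the participation count and then
#' the infection-thinned offspring of each participant; `"compound"` first
#' draws the binomial number of survivors among participants and then their
#' offspring.
#'
#' @param law an [env_law].
#' @param N0 initial population size (`>= 1`).
#' @param n_max number of generations to simulate (`>= 0`).
#' @param seed optional integer seed (recorded in the result).
#' @param mode `"compound"` (default) or `"per_individual"`.
#' @param env_fixed optional integer vector of state indices fixing the
#'   environment sequence (quenched simulation).
#' @param cap population cap; a path exceeding it is aborted with status
#'   `"overflow"` rather than silently clipped (default `1e8`).
#' @return an object of class `cbre_trajectory` with fields `Z` (sizes for
#'   generations `0..n_max`), `env_indices`, `phi`, `survivors`,
#'   `extinct_at` (first generation at 0, or `NA`), `status`, `seed`.
#' @export
simulate_path <- function(law, N0, n_max, seed = NULL,
                          mode = c("compound", "per_individual"),
                          env_fixed = NULL, cap = 1e8) {
  mode <- match.arg(mode)
  stopifnot(inherits(law, "env_law"), N0 >= 1, n_max >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(env_fixed)) stopifnot(length(env_fixed) >= n_max)
  Z <- numeric(n_max + 1L); Z[1L] <- N0
  env <- integer(max(n_max, 0L))
  phi <- numeric(max(n_max, 0L))
  surv <- numeric(max(n_max, 0L))
  status <- "ok"
  if (n_max > 0) for (t in seq_len(n_max)) {
    e <- if (is.null(env_fixed))
      sample.int(length(law$states), 1L, prob = law$probs)
    else as.integer(env_fixed[t])
    env[t] <- e
    if (Z[t] == 0) { Z[t + 1L] <- 0; next }
    st <- mc_step(law$states[[e]], Z[t], mode)
    phi[t] <- st$phi; surv[t] <- st$surv
    Z[t + 1L] <- st$Z1
    if (Z[t + 1L] > cap) {
      status <- "overflow"
      Z[(t + 1L):(n_max + 1L)] <- Z[t + 1L]
      break
    }
  }
  zero <- which(Z == 0)
  structure(list(Z = Z, env_indices = env, phi = phi, survivors = surv,
                 extinct_at = if (length(zero)) zero[1L] - 1L else NA_integer_,
                 status = status, seed = seed, N0 = N0, mode = mode),
            class = "cbre_trajectory")
}

#' @export
print.cbre_trajectory <- function(x, ...) {
  cat("<cbre_trajectory> N0 =", x$N0, ", generations 0..",
      length(x$Z) - 1L, ", status ", x$status, "\n", sep = "")
  cat("  extinct_at:", if (is.na(x$extinct_at)) "never (within horizon)"
      else x$extinct_at, "\n")
  cat("  Z head:", paste(utils::head(x$Z, 10), collapse = " "), "\n")
  invisible(x)
}

# core vectorised ensemble runner; returns per-generation summaries and,
# if keep = TRUE, the full replicate-by-generation matrices
run_ensemble <- function(law, N0, n_max, reps, seed = NULL,
                         mode = "compound", env_fixed = NULL,
                         cap = 1e8, keep = FALSE) {
  stopifnot(inherits(law, "env_law"), reps >= 1, n_max >= 0, N0 >= 1)
  if (!is.null(seed)) set.seed(seed)
  sms <- law_summaries(law)
  log_g_sup <- vapply(sms, function(s) log(s$m * s$alpha * s$eps_sup), numeric(1))
  eps_inf <- vapply(sms, `[[`, numeric(1), "eps_inf")
  wbar_ok <- all(eps_inf > 0)
  log_g_inf <- ifelse(eps_inf > 0,
                      vapply(sms, function(s) log(s$m * s$alpha * s$eps_inf),
                             numeric(1)), NA_real_)
  Z <- rep(as.numeric(N0), reps)
  logS <- rep(log(N0), reps)
  logI <- rep(log(N0), reps)
  frozen <- logical(reps)   # overflowed paths, frozen in place
  extinct_at <- rep(NA_real_, reps)
  id_csum <- numeric(reps)  # running sum of W-hat_k * eps_{Z_k}/eps
  gens <- 0:n_max
  summ <- function(v) c(mean(v), stats::var(v))
  mean_Z <- var_Z <- mean_What <- var_What <- mean_Wbar <- var_Wbar <-
    ext_freq <- numeric(n_max + 1L)
  if (keep) {
    Zmat <- matrix(NA_real_, reps, n_max + 1L)
    Wmat <- matrix(NA_real_, reps, n_max + 1L)
    Emat <- matrix(NA_integer_, reps, max(n_max, 1L))
  }
  record <- function(t) {
    What <- ifelse(Z == 0, 0, exp(log(Z) - logS))
    Wbar <- if (wbar_ok) ifelse(Z == 0, 0, exp(log(Z) - logI)) else NULL
    ext_freq[t] <<- mean(Z == 0)
    s <- summ(Z); mean_Z[t] <<- s[1]; var_Z[t] <<- s[2]
    s <- summ(What); mean_What[t] <<- s[1]; var_What[t] <<- s[2]
    if (wbar_ok) { s <- summ(Wbar); mean_Wbar[t] <<- s[1]; var_Wbar[t] <<- s[2] }
    else { mean_Wbar[t] <<- NA_real_; var_Wbar[t] <<- NA_real_ }
    if (keep) { Zmat[, t] <<- Z; Wmat[, t] <<- What }
    invisible(NULL)
  }
  record(1L)
  if (n_max > 0) for (t in seq_len(n_max)) {
    e <- if (is.null(env_fixed))
      sample.int(length(law$states), reps, replace = TRUE, prob = law$probs)
    else rep(as.integer(env_fixed[t]), reps)
    if (keep) Emat[, t] <- e
    for (si in unique(e)) {
      sel <- which(e == si & !frozen)
      if (!length(sel)) next
      sm <- sms[[si]]
      # mean-identity correction term at generation t-1 (before stepping)
      alive <- sel[Z[sel] > 0]
      if (length(alive)) {
        epsk <- sm$eps_of_k(Z[alive])
        What_k <- exp(log(Z[alive]) - logS[alive])
        id_csum[alive] <- id_csum[alive] +
          What_k * (sm$eps_sup - epsk) / sm$eps_sup
      }
      st <- mc_step(law$states[[si]], Z[sel], mode)
      Z[sel] <- st$Z1
      logS[sel] <- logS[sel] + log_g_sup[si]
      if (wbar_ok) logI[sel] <- logI[sel] + log_g_inf[si]
      over <- sel[Z[sel] > cap]
      frozen[over] <- TRUE
    }
    extinct_at[is.na(extinct_at) & Z == 0] <- t
    record(t + 1L)
  }
  structure(list(
    reps = reps, generations = gens, mode = mode, seed = seed, N0 = N0,
    ext_freq = ext_freq, mean_Z = mean_Z, var_Z = var_Z,
    mean_What = mean_What, var_What = var_What,
    mean_Wbar = mean_Wbar, var_Wbar = var_Wbar,
    wbar_defined = wbar_ok,
    extinct_at = extinct_at, n_overflow = sum(frozen),
    identity_csum = id_csum,
    final_Z = Z, final_logS = logS,
    Z_paths = if (keep) Zmat else NULL,
    What_paths = if (keep) Wmat else NULL,
    env_paths = if (keep) Emat else NULL),
    class = "cbre_ensemble")
}

#' Simulate an ensemble of independent replicates
#'
#' Runs `reps` independent trajectories (each with its own i.i.d.
#' environment sequence) under a single master seed and returns
#' per-generation summary statistics of `Z_n` and of the normalized
#' processes `W-hat_n = Z_n / S_n` and `W-bar_n = Z_n / I_n`.
#'
#' @inheritParams simulate_path
#' @param reps number of replicates (`>= 1`).
#' @param keep_paths keep the replicate-by-generation matrices (size and
#'   normalized size) in the result.
#' @return an object of class `cbre_ensemble`.
#' @export
simulate_ensemble <- function(law, N0, n_max, reps, seed = NULL,
                              mode = c("compound", "per_individual"),
                              cap = 1e8, keep_paths = FALSE) {
  mode <- match.arg(mode)
  run_ensemble(law, N0, n_max, reps, seed, mode, NULL, cap, keep_paths)
}

#' Simulate an ensemble under a fixed (quenched) environment sequence
#'
#' All replicates share the given environment sequence, so sample means are
#' directly comparable with the exact quenched law from
#' [propagate_distribution()].
#'
#' @inheritParams simulate_ensemble
#' @param env_sequence integer state indices for generations `0..n_max-1`.
#' @return an object of class `cbre_ensemble`.
#' @export
quenched_ensemble <- function(law, env_sequence, N0, reps, seed = NULL,
                              mode = c("compound", "per_individual"),
                              cap = 1e8, keep_paths = FALSE) {
  mode <- match.arg(mode)
  run_ensemble(law, N0, length(env_sequence), reps, seed, mode,
               env_sequence, cap, keep_paths)
}

#' @export
print.cbre_ensemble <- function(x, ...) {
  n <- length(x$generations) - 1L
  cat("<cbre_ensemble>", x$reps, "replicates, generations 0..", n, "\n")
  cat(sprintf("  final: extinct %.4f, mean Z %.6g, mean W-hat %.6g%s\n",
              x$ext_freq[n + 1L], x$mean_Z[n + 1L], x$mean_What[n + 1L],
              if (x$wbar_defined)
                sprintf(", mean W-bar %.6g", x$mean_Wbar[n + 1L]) else ""))
  if (x$n_overflow > 0)
    cat("  ", x$n_overflow, "path(s) hit the population cap (overflow)\n")
  invisible(x)
}
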