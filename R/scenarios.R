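#' Built-in fixture scenarios
#'
#' Six reference configurations spanning the qualitative regimes of the
#' model.  With the thinned mean growth factor `g = m * alpha * eps`:
#'
#' * `S1_critical` - offspring `{0:.25, 1:.25, 2:.5}`, `alpha = 0.8`,
#'   identity control, `N0 = 1`; `g = 1` and the extinction criterion is
#'   exactly 0.
#' * `S2_subcritical` - same offspring, `alpha = 0.72`; criterion `log 0.9`.
#' * `S3_supercritical_gw` - offspring `{0:.2, 1:.2, 2:.6}`, `alpha = 0.8`,
#'   identity control; criterion `log 1.12`, classical extinction
#'   probability 0.75 (smaller root of the thinned pgf).
#' * `S4_two_state` - the subcritical and supercritical states mixed with
#'   probabilities 0.5/0.5 under binomial participation `p = 0.9`.
#' * `S5_emigration` - offspring `{0:.1, 2:.3, 4:.6}` (`m = 3`),
#'   `alpha = 0.8`, one potential emigrant (`E` uniform on `{0, 1}`),
#'   `N0 = 2`; the nondegeneracy product stabilizes above 0.
#' * `S6_reduction_alpha1` - `alpha = 1`, identity control: the classical
#'   controlled-free branching process in a random environment, with
#'   quenched mean `N0 * prod m(xi_i)`.
#'
#' @return named list of `cbre_scenario` objects with fields `name`, `law`,
#'   `N0`, `horizon`, `reps`, `seed` and an `annotations` list of expected
#'   behaviours used by [scenario_selftest()].
#' @export
builtin_scenarios <- function() {
  sc <- function(name, law, N0, horizon, reps, annotations)
    structure(list(name = name, law = law, N0 = N0, horizon = horizon,
                   reps = reps, seed = 1L, annotations = annotations),
              class = "cbre_scenario")
  th1 <- env_state("theta1", c(0.25, 0.25, 0.5), 0.8)
  th2 <- env_state("theta2", c(0.25, 0.25, 0.5), 0.72)
  th3 <- env_state("theta3", c(0.2, 0.2, 0.6), 0.8)
  em <- kernel_emigration(c(0.5, 0.5))
  th_strong <- env_state("theta_strong", c(0.1, 0, 0.3, 0, 0.6), 0.8, em)
  list(
    S1_critical = sc("S1_critical", env_law(th1), 1L, 50L, 1e4L,
      list(criterion = 0, mean_Z = 1)),
    S2_subcritical = sc("S2_subcritical", env_law(th2), 1L, 200L, 2e4L,
      list(criterion = log(0.9))),
    S3_supercritical_gw = sc("S3_supercritical_gw", env_law(th3), 1L, 300L,
      2e4L, list(criterion = log(1.12), extinction_prob = 0.75)),
    S4_two_state = sc("S4_two_state",
      env_law(list(
        env_state("theta2", c(0.25, 0.25, 0.5), 0.72, kernel_binomial(0.9)),
        env_state("theta3", c(0.2, 0.2, 0.6), 0.8, kernel_binomial(0.9))),
        c(0.5, 0.5)),
      1L, 200L, 2e4L,
      list(criterion = 0.5 * (log(0.9) + log(1.12)))),
    S5_emigration = sc("S5_emigration", env_law(th_strong), 2L, 50L, 1e4L,
      list(nondegenerate = TRUE)),
    S6_reduction_alpha1 = sc("S6_reduction_alpha1",
      env_law(env_state("theta1_a1", c(0.25, 0.25, 0.5), 1)), 1L, 50L, 1e4L,
      list(quenched_mean_is_prod_m = TRUE)))
}

#' @export
print.cbre_scenario <- function(x, ...) {
  cat("<cbre_scenario>", x$name, " N0 =", x$N0, "\n")
  print(x$law)
  invisible(x)
}

parse_pmf_map <- function(x, what) {
  if (is.null(names(x))) return(check_prob_vec(unlist(x), what))
  idx <- suppressWarnings(as.integer(names(x)))
  if (any(is.na(idx)) || any(idx < 0))
    stop(sprintf("config error at %s: keys must be non-negative integers",
                 what), call. = FALSE)
  v <- numeric(max(idx) + 1L)
  v[idx + 1L] <- unlist(x)
  check_prob_vec(v, what)
}

parse_control <- function(ctl, where) {
  kind <- ctl$kind
  if (is.null(kind))
    stop(sprintf("config error at %s/control: missing 'kind'", where),
         call. = FALSE)
  switch(kind,
    identity = kernel_identity(),
    binomial_thinning = {
      if (is.null(ctl$p))
        stop(sprintf("config error at %s/control: missing 'p'", where),
             call. = FALSE)
      kernel_binomial(ctl$p)
    },
    random_emigration = kernel_emigration(
      parse_pmf_map(ctl$removals, paste0(where, "/control/removals"))),
    random_immigration = kernel_immigration(
      parse_pmf_map(ctl$additions, paste0(where, "/control/additions"))),
    tabulated = kernel_tabulated(lapply(ctl$tab, unlist)),
    stop(sprintf("config error at %s/control: unknown kind '%s'",
                 where, kind), call. = FALSE))
}

#' Read a scenario configuration from JSON
#'
#' Schema: `{"states": [{"label", "offspring_pmf": {r: p}, "alpha",
#' "control": {"kind", ...}}], "probs": [...], "N0", "seed"}`.  Validation
#' errors name the offending field.
#'
#' @param path path to a JSON file.
#' @return a `cbre_scenario`.
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(cfg$states) || !length(cfg$states))
    stop("config error at /states: at least one state required",
         call. = FALSE)
  states <- lapply(seq_along(cfg$states), function(i) {
    s <- cfg$states[[i]]
    where <- sprintf("/states[%d]", i)
    for (fld in c("label", "offspring_pmf", "alpha"))
      if (is.null(s[[fld]]))
        stop(sprintf("config error at %s: missing '%s'", where, fld),
             call. = FALSE)
    env_state(s$label,
              parse_pmf_map(s$offspring_pmf, paste0(where, "/offspring_pmf")),
              s$alpha,
              if (is.null(s$control)) kernel_identity()
              else parse_control(s$control, where))
  })
  probs <- if (is.null(cfg$probs)) NULL else unlist(cfg$probs)
  law <- env_law(states, probs)
  structure(list(
    name = if (is.null(cfg$name)) basename(path) else cfg$name,
    law = law,
    N0 = if (is.null(cfg$N0)) 1L else as.integer(cfg$N0),
    horizon = if (is.null(cfg$horizon)) 100L else as.integer(cfg$horizon),
    reps = if (is.null(cfg$reps)) 1e4L else as.integer(cfg$reps),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    annotations = list()),
    class = "cbre_scenario")
}

#' Re-derive every built-in scenario annotation
#'
#' Recomputes each scenario's expected-behaviour annotation with the
#' analysis functions and fails loudly on mismatch.
#'
#' @param tol_criterion tolerance on criterion values (default 1e-12).
#' @param tol_mu tolerance on the extinction fixed point (default 1e-6).
#' @param stop_on_failure raise an error when a check fails (default TRUE).
#' @return data frame of check results, invisibly when all pass.
#' @export
scenario_selftest <- function(tol_criterion = 1e-12, tol_mu = 1e-6,
                              stop_on_failure = TRUE) {
  scen <- builtin_scenarios()
  rows <- list()
  add <- function(name, check, ok, detail)
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario = name, check = check, ok = ok, detail = detail,
      stringsAsFactors = FALSE)
  for (s in scen) {
    a <- s$annotations
    if (!is.null(a$criterion)) {
      got <- extinction_criterion(s$law, s$N0, grid_size = 2000)$expectation
      add(s$name, "criterion", abs(got - a$criterion) <= tol_criterion,
          sprintf("got %.12g want %.12g", got, a$criterion))
    }
    if (!is.null(a$mean_Z)) {
      pmfs <- propagate_distribution(s$law, rep(1L, 5L), s$N0, J_max = 64L)
      got <- pmf_mean(pmfs[[6L]])
      add(s$name, "mean_Z", abs(got - a$mean_Z) <= 1e-9,
          sprintf("E(Z_5) = %.12g", got))
    }
    if (!is.null(a$extinction_prob)) {
      mu <- iterate_mu(s$law, rep(1L, 400L), s$N0)
      add(s$name, "extinction_prob",
          abs(mu$limit_estimate - a$extinction_prob) <= tol_mu,
          sprintf("mu limit %.8g want %.8g", mu$limit_estimate,
                  a$extinction_prob))
    }
    if (!is.null(a$nondegenerate)) {
      nd <- nondegeneracy_condition(s$law, s$N0, n_terms = 80L)
      add(s$name, "nondegenerate", identical(nd$verdict, "positive"),
          nd$note)
    }
    if (!is.null(a$quenched_mean_is_prod_m)) {
      pmfs <- propagate_distribution(s$law, rep(1L, 4L), s$N0, J_max = 64L)
      m <- state_summaries(s$law$states[[1L]])$m
      got <- pmf_mean(pmfs[[5L]])
      add(s$name, "quenched_mean", abs(got - s$N0 * m^4) <= 1e-9,
          sprintf("E(Z_4|xi) = %.12g want %.12g", got, s$N0 * m^4))
    }
  }
  res <- do.call(rbind, rows)
  if (stop_on_failure && !all(res$ok)) {
    bad <- res[!res$ok, , drop = FALSE]
    stop("scenario self-test failed:\n",
         paste(sprintf("  %s/%s: %s", bad$scenario, bad$check, bad$detail),
               collapse = "\n"))
  }
  invisible(res)
}

#' Run an orchestrated analysis from a configuration file
#'
#' Reads a scenario JSON (or takes a built-in scenario by name), runs the
#' requested analyses and writes CSV/JSON artifacts to `out_dir`.  Requested
#' analyses default to `c("simulate", "extinction")`; available:
#' `"simulate"` (one trajectory CSV + ensemble summary JSON),
#' `"transition"` (one-step pmf CSV), `"extinction"` (criterion + mu +
#' Monte Carlo report JSON), `"limits"` (normalizer/martingale/series report
#' JSON).
#'
#' @param path path to a scenario JSON, or the name of a built-in scenario.
#' @param out_dir output directory (created if missing).
#' @param analyses character vector of analysis names.
#' @param n,reps,seed overrides of the scenario defaults.
#' @param transition_size current size `i` for the `"transition"` analysis.
#' @param J_max truncation cap passed through to exact computations.
#' @return invisibly, the list of file paths written.
#' @export
run_config <- function(path, out_dir = ".",
                       analyses = c("simulate", "extinction"),
                       n = NULL, reps = NULL, seed = NULL,
                       transition_size = 1L, J_max = 4096L) {
  scen <- if (file.exists(path)) read_scenario(path)
          else {
    b <- builtin_scenarios()
    if (!path %in% names(b))
      stop(sprintf("config error: '%s' is neither a file nor a built-in %s",
                   path, "scenario name"), call. = FALSE)
    b[[path]]
  }
  n <- if (is.null(n)) scen$horizon else n
  reps <- if (is.null(reps)) scen$reps else reps
  seed <- if (is.null(seed)) scen$seed else seed
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ver <- as.character(utils::packageVersion("cbre"))
  written <- character(0)
  meta <- list(scenario = scen$name, seed = seed, package_version = ver)
  if ("simulate" %in% analyses) {
    tr <- simulate_path(scen$law, scen$N0, n, seed = seed)
    df <- data.frame(generation = seq_along(tr$Z) - 1L,
                     env_label = c(NA, scen$law$labels[tr$env_indices]),
                     Z = tr$Z,
                     phi = c(NA, tr$phi), survivors = c(NA, tr$survivors))
    f <- file.path(out_dir, paste0(scen$name, "_trajectory.csv"))
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE, eol = "\n")
    ens <- simulate_ensemble(scen$law, scen$N0, n, reps, seed = seed)
    g <- file.path(out_dir, paste0(scen$name, "_ensemble.json"))
    jsonlite::write_json(c(meta, list(
      generations = ens$generations, ext_freq = ens$ext_freq,
      mean_Z = ens$mean_Z, var_Z = ens$var_Z,
      mean_What = ens$mean_What,
      mean_Wbar = if (ens$wbar_defined) ens$mean_Wbar else NULL,
      n_overflow = ens$n_overflow)), g, digits = NA, auto_unbox = TRUE)
    written <- c(written, f, g)
  }
  if ("transition" %in% analyses) {
    st_idx <- 1L
    pmf <- one_step_pmf(scen$law$states[[st_idx]], transition_size, J_max)
    f <- file.path(out_dir, paste0(scen$name, "_transition.csv"))
    con <- file(f, "w")
    writeLines(sprintf("# tail_mass %.17g", pmf$tail_mass), con)
    utils::write.table(
      data.frame(size = seq_along(pmf$probs) - 1L, probability = pmf$probs),
      con, sep = ",", row.names = FALSE, quote = FALSE, eol = "\n")
    close(con)
    written <- c(written, f)
  }
  if ("extinction" %in% analyses) {
    crit <- extinction_criterion(scen$law, scen$N0)
    env <- sample_environment_sequence(scen$law, n, seed = seed)
    mu <- iterate_mu(scen$law, env, scen$N0, n = n)
    mc <- mc_extinction_probability(scen$law, scen$N0, n, max(reps, 100L),
                                    seed = seed)
    f <- file.path(out_dir, paste0(scen$name, "_extinction.json"))
    jsonlite::write_json(c(meta, list(
      criterion = crit$expectation,
      per_state_terms = as.list(stats::setNames(crit$per_state_term,
                                                crit$labels)),
      monotonicity = crit$monotonicity_ok, conclusion = crit$conclusion,
      mu_limit = mu$limit_estimate, mu_converged = mu$converged,
      mc_estimate = mc$estimate,
      wilson_ci = c(mc$ci[["lower"]], mc$ci[["upper"]]))),
      f, digits = NA, auto_unbox = TRUE)
    written <- c(written, f)
  }
  if ("limits" %in% analyses) {
    sms <- law_summaries(scen$law)
    if (any(vapply(sms, `[[`, numeric(1), "eps_inf") == 0)) {
      bad <- scen$law$labels[vapply(sms, `[[`, numeric(1), "eps_inf") == 0]
      stop(sprintf("numeric error: eps_1 = 0 in state %s; %s",
                   paste(bad, collapse = ", "),
                   "inf-normalized process undefined"), call. = FALSE)
    }
    env <- sample_environment_sequence(scen$law, n, seed = seed)
    nz <- normalizers(scen$law, env, scen$N0)
    sc <- series_conditions(scen$law, scen$N0)
    lb <- l2_bound(scen$law, scen$N0, n)
    probe <- c(1L, 2L, 4L, 8L)
    ratios <- lapply(seq_along(scen$law$states), function(i) list(
      state = scen$law$labels[i],
      supermartingale = vapply(probe, function(k)
        supermartingale_ratio(scen$law$states[[i]], k), numeric(1)),
      submartingale = vapply(probe, function(k)
        submartingale_ratio(scen$law$states[[i]], k), numeric(1))))
    f <- file.path(out_dir, paste0(scen$name, "_limits.json"))
    jsonlite::write_json(c(meta, list(
      log_S = nz$log_S, log_I = nz$log_I,
      martingale_ratios = ratios,
      l2_bound = if (lb$finite) lb$bound else "infinite",
      conditions = lapply(sc, function(x)
        list(id = x$id, verdict = x$verdict,
             last_partial = if (length(x$partial))
               utils::tail(x$partial, 1L) else NULL)))),
      f, digits = NA, auto_unbox = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
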