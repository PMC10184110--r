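scen <- builtin_scenarios()
th1 <- env_state("theta1", c(0.25, 0.25, 0.5), 0.8)
th_em <- env_state("theta_em", c(0.25, 0.25, 0.5), 0.8,
                   kernel_emigration(c(0.5, 0.5)))

test_that("normalizers multiply the per-step mean growth factors", {
  law <- env_law(th1)
  nz <- normalizers(law, rep(1L, 6L), N0 = 1)
  expect_equal(nz$log_S, rep(0, 7))  # m alpha eps = 1 in the critical state
  expect_equal(nz$log_I, rep(0, 7))
  law_em <- env_law(th_em)
  nz2 <- normalizers(law_em, rep(1L, 5L), N0 = 1)
  expect_equal(nz2$log_S, rep(0, 6))          # m alpha eps_sup = 1
  expect_equal(nz2$log_I, log(0.5) * (0:5))   # eps_1 = 0.5
  nz0 <- normalizers(law, integer(0), N0 = 3)
  expect_equal(exp(nz0$log_S), 3)
  all_out <- env_state("gone", c(0.25, 0.25, 0.5), 0.8,
                       kernel_emigration(c(0, 1)))  # E = 1 always: eps(1) = 0
  expect_error(normalizers(env_law(all_out), rep(1L, 3L), 1), "eps_1 = 0")
})

test_that("normalized paths order correctly and vanish after extinction", {
  law_em <- env_law(th_em)
  tr <- simulate_path(law_em, N0 = 3, n_max = 25, seed = 77)
  np <- normalized_path(law_em, tr)
  expect_true(all(np$W_bar >= np$W_hat - 1e-12))
  if (!is.na(tr$extinct_at))
    expect_true(all(np$W_hat[(tr$extinct_at + 1):length(np$W_hat)] == 0))
  expect_equal(np$W_hat[1], 1)  # Z_0 / N0
})

test_that("martingale step ratios take their closed-form values", {
  expect_equal(supermartingale_ratio(th1, 5), 1)
  expect_equal(supermartingale_ratio(th_em, 1), 0.5)
  expect_equal(supermartingale_ratio(th_em, 10), 0.95)
  expect_equal(submartingale_ratio(th1, 5), 1)
  expect_equal(submartingale_ratio(th_em, 1), 1)
  expect_equal(submartingale_ratio(th_em, 4), 1.75)
  for (i in c(1, 2, 7, 19)) {
    expect_lte(supermartingale_ratio(th_em, i), 1)
    expect_gte(submartingale_ratio(th_em, i), 1)
  }
  expect_true(attr(supermartingale_ratio(th_em, 0), "extinct"))
})

test_that("the mean identity holds: exactly under identity control, within MC error otherwise", {
  mi <- mean_identity_check(scen$S3_supercritical_gw$law, 1, 10, 4000,
                            seed = 83)
  expect_equal(mi$mean_correction, 0)  # identity control: no correction
  expect_lt(abs(mi$z), 4)
  mi5 <- mean_identity_check(scen$S5_emigration$law, 2, 12, 4000, seed = 84)
  expect_gt(mi5$mean_correction, 0)
  expect_lt(abs(mi5$z), 4)
})

test_that("the second-moment bound is finite, correct, and dominates", {
  lb <- l2_bound(scen$S3_supercritical_gw$law, 1, 400)
  # geometric series: 1 + (2.6 / 1.568) * 1.12 / 0.12
  expect_equal(lb$bound, 1 + (2.6 / 1.568) * (1.12 / 0.12),
               tolerance = 1e-9)
  expect_true(all(lb$terms_delta2 == 0))  # identity control
  binom_law <- scen$S4_two_state$law
  expect_false(l2_bound(binom_law, 1, 10)$finite)  # delta2_sup = Inf
  ens <- simulate_ensemble(scen$S3_supercritical_gw$law, 1, 15, 4000,
                           seed = 85, keep_paths = TRUE)
  w2 <- ens$What_paths[, 16]^2
  expect_lte(mean(w2), lb$bound + 3 * stats::sd(w2) / sqrt(length(w2)))
})

test_that("hypothesis series get the right verdicts per regime", {
  sc3 <- series_conditions(scen$S3_supercritical_gw$law, 1)
  expect_equal(sc3$l2_m2$verdict, "converged-to-finite")
  expect_equal(sc3$l2_delta2$verdict, "converged-to-finite")
  expect_equal(sc3$l2conv_eps$verdict, "converged-to-finite")
  expect_equal(sc3$submg_product$verdict, "converged-to-finite")
  sc2 <- series_conditions(scen$S2_subcritical$law, 1)
  expect_equal(sc2$l2_m2$verdict, "diverging")  # S_i -> 0 geometrically
  sc5 <- series_conditions(scen$S5_emigration$law, 2)
  expect_equal(sc5$submg_product$verdict, "diverging")  # (eps/eps_1)^n = 2^n
})

test_that("nondegeneracy products behave as the growth regime dictates", {
  nd1 <- nondegeneracy_condition(env_law(th1), 1, n_terms = 50)
  expect_equal(nd1$verdict, "positive")
  expect_equal(utils::tail(nd1$partial, 1), 1)  # identity: every factor 1
  nd5 <- nondegeneracy_condition(scen$S5_emigration$law, 2, n_terms = 80)
  expect_equal(nd5$verdict, "positive")
  expect_gt(utils::tail(nd5$partial, 1), 0.1)
  sub_em <- env_state("sub_em", c(0.25, 0.25, 0.5), 0.72,
                      kernel_emigration(c(0.5, 0.5)))
  nd_sub <- nondegeneracy_condition(env_law(sub_em), 1, n_terms = 120)
  expect_equal(nd_sub$verdict, "inconclusive")  # factors -> eps(1)/eps < 1
})

test_that("r-statistics match hand values and the degenerate reduction", {
  expect_equal(r_statistic(th1, 1), 0.8)
  expect_equal(r_statistic(th1, 2), 0.48)
  certain <- env_state("sure", c(0, 1), 1)  # P1 = 1, alpha = 1, identity
  for (k in c(1, 3, 9)) expect_equal(r_statistic(certain, k), 0)
})

test_that("envelopes keep the required shape and bounding directions", {
  sm <- state_summaries(th_em)
  ks <- seq_len(64)
  conv <- envelope_interp(sm$eps_of_k(ks), "convex")
  expect_true(conv$shape_ok)
  expect_true(all(conv$fn(ks) <= sm$eps_of_k(ks) + 1e-9))
  expect_true(all(conv$fn(seq(0.1, 80, by = 0.7)) >= sm$eps_of_k(1) - 1e-9))
  rk <- vapply(1:16, function(k) r_statistic(th1, k), numeric(1))
  conc <- envelope_interp(rk, "concave")
  expect_true(conc$shape_ok)
  expect_true(all(conc$fn(1:16) >= rk - 1e-9))
  expect_true(all(conc$fn(seq(0.1, 20, by = 0.3)) <= rk[1] + 1e-9))
})

test_that("survival-series diagnostic is zero under identity control and summable on growth", {
  tr <- simulate_path(scen$S3_supercritical_gw$law, 1, 20, seed = 91)
  sp <- surviving_path_condition(scen$S3_supercritical_gw$law, tr)
  expect_true(all(sp$terms == 0))
  law5 <- scen$S5_emigration$law
  tr5 <- simulate_path(law5, 2, 20, seed = 92)
  sp5 <- surviving_path_condition(law5, tr5)
  alive <- which(tr5$Z[seq_along(sp5$terms)] > 0)
  expect_equal(sp5$terms[alive], 0.5 / tr5$Z[alive])
})

test_that("the L1 condition separates the decidable regimes", {
  certain <- env_state("sure", c(0, 1), 1)   # Z' = k a.s.: r_k = 0
  expect_equal(l1_condition(env_law(certain), 1)$verdict,
               "converged-to-finite")
  # critical identity: the envelope argument stays at N0, terms are constant
  l1_id <- l1_condition(env_law(th1), 1, n_terms = 30)
  expect_equal(l1_id$verdict, "diverging")
  expect_equal(diff(range(l1_id$terms)), 0)
  l1_em <- l1_condition(scen$S5_emigration$law, 2)
  expect_equal(l1_em$verdict, "theorem_inapplicable")  # r_k not monotone
})
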