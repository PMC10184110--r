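th1 <- env_state("theta1", c(0.25, 0.25, 0.5), 0.8)
th_em <- env_state("theta_em", c(0.25, 0.25, 0.5), 0.8,
                   kernel_emigration(c(0.5, 0.5)))

test_that("thinned offspring pmf folds infection into the zero class", {
  p <- thinned_offspring_pmf(th1)
  expect_equal(p$probs, c(0.4, 0.2, 0.4))
  expect_equal(p$tail_mass, 0)
  a1 <- env_state("a1", c(0.25, 0.25, 0.5), 1)
  expect_equal(thinned_offspring_pmf(a1)$probs, c(0.25, 0.25, 0.5))
  tiny <- env_state("tiny", c(0.25, 0.25, 0.5), 1e-9)
  expect_gt(thinned_offspring_pmf(tiny)$probs[1], 1 - 1e-8)
})

test_that("convolution powers are exact and track truncation", {
  base <- sized_pmf(c(0.4, 0.2, 0.4))
  expect_equal(convolve_power(base, 2)$probs,
               c(0.16, 0.16, 0.36, 0.16, 0.16))
  expect_equal(convolve_power(base, 0)$probs, 1)
  expect_equal(convolve_power(base, 1)$probs, base$probs)
  # truncate a 10-fold power at J_max = 5: mass is conserved into the tail
  tr <- convolve_power(base, 10, J_max = 5)
  expect_equal(sum(tr$probs) + tr$tail_mass, 1, tolerance = 1e-12)
  expect_gt(tr$tail_mass, 0)
  full <- convolve_power(base, 10, J_max = 64)
  expect_equal(tr$probs, full$probs[1:6], tolerance = 1e-12)
})

test_that("one-step law reproduces worked values and the enumeration oracle", {
  expect_equal(one_step_pmf(th1, 1)$probs, c(0.4, 0.2, 0.4))
  expect_equal(one_step_pmf(th1, 2)$probs, c(0.16, 0.16, 0.36, 0.16, 0.16))
  expect_equal(one_step_pmf(th1, 0)$probs, 1)
  expect_equal(one_step_pmf(th_em, 1)$probs, c(0.7, 0.1, 0.2))
  for (st in list(th1, th_em)) for (i in 0:3) {
    exact <- one_step_pmf(st, i, J_max = 64)
    oracle <- enumerate_one_step(st, i, jmax = 64)
    expect_equal(exact$probs, oracle[seq_along(exact$probs)],
                 tolerance = 1e-12)
    expect_lt(sum(abs(oracle)) - sum(exact$probs), 1e-12)
  }
})

test_that("conditional moments match the exact one-step law", {
  expect_equal(conditional_mean(th1, 1), 1)
  expect_equal(conditional_mean(th1, 2), 2)
  expect_equal(conditional_mean(th1, 0), 0)
  expect_equal(conditional_mean(th_em, 1), 0.5)
  expect_equal(conditional_variance(th1, 1), 0.8)
  expect_equal(conditional_variance(th1, 2), 1.6)
  expect_equal(conditional_variance(th_em, 1), 0.65)
  for (st in list(th1, th_em)) for (i in c(1L, 5L, 13L)) {
    pmf <- one_step_pmf(st, i, J_max = 512)
    expect_equal(pmf_mean(pmf), conditional_mean(st, i), tolerance = 1e-9)
    expect_equal(pmf_var(pmf), conditional_variance(st, i),
                 tolerance = 1e-9)
  }
})

test_that("quenched propagation is exact, absorbing, and sandwiched", {
  law <- env_law(th1)
  pmfs <- propagate_distribution(law, rep(1L, 10L), N0 = 1, J_max = 2048)
  expect_equal(pmfs[[2]]$probs, c(0.4, 0.2, 0.4))
  means <- vapply(pmfs, pmf_mean, numeric(1))
  expect_equal(means, rep(1, 11), tolerance = 1e-9)  # critical: m alpha eps = 1
  p0 <- vapply(pmfs, function(p) p$probs[1], numeric(1))
  expect_true(all(diff(p0) >= -1e-12))
  tails <- vapply(pmfs, `[[`, numeric(1), "tail_mass")
  expect_true(all(diff(tails) >= -1e-15))

  # sandwich between the inf and sup quenched mean products
  law_em <- env_law(th_em)
  pm <- propagate_distribution(law_em, rep(1L, 8L), N0 = 2, J_max = 1024)
  sm <- state_summaries(th_em)
  g_lo <- sm$m * sm$alpha * sm$eps_inf
  g_hi <- sm$m * sm$alpha * sm$eps_sup
  for (n in 0:8) {
    mu <- pmf_mean(pm[[n + 1]])
    tail_corr <- pm[[n + 1]]$tail_mass * 1024
    expect_gte(mu + tail_corr, 2 * g_lo^n - 1e-9)
    expect_lte(mu, 2 * g_hi^n + 1e-9)
  }
})
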