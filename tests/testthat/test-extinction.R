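scen <- builtin_scenarios()

test_that("the annealed criterion takes its closed-form values", {
  expect_equal(extinction_criterion(scen$S1_critical$law, 1,
                                    grid_size = 2000)$expectation, 0)
  expect_equal(extinction_criterion(scen$S2_subcritical$law, 1,
                                    grid_size = 2000)$expectation, log(0.9))
  cr3 <- extinction_criterion(scen$S3_supercritical_gw$law, 1,
                              grid_size = 2000)
  expect_equal(cr3$expectation, log(1.12))
  expect_equal(cr3$conclusion, "criterion_positive")
  expect_equal(extinction_criterion(scen$S1_critical$law, 1,
                                    grid_size = 2000)$conclusion,
               "certain_extinction")
  # N0 enters multiplicatively inside the logarithm
  cr_n2 <- extinction_criterion(scen$S1_critical$law, 2, grid_size = 2000)
  expect_equal(cr_n2$expectation, log(2))
  expect_equal(cr_n2$conclusion, "criterion_positive")
})

test_that("criterion sign matches the classical thinned-GW condition", {
  for (am in c(0.7, 1, 1.3)) {
    # mean-am offspring on {0, 2}: P2 = am/2 with alpha = 1
    st <- env_state("gw", c(1 - am / 2, 0, am / 2), 1)
    cr <- extinction_criterion(env_law(st), 1, grid_size = 500)
    expect_equal(cr$expectation <= 0, am <= 1)
  }
})

test_that("the monotonicity certificate accepts and rejects correctly", {
  g <- check_monotonicity(scen$S1_critical$law$states[[1]], 1,
                          grid_size = 2000)
  expect_true(g$increasing)
  expect_equal(g$g_at_0, 0.6)
  expect_equal(g$g_at_1, 1)
  deg <- env_state("deg", c(0, 1), 0.8)
  expect_false(check_monotonicity(deg, 1, grid_size = 2000)$increasing)
})

test_that("mu iteration reproduces worked values and fixed points", {
  law3 <- scen$S3_supercritical_gw$law
  mu <- iterate_mu(law3, rep(1L, 400L), 1)
  expect_equal(mu$mu[1], 0.36)
  expect_equal(mu$mu[2], 0.479808)
  expect_true(mu$converged)
  # independent oracle: smallest root of the thinned pgf fixed point
  st <- law3$states[[1]]
  root <- stats::uniroot(function(s) thinned_pgf(st, s) - s,
                         c(0, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(mu$limit_estimate, root, tolerance = 1e-6)
  expect_equal(mu$limit_estimate, 0.75, tolerance = 1e-6)
  # iterates are a monotone sandwich in [0, 1]
  expect_true(all(diff(mu$mu) >= -1e-15))
  expect_true(all(mu$mu >= 0 & mu$mu <= 1))
  # critical case creeps to 1 and is reported unconverged early
  mu1 <- iterate_mu(scen$S1_critical$law, rep(1L, 10000L), 1, tol = 1e-12)
  expect_equal(mu1$limit_estimate, 1, tolerance = 1e-3)
  # a mixed random environment keeps the monotone sandwich
  env <- sample_environment_sequence(scen$S4_two_state$law, 60, seed = 4)
  mu4 <- iterate_mu(scen$S4_two_state$law, env, 1)
  expect_true(all(diff(mu4$mu) >= -1e-12))
  expect_true(all(mu4$mu <= 1 + 1e-15))
})

test_that("Wilson intervals match the reference implementation", {
  for (case in list(c(75, 100), c(19900, 20000), c(3, 500))) {
    ours <- wilson_ci(case[1], case[2])
    ref <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(ours[["lower"]]), ref[1], tolerance = 1e-9)
    expect_equal(unname(ours[["upper"]]), ref[2], tolerance = 1e-9)
  }
})

test_that("Monte Carlo extinction estimates are consistent with the bounds", {
  mc2 <- mc_extinction_probability(scen$S2_subcritical$law, 1, 200, 5e3,
                                   seed = 61)
  expect_gte(mc2$estimate, 0.99)
  mc3 <- mc_extinction_probability(scen$S3_supercritical_gw$law, 1, 300,
                                   5e3, seed = 62)
  expect_lt(abs(mc3$estimate - 0.75), 0.02)
  # the mu limit is a lower bound for extinction probability
  mu <- iterate_mu(scen$S3_supercritical_gw$law, rep(1L, 400L), 1)
  expect_lte(mu$limit_estimate,
             mc3$estimate + 3 * mc3$ci[["half_width"]])
})
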