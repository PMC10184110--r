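th1 <- env_state("theta1", c(0.25, 0.25, 0.5), 0.8)
th_em <- env_state("theta_em", c(0.25, 0.25, 0.5), 0.8,
                   kernel_emigration(c(0.5, 0.5)))

test_that("offspring and thinned pgfs evaluate correctly", {
  expect_equal(offspring_pgf(th1, 0), 0.25)
  expect_equal(offspring_pgf(th1, 1), 1)
  expect_equal(offspring_pgf(th1, 0.5), 0.5)
  expect_equal(thinned_pgf(th1, 0), 0.4)
  expect_equal(thinned_pgf(th1, 1), 1)
  a1 <- env_state("a1", c(0.25, 0.25, 0.5), 1)
  s <- seq(0, 1, by = 0.1)
  expect_equal(thinned_pgf(a1, s), offspring_pgf(a1, s))
  expect_error(offspring_pgf(th1, 1.5), "\\[0, 1\\]")
  # convexity / monotonicity on a grid
  g <- offspring_pgf(th1, s)
  expect_true(all(diff(g) >= 0))
  expect_true(all(diff(diff(g)) >= -1e-12))
})

test_that("state summaries match closed forms", {
  sm <- state_summaries(th1)
  expect_equal(sm$m, 1.25)
  expect_equal(sm$m2, 2.25)
  expect_equal(sm$var_xi_product, 2.25 * 0.8 - (1.25 * 0.8)^2)
  expect_equal(sm$eps_sup, 1)
  expect_equal(sm$eps_inf, 1)
  expect_equal(sm$delta2_sup, 0)
  expect_equal(sm$eta, 1)

  sme <- state_summaries(th_em)
  k <- c(1, 2, 5, 50)
  expect_equal(sme$eps_of_k(k), 1 - 0.5 / k)
  expect_equal(sme$eps_inf, 0.5)
  expect_equal(sme$eps_sup, 1)
  expect_equal(sme$delta2_of_k(k), rep(0.25, 4))
  expect_equal(sme$eta, 1)

  deg <- state_summaries(env_state("deg", c(0, 1), 0.3))
  expect_equal(deg$m, 1)
  expect_equal(deg$m2, 1)
  expect_equal(deg$var_xi_product, 0.3 - 0.09)
})

test_that("kernel pmfs agree with their moment summaries for k = 1..50", {
  kernels <- list(kernel_identity(), kernel_binomial(0.9),
                  kernel_emigration(c(0.5, 0.3, 0.2)),
                  kernel_immigration(c(0.6, 0.4)),
                  kernel_tabulated(lapply(1:50, function(k)
                    stats::dbinom(0:k, k, 0.7))))
  for (ker in kernels) {
    st <- env_state("probe", c(0.25, 0.25, 0.5), 0.8, ker)
    sm <- state_summaries(st, K_analysis = 50L)
    for (k in 1:50) {
      p <- kernel_pmf(ker, k)
      j <- seq_along(p) - 1
      mu <- sum(j * p)
      expect_lt(abs(mu - k * sm$eps_of_k(k)), 1e-12)
      expect_lt(abs(sum((j - mu)^2 * p) - sm$delta2_of_k(k)), 1e-12)
      expect_lte(max(j[p > 0]), sm$eta * k + 1e-12)
      expect_lte(sm$eps_inf, sm$eps_of_k(k) + 1e-12)
      expect_lte(sm$eps_of_k(k), sm$eps_sup + 1e-12)
    }
    expect_equal(kernel_pmf(ker, 0), 1)  # extinction absorbing
  }
})

test_that("thinned pgf derivative at 1 equals alpha * m", {
  for (st in list(th1, th_em,
                  env_state("s", c(0.1, 0, 0.3, 0, 0.6), 0.8))) {
    sm <- state_summaries(st)
    h <- 1e-6
    num <- (thinned_pgf(st, 1) - thinned_pgf(st, 1 - h)) / h
    expect_equal(num, sm$alpha * sm$m, tolerance = 1e-5)
  }
})

test_that("assumption checks warn on reduction cases, pass otherwise", {
  rep1 <- validate_assumptions(env_law(th1))
  expect_equal(rep1$status[rep1$check == "A1_control"], "warn")
  expect_equal(rep1$status[rep1$check == "A2_alpha"], "pass")
  a1 <- env_state("a1", c(0.25, 0.25, 0.5), 1, kernel_binomial(0.9))
  rep2 <- validate_assumptions(env_law(a1))
  expect_equal(rep2$status[rep2$check == "A2_alpha"], "warn")
  expect_equal(rep2$status[rep2$check == "A1_control"], "pass")
  ok <- env_state("ok", c(0.25, 0.25, 0.5), 0.8, kernel_binomial(0.9))
  expect_true(all(validate_assumptions(env_law(ok))$status == "pass"))
  expect_error(env_state("bad", c(0.5, 0.6), 0.8), "sum to 1")
})

test_that("environment sampling is reproducible and matches the law", {
  one <- env_law(th1)
  expect_equal(as.integer(sample_environment_sequence(one, 5)),
               rep(1L, 5))
  two <- env_law(list(th1, env_state("b", c(0.2, 0.2, 0.6), 0.8)), c(1, 0))
  expect_equal(as.integer(sample_environment_sequence(two, 3)), rep(1L, 3))
  half <- env_law(list(th1, env_state("b", c(0.2, 0.2, 0.6), 0.8)),
                  c(0.5, 0.5))
  s <- sample_environment_sequence(half, 1e5, seed = 42)
  expect_lt(abs(mean(s == 1L) - 0.5), 0.01)
  s2 <- sample_environment_sequence(half, 1e5, seed = 42)
  expect_identical(as.integer(s), as.integer(s2))
})
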