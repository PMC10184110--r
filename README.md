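# cbre — controlled branching with infection thinning in random environments

`cbre` is an R package for a discrete-generation population model in which
three mechanisms are all driven by one i.i.d. environmental sequence
ξ₀, ξ₁, …:

* **random reproduction** — each individual alive in generation *n* would
  produce offspring according to a finite pmf {P_r(ξₙ)};
* **infection thinning** — each individual independently survives a viral
  infection with probability α(ξₙ); an infected individual (indicator
  I = 0) leaves no offspring;
* **random control** — out of Zₙ individuals present, a random number
  φₙ(Zₙ) with conditional law Q(ξₙ; Zₙ, ·) actually participates in
  reproduction (emigration, immigration, binomial participation, or any
  tabulated rule).

The population evolves as

    Z_{n+1} = Σ_{j=1..φₙ(Zₙ)} X_{nj} · I_{nj},

a Markov chain in the random environment with one-step law equal to the
Q-mixture of convolution powers of the thinned offspring pmf
(pgf `1 − α + α f_θ(s)`). The package provides, for any finite environment
law:

* **exact transition machinery** — `one_step_pmf()`, conditional moments
  `E(Z_{n+1}|Zₙ=i) = i·m·α·ε(θ,i)` and the matching variance formula, and
  exact quenched distribution propagation with explicitly tracked
  truncation tails;
* **seeded simulation** — vectorised trajectory/ensemble sampling in two
  distributionally identical modes (per-individual thinning vs. compound
  survivor counts);
* **extinction analysis** — the annealed certain-extinction criterion
  `E[log(η N₀ α(ξ₀) f′(1))] ≤ 0` with its numerically certified
  monotonicity hypothesis, the nested pgf lower-bound iteration μₙ for the
  quenched extinction probability, and Monte-Carlo extinction frequencies
  with Wilson intervals;
* **normalized-limit diagnostics** — the normalizers
  Sₙ = N₀·Π m α ε(ξ_k) and Iₙ (with ε₁), the supermartingale Ŵₙ = Zₙ/Sₙ
  and submartingale W̄ₙ = Zₙ/Iₙ, their one-step ratio checks, the exact
  mean identity E(Ŵ_{n+1}) = 1 − Σ E(Ŵ_k ε_{Z_k}/ε), the second-moment
  bound, nondegeneracy and L¹ condition certificates with hull-based
  envelope functions, and the r_k mean-deviation statistic.

## Worked example

A harsh environment: offspring {0: 0.2, 1: 0.2, 2: 0.6} (mean m = 1.4),
infection survival α = 0.8, and one potential emigrant per generation
(E uniform on {0, 1}), started from N₀ = 2:

```r
library(cbre)
law <- env_law(env_state("harsh", c(0.2, 0.2, 0.6), alpha = 0.8,
                         control = kernel_emigration(c(0.5, 0.5))))
state_summaries(law$states[[1]])
#> <state_summaries> harsh
#>   m = 1.4, m2 = 2.6, alpha = 0.8, Var(XI) = 0.8256
#>   eps: inf 0.5, sup 1 (nondecreasing in k); delta2_sup 0.25; eta 1

one_step_pmf(law$states[[1]], 2)
#> <sized_pmf> support 0..4, tail_mass 0
#>        0  0.2448
#>        1  0.1376
#>        2  0.4256
#>        3  0.0768
#>        4  0.1152

extinction_criterion(law, N0 = 2)
#> <extinction_criterion_report> N0 = 2
#>   harsh      log(eta N0 alpha m) = +0.806476  monotonicity TRUE
#>   expectation +0.806476 -> criterion_positive

mc <- mc_extinction_probability(law, N0 = 2, n_max = 200, reps = 10000, seed = 42)
#> MC extinction frequency 0.9249 (95% CI 0.9196-0.9299)

iterate_mu(law, rep(1L, 300), N0 = 2)
#> <mu_iteration> 189 iterate(s), converged
#>   limit estimate (lower bound for q): 0.5625
```

Reading the numbers: the thinned mean growth αm = 1.12 exceeds 1, so the
certain-extinction criterion is positive and silent. The pgf lower bound
0.5625 = 0.75² is the extinction probability the process would have with
full participation; the random emigration pushes the actual extinction
frequency up to ≈ 0.92 — the gap is exactly what the control function
costs the population.

Six built-in scenarios (`builtin_scenarios()`) cover the critical,
subcritical, supercritical, mixed-environment, emigration and α = 1
reduction regimes; `scenario_selftest()` re-derives every annotated
expectation. A thin command-line front end over the same functions ships
in `inst/cli/cbre.R` (subcommands `scenario list`, `simulate`,
`transition`, `extinction`, `limits`, `selftest`).

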