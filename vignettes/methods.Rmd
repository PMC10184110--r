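---
title: "Methods: controlled branching with infection thinning in random environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: controlled branching with infection thinning in random environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbre)
```

## The model

One i.i.d. environmental sequence $\vec\xi = \{\xi_0, \xi_1, \dots\}$ over a
finite state space drives three mechanisms at once. Given the state
$\xi_n = \theta$ of generation $n$:

* each individual $j$ would produce $X_{nj}$ offspring with pmf
  $P_r(\theta)$ (finite support);
* each individual carries an infection indicator $I_{nj} \sim
  \mathrm{Bernoulli}(\alpha(\theta))$; $I = 0$ means death by infection and
  no offspring;
* out of $Z_n$ individuals present, a random control function selects
  $\phi_n(Z_n)$ participants, with conditional law $Q(\theta; Z_n, \cdot)$.

The next generation is $Z_{n+1} = \sum_{j=1}^{\phi_n(Z_n)} X_{nj} I_{nj}$,
and given $\vec\xi$ all three ingredients are conditionally independent.
The process is a Markov chain in the random environment; because the
thinned offspring $X \cdot I$ of one participant has pgf
$1 - \alpha + \alpha f_\theta(s)$, the one-step law at size $i$ is the
$Q(\theta; i, \cdot)$-mixture of convolution powers of the thinned
offspring pmf. `one_step_pmf()` computes exactly that; a brute-force
enumeration over all participant configurations survives in the test suite
as the independent oracle on tiny instances.

The scalar summaries that every result uses are $m(\theta) = E X$,
$m_2(\theta) = E X^2$, the participation rate
$\varepsilon(\theta, k) = E\phi(k)/k$ with supremum
$\varepsilon(\theta)$ and infimum $\varepsilon_1(\theta)$ over $k \ge 1$,
the control variance $\delta^2(\theta, k) = \mathrm{Var}\,\phi(k)$ with its
supremum, and the minimal deterministic dominating ratio
$\eta(\theta) = \sup_k \max\text{-support}(\phi(k))/k$. The conditional
moments are
$E(Z_{n+1}\mid Z_n = i, \theta) = i\, m\, \alpha\, \varepsilon(\theta, i)$
and
$\mathrm{Var}(Z_{n+1}\mid Z_n = i, \theta) =
i\, \varepsilon(\theta, i)\,\mathrm{Var}(XI) +
m^2 \alpha^2 \delta^2(\theta, i)$; both are verified against the exact
kernel at tolerance $10^{-9}$ plus a truncation correction.

### Conventions at the boundary

* **Extinction is absorbing.** $Q(\theta; 0, 0) = 1$ for every kernel, and
  the $\varepsilon$-summaries are taken over $k \ge 1$ only: the rate at
  $k = 0$ would be $0/0$, and the extinction event is exactly
  $\{Z_n = 0\}$.
* **Reduction cases are admitted.** The non-triviality assumptions
  ($0 < P_0 + P_1 < 1$, $0 < Q(k,k) < 1$, $0 < \alpha < 1$) are checked by
  `validate_assumptions()` as *warnings*, never errors, because the
  classical reductions — identity control, $\alpha = 1$ — are precisely
  the oracles that tie the model back to classical (thinned)
  Galton–Watson and environment-driven branching processes. $\alpha = 0$
  is excluded at the type level ($\alpha \in (0, 1]$); total reproductive
  failure can be expressed through the offspring pmf instead.
* **Total emigration is allowed.** Kernels may put mass on
  $\phi(i) = 0$ for $i > 0$; the transition formula handles $k = 0$
  naturally as a point mass at 0.
* **$\eta$ is the minimal deterministic dominator.** Any i.i.d. sequence
  dominating $\phi_n(k)/k$ works in the extinction bound; we use the
  per-state $\sup_k \max\text{-support}(\phi(k))/k$, which is a function
  of $\xi_n$ and hence i.i.d. It is overridable (`eta_override` in
  `iterate_mu()`, `eta` in `check_monotonicity()`) for users who want a
  looser random dominator; $\eta = \infty$ (possible for tabulated
  kernels) disables the criterion with an explicit
  `"theorem_inapplicable"`.

## Extinction analysis

The certain-extinction criterion evaluates
$E[\log(\eta\, N_0\, \alpha(\xi_0) f'_{\xi_0}(1))]$ exactly over the finite
environment law (never by sampling). Two hypotheses gate the conclusion:
$\eta$ finite, and strict monotonicity of
$g(s) = (1 - (1-\alpha+\alpha f(s))^{\eta N_0})/(1 - s)$ on $(0, 1]$. The
monotonicity check evaluates $g$ on a uniform grid (default $10^4$ points)
completed by the l'Hôpital limit $\eta N_0 \alpha f'(1)$ at $s \to 1$; a
finite grid is a numerical certificate, not a symbolic proof, and the
report says so. $N_0$ sits inside the logarithm exactly as the criterion
states, so certain extinction can depend on the initial size; the report
carries the $N_0$ at which the sign flips.

The lower-bound iteration $\mu_n$ composes the per-generation maps
$s \mapsto (1-\alpha+\alpha f(s))^{\eta}$ innermost-first at $s = 0$, with
the outer exponent $\eta_0 N_0$. Exponents may be non-integral (real
powers). A constant environment sequence is detected and iterated forward
in $O(n)$; a varying sequence is recomputed backward per prefix,
$O(n^2)$, with early stopping when successive iterates differ by less
than $10^{-12}$. Critical cases converge like $c/n$ and are reported
unconverged rather than extrapolated. The limit lower-bounds the quenched
extinction probability; at matched horizons, $\mu_n$ lower-bounds
$P(Z_n = 0 \mid \vec\xi)$, which is what the Monte-Carlo consistency test
uses (with identity control, $\eta N_0 = 1$ makes the bound an equality —
another oracle).

## Normalized processes

With $S_n = N_0 \prod_{k<n} m\alpha\varepsilon(\xi_k)$ and $I_n$ built
from $\varepsilon_1$, the processes $\hat W_n = Z_n/S_n$ (supermartingale,
one-step ratio $\varepsilon(\theta, i)/\varepsilon(\theta) \le 1$) and
$\bar W_n = Z_n/I_n$ (submartingale, ratio
$\varepsilon(\theta, i)/\varepsilon_1(\theta) \ge 1$) are computed in log
space throughout; after extinction both are exact zeros, avoiding $0/0$.
If $\varepsilon_1 = 0$ for a reachable state, $I_n$ is identically zero
and the package refuses $\bar W$ with an explicit error naming the state.

Three families of finite-$n$ facts are checked numerically:

* **Mean identity.** $E(\hat W_{n+1}) = 1 - \sum_{k \le n}
  E(\hat W_k \varepsilon_{Z_k}(\xi_k)/\varepsilon(\xi_k))$ is exact; the
  per-path statistic has mean exactly 1, and `mean_identity_check()`
  verifies it to four Monte-Carlo standard errors.
* **Second-moment bound.** $E(\hat W_{n+1}^2) \le 1 + \sum_i
  E[m_2/(S_i\, m^2 \alpha \varepsilon)] + \sum_i
  E[\delta^2/(S_i^2 \varepsilon^2)]$. For an i.i.d. finite law the
  annealed expectations factorise
  ($E[S_i^{-p} g(\xi_i)] = N_0^{-p} E[(m\alpha\varepsilon)^{-p}]^i E[g]$),
  so the bound and all hypothesis series of the convergence theorems are
  computed *exactly* for any finite law, single- or multi-state. A
  supremum control variance of $+\infty$ (binomial participation) makes
  the bound honestly inapplicable.
* **Condition certificates.** Series/product hypotheses are summarised by
  a ratio test over the last 10 computed terms (ratios $< 0.999$
  converging, $> 1.001$ diverging, else inconclusive), with one
  refinement: terms bounded away from zero with ratio $\approx 1$ are
  classified diverging, since divergence is then certain. Any finite
  computation is a certificate about the computed horizon, not a proof.

### Envelope functions

The nondegeneracy and $L^1$ conditions need envelopes: a nondecreasing
$\varphi$ with $x\varphi(x)$ convex lying below
$\varepsilon(\theta, k)$ at integers, and a nonincreasing $\psi$ with
$x\psi(x)$ concave lying above the deviation statistic
$r_k = k^{-1} E|Z' - k\varepsilon_1 m \alpha|$. Their existence is
non-constructive, so the package builds defaults from the hull of the
points $(k,\, k a_k)$ — lower convex hull for $\varphi$, upper concave
hull for $\psi$ — extended linearly beyond the probe horizon with the last
hull slope and constant on $(0, 1]$. This construction satisfies the shape
and bounding requirements by design; both are still verified numerically
on a grid, and user-supplied envelopes are accepted. The linear tail makes
the default $\psi$ conservative: it cannot certify convergence of the
$L^1$ series when that convergence relies on $r_k \to 0$ beyond the probe
horizon, only a decaying user-supplied $\psi$ can.

A fact worth recording: $r_k$ is **not** monotone in general. Because it
is centred at $k \varepsilon_1 m \alpha$ while the conditional mean is
$k \varepsilon(k) m \alpha$, the law of large numbers forces
$r_k \to (\varepsilon - \varepsilon_1) m \alpha$ whenever the
participation rate varies with $k$; for the emigration scenario the exact
sequence dips and then rises toward $1.2$. The nonincreasing-$r_k$
hypothesis of the $L^1$ result therefore fails for that kernel, and
`l1_condition()` reports `"theorem_inapplicable"` — the honest verdict.

## Simulation design

Sampling is generation-major and vectorised across replicates. A sum of
$s$ i.i.d. offspring is drawn by the multinomial decomposition
(sequential conditional binomials over the offspring categories), so cost
per generation is proportional to the number of categories, not the
population size. Two modes are exposed and tested for equality in
distribution: `per_individual` (multinomial over the thinned pmf, with
survivors recovered from the zero class) and `compound` (binomial
survivors, then offspring), the default.

* **Seeding.** A single master seed drives an ensemble; runs are
  bit-reproducible given the seed. `simulate_path()` keeps a per-path seed
  so any single trajectory is reproducible in isolation. We chose one
  vectorised stream over per-replicate counter streams deliberately: in R
  the vectorised engine is two orders of magnitude faster, and ensemble
  reproducibility is at the level users actually rerun.
* **Population cap.** Supercritical paths grow geometrically; a path
  exceeding the cap (default $10^8$) is frozen with an explicit
  `overflow` status, never silently clipped. Frozen paths are alive for
  extinction purposes, which is the correct accounting.
* **Very large sizes.** Binomial draws with size beyond $2^{30}$ use a
  rounded, clamped Gaussian approximation (R's `rbinom` cannot return
  counts above the integer maximum); at those sizes the relative error is
  below $10^{-4}$. Only long-horizon diagnostics on strongly supercritical
  scenarios reach this branch.

## Numerical choices

* Probabilities are doubles; pmf normalisation drift up to $10^{-12}$ is
  renormalised silently, drift above $10^{-9}$ is an error — never a
  silent fix.
* Convolution is direct (not FFT) over the sparser operand, keeping the
  $10^{-12}$ exactness the transition oracle demands; convolution powers
  use binary exponentiation. Truncation at `J_max` (default 4096) is
  tracked as an explicit tail mass; since convolution never moves mass to
  a smaller index, retained entries are exact and the deficiency from 1
  is a valid tail bound, monotone along propagation. Moment cross-checks
  use the truncation-aware tolerance $10^{-9} + J_{\max} \cdot
  \text{tail}$.
* Variances use the centred form $\sum (j - \mu)^2 p_j$ — the raw-moment
  form loses digits at large sizes.
* Supremum/infimum participation rates come from closed forms for the
  built-in kernel families; tabulated kernels are scanned over
  $k \le K_{\text{analysis}}$ (default 512) and flagged numeric.

## Scenarios and what the tests show

The built-in scenarios fix the study conditions: a critical state
(offspring mean 1.25, $\alpha = 0.8$, thinned growth exactly 1), its
subcritical variant ($\alpha = 0.72$, growth 0.9), a supercritical state
(growth 1.12, classical extinction probability 0.75), a two-state mixture
under binomial participation 0.9, a strongly supercritical emigration
scenario (offspring mean 3, one potential emigrant, $N_0 = 2$), and the
$\alpha = 1$ reduction. Monte-Carlo checks use $10^4$–$10^5$ replicates
at horizons 15–300, and exact propagation runs to generation 10 with tail
mass zero; these sizes put 3–4 standard errors well inside the asserted
tolerances.

Passing tests show that the implementation reproduces the exact
finite-state mathematics and that the sampler agrees with the exact laws
at those sizes. They do not show anything about infinite environment
spaces, offspring laws with unbounded support (a user must truncate),
non-i.i.d. (stationary-ergodic) environments, convergence *rates*, or
central-limit behaviour — all outside the package's scope. Surviving-path
diagnostics condition on survival by rejection and are biased at small
horizons; the package labels them diagnostic-only.
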