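#' Control kernels
#'
#' A control kernel is the conditional law `Q(theta; k, .)` of the number of
#' individuals, out of `k` present, that participate in reproduction.  State
#' 0 is always absorbing: `Q(theta; 0, 0) = 1`.  Built-in families:
#'
#' * `kernel_identity()` - every individual participates, `phi(k) = k`.
#' * `kernel_binomial(p)` - independent participation, `phi(k) ~ Binomial(k, p)`.
#' * `kernel_emigration(removals)` - a random number `E` of individuals
#'   emigrates before reproduction, `phi(k) = max(k - E, 0)`; `removals` is
#'   the pmf of `E` over `0..E_max` (index 1 is `E = 0`).
#' * `kernel_immigration(additions)` - a random number `M` of immigrants
#'   joins reproduction, `phi(k) = k + M`; `additions` is the pmf of `M`.
#' * `kernel_tabulated(tab)` - explicit pmfs: `tab[[k]]` is the mass vector
#'   of `phi(k)` over `0..length-1`, supplied for `k = 1..length(tab)`.
#'
#' @param p participation probability in `(0, 1]`.
#' @param removals,additions probability vectors over counts `0, 1, ...`.
#' @param tab list of probability vectors, indexed by current size `k`.
#' @return an object of class `control_kernel`.
#' @name control_kernels
NULL

new_kernel <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "control_kernel")
}

check_prob_vec <- function(p, what) {
  if (!is.numeric(p) || length(p) < 1L || any(p < 0))
    stop(sprintf("%s must be a nonnegative probability vector", what))
  if (abs(sum(p) - 1) > 1e-9)
    stop(sprintf("%s does not sum to 1 (drift %.3g > 1e-9)", what, abs(sum(p) - 1)))
  if (abs(sum(p) - 1) > 1e-12) p / sum(p) else p
}

#' @rdname control_kernels
#' @export
kernel_identity <- function() new_kernel("identity")

#' @rdname control_kernels
#' @export
kernel_binomial <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p <= 1)
  new_kernel("binomial_thinning", p = p)
}

#' @rdname control_kernels
#' @export
kernel_emigration <- function(removals) {
  removals <- check_prob_vec(removals, "removals pmf")
  new_kernel("random_emigration", removals = removals)
}

#' @rdname control_kernels
#' @export
kernel_immigration <- function(additions) {
  additions <- check_prob_vec(additions, "additions pmf")
  new_kernel("random_immigration", additions = additions)
}

#' @rdname control_kernels
#' @export
kernel_tabulated <- function(tab) {
  stopifnot(is.list(tab), length(tab) >= 1L)
  tab <- lapply(seq_along(tab), function(k)
    check_prob_vec(tab[[k]], sprintf("tabulated pmf for k = %d", k)))
  new_kernel("tabulated", tab = tab)
}

#' @export
print.control_kernel <- function(x, ...) {
  cat("<control_kernel>", x$kind)
  if (x$kind == "binomial_thinning") cat(" p =", x$p)
  if (x$kind == "random_emigration") cat(" E_max =", length(x$removals) - 1L)
  if (x$kind == "random_immigration") cat(" M_max =", length(x$additions) - 1L)
  if (x$kind == "tabulated") cat(" k <=", length(x$tab))
  cat("\n")
  invisible(x)
}

#' Conditional participation pmf Q(theta; k, .)
#'
#' @param kernel a [control_kernels] object.
#' @param k current population size (non-negative integer).
#' @return numeric mass vector over participant counts `0..max`.
#' @export
kernel_pmf <- function(kernel, k) {
  stopifnot(inherits(kernel, "control_kernel"), k >= 0, k == as.integer(k))
  if (k == 0) return(1)  # extinction absorbing by convention
  switch(kernel$kind,
    identity = c(numeric(k), 1),
    binomial_thinning = stats::dbinom(0:k, k, kernel$p),
    random_emigration = {
      e <- kernel$removals
      out <- numeric(k + 1L)
      for (E in seq_along(e) - 1L) {
        i <- max(k - E, 0L)
        out[i + 1L] <- out[i + 1L] + e[E + 1L]
      }
      out
    },
    random_immigration = {
      a <- kernel$additions
      c(numeric(k), a)
    },
    tabulated = {
      if (k > length(kernel$tab))
        stop(sprintf("tabulated kernel has no pmf for k = %d", k))
      kernel$tab[[k]]
    },
    stop("unknown kernel kind: ", kernel$kind)
  )
}

# largest participant count phi(k) can take
kernel_max_support <- function(kernel, k) {
  if (k == 0) return(0L)
  switch(kernel$kind,
    identity = k,
    binomial_thinning = k,
    random_emigration = {
      emin <- min(which(kernel$removals > 0)) - 1L
      max(k - emin, 0L)
    },
    random_immigration = k + max(which(kernel$additions > 0)) - 1L,
    tabulated = {
      p <- kernel_pmf(kernel, k)
      max(which(p > 0)) - 1L
    })
}

# E[phi(k)] / k and Var(phi(k)) with closed forms where available
kernel_eps_k <- function(kernel, k) {
  stopifnot(all(k >= 1))
  switch(kernel$kind,
    identity = rep(1, length(k)),
    binomial_thinning = rep(kernel$p, length(k)),
    random_emigration = {
      e <- kernel$removals
      ev <- vapply(k, function(kk)
        sum(pmin(seq_along(e) - 1, kk) * e), numeric(1))
      (k - ev) / k
    },
    random_immigration = {
      em <- sum((seq_along(kernel$additions) - 1) * kernel$additions)
      (k + em) / k
    },
    tabulated = vapply(k, function(kk) {
      p <- kernel_pmf(kernel, kk)
      sum((seq_along(p) - 1) * p) / kk
    }, numeric(1)))
}

kernel_delta2_k <- function(kernel, k) {
  stopifnot(all(k >= 1))
  var_of <- function(p) {
    j <- seq_along(p) - 1
    mu <- sum(j * p)
    sum((j - mu)^2 * p)  # centered form: no cancellation at large k
  }
  switch(kernel$kind,
    identity = rep(0, length(k)),
    binomial_thinning = k * kernel$p * (1 - kernel$p),
    random_emigration = vapply(k, function(kk) var_of(kernel_pmf(kernel, kk)),
                               numeric(1)),
    random_immigration = rep(var_of(kernel$additions), length(k)),
    tabulated = vapply(k, function(kk) var_of(kernel_pmf(kernel, kk)),
                       numeric(1)))
}

# vectorised draw of phi given sizes z (all under the same kernel)
kernel_draw <- function(kernel, z) {
  n <- length(z)
  out <- numeric(n)
  alive <- z > 0
  if (!any(alive)) return(out)
  za <- z[alive]
  out[alive] <- switch(kernel$kind,
    identity = za,
    binomial_thinning = rbinom_big(length(za), za, kernel$p),
    random_emigration = {
      e <- kernel$removals
      E <- sample.int(length(e), length(za), replace = TRUE, prob = e) - 1L
      pmax(za - E, 0)
    },
    random_immigration = {
      a <- kernel$additions
      M <- sample.int(length(a), length(za), replace = TRUE, prob = a) - 1L
      za + M
    },
    tabulated = {
      res <- numeric(length(za))
      for (kk in unique(za)) {
        p <- kernel_pmf(kernel, kk)
        sel <- za == kk
        res[sel] <- sample.int(length(p), sum(sel), replace = TRUE, prob = p) - 1L
      }
      res
    })
  out
}
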