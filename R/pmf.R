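#' Finite probability vector over population sizes
#'
#' A `sized_pmf` stores a probability mass function over population sizes
#' `0..J_max` together with the probability mass known to lie beyond `J_max`
#' (an upper bound on what truncation discarded).  Truncation is always
#' tracked explicitly and never silently renormalized.
#'
#' @param probs numeric vector; `probs[j + 1]` is the mass at size `j`.
#' @param tail_mass probability mass beyond the last index (default 0).
#' @return an object of class `sized_pmf`.
#' @export
sized_pmf <- function(probs, tail_mass = 0) {
  stopifnot(is.numeric(probs), length(probs) >= 1L)
  if (any(probs < -1e-12)) stop("sized_pmf: negative probabilities")
  probs <- pmax(probs, 0)
  if (tail_mass < -1e-12) stop("sized_pmf: negative tail_mass")
  tail_mass <- max(tail_mass, 0)
  tot <- sum(probs) + tail_mass
  if (abs(tot - 1) > 1e-9)
    stop(sprintf("sized_pmf: total mass %.12g drifts from 1 beyond 1e-9", tot))
  structure(list(probs = probs, tail_mass = tail_mass), class = "sized_pmf")
}

#' @export
print.sized_pmf <- function(x, max_rows = 12L, ...) {
  supp <- which(x$probs > 0) - 1L
  cat("<sized_pmf> support 0..", length(x$probs) - 1L,
      ", tail_mass ", format(x$tail_mass), "\n", sep = "")
  show <- utils::head(supp, max_rows)
  for (j in show)
    cat(sprintf("  %6d  %.10g\n", j, x$probs[j + 1L]))
  if (length(supp) > max_rows) cat("  ...\n")
  invisible(x)
}

# mass at exact sizes (vectorised over j)
pmf_at <- function(pmf, j) {
  out <- numeric(length(j))
  ok <- j >= 0 & j < length(pmf$probs)
  out[ok] <- pmf$probs[j[ok] + 1L]
  out
}

#' Mean of a truncated pmf
#'
#' Mean over the retained support; the truncation error is at most
#' `tail_mass` times the (unknown) sizes beyond `J_max`, so callers
#' compare with tolerance `1e-9 + J_max * tail_mass` style corrections.
#' @param pmf a [sized_pmf].
#' @return numeric mean of the retained mass.
#' @export
pmf_mean <- function(pmf) {
  j <- seq_along(pmf$probs) - 1
  sum(j * pmf$probs)
}

#' Variance of a truncated pmf
#' @param pmf a [sized_pmf].
#' @return numeric variance of the retained mass.
#' @export
pmf_var <- function(pmf) {
  j <- seq_along(pmf$probs) - 1
  m <- sum(j * pmf$probs)
  sum((j - m)^2 * pmf$probs)
}

# direct O(n*m) convolution of two nonnegative mass vectors, truncated at
# length cap; returns list(v, lost). Direct (not FFT) convolution keeps
# exactness at the 1e-12 tolerances the transition-law checks use.
conv_trunc <- function(a, b, cap) {
  # iterate over the sparser/shorter operand; each nonzero entry contributes
  # one vectorised shifted add
  if (sum(b > 0) < sum(a > 0)) { tmp <- a; a <- b; b <- tmp }
  la <- length(a); lb <- length(b)
  out_len <- min(la + lb - 1L, cap)
  v <- numeric(out_len)
  for (i in seq_len(la)) {
    ai <- a[i]
    if (ai == 0) next
    jmax <- min(lb, out_len - i + 1L)
    if (jmax >= 1L) {
      idx <- i:(i + jmax - 1L)
      v[idx] <- v[idx] + ai * b[seq_len(jmax)]
    }
  }
  list(v = v, lost = max(sum(a) * sum(b) - sum(v), 0))
}

#' k-fold convolution power of a pmf
#'
#' Computes the law of a sum of `k` i.i.d. copies of the given size
#' distribution by binary exponentiation of truncated convolutions.  The
#' probability mass pushed beyond `J_max` is accumulated in `tail_mass`.
#'
#' @param pmf a [sized_pmf] (its own tail mass is carried through).
#' @param k non-negative integer number of summands; `k = 0` gives a point
#'   mass at 0.
#' @param J_max truncation cap for the support (default 4096).
#' @return a [sized_pmf] for the k-fold sum.
#' @export
convolve_power <- function(pmf, k, J_max = 4096L) {
  stopifnot(inherits(pmf, "sized_pmf"), k >= 0, k == as.integer(k))
  if (J_max < 0) stop("convolve_power: J_max must be >= 0")
  cap <- as.integer(J_max) + 1L
  if (k == 0) return(sized_pmf(c(1, numeric(0))))
  base <- pmf$probs
  acc <- NULL
  while (k > 0L) {
    if (k %% 2L == 1L) {
      acc <- if (is.null(acc)) base else conv_trunc(acc, base, cap)$v
    }
    k <- k %/% 2L
    if (k > 0L) base <- conv_trunc(base, base, cap)$v
  }
  # convolution never moves mass to a smaller index, so the retained
  # entries are exact and the whole deficiency from 1 is tail mass
  sized_pmf(acc, max(1 - sum(acc), 0))
}

# incremental convolution powers 0..K of a mass vector, truncated at cap
# entries; returns list of mass vectors (tail implicit as 1 - sum).
conv_powers_upto <- function(v, K, cap) {
  out <- vector("list", K + 1L)
  out[[1L]] <- 1
  if (K >= 1L) out[[2L]] <- v
  if (K >= 2L) for (k in 2:K) {
    cv <- conv_trunc(out[[k]], v, cap)
    out[[k + 1L]] <- cv$v
  }
  out
}
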