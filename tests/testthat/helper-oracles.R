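# Brute-force one-step law: explicit enumeration over all participant
# configurations (r_l, d_l) with sum r_l * d_l = j -- the definition the
# convolution implementation must reproduce.  Tractable only for tiny i.
enumerate_one_step <- function(state, i, jmax = 64L) {
  q <- kernel_pmf(state$control, i)
  out <- numeric(jmax + 1L)
  rs <- which(state$offspring > 0) - 1L
  a <- state$alpha
  for (k in seq_along(q) - 1L) {
    qk <- q[k + 1L]
    if (qk == 0) next
    if (k == 0L) { out[1L] <- out[1L] + qk; next }
    # each participant contributes a pair (r, d): offspring r, indicator d
    pairs <- expand.grid(r = rs, d = 0:1)
    pairs$p <- state$offspring[pairs$r + 1L] * a^pairs$d * (1 - a)^(1 - pairs$d)
    combo <- expand.grid(rep(list(seq_len(nrow(pairs))), k))
    for (ci in seq_len(nrow(combo))) {
      rows <- as.integer(combo[ci, ])
      pr <- qk * prod(pairs$p[rows])
      j <- sum(pairs$r[rows] * pairs$d[rows])
      out[j + 1L] <- out[j + 1L] + pr
    }
  }
  out
}

# total-variation distance between an empirical sample of sizes and an
# exact sized_pmf
tv_distance <- function(samples, pmf) {
  jmax <- max(c(samples, length(pmf$probs) - 1L))
  emp <- tabulate(samples + 1L, nbins = jmax + 1L) / length(samples)
  exact <- c(pmf$probs, numeric(jmax + 1L - length(pmf$probs)))
  0.5 * sum(abs(emp - exact)) + 0.5 * pmf$tail_mass
}

# homogeneity chi-square between two samples of counts, pooling sparse bins
two_sample_chisq_p <- function(x, y, min_expected = 5) {
  jmax <- max(c(x, y))
  cx <- tabulate(x + 1L, nbins = jmax + 1L)
  cy <- tabulate(y + 1L, nbins = jmax + 1L)
  keep <- (cx + cy) > 0
  cx <- cx[keep]; cy <- cy[keep]
  # pool from the right until every pooled bin is well filled
  while (length(cx) > 2L &&
         min(utils::tail(cx + cy, 1L)) < 2 * min_expected) {
    n <- length(cx)
    cx[n - 1L] <- cx[n - 1L] + cx[n]; cx <- cx[-n]
    cy[n - 1L] <- cy[n - 1L] + cy[n]; cy <- cy[-n]
  }
  suppressWarnings(stats::chisq.test(rbind(cx, cy))$p.value)
}

# one-generation sample of Z_1 for a single state, via the ensemble engine
sample_one_step <- function(state, i, reps, seed, mode = "compound") {
  law <- env_law(state)
  ens <- quenched_ensemble(law, 1L, N0 = i, reps = reps, seed = seed,
                           mode = mode, keep_paths = TRUE)
  ens$Z_paths[, 2L]
}
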