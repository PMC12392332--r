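# Independent oracles used across the suite.  These re-derive expected
# values by brute force or closed form, independent of the implementation
# paths they check.

# Exact two-sided signed-rank p-value by dynamic programming over the
# distribution of the positive-rank sum (untied integer ranks 1..n).
signed_rank_exact_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vmax <- n * (n + 1) / 2
  counts <- numeric(vmax + 1)  # counts[v + 1] = #assignments with sum v
  counts[1] <- 1
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts)[seq_len(vmax + 1)]
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  lower <- sum(probs[seq_len(v_obs + 1)])
  upper <- sum(probs[(v_obs + 1):(vmax + 1)])
  min(1, 2 * min(lower, upper))
}

# Exact Steel-Dwass oracle for k groups: enumerate all relabelings of the
# pooled sample into the observed group sizes and refer each pair's
# sqrt(2)*|t| to the permutation distribution of the familywise maximum.
pair_sqrt2_abs_t <- function(a, b) {
  s <- steel_dwass_pair_stat(a, b)
  sqrt(2) * abs(s$t_stat)
}

steel_dwass_exact_oracle <- function(groups) {
  stopifnot(length(groups) == 3L)
  sizes <- lengths(groups)
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  obs_stats <- c(
    pair_sqrt2_abs_t(groups[[1]], groups[[2]]),
    pair_sqrt2_abs_t(groups[[1]], groups[[3]]),
    pair_sqrt2_abs_t(groups[[2]], groups[[3]])
  )
  idx <- seq_len(N)
  a_sets <- utils::combn(idx, sizes[1])
  n_b <- choose(N - sizes[1], sizes[2])
  max_stats <- numeric(ncol(a_sets) * n_b)
  pos <- 0L
  for (i in seq_len(ncol(a_sets))) {
    a_idx <- a_sets[, i]
    rest <- setdiff(idx, a_idx)
    b_sets <- utils::combn(rest, sizes[2])
    for (j in seq_len(ncol(b_sets))) {
      b_idx <- b_sets[, j]
      c_idx <- setdiff(rest, b_idx)
      ga <- pooled[a_idx]; gb <- pooled[b_idx]; gc <- pooled[c_idx]
      pos <- pos + 1L
      max_stats[pos] <- max(pair_sqrt2_abs_t(ga, gb),
                            pair_sqrt2_abs_t(ga, gc),
                            pair_sqrt2_abs_t(gb, gc))
    }
  }
  data.frame(
    # inclusive: the standard valid permutation p, P(max >= observed)
    incl = vapply(obs_stats, function(s) mean(max_stats >= s - 1e-9), 0.0),
    # strict: P(max > observed); the atom at the observed value sits between
    strict = vapply(obs_stats, function(s) mean(max_stats > s + 1e-9), 0.0)
  )
}
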