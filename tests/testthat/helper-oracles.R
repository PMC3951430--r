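# Brute-force oracles kept independent of the package implementation.

# Exact two-sided rank-sum p by enumerating all C(n+m, n) group assignments
# of the pooled sample (tie-free data assumed).
enumerate_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  idx <- utils::combn(length(pooled), n)
  U_all <- apply(idx, 2, function(i) sum(r[i]) - n * (n + 1) / 2)
  lower <- mean(U_all <= U_obs)
  upper <- mean(U_all >= U_obs)
  min(1, 2 * min(lower, upper))
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
enumerate_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(V_all <= V_obs), mean(V_all >= V_obs)))
}

# Hypergeometric upper-tail sum by direct enumeration.
enumerate_hyper_tail <- function(k, n, K, N) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Small synthetic chip experiment shared by several tests.
make_noiseless_experiment <- function(seed = 7, n_probesets = 60) {
  truth <- expression_truth(n_probesets = n_probesets, n_hfs_only = 4,
                            n_lesion_only = 3, n_counter = 3,
                            animal_sd = 0, hemi_sd = 0, probe_noise_sd = 0,
                            seed = seed)
  gen_expression_dataset(truth)
}
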