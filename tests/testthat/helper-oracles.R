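# Independent reference implementations used as oracles. These enumerate or
# tally directly from the model definition and share no code with the
# package's scaled/recursive implementations.

# transition probability written straight from the model definition
oracle_trans <- function(k, j, d, rates, pi) {
  exp(-rates[k] * d) * (k == j) + (1 - exp(-rates[k] * d)) * pi[j]
}

# exhaustive path enumeration: exact marginal posteriors, log-likelihood and
# the maximum-probability path for one chain (feasible for K^T <= ~10^5)
oracle_enumerate <- function(emis, d, rates, pi) {
  T <- nrow(emis)
  K <- ncol(emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))[, T:1, drop = FALSE]
  probs <- apply(paths, 1, function(s) {
    p <- pi[s[1]] * emis[1, s[1]]
    if (T > 1) {
      for (t in 2:T) {
        p <- p * oracle_trans(s[t - 1], s[t], d[t - 1], rates, pi) *
          emis[t, s[t]]
      }
    }
    p
  })
  total <- sum(probs)
  gamma <- matrix(0, T, K)
  for (t in seq_len(T)) {
    for (k in seq_len(K)) {
      gamma[t, k] <- sum(probs[paths[, t] == k]) / total
    }
  }
  list(gamma = gamma, loglik = log(total),
       viterbi = paths[which.max(probs), ], max_prob = max(probs),
       path_probs = probs, paths = paths)
}

# direct exact Hardy-Weinberg p-value: sum the conditional probabilities of
# all heterozygote counts at most as probable as the observed one, computing
# each probability from the counting formula (no shared code with hwe_exact_p)
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  prob_h <- function(h) {
    naa <- (n_a - h) / 2
    nbb <- n - naa - h
    exp(lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
          h * log(2) +
          lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1))
  }
  hs <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  ps <- vapply(hs, prob_h, numeric(1))
  sum(ps[ps <= prob_h(n_ab) * (1 + 1e-12)])
}

# small deterministic fit for tests that need a fitted model quickly
quick_sim_fit <- function(target_f = 0.25, n_individuals = 3, n_chr = 4,
                          chr_bp = 5e7, density = 15, seed = 99, ...) {
  cfg <- sim_config(
    n_individuals = n_individuals,
    chromosomes = setNames(rep(chr_bp, n_chr), paste0("chr", seq_len(n_chr))),
    marker_density = density,
    mixing_proportions = mixing_for_autozygosity(target_f),
    seed = seed, ...
  )
  sim <- simulate_dataset(cfg)
  fit <- suppressWarnings(fit_hbd(sim$data))
  list(sim = sim, fit = fit)
}
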