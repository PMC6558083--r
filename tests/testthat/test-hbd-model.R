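# small 2-HBD-class configuration used throughout: 3 states total
cfg3 <- hbd_config(hbd_rates = c(4, 64), nonhbd_rate = 64)

chain_data <- function(geno_row, bp, freq, chrom = "1") {
  geno <- matrix(geno_row, 1, length(geno_row))
  rownames(geno) <- "i1"
  map <- tibble::tibble(chrom = chrom, marker = paste0("m", seq_along(bp)),
                        bp = bp, morgan = bp / 1e8)
  ds <- hbd_data(geno, map)
  freqs <- tibble::tibble(marker = map$marker, freq = freq,
                          maf = pmin(freq, 1 - freq), informative = TRUE)
  list(ds = ds, freqs = freqs)
}

test_that("emission probabilities follow the HBD and Hardy-Weinberg laws", {
  # pure autozygosity forbids heterozygotes
  expect_equal(emission_probability(1, 0.3, 0, "hbd"), 0)
  # non-HBD heterozygote at p = 0.5 is 2pq = 0.5
  expect_equal(emission_probability(1, 0.5, 0.001, "nonhbd"), 0.5)
  # HBD heterozygote arises only through error: e * 2pq
  expect_equal(emission_probability(1, 0.5, 0.001, "hbd"), 0.0005)
  # full laws at a generic p, e
  p <- 0.3; e <- 0.01
  expect_equal(emission_probability(0, p, e, "hbd"),
               (1 - e) * (1 - p) + e * (1 - p)^2)
  expect_equal(emission_probability(2, p, e, "hbd"), (1 - e) * p + e * p^2)
  expect_equal(emission_probability(0:2, p, e, "nonhbd"),
               c((1 - p)^2, 2 * p * (1 - p), p^2))
  # missing genotypes are uninformative in every state
  expect_equal(emission_probability(NA, p, e, "hbd"), 1)
  expect_error(emission_probability(1, 1.2, e, "hbd"), "outside")
})

test_that("transition matrices interpolate identity and the mixing law", {
  pi <- c(0.2, 0.3, 0.5)
  expect_equal(transition_matrix(0, cfg3, pi), diag(3))
  far <- transition_matrix(100, cfg3, pi)
  expect_equal(far, matrix(pi, 3, 3, byrow = TRUE), tolerance = 1e-10)
  # rows sum to 1 for random d, rates, pi
  set.seed(42)
  for (i in 1:20) {
    rr <- sort(runif(2, 0.1, 50))
    cfg <- hbd_config(hbd_rates = rr, nonhbd_rate = runif(1, 50, 3000))
    w <- runif(3); w <- w / sum(w)
    tm <- transition_matrix(runif(1, 0, 2), cfg, w)
    expect_equal(rowSums(tm), rep(1, 3))
    expect_true(all(tm >= 0))
  }
})

test_that("single-marker posteriors are one-step Bayes", {
  cd <- chain_data(2L, bp = 5e6, freq = 0.2)
  pi <- c(0.1, 0.2, 0.7)
  fb <- forward_backward(cd$ds, "i1", cd$freqs, cfg3, pi)
  e <- c(rep(emission_probability(2, 0.2, cfg3$genotype_error, "hbd"), 2),
         emission_probability(2, 0.2, cfg3$genotype_error, "nonhbd"))
  expect_equal(as.vector(fb$gamma), pi * e / sum(pi * e), tolerance = 1e-12)
  expect_equal(fb$loglik, log(sum(pi * e)))
})

test_that("an all-missing chain has log-likelihood 0 and prior-driven posteriors", {
  cd <- chain_data(rep(NA_integer_, 8), bp = seq(1e6, 8e6, by = 1e6),
                   freq = rep(0.4, 8))
  pi <- c(0.25, 0.25, 0.5)
  fb <- forward_backward(cd$ds, "i1", cd$freqs, cfg3, pi)
  expect_equal(fb$loglik, 0)
  expect_equal(as.vector(fb$gamma[1, ]), pi, tolerance = 1e-12)
  # when all classes share one rate the chain marginal stays exactly pi
  cfg_eq <- hbd_config(hbd_rates = c(16, 16 + 1e-9), nonhbd_rate = 16)
  fb2 <- forward_backward(cd$ds, "i1", cd$freqs, cfg_eq, pi)
  expect_equal(fb2$gamma, matrix(pi, 8, 3, byrow = TRUE), tolerance = 1e-6)
})

test_that("forward-backward matches exhaustive path enumeration", {
  set.seed(13)
  for (rep in 1:5) {
    T <- sample(4:6, 1)
    bp <- sort(sample.int(3e7, T))
    g <- sample(c(0:2, NA), T, replace = TRUE)
    freq <- runif(T, 0.05, 0.95)
    cd <- chain_data(g, bp, freq)
    pi <- runif(3); pi <- pi / sum(pi)
    fb <- forward_backward(cd$ds, "i1", cd$freqs, cfg3, pi)
    emis <- cbind(
      emission_probability(g, freq, cfg3$genotype_error, "hbd"),
      emission_probability(g, freq, cfg3$genotype_error, "hbd"),
      emission_probability(g, freq, cfg3$genotype_error, "nonhbd"))
    d <- pmax(diff(bp / 1e8), 1e-8)
    oracle <- oracle_enumerate(emis, d, cfg3$rates, pi)
    expect_lt(max(abs(fb$gamma - oracle$gamma)), 1e-10)
    expect_equal(fb$loglik, oracle$loglik, tolerance = 1e-10)
  }
})

test_that("chromosome processing order does not change the likelihood", {
  set.seed(14)
  bp <- c(sort(sample.int(2e7, 30)), sort(sample.int(2e7, 25)))
  chrom <- rep(c("chr1", "chr2"), c(30, 25))
  g <- sample(0:2, 55, replace = TRUE)
  freq <- runif(55, 0.1, 0.9)
  geno <- matrix(g, 1); rownames(geno) <- "i1"
  mk <- sprintf("m%02d", 1:55)
  ds1 <- hbd_data(geno, tibble::tibble(chrom = chrom, marker = mk, bp = bp,
                                       morgan = bp / 1e8))
  ord <- c(31:55, 1:30)
  morg <- bp / 1e8
  ds2 <- hbd_data(geno[, ord, drop = FALSE],
                  tibble::tibble(chrom = chrom[ord], marker = mk[ord],
                                 bp = .env$bp[ord], morgan = morg[ord]))
  fr1 <- tibble::tibble(marker = mk, freq = freq, informative = TRUE)
  fr2 <- fr1[ord, ]
  pi <- c(0.3, 0.1, 0.6)
  fb1 <- forward_backward(ds1, "i1", fr1, cfg3, pi)
  fb2 <- forward_backward(ds2, "i1", fr2, cfg3, pi)
  expect_equal(fb1$loglik, fb2$loglik, tolerance = 1e-10)
})

test_that("a heterozygous observation never increases the local HBD posterior", {
  set.seed(15)
  for (rep in 1:10) {
    T <- 12
    bp <- sort(sample.int(4e7, T))
    g <- sample(c(0L, 2L), T, replace = TRUE)
    freq <- runif(T, 0.1, 0.9)
    pos <- sample(2:(T - 1), 1)
    g_missing <- g; g_missing[pos] <- NA
    g_het <- g; g_het[pos] <- 1L
    pi <- runif(3); pi <- pi / sum(pi)
    tot_hbd <- function(gg) {
      cd <- chain_data(gg, bp, freq)
      fb <- forward_backward(cd$ds, "i1", cd$freqs, cfg3, pi)
      1 - fb$gamma[pos, 3]
    }
    expect_lte(tot_hbd(g_het), tot_hbd(g_missing) + 1e-12)
  }
})

test_that("EM log-likelihood is non-decreasing and recovers autozygosity", {
  # fully non-HBD individual: estimated F_G below 0.01
  cfg0 <- sim_config(n_individuals = 1,
                     chromosomes = setNames(rep(1e8, 3), paste0("c", 1:3)),
                     marker_density = 100, seed = 101)
  sim0 <- simulate_dataset(cfg0)
  fit0 <- fit_hbd(sim0$data)
  expect_lt(glance(fit0)$f_g, 0.01)
  expect_true(all(diff(fit0$loglik_history[[1]]) > -1e-8))

  # autozygosity 0.25 in the rate-4 class: F_G within 0.05 of realized truth
  cfg1 <- sim_config(n_individuals = 2,
                     chromosomes = setNames(rep(1e8, 10), paste0("c", 1:10)),
                     marker_density = 30,
                     mixing_proportions = mixing_for_autozygosity(0.25),
                     seed = 102)
  sim1 <- simulate_dataset(cfg1)
  fit1 <- suppressWarnings(fit_hbd(sim1$data))
  err <- abs(glance(fit1)$f_g - sim1$truth$autozygosity$autozygosity)
  expect_true(all(err < 0.05))
  for (h in fit1$loglik_history) expect_true(all(diff(h) > -1e-8))
})

test_that("mixing proportions stay on the simplex and posteriors normalise", {
  res <- quick_sim_fit(target_f = 0.15, n_individuals = 2, n_chr = 2,
                       density = 10, seed = 103)
  fit <- res$fit
  expect_equal(unname(rowSums(fit$mixing)), rep(1, 2), tolerance = 1e-10)
  expect_true(all(fit$mixing >= 0))
  for (g in fit$posterior) {
    expect_equal(rowSums(g), rep(1, nrow(g)), tolerance = 1e-8)
    expect_true(all(g >= 0 & g <= 1))
  }
})

test_that("class inbreeding decomposes additively into F_G", {
  res <- quick_sim_fit(target_f = 0.2, n_individuals = 3, n_chr = 3,
                       density = 10, seed = 104)
  ci <- global_and_class_inbreeding(res$fit)
  sums <- tapply(ci$per_class$f, ci$per_class$individual, sum)
  expect_equal(as.numeric(sums[ci$global$individual]),
               unname(ci$global$f_g), tolerance = 1e-10)
  expect_true(all(ci$global$f_g >= 0 & ci$global$f_g <= 1))
  # tidy/glance agree with the decomposition
  td <- tidy(res$fit)
  expect_equal(sum(td$f[td$individual == ci$global$individual[1]]), 1,
               tolerance = 1e-8)
  gl <- glance(res$fit)
  expect_equal(gl$f_g, ci$global$f_g)
})

test_that("impossible observations raise a diagnostic error", {
  # e = 0 makes a heterozygote impossible under an all-HBD prior
  cd <- chain_data(c(0L, 1L), bp = c(1e6, 2e6), freq = c(0.5, 0.5))
  cfg <- hbd_config(hbd_rates = c(4, 8), nonhbd_rate = 8, genotype_error = 0)
  expect_error(forward_backward(cd$ds, "i1", cd$freqs, cfg, c(0.5, 0.5, 0)),
               "impossible")
})

test_that("model configuration is validated", {
  expect_error(hbd_config(hbd_rates = c(4, 2)), "increasing")
  expect_error(hbd_config(genotype_error = 0.7), "genotype_error")
  expect_error(hbd_config(nonhbd_rate = -1), "positive")
})
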