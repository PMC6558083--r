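#' HBD model configuration
#'
#' Parameters of the multi-class homozygosity-by-descent hidden Markov model.
#' The genome is a mosaic of segments from `K` HBD classes plus one non-HBD
#' class; class `k` segments have exponential lengths with rate `R_k` per
#' Morgan, so `R_k` is tied to the number of generations `G` to the common
#' ancestor through `R = 2G` (small rate = long segments = recent inbreeding).
#' The defaults are eleven HBD classes with doubling rates 2, 4, ..., 2048 and
#' a non-HBD class sharing the largest rate; rates are held fixed and only the
#' per-individual mixing proportions are estimated by EM.
#'
#' @param hbd_rates Strictly increasing positive rates for the HBD classes.
#' @param nonhbd_rate Rate of the non-HBD class.
#' @param genotype_error Probability `e` in `[0, 0.5)` that an autozygous
#'   marker shows an ordinary (possibly heterozygous) genotype.
#' @param maf_min Markers with minor-allele frequency below this floor are
#'   treated as uninformative (emission 1 in every state).
#' @param cm_per_mb Genetic-map scaling used when the map lacks genetic
#'   positions.
#' @param em_tol Stop EM when the log-likelihood gain drops below this.
#' @param em_max_iter Iteration cap.
#' @return Object of class `hbd_config`.
#' @export
hbd_config <- function(hbd_rates = 2 * 2^(0:10), nonhbd_rate = 2048,
                       genotype_error = 0.001, maf_min = 0.01, cm_per_mb = 1,
                       em_tol = 1e-6, em_max_iter = 1000L) {
  if (any(diff(hbd_rates) <= 0) || any(hbd_rates <= 0)) {
    abort("hbd_rates must be strictly increasing and positive")
  }
  if (nonhbd_rate <= 0) abort("nonhbd_rate must be positive")
  if (genotype_error < 0 || genotype_error >= 0.5) {
    abort("genotype_error must lie in [0, 0.5)")
  }
  structure(list(hbd_rates = hbd_rates, nonhbd_rate = nonhbd_rate,
                 rates = c(hbd_rates, nonhbd_rate),
                 genotype_error = genotype_error, maf_min = maf_min,
                 cm_per_mb = cm_per_mb, em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter)),
            class = "hbd_config")
}

#' Genotype emission probability
#'
#' Under an HBD state the two haplotypes are copies of one ancestral
#' haplotype, so `P(AA) = (1-e)(1-p) + e(1-p)^2`, `P(AB) = e 2p(1-p)`,
#' `P(BB) = (1-e)p + e p^2` where `p` is the B-allele frequency and `e` the
#' genotyping-error rate; under non-HBD, Hardy-Weinberg proportions apply.
#' Missing genotypes emit probability 1 in every state.
#'
#' @param genotype B-allele dosage 0/1/2 or `NA`.
#' @param p B-allele frequency in `[0, 1]`.
#' @param e Genotyping-error rate.
#' @param state `"hbd"` or `"nonhbd"`.
#' @return Emission probability (vectorised over `genotype` and `p`).
#' @export
emission_probability <- function(genotype, p, e, state = c("hbd", "nonhbd")) {
  state <- match.arg(state)
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("allele frequency p outside [0, 1]")
  if (state == "hbd") {
    out <- ifelse(genotype == 0, (1 - e) * (1 - p) + e * (1 - p)^2,
           ifelse(genotype == 1, e * 2 * p * (1 - p),
                  (1 - e) * p + e * p^2))
  } else {
    out <- ifelse(genotype == 0, (1 - p)^2,
           ifelse(genotype == 1, 2 * p * (1 - p), p^2))
  }
  out[is.na(genotype)] <- 1
  out
}

#' Transition matrix between HBD classes
#'
#' Over a genetic distance `d` (Morgans) the current segment of class `k`
#' survives with probability `exp(-R_k d)`; otherwise a new segment class is
#' drawn from the mixing proportions, so any class can follow any class:
#' `T[k, j] = exp(-R_k d) [k = j] + (1 - exp(-R_k d)) pi_j`.
#'
#' @param d Genetic distance in Morgans, `d >= 0`.
#' @param config An [hbd_config()].
#' @param pi Mixing proportions over all `K + 1` classes.
#' @return `(K+1) x (K+1)` row-stochastic matrix.
#' @export
transition_matrix <- function(d, config, pi) {
  stopifnot(d >= 0, length(pi) == length(config$rates))
  s <- exp(-config$rates * d)
  diag(s) + outer(1 - s, pi)
}

# Emission matrix (markers x K+1 classes) for one individual. HBD classes
# share one emission column; uninformative markers emit 1 everywhere.
build_emissions <- function(g, freqs, config) {
  K <- length(config$hbd_rates)
  p <- freqs$freq
  inf <- freqs$informative & !is.na(p)
  e_hbd <- rep(1, length(g))
  e_non <- rep(1, length(g))
  e_hbd[inf] <- emission_probability(g[inf], p[inf], config$genotype_error, "hbd")
  e_non[inf] <- emission_probability(g[inf], p[inf], config$genotype_error, "nonhbd")
  cbind(matrix(e_hbd, length(g), K), e_non)
}

# Chain structure shared by all individuals: per-chromosome lengths and the
# concatenated adjacent-marker distances in Morgans (floored at 1e-8 so
# duplicate positions cannot produce a zero distance).
chain_structure <- function(map, config) {
  if (!"morgan" %in% names(map)) {
    map$morgan <- map$bp * config$cm_per_mb / 1e8
  }
  chroms <- unique(map$chrom)
  lengths <- integer(length(chroms))
  dlist <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    m <- map$morgan[map$chrom == chroms[i]]
    lengths[i] <- length(m)
    dlist[[i]] <- if (length(m) > 1) pmax(diff(m), 1e-8) else numeric(0)
  }
  list(lengths = lengths, d = unlist(dlist))
}

#' Forward-backward HBD posteriors for one individual
#'
#' Exact scaled forward-backward over each chromosome (chromosomes are
#' independent chains with initial distribution `pi`).
#'
#' @param ds An [hbd_data()].
#' @param individual Individual id (or row index).
#' @param freqs Allele-frequency tibble from [allele_frequencies()].
#' @param config An [hbd_config()].
#' @param pi Mixing proportions over all classes.
#' @return List: `gamma` (markers x K+1 posterior matrix, rows sum to 1),
#'   `loglik`, `entries` (expected segment entries per class).
#' @export
forward_backward <- function(ds, individual, freqs, config = hbd_config(),
                             pi = NULL) {
  i <- if (is.character(individual)) match(individual, rownames(ds$geno)) else individual
  K1 <- length(config$rates)
  if (is.null(pi)) pi <- rep(1 / K1, K1)
  emis <- build_emissions(ds$geno[i, ], freqs, config)
  cs <- chain_structure(ds$map, config)
  cpp_forward_backward(emis, cs$d, cs$lengths, config$rates, pi)
}

#' Fit the multi-class HBD model to every individual
#'
#' Per-individual EM with class rates held fixed: the E-step is scaled
#' forward-backward over all chromosomes; the M-step sets each mixing
#' proportion proportional to the expected number of segment entries into the
#' class (initial-state posterior plus expected switch events). Iterates from
#' a uniform start until the log-likelihood gain falls below `em_tol` or
#' `em_max_iter` is reached (a warning flags non-convergence). Per-iteration
#' log-likelihood is non-decreasing.
#'
#' @param ds An [hbd_data()].
#' @param freqs Allele frequencies from [allele_frequencies()]; computed from
#'   `ds` (with `config$maf_min`) when `NULL`.
#' @param config An [hbd_config()].
#' @return Object of class `hbd_fit`: per-individual mixing proportions,
#'   posteriors, log-likelihood traces, and realized inbreeding; see
#'   [tidy.hbd_fit()], [glance.hbd_fit()], [global_and_class_inbreeding()].
#' @export
fit_hbd <- function(ds, freqs = NULL, config = hbd_config()) {
  stopifnot(inherits(ds, "hbd_data"), inherits(config, "hbd_config"))
  if (is.null(freqs)) freqs <- allele_frequencies(ds, config$maf_min)
  stopifnot(identical(freqs$marker, ds$map$marker))
  cs <- chain_structure(ds$map, config)
  K1 <- length(config$rates)
  ids <- rownames(ds$geno)
  pi0 <- rep(1 / K1, K1)
  res <- purrr::map(seq_along(ids), function(i) {
    emis <- build_emissions(ds$geno[i, ], freqs, config)
    fit <- cpp_fit_em(emis, cs$d, cs$lengths, config$rates, pi0,
                      config$em_tol, config$em_max_iter)
    if (!fit$converged) {
      warn(sprintf("EM did not converge for %s within %d iterations",
                   ids[i], config$em_max_iter))
    }
    fit
  })
  mixing <- do.call(rbind, lapply(res, `[[`, "pi"))
  rownames(mixing) <- ids
  posterior <- lapply(res, `[[`, "gamma")
  names(posterior) <- ids
  structure(list(
    mixing = mixing,
    posterior = posterior,
    entries = do.call(rbind, lapply(res, `[[`, "entries")),
    loglik = tibble(
      individual = ids,
      loglik = vapply(res, `[[`, numeric(1), "loglik"),
      iterations = vapply(res, `[[`, integer(1), "iterations"),
      converged = vapply(res, `[[`, logical(1), "converged")
    ),
    loglik_history = lapply(res, `[[`, "loglik_history"),
    config = config, freqs = freqs, data = ds
  ), class = "hbd_fit")
}

#' @export
print.hbd_fit <- function(x, ...) {
  fg <- global_and_class_inbreeding(x)$global$f_g
  cat(sprintf("<hbd_fit> %d individuals, %d HBD classes (rates %s) + non-HBD\n",
              nrow(x$mixing), length(x$config$hbd_rates),
              paste(x$config$hbd_rates, collapse = ",")))
  cat(sprintf("  F_G: mean %.4f, range [%.4f, %.4f]; %d/%d converged\n",
              mean(fg), min(fg), max(fg), sum(x$loglik$converged),
              nrow(x$loglik)))
  invisible(x)
}

#' Global and per-class inbreeding coefficients
#'
#' The realized inbreeding in class `k` is the genome-wide mean of the
#' posterior mass in that class, `F_k = mean_t gamma_t(k)`; the global
#' coefficient is their sum over the HBD classes,
#' `F_G = sum_k F_k = 1 - mean_t gamma_t(nonHBD)`.
#'
#' @param fit An `hbd_fit`.
#' @return List: `global` (tibble `individual`, `f_g`) and `per_class`
#'   (tibble `individual`, `class`, `rate`, `f`).
#' @export
global_and_class_inbreeding <- function(fit) {
  stopifnot(inherits(fit, "hbd_fit"))
  K <- length(fit$config$hbd_rates)
  fk <- do.call(rbind, lapply(fit$posterior, colMeans))
  per_class <- tibble(
    individual = rep(rownames(fit$mixing), each = K),
    class = rep(seq_len(K), nrow(fit$mixing)),
    rate = rep(fit$config$hbd_rates, nrow(fit$mixing)),
    f = as.vector(t(fk[, seq_len(K), drop = FALSE]))
  )
  global <- tibble(individual = rownames(fit$mixing),
                   f_g = unname(rowSums(fk[, seq_len(K), drop = FALSE])))
  list(global = global, per_class = per_class)
}

#' Tidy an HBD fit: one row per individual and class
#'
#' @param x An `hbd_fit`.
#' @param ... Unused.
#' @return Tibble `individual`, `class`, `rate`, `mixing` (estimated segment
#'   proportion) and `f` (realized inbreeding mass in the class; the non-HBD
#'   row reports the residual `1 - F_G`).
#' @export
tidy.hbd_fit <- function(x, ...) {
  K1 <- length(x$config$rates)
  fk <- do.call(rbind, lapply(x$posterior, colMeans))
  tibble(
    individual = rep(rownames(x$mixing), each = K1),
    class = rep(c(seq_len(K1 - 1), NA_integer_), nrow(x$mixing)),
    rate = rep(x$config$rates, nrow(x$mixing)),
    hbd = rep(c(rep(TRUE, K1 - 1), FALSE), nrow(x$mixing)),
    mixing = as.vector(t(x$mixing)),
    f = as.vector(t(fk))
  )
}

#' One-row-per-individual summary of an HBD fit
#'
#' @param x An `hbd_fit`.
#' @param ... Unused.
#' @return Tibble `individual`, `f_g`, `loglik`, `iterations`, `converged`.
#' @export
glance.hbd_fit <- function(x, ...) {
  dplyr::left_join(global_and_class_inbreeding(x)$global, x$loglik,
                   by = "individual")
}
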