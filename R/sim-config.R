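#' Configuration for the synthetic HBD-mosaic generator
#'
#' Bundles every knob of the simulator. The genome of each simulated diploid
#' individual is tiled, chromosome by chromosome, with segments that are either
#' homozygous-by-descent (HBD, one of `length(class_rates) - 1` age classes) or
#' non-HBD; segment lengths are exponential with class rate `R` per Morgan, so
#' class `k` emulates common ancestors roughly `R_k / 2` generations back.
#' Genotypes are emitted from population allele frequencies with genotyping
#' error, and hemizygous deletions can be injected to produce apparent
#' homozygosity with depressed log R ratio (LRR), mimicking copy-loss regions
#' that array genotyping mistypes as homozygous.
#'
#' @param n_individuals Number of diploid individuals.
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param marker_density Markers per Mb.
#' @param allele_freq_law Function `n -> numeric(n)` drawing reference B-allele
#'   frequencies on (0, 1); draws are truncated to `[0.01, 0.99]`.
#' @param class_rates Positive rates per class, HBD classes first, the non-HBD
#'   class last. Defaults to the eleven doubling rates 2, 4, ..., 2048 plus
#'   2048 for the non-HBD class.
#' @param mixing_proportions Simplex weights over all classes (same length and
#'   order as `class_rates`). Default puts all mass on the non-HBD class.
#' @param genotype_error Probability `e` in `[0, 0.5)` that an autozygous
#'   marker is emitted as an ordinary Hardy-Weinberg draw.
#' @param missing_rate Probability a genotype call is set missing.
#' @param cm_per_mb Genetic-map scaling, centimorgan per megabase.
#' @param n_deletions Hemizygous (copy-number 1) deletions per individual.
#' @param deletion_length_law Function `n -> numeric(n)` drawing deletion
#'   lengths in bp. Default: exponential with mean 600 kb truncated to
#'   \[200 kb, 5 Mb\].
#' @param deletion_placement `"non-hbd"` places deletions in the individual's
#'   non-HBD genome (the configuration under which a hemizygous region
#'   masquerades as a run of homozygosity); `"anywhere"` places them uniformly.
#' @param lrr_del_mean,lrr_del_sd LRR distribution inside deletions (copy
#'   number 1).
#' @param lrr_noise_sd LRR noise at normal (copy-number 2) markers, mean 0.
#' @param baf_noise_sd B-allele-frequency noise, clipped to `[0, 1]`.
#' @param seed Integer seed; a fixed seed makes the whole dataset reproducible.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 2, chromosomes = c(chr1 = 5e7), seed = 1)
#' cfg$class_rates
sim_config <- function(n_individuals = 10,
                       chromosomes = setNames(rep(1e8, 5), paste0("chr", 1:5)),
                       marker_density = 10,
                       allele_freq_law = function(n) runif(n),
                       class_rates = c(2 * 2^(0:10), 2048),
                       mixing_proportions = c(rep(0, 11), 1),
                       genotype_error = 0.001,
                       missing_rate = 0,
                       cm_per_mb = 1,
                       n_deletions = 0,
                       deletion_length_law = function(n) {
                         pmin(pmax(rexp(n, 1 / 6e5), 2e5), 5e6)
                       },
                       deletion_placement = c("non-hbd", "anywhere"),
                       lrr_del_mean = -0.55,
                       lrr_del_sd = 0.20,
                       lrr_noise_sd = 0.15,
                       baf_noise_sd = 0.03,
                       seed = 1L) {
  deletion_placement <- match.arg(deletion_placement)
  if (length(chromosomes) < 1) abort("at least one chromosome is required")
  if (is.null(names(chromosomes)) || anyNA(names(chromosomes))) {
    names(chromosomes) <- paste0("chr", seq_along(chromosomes))
  }
  if (any(chromosomes <= 0)) abort("zero-length chromosome: all lengths must be > 0 bp")
  if (marker_density <= 0) abort("marker_density must be > 0")
  if (length(mixing_proportions) != length(class_rates)) {
    abort("mixing_proportions must have one weight per class rate")
  }
  if (any(class_rates <= 0)) abort("all class rates must be > 0")
  if (any(mixing_proportions < 0) ||
      abs(sum(mixing_proportions) - 1) > 1e-12) {
    abort("mixing_proportions must be a simplex (non-negative, summing to 1)")
  }
  if (genotype_error < 0 || genotype_error >= 0.5) {
    abort("genotype_error must lie in [0, 0.5)")
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      chromosomes = chromosomes,
      marker_density = marker_density,
      allele_freq_law = allele_freq_law,
      class_rates = class_rates,
      mixing_proportions = mixing_proportions,
      genotype_error = genotype_error,
      missing_rate = missing_rate,
      cm_per_mb = cm_per_mb,
      n_deletions = as.integer(n_deletions),
      deletion_length_law = deletion_length_law,
      deletion_placement = deletion_placement,
      lrr_del_mean = lrr_del_mean,
      lrr_del_sd = lrr_del_sd,
      lrr_noise_sd = lrr_noise_sd,
      baf_noise_sd = baf_noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Mixing proportions targeting a given autozygosity level
#'
#' Under the renewal model the long-run autozygous genome fraction is
#' `sum_HBD(pi_k / R_k) / sum_all(pi_j / R_j)` (segment classes weighted by
#' their mean length `1 / R`). This helper returns the two-point mixture
#' (one HBD class plus the non-HBD class) whose expected autozygosity equals
#' `target_f`, which is how simulated cohorts are pinned to inbreeding strata.
#'
#' @param target_f Desired expected autozygous fraction in `[0, 1)`.
#' @param hbd_class Index of the HBD class carrying the mass (default 2, the
#'   rate-4 class, i.e. very recent inbreeding).
#' @param class_rates Full rate vector, non-HBD last.
#' @return Simplex weight vector over all classes.
#' @export
mixing_for_autozygosity <- function(target_f, hbd_class = 2,
                                    class_rates = c(2 * 2^(0:10), 2048)) {
  stopifnot(target_f >= 0, target_f < 1,
            hbd_class >= 1, hbd_class < length(class_rates))
  K1 <- length(class_rates)
  pi <- rep(0, K1)
  if (target_f == 0) {
    pi[K1] <- 1
    return(pi)
  }
  r_h <- class_rates[hbd_class]
  r_n <- class_rates[K1]
  a <- target_f * r_h / ((1 - target_f) * r_n)
  pi[hbd_class] <- a / (1 + a)
  pi[K1] <- 1 - pi[hbd_class]
  pi
}
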