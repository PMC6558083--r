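#' Call-rate quality-control filters
#'
#' Removes markers whose missingness exceeds `max_marker_missing`, then
#' individuals whose missingness (over the retained markers) exceeds
#' `max_ind_missing`. The marker-before-individual order is fixed and part of
#' the contract; removal is triggered by missingness strictly greater than the
#' threshold, i.e. a call rate of at least `1 - threshold` is required to pass.
#'
#' @param ds An [hbd_data()].
#' @param max_ind_missing,max_marker_missing Missingness thresholds in `[0,1]`.
#' @return List with `data` (filtered [hbd_data()]) and `report` (a
#'   [qc_report()]-style list of counts).
#' @export
apply_callrate_filters <- function(ds, max_ind_missing = 0.04,
                                   max_marker_missing = 0.02) {
  stopifnot(inherits(ds, "hbd_data"),
            max_ind_missing >= 0, max_ind_missing <= 1,
            max_marker_missing >= 0, max_marker_missing <= 1)
  n_ind_in <- nrow(ds$geno)
  n_mark_in <- ncol(ds$geno)
  marker_miss <- unname(colMeans(is.na(ds$geno)))
  keep_m <- marker_miss <= max_marker_missing
  geno <- ds$geno[, keep_m, drop = FALSE]
  ind_miss <- rowMeans(is.na(geno))
  keep_i <- ind_miss <= max_ind_missing
  out <- hbd_data(geno[keep_i, , drop = FALSE], ds$map[keep_m, ],
                  ds$individuals[keep_i, ])
  list(
    data = out,
    report = list(
      filter = "call_rate",
      n_markers_in = n_mark_in, n_markers_out = sum(keep_m),
      n_markers_removed = sum(!keep_m),
      n_individuals_in = n_ind_in, n_individuals_out = sum(keep_i),
      n_individuals_removed = sum(!keep_i),
      marker_missingness = tibble(marker = ds$map$marker,
                                  missingness = marker_miss,
                                  removed = !keep_m)
    )
  )
}

#' Exact Hardy-Weinberg test p-value
#'
#' Exact conditional test: given the individual count and allele counts, the
#' p-value sums the probabilities of all heterozygote counts no more probable
#' than the observed one. Monomorphic markers have a single attainable
#' configuration and p = 1.
#'
#' @param n_aa,n_ab,n_bb Genotype counts.
#' @return p-value in `[0, 1]`.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- lfactorial(n) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2) +
    hets * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

#' Hardy-Weinberg equilibrium filter
#'
#' Tests every marker for departure from Hardy-Weinberg proportions with the
#' exact conditional test on the non-missing genotypes pooled across all
#' individuals, and removes markers with `p < alpha`.
#'
#' @param ds An [hbd_data()].
#' @param alpha Removal threshold (strict inequality); `alpha = 0` removes
#'   nothing.
#' @return List with `data` and `report` (including per-marker p-values).
#' @export
hwe_filter <- function(ds, alpha = 0.001) {
  stopifnot(inherits(ds, "hbd_data"))
  pvals <- vapply(seq_len(ncol(ds$geno)), function(j) {
    g <- ds$geno[, j]
    hwe_exact_p(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  keep <- !(pvals < alpha)
  out <- hbd_data(ds$geno[, keep, drop = FALSE], ds$map[keep, ],
                  ds$individuals)
  list(
    data = out,
    report = list(
      filter = "hwe",
      n_markers_in = ncol(ds$geno), n_markers_out = sum(keep),
      n_markers_removed = sum(!keep),
      n_individuals_in = nrow(ds$geno), n_individuals_out = nrow(ds$geno),
      n_individuals_removed = 0L,
      hwe = tibble(marker = ds$map$marker, p_hwe = pvals, removed = !keep)
    )
  )
}

#' Per-marker B-allele frequencies with a MAF floor
#'
#' Frequencies are computed from non-missing calls. Markers with minor-allele
#' frequency below `maf_min` are flagged uninformative rather than removed:
#' the HBD model emits probability 1 for them in every state, so genomic
#' coordinates (and therefore ROH lengths) are unaffected by the floor.
#' Markers with no non-missing call get an undefined frequency and are
#' likewise flagged (with a warning).
#'
#' @param ds An [hbd_data()].
#' @param maf_min Minor-allele-frequency floor.
#' @return Tibble `marker`, `freq` (B-allele), `maf`, `informative`.
#' @export
allele_frequencies <- function(ds, maf_min = 0.01) {
  stopifnot(inherits(ds, "hbd_data"))
  nb <- unname(colSums(ds$geno, na.rm = TRUE))
  ntot <- 2 * unname(colSums(!is.na(ds$geno)))
  freq <- ifelse(ntot > 0, nb / ntot, NA_real_)
  if (any(ntot == 0)) {
    warn(sprintf("%d marker(s) with all calls missing: frequency undefined, flagged uninformative",
                 sum(ntot == 0)))
  }
  maf <- pmin(freq, 1 - freq)
  tibble(marker = ds$map$marker, freq = freq, maf = maf,
         informative = !is.na(freq) & maf >= maf_min)
}

#' Combine per-filter QC reports into one summary tibble
#'
#' @param ... Reports from [apply_callrate_filters()] / [hwe_filter()] (the
#'   `report` elements or the whole result lists).
#' @return Tibble with one row per filter and the in/out/removed counts for
#'   both axes.
#' @export
qc_report <- function(...) {
  reps <- lapply(list(...), function(x) if (!is.null(x$report)) x$report else x)
  dplyr::bind_rows(lapply(reps, function(r) {
    tibble(filter = r$filter,
           n_markers_in = r$n_markers_in, n_markers_out = r$n_markers_out,
           n_markers_removed = r$n_markers_removed,
           n_individuals_in = r$n_individuals_in,
           n_individuals_out = r$n_individuals_out,
           n_individuals_removed = r$n_individuals_removed)
  }))
}
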