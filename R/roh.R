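# run-length segments of a logical vector -> (start_idx, end_idx) pairs
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Seed-and-extend ROH marker runs from total-HBD posteriors
#'
#' The segment rule applied to one chromosome: a candidate run is any maximal
#' stretch of markers with total HBD probability above `extend_prob`, and it
#' becomes a segment only if it contains at least one seed marker above
#' `seed_prob` (segments are therefore centred on high-confidence markers and
#' stop at the first marker below the extension threshold).
#'
#' @param tot_hbd Numeric vector of per-marker total HBD probabilities
#'   (1 minus the non-HBD posterior) along one chromosome.
#' @param seed_prob,extend_prob Thresholds (strict `>`).
#' @return Integer matrix with columns `start`, `end`: marker-index runs.
#' @export
posterior_roh_runs <- function(tot_hbd, seed_prob = 0.999,
                               extend_prob = 0.99) {
  runs <- logical_runs(tot_hbd > extend_prob)
  if (nrow(runs)) {
    seeded <- vapply(seq_len(nrow(runs)), function(r) {
      any(tot_hbd[runs[r, 1]:runs[r, 2]] > seed_prob)
    }, logical(1))
    runs <- runs[seeded, , drop = FALSE]
  }
  runs
}

#' Viterbi decoding of HBD class paths
#'
#' Maximum a-posteriori state sequence per chromosome under the fitted
#' per-individual mixing proportions; ties are broken toward the lower class
#' index (the older, lower-rate reading), deterministically.
#'
#' @param fit An `hbd_fit` from [fit_hbd()].
#' @param individuals Ids to decode (default all).
#' @return Tibble `individual`, `marker`, `chrom`, `bp`, `state` (1..K = HBD
#'   classes in rate order, K+1 = non-HBD).
#' @export
decode_viterbi <- function(fit, individuals = rownames(fit$mixing)) {
  stopifnot(inherits(fit, "hbd_fit"))
  ds <- fit$data
  cs <- chain_structure(ds$map, fit$config)
  out <- purrr::map(individuals, function(id) {
    i <- match(id, rownames(ds$geno))
    emis <- build_emissions(ds$geno[i, ], fit$freqs, fit$config)
    path <- cpp_viterbi(emis, cs$d, cs$lengths, fit$config$rates,
                        fit$mixing[id, ])
    tibble(individual = id, marker = ds$map$marker, chrom = ds$map$chrom,
           bp = ds$map$bp, state = path)
  })
  dplyr::bind_rows(out)
}

#' Call ROH segments from HBD posteriors
#'
#' Default (`mode = "posterior"`): a segment is seeded at any marker whose
#' total HBD probability (1 minus the non-HBD posterior) exceeds `seed_prob`
#' and extended bidirectionally over all surrounding markers above
#' `extend_prob`, stopping at the first marker below it; overlapping
#' extensions merge. `mode = "viterbi"` instead takes maximal runs of HBD
#' Viterbi states. Either way each segment is annotated with the modal
#' Viterbi class of its markers (ties toward the lower class index).
#'
#' @param fit An `hbd_fit`.
#' @param mode `"posterior"` (seed/extend on posteriors) or `"viterbi"`.
#' @param seed_prob,extend_prob Posterior thresholds for the default mode.
#' @param viterbi Optional precomputed result of [decode_viterbi()] (it is
#'   computed on demand otherwise).
#' @return Tibble of segments: `individual`, `chrom`, `start`, `end`
#'   (0-based half-open, from first to last included marker), `n_markers`,
#'   `class`, `length_bp`.
#' @export
call_roh <- function(fit, mode = c("posterior", "viterbi"),
                     seed_prob = 0.999, extend_prob = 0.99, viterbi = NULL) {
  stopifnot(inherits(fit, "hbd_fit"))
  mode <- match.arg(mode)
  K1 <- length(fit$config$rates)
  map <- fit$data$map
  if (is.null(viterbi)) viterbi <- decode_viterbi(fit)
  ids <- rownames(fit$mixing)
  chroms <- unique(map$chrom)
  segs <- list()
  for (id in ids) {
    tot_hbd <- 1 - fit$posterior[[id]][, K1]
    vpath <- viterbi$state[viterbi$individual == id]
    for (ch in chroms) {
      m <- which(map$chrom == ch)
      if (mode == "posterior") {
        runs <- posterior_roh_runs(tot_hbd[m], seed_prob, extend_prob)
      } else {
        runs <- logical_runs(vpath[m] < K1)
      }
      if (!nrow(runs)) next
      segs[[length(segs) + 1L]] <- tibble(
        individual = id, chrom = ch,
        start = map$bp[m][runs[, 1]] - 1,
        end = as.numeric(map$bp[m][runs[, 2]]),
        n_markers = runs[, 2] - runs[, 1] + 1L,
        class = vapply(seq_len(nrow(runs)), function(r) {
          v <- vpath[m][runs[r, 1]:runs[r, 2]]
          v <- v[v < K1]
          if (!length(v)) return(NA_integer_)
          tab <- tabulate(v, K1 - 1)
          which.max(tab)  # ties: lowest class index
        }, integer(1))
      )
    }
  }
  if (!length(segs)) {
    return(tibble(individual = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0),
                  n_markers = integer(0), class = integer(0),
                  length_bp = numeric(0)))
  }
  out <- dplyr::bind_rows(segs)
  out$length_bp <- out$end - out$start
  out
}

# mapped genome length: sum over chromosomes of (last - first marker bp)
mapped_length <- function(map) {
  if (nrow(map) == 0) abort("empty marker map")
  sum(tapply(map$bp, map$chrom, function(b) max(b) - min(b)))
}

#' ROH-based inbreeding coefficient
#'
#' `F = sum of segment lengths strictly longer than min_length_bp, divided by
#' the mapped genome length` (sum over chromosomes of last-minus-first marker
#' position). `min_length_bp = 0` gives `F_ROH`; `2e6` gives `F_ROH>2Mb`.
#'
#' @param segments Segment tibble from [call_roh()].
#' @param map Marker map.
#' @param min_length_bp Strict length threshold in bp.
#' @param individuals Ids to report (individuals without segments get 0).
#' @return Tibble `individual`, `f`, `denominator_bp`.
#' @export
roh_inbreeding <- function(segments, map, min_length_bp = 0,
                           individuals = unique(segments$individual)) {
  den <- mapped_length(map)
  keep <- segments[segments$length_bp > min_length_bp, ]
  tot <- tapply(keep$length_bp, factor(keep$individual, levels = individuals),
                sum)
  tot[is.na(tot)] <- 0
  tibble(individual = individuals, f = as.numeric(tot) / den,
         denominator_bp = den)
}

#' Both ROH inbreeding metrics at once
#'
#' @inheritParams roh_inbreeding
#' @param long_bp Threshold for the long-ROH metric (default 2 Mb, strict).
#' @return Tibble `individual`, `f_roh`, `f_roh_long`, `denominator_bp`.
#' @export
roh_metrics <- function(segments, map, long_bp = 2e6,
                        individuals = unique(segments$individual)) {
  a <- roh_inbreeding(segments, map, 0, individuals)
  b <- roh_inbreeding(segments, map, long_bp, individuals)
  tibble(individual = a$individual, f_roh = a$f, f_roh_long = b$f,
         denominator_bp = a$denominator_bp)
}

#' ROH length distribution per group
#'
#' @param segments Segment tibble from [call_roh()].
#' @param labels Tibble `individual`, `breed`.
#' @param breaks_mb Bin breakpoints in Mb (default <1, 1-2, 2-4, 4-8, >8).
#' @return Tibble `breed`, `bin`, `n`, `proportion`; proportions sum to 1
#'   within each breed that has at least one segment.
#' @export
roh_length_distribution <- function(segments, labels,
                                    breaks_mb = c(0, 1, 2, 4, 8, Inf)) {
  segs <- dplyr::left_join(segments, labels, by = "individual")
  if (anyNA(segs$breed)) abort("segments reference individuals missing from labels")
  segs$bin <- cut(segs$length_bp / 1e6, breaks = breaks_mb, right = FALSE)
  segs %>%
    dplyr::count(.data$breed, .data$bin, .drop = FALSE) %>%
    dplyr::group_by(.data$breed) %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
}
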