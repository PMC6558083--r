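#' Descriptive statistics per breed and metric
#'
#' Computes min, Q1, median, mean, sd, Q3, max and n for every numeric metric
#' column, per breed plus an overall row pooling all individuals. Quantiles
#' use linear interpolation (R type 7).
#'
#' @param metrics Tibble with an `individual` column and numeric metric
#'   columns (e.g. the output of [adjust_inbreeding()]).
#' @param labels Tibble `individual`, `breed`.
#' @return Tibble `breed`, `metric`, `min`, `q1`, `median`, `mean`, `sd`,
#'   `q3`, `max`, `n`.
#' @export
breed_summary <- function(metrics, labels) {
  unknown <- setdiff(metrics$individual, labels$individual)
  if (length(unknown)) {
    abort(sprintf("no breed label for: %s (valid individuals: %s, ...)",
                  paste(unknown, collapse = ", "),
                  paste(head(labels$individual, 5), collapse = ", ")))
  }
  m <- dplyr::left_join(metrics, labels[, c("individual", "breed")],
                        by = "individual")
  long <- tidyr::pivot_longer(m, cols = dplyr::where(is.numeric),
                              names_to = "metric", values_to = "value")
  summarise_group <- function(df) {
    df %>%
      dplyr::group_by(.data$breed, .data$metric) %>%
      dplyr::summarise(
        min = min(.data$value), q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
        median = median(.data$value), mean = mean(.data$value),
        sd = sd(.data$value), q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
        max = max(.data$value), n = dplyr::n(), .groups = "drop"
      )
  }
  overall <- long
  overall$breed <- "Overall"
  dplyr::bind_rows(summarise_group(long), summarise_group(overall))
}

#' Pairwise Pearson correlations between inbreeding metrics
#'
#' @param metrics Tibble with an `individual` column and numeric metric
#'   columns; at least 3 individuals.
#' @return Tibble `metric_x`, `metric_y`, `r` covering all ordered pairs
#'   (symmetric, unit diagonal). Zero-variance metrics yield `NA` with a
#'   warning.
#' @export
metric_correlations <- function(metrics) {
  num <- dplyr::select(metrics, dplyr::where(is.numeric))
  if (nrow(num) < 3) abort("need at least 3 individuals for correlations")
  novar <- vapply(num, function(x) sd(x) == 0, logical(1))
  if (any(novar)) {
    warn(sprintf("zero-variance metric(s): %s; correlations undefined",
                 paste(names(num)[novar], collapse = ", ")))
  }
  cm <- suppressWarnings(cor(as.matrix(num)))
  tibble(
    metric_x = rep(rownames(cm), ncol(cm)),
    metric_y = rep(colnames(cm), each = nrow(cm)),
    r = as.vector(cm)
  )
}

#' Local (per-marker) inbreeding profile by breed
#'
#' Averages the total-HBD posterior probability across the individuals of
#' each breed at every marker: the local analogue of F_G, highlighting
#' genomic regions of elevated autozygosity.
#'
#' @param fit An `hbd_fit`.
#' @param labels Tibble `individual`, `breed`.
#' @param by_class Also return the per-HBD-class decomposition.
#' @return Tibble `marker`, `chrom`, `bp`, `breed`, `f_local` (plus `class`
#'   when `by_class = TRUE`).
#' @export
local_inbreeding_profile <- function(fit, labels, by_class = FALSE) {
  stopifnot(inherits(fit, "hbd_fit"))
  K1 <- length(fit$config$rates)
  map <- fit$data$map
  ids <- rownames(fit$mixing)
  breeds <- labels$breed[match(ids, labels$individual)]
  if (anyNA(breeds)) abort("fit contains individuals missing from labels")
  out <- purrr::map(unique(breeds), function(b) {
    members <- ids[breeds == b]
    if (!by_class) {
      tot <- rowMeans(vapply(members, function(id) {
        1 - fit$posterior[[id]][, K1]
      }, numeric(nrow(map))))
      tibble(marker = map$marker, chrom = map$chrom, bp = map$bp,
             breed = b, f_local = tot)
    } else {
      acc <- Reduce(`+`, fit$posterior[members]) / length(members)
      tibble(marker = rep(map$marker, K1 - 1),
             chrom = rep(map$chrom, K1 - 1), bp = rep(map$bp, K1 - 1),
             breed = b, class = rep(seq_len(K1 - 1), each = nrow(map)),
             f_local = as.vector(acc[, seq_len(K1 - 1)]))
    }
  })
  dplyr::bind_rows(out)
}

#' Age distribution of HBD segments by breed
#'
#' Proportion of HBD segments attributable to each HBD class, per breed. With
#' ROH segments (from [call_roh()]) the class annotation of each called
#' segment is counted; with an `hbd_fit` the EM expected segment-entry counts
#' are used, which also cover segments too short to be called.
#'
#' @param x Segment tibble with `individual` and `class`, or an `hbd_fit`.
#' @param labels Tibble `individual`, `breed`.
#' @param n_classes Number of HBD classes (taken from the fit when given one).
#' @return Tibble `breed`, `class`, `proportion`; proportions sum to 1 within
#'   each breed with at least one HBD segment.
#' @export
segment_age_distribution <- function(x, labels, n_classes = 11) {
  if (inherits(x, "hbd_fit")) {
    K <- length(x$config$hbd_rates)
    counts <- x$entries[, seq_len(K), drop = FALSE]
    df <- tibble(
      individual = rep(rownames(x$mixing), each = K),
      class = rep(seq_len(K), nrow(x$mixing)),
      n = as.vector(t(counts))
    )
  } else {
    K <- n_classes
    segs <- x[!is.na(x$class), ]
    df <- segs %>% dplyr::count(.data$individual, .data$class)
  }
  df <- dplyr::left_join(df, labels[, c("individual", "breed")],
                         by = "individual")
  if (anyNA(df$breed)) abort("individuals missing from labels")
  out <- df %>%
    dplyr::group_by(.data$breed, .data$class) %>%
    dplyr::summarise(n = sum(.data$n), .groups = "drop_last") %>%
    dplyr::mutate(proportion = .data$n / sum(.data$n)) %>%
    dplyr::ungroup()
  tidyr::complete(out, .data$breed, class = seq_len(K),
                  fill = list(n = 0, proportion = 0))
}
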