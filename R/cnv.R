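#' Intersect ROH with copy-loss CNV calls
#'
#' Pairwise half-open interval intersections per (individual, chromosome)
#' between ROH segments and CNV calls with copy number 0 or 1 (duplications
#' are excluded): the overlap is `[max(starts), min(ends))` when positive.
#'
#' @param roh Segment tibble from [call_roh()].
#' @param cnv_calls CNV tibble (`individual`, `chrom`, `start`, `end`, `cn`).
#' @return Tibble of candidate loss regions: `individual`, `chrom`, `start`,
#'   `end`, `roh_id`, `cnv_id`, `roh_length_bp`.
#' @export
intersect_roh_losses <- function(roh, cnv_calls) {
  bad <- which(cnv_calls$start >= cnv_calls$end)
  if (length(bad)) {
    abort(sprintf("malformed CNV interval (start >= end) at row %s",
                  paste(bad, collapse = ", ")))
  }
  bad <- which(roh$start >= roh$end)
  if (length(bad)) {
    abort(sprintf("malformed ROH interval (start >= end) at row %s",
                  paste(bad, collapse = ", ")))
  }
  loss <- cnv_calls[cnv_calls$cn %in% c(0L, 1L), ]
  r <- roh
  r$roh_id <- seq_len(nrow(r))
  loss$cnv_id <- seq_len(nrow(cnv_calls))[cnv_calls$cn %in% c(0L, 1L)]
  j <- dplyr::inner_join(
    r[, c("individual", "chrom", "start", "end", "length_bp", "roh_id")],
    loss[, c("individual", "chrom", "start", "end", "cnv_id")],
    by = c("individual", "chrom"), suffix = c("_roh", "_cnv"),
    relationship = "many-to-many")
  j$start <- pmax(j$start_roh, j$start_cnv)
  j$end <- pmin(j$end_roh, j$end_cnv)
  j <- j[j$end > j$start, ]
  tibble(individual = j$individual, chrom = j$chrom, start = j$start,
         end = j$end, roh_id = j$roh_id, cnv_id = j$cnv_id,
         roh_length_bp = j$length_bp)
}

#' Classify candidate regions as copy losses by mean LRR
#'
#' Computes the mean log R ratio over the markers strictly inside each
#' region for its carrier individual and flags the region as a confirmed
#' copy loss when the mean is strictly below `lrr_threshold`. Regions
#' containing no markers cannot be classified and are never flagged (column
#' `n_markers` = 0 identifies them).
#'
#' @param regions Tibble from [intersect_roh_losses()] (any tibble with
#'   `individual`, `chrom`, `start`, `end` works).
#' @param intensity Intensity tibble (`marker`, `individual`, `lrr`, `baf`).
#' @param map Marker map (for marker positions).
#' @param lrr_threshold Flagging threshold on the mean LRR (default -0.3).
#' @return `regions` with `n_markers`, `mean_lrr`, `flagged` added.
#' @export
classify_copy_loss <- function(regions, intensity, map, lrr_threshold = -0.3) {
  if (nrow(regions) == 0) {
    return(dplyr::mutate(regions, n_markers = integer(0),
                         mean_lrr = numeric(0), flagged = logical(0)))
  }
  pos <- map$bp - 1  # 0-based marker points
  stats <- purrr::map(seq_len(nrow(regions)), function(r) {
    mk <- map$marker[map$chrom == regions$chrom[r] &
                     pos >= regions$start[r] & pos < regions$end[r]]
    lrr <- intensity$lrr[intensity$individual == regions$individual[r] &
                         intensity$marker %in% mk]
    tibble(n_markers = length(lrr),
           mean_lrr = if (length(lrr)) mean(lrr) else NA_real_)
  })
  out <- dplyr::bind_cols(regions, dplyr::bind_rows(stats))
  out$flagged <- !is.na(out$mean_lrr) & out$n_markers > 0 &
    out$mean_lrr < lrr_threshold
  out
}

# merge overlapping intervals per (individual, chrom); returns merged tibble
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(regions[, c("individual", "chrom", "start", "end")])
  regions %>%
    dplyr::group_by(.data$individual, .data$chrom) %>%
    dplyr::reframe({
      ir <- IRanges::reduce(IRanges::IRanges(start = .data$start + 1,
                                             end = .data$end))
      tibble(start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir)))
    })
}

#' Adjust inbreeding metrics for confirmed copy losses
#'
#' Flagged loss regions are merged per individual (so overlaps are not
#' double-counted) and their total length `L` is subtracted, as the fraction
#' `L / denominator`, from `F_ROH` and `F_G`. The long-ROH metric subtracts
#' only the flagged lengths falling inside ROH longer than `long_bp`. All
#' adjusted values are clamped at 0.
#'
#' @param roh_inb Tibble from [roh_metrics()] (`individual`, `f_roh`,
#'   `f_roh_long`, `denominator_bp`).
#' @param global_inb Tibble (`individual`, `f_g`) from
#'   [global_and_class_inbreeding()]`$global`.
#' @param flagged_regions Output of [classify_copy_loss()]; only rows with
#'   `flagged` are used.
#' @param long_bp Strict length threshold of the long-ROH metric.
#' @return Tibble per individual: raw and adjusted `f_roh`, `f_roh_long`,
#'   `f_g`, plus `loss_bp` (merged flagged length).
#' @export
adjust_inbreeding <- function(roh_inb, global_inb, flagged_regions,
                              long_bp = 2e6) {
  unknown <- setdiff(flagged_regions$individual, roh_inb$individual)
  if (length(unknown)) {
    abort(sprintf("flagged region references unknown individual(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  fl <- flagged_regions[flagged_regions$flagged, ]
  merged_all <- merge_regions(fl)
  loss_all <- tapply(merged_all$end - merged_all$start,
                     factor(merged_all$individual,
                            levels = roh_inb$individual), sum)
  loss_all[is.na(loss_all)] <- 0
  fl_long <- fl[fl$roh_length_bp > long_bp, ]
  merged_long <- merge_regions(fl_long)
  loss_long <- tapply(merged_long$end - merged_long$start,
                      factor(merged_long$individual,
                             levels = roh_inb$individual), sum)
  loss_long[is.na(loss_long)] <- 0
  out <- dplyr::left_join(roh_inb, global_inb, by = "individual")
  den <- out$denominator_bp
  tibble(
    individual = out$individual,
    f_roh_raw = out$f_roh,
    f_roh_adj = pmax(0, out$f_roh - as.numeric(loss_all) / den),
    f_roh_long_raw = out$f_roh_long,
    f_roh_long_adj = pmax(0, out$f_roh_long - as.numeric(loss_long) / den),
    f_g_raw = out$f_g,
    f_g_adj = pmax(0, out$f_g - as.numeric(loss_all) / den),
    loss_bp = as.numeric(loss_all)
  )
}

#' Per-region BAF/LRR evidence summary
#'
#' For each region, summarises the intensity evidence used in judging whether
#' an apparent ROH is a hemizygous deletion: marker count, mean/min/max LRR,
#' and the fraction of BAF values near 0, 0.5, and 1 (within 0.1). A true ROH
#' shows LRR near 0 and BAF mass only at the homozygous poles; a copy loss
#' shows depressed LRR.
#'
#' @param regions Tibble with `individual`, `chrom`, `start`, `end`.
#' @param intensity Intensity tibble.
#' @param map Marker map.
#' @return One row per region with the summaries appended.
#' @export
region_evidence_report <- function(regions, intensity, map) {
  if (nrow(regions) == 0) {
    return(dplyr::mutate(regions, n_markers = integer(0), mean_lrr = numeric(0),
                         min_lrr = numeric(0), max_lrr = numeric(0),
                         baf_near_0 = numeric(0), baf_near_half = numeric(0),
                         baf_near_1 = numeric(0)))
  }
  pos <- map$bp - 1
  stats <- purrr::map(seq_len(nrow(regions)), function(r) {
    mk <- map$marker[map$chrom == regions$chrom[r] &
                     pos >= regions$start[r] & pos < regions$end[r]]
    sub <- intensity[intensity$individual == regions$individual[r] &
                     intensity$marker %in% mk, ]
    n <- nrow(sub)
    tibble(
      n_markers = n,
      mean_lrr = if (n) mean(sub$lrr) else NA_real_,
      min_lrr = if (n) min(sub$lrr) else NA_real_,
      max_lrr = if (n) max(sub$lrr) else NA_real_,
      baf_near_0 = if (n) mean(sub$baf < 0.1, na.rm = TRUE) else NA_real_,
      baf_near_half = if (n) mean(abs(sub$baf - 0.5) < 0.1, na.rm = TRUE) else NA_real_,
      baf_near_1 = if (n) mean(sub$baf > 0.9, na.rm = TRUE) else NA_real_
    )
  })
  dplyr::bind_cols(regions, dplyr::bind_rows(stats))
}
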