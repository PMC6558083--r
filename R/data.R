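#' Published CNV copy-number counts for the African goat cohort
#'
#' The per-copy-number CNV call counts reported for the 608-animal AdaptMap
#' African goat cohort (Illumina Goat 50k): copy numbers 0 and 1 are
#' deletions, 3 and 4 duplications. Shipped as a small text table so
#' desk-scale bookkeeping (total CNV count, per-animal mean) can be
#' recomputed without the full genotype download.
#'
#' @return Tibble `copy_number`, `count`, with attribute `n_animals = 608`.
#' @export
#' @examples
#' cc <- adaptmap_cnv_counts()
#' sum(cc$count)                      # total CNV calls
#' sum(cc$count) / attr(cc, "n_animals")  # mean per animal
adaptmap_cnv_counts <- function() {
  path <- system.file("extdata", "adaptmap_cnv_copy_number_counts.tsv",
                      package = "mosaicf", mustWork = TRUE)
  out <- readr::read_tsv(path, col_types = "ii")
  attr(out, "n_animals") <- 608L
  out
}
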