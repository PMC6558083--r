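#' Genotype dataset container
#'
#' Holds an individuals-by-markers B-allele dosage matrix together with its
#' marker map and individual metadata. Markers are kept sorted by
#' (chromosome, bp); the dosage matrix columns follow the map order.
#'
#' @param geno Integer matrix individuals x markers, entries 0/1/2 (B-allele
#'   dosage) or `NA` for missing.
#' @param map Tibble with columns `chrom`, `marker`, `bp` and optionally
#'   `morgan`, `freq`.
#' @param individuals Tibble with columns `id` and `breed` (group label).
#' @return An object of class `hbd_data`.
#' @export
hbd_data <- function(geno, map,
                     individuals = tibble(id = rownames(geno), breed = "ALL")) {
  map <- as_tibble(map)
  stopifnot(is.matrix(geno), nrow(map) == ncol(geno),
            all(c("chrom", "marker", "bp") %in% names(map)))
  if (anyDuplicated(map$marker)) abort("duplicate marker ids in map")
  ord <- order(match(map$chrom, unique(map$chrom)), map$bp)
  if (!identical(ord, seq_len(nrow(map)))) {
    warn("marker map not sorted by (chromosome, bp); sorting and permuting calls")
    map <- map[ord, ]
    geno <- geno[, ord, drop = FALSE]
  }
  if (!"morgan" %in% names(map)) map$morgan <- map$bp / 1e8
  colnames(geno) <- map$marker
  rownames(geno) <- individuals$id
  structure(list(geno = geno, map = map, individuals = as_tibble(individuals)),
            class = "hbd_data")
}

#' @export
print.hbd_data <- function(x, ...) {
  cat(sprintf("<hbd_data> %d individuals x %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing calls: %.2f%%; breeds: %s\n", 100 * miss,
              paste(unique(x$individuals$breed), collapse = ", ")))
  invisible(x)
}

#' @export
dim.hbd_data <- function(x) dim(x$geno)

#' Tidy a genotype dataset into long form
#'
#' @param x An [hbd_data()].
#' @param ... Unused.
#' @return Tibble with one row per (individual, marker) call: `individual`,
#'   `marker`, `chrom`, `bp`, `dosage`.
#' @export
tidy.hbd_data <- function(x, ...) {
  tibble(
    individual = rep(rownames(x$geno), ncol(x$geno)),
    marker = rep(x$map$marker, each = nrow(x$geno)),
    chrom = rep(x$map$chrom, each = nrow(x$geno)),
    bp = rep(x$map$bp, each = nrow(x$geno)),
    dosage = as.vector(x$geno)
  )
}
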