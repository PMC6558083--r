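geno_to_ped_row <- function(fam, id, g) {
  al <- c("A A", "A B", "B B")
  calls <- ifelse(is.na(g), "0 0", al[g + 1L])
  paste(fam, id, 0, 0, 0, -9, paste(calls, collapse = " "))
}

#' Write a simulated dataset to disk
#'
#' Emits the text formats the loaders consume: PLINK PED/MAP genotypes
#' (alleles coded A/B, missing `0 0`), a tab-separated LRR/BAF intensity
#' table, a tab-separated CNV-call list, truth BED files (HBD segments with
#' class, and deletions; 0-based half-open), and a JSON manifest echoing the
#' seed and scalar configuration.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  ds <- sim$data
  paths <- c(
    ped = file.path(out_dir, "genotypes.ped"),
    map = file.path(out_dir, "genotypes.map"),
    intensity = file.path(out_dir, "intensity.tsv"),
    cnv = file.path(out_dir, "cnv_calls.tsv"),
    truth_hbd = file.path(out_dir, "truth_hbd.bed"),
    truth_del = file.path(out_dir, "truth_deletions.bed"),
    manifest = file.path(out_dir, "manifest.json")
  )
  ped_lines <- vapply(seq_len(nrow(ds$geno)), function(i) {
    geno_to_ped_row(ds$individuals$breed[i], ds$individuals$id[i], ds$geno[i, ])
  }, character(1))
  writeLines(ped_lines, paths["ped"])
  map_out <- data.frame(ds$map$chrom, ds$map$marker,
                        ds$map$morgan * 100,  # MAP stores centimorgans
                        ds$map$bp)
  readr::write_tsv(map_out, paths["map"], col_names = FALSE)
  readr::write_tsv(sim$intensity, paths["intensity"])
  readr::write_tsv(sim$cnv, paths["cnv"])
  segs <- sim$truth$segments
  readr::write_tsv(
    data.frame(segs$chrom, segs$start, segs$end,
               paste0(segs$individual, ":class", segs$class)),
    paths["truth_hbd"], col_names = FALSE)
  dels <- sim$deletions
  readr::write_tsv(
    data.frame(dels$chrom, dels$start, dels$end, dels$individual),
    paths["truth_del"], col_names = FALSE)
  cfg <- sim$config
  scalars <- cfg[vapply(cfg, function(x) is.numeric(x) || is.character(x),
                        logical(1))]
  jsonlite::write_json(c(scalars, list(freq_law = "truncated to [0.01, 0.99]")),
                       paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read PLINK PED/MAP text genotypes
#'
#' Parses the white-space-delimited PED dialect (family, id, father, mother,
#' sex, phenotype, then one allele pair per marker, alleles `A`/`B`, missing
#' `0`) and the 4-column MAP (chromosome, marker id, genetic position in cM,
#' bp). Genotypes are coded as B-allele dosage. Unsorted maps are sorted with
#' the calls permuted to match (with a warning).
#'
#' @param ped_path,map_path File paths.
#' @return An [hbd_data()].
#' @export
read_plink <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) abort(sprintf("PED file not found: %s", ped_path))
  if (!file.exists(map_path)) abort(sprintf("MAP file not found: %s", map_path))
  map_raw <- utils::read.table(map_path, header = FALSE,
                               col.names = c("chrom", "marker", "cm", "bp"),
                               colClasses = c("character", "character",
                                              "numeric", "numeric"))
  map <- tibble(chrom = map_raw$chrom, marker = map_raw$marker,
                bp = map_raw$bp, morgan = map_raw$cm / 100)
  n_mark <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  geno <- matrix(NA_integer_, length(lines), n_mark)
  ids <- character(length(lines))
  fams <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * n_mark) {
      abort(sprintf(
        "PED line %d has %d fields; expected %d for %d markers in MAP",
        i, length(f), 6 + 2 * n_mark, n_mark))
    }
    fams[i] <- f[1]
    ids[i] <- f[2]
    a1 <- f[seq(7, length(f), by = 2)]
    a2 <- f[seq(8, length(f), by = 2)]
    g <- (a1 == "B") + (a2 == "B")
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    geno[i, ] <- g
  }
  hbd_data(geno, map, individuals = tibble(id = ids, breed = fams))
}

#' Read a tab-separated LRR/BAF intensity table
#'
#' @param path TSV with header `marker individual lrr baf`.
#' @return Tibble with those columns.
#' @export
read_intensity <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker = readr::col_character(), individual = readr::col_character(),
    lrr = readr::col_double(), baf = readr::col_double()))
}

#' Read a CNV-call region list
#'
#' Expects the tab-separated layout written by [write_dataset()] (or converted
#' from a PennCNV-style region list): header
#' `individual chrom start end cn`, 0-based half-open intervals, copy number
#' in \{0, 1, 3, 4\}.
#'
#' @param path TSV path.
#' @return Tibble of CNV calls.
#' @export
read_cnv_calls <- function(path) {
  cnv <- readr::read_tsv(path, col_types = readr::cols(
    individual = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    cn = readr::col_integer()))
  bad <- which(!(cnv$cn %in% c(0L, 1L, 3L, 4L)) | cnv$start >= cnv$end)
  if (length(bad)) {
    abort(sprintf("malformed CNV call at row %s: need start < end and copy number in {0,1,3,4}",
                  paste(bad, collapse = ", ")))
  }
  cnv
}
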