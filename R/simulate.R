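#' Simulate a marker map
#'
#' Draws marker positions uniformly along each chromosome at the configured
#' density and assigns each marker a reference B-allele frequency from the
#' configured law (truncated to `[0.01, 0.99]`, the usual informative range for
#' array SNPs). Genetic positions use a constant `cm_per_mb` scaling, so a
#' marker at `bp` sits at `bp * cm_per_mb / 1e8` Morgans.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `chrom`, `marker`, `bp` (1-based position),
#'   `morgan`, `freq`, sorted by (`chrom`, `bp`).
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    maps <- purrr::imap(config$chromosomes, function(len, name) {
      n <- max(1L, as.integer(round(len / 1e6 * config$marker_density)))
      bp <- sort(sample.int(as.integer(len), n))
      tibble(chrom = name, bp = bp)
    })
    map <- dplyr::bind_rows(maps)
    map$marker <- sprintf("snp%06d", seq_len(nrow(map)))
    map$morgan <- map$bp * config$cm_per_mb / 1e8
    map$freq <- pmin(pmax(config$allele_freq_law(nrow(map)), 0.01), 0.99)
  })
  map[, c("chrom", "marker", "bp", "morgan", "freq")]
}

# Tile one chromosome with segments; returns tibble(start, end, class),
# 0-based half-open bp intervals. Renewal process from the chromosome start:
# class ~ mixing proportions, length ~ Exp(rate R_class) in Morgans.
tile_chromosome <- function(len_bp, rates, pi, morgan_per_bp) {
  len_morgan <- len_bp * morgan_per_bp
  mean_len <- sum(pi / rates)
  chunk <- max(16L, ceiling(1.5 * len_morgan / mean_len))
  classes <- integer(0)
  lengths <- numeric(0)
  total <- 0
  while (total < len_morgan) {
    cl <- sample.int(length(rates), chunk, replace = TRUE, prob = pi)
    ln <- rexp(chunk, rates[cl])
    classes <- c(classes, cl)
    lengths <- c(lengths, ln)
    total <- total + sum(ln)
  }
  ends_m <- cumsum(lengths)
  keep <- seq_len(which(ends_m >= len_morgan)[1])
  classes <- classes[keep]
  ends <- pmin(round(ends_m[keep] / morgan_per_bp), len_bp)
  starts <- c(0, ends[-length(ends)])
  ok <- ends > starts  # rounding can collapse tiny segments; drop empties
  tibble(start = starts[ok], end = ends[ok], class = classes[ok])
}

#' Simulate HBD/non-HBD segment mosaics
#'
#' Tiles every chromosome of every individual left to right with segments whose
#' class is drawn from the mixing proportions and whose length is exponential
#' with the class rate (mean `1/R` Morgans), truncated at the chromosome end.
#' Every bp of the genome belongs to exactly one segment.
#'
#' @param config A [sim_config()]. `mixing_proportions` may also be a matrix
#'   with one row per individual to simulate heterogeneous cohorts.
#' @param map Marker map from [simulate_marker_map()] (used only to echo the
#'   chromosome set; tiling is over the configured chromosome lengths).
#' @return A list of class `hbd_truth`: `segments` (tibble `individual`,
#'   `chrom`, `start`, `end`, `class`; 0-based half-open; class indexes
#'   `config$class_rates`, the last index being non-HBD) and `autozygosity`
#'   (tibble `individual`, `autozygosity` = realized HBD genome fraction).
#' @export
simulate_hbd_mosaic <- function(config, map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  K1 <- length(config$class_rates)
  mix <- config$mixing_proportions
  if (is.matrix(mix)) {
    stopifnot(nrow(mix) == config$n_individuals, ncol(mix) == K1)
  } else {
    mix <- matrix(mix, config$n_individuals, K1, byrow = TRUE)
  }
  morgan_per_bp <- config$cm_per_mb / 1e8
  ids <- sprintf("ind%04d", seq_len(config$n_individuals))
  withr::with_seed(config$seed + 1L, {
    segs <- purrr::map(seq_len(config$n_individuals), function(i) {
      per_chrom <- purrr::imap(config$chromosomes, function(len, name) {
        tl <- tile_chromosome(len, config$class_rates, mix[i, ], morgan_per_bp)
        tl$chrom <- name
        tl
      })
      out <- dplyr::bind_rows(per_chrom)
      out$individual <- ids[i]
      out
    })
  })
  segments <- dplyr::bind_rows(segs)[, c("individual", "chrom", "start", "end",
                                         "class")]
  genome <- sum(config$chromosomes)
  auto <- segments %>%
    dplyr::group_by(.data$individual) %>%
    dplyr::summarise(
      autozygosity = sum((.data$end - .data$start)[.data$class < K1]) / genome
    )
  structure(list(segments = segments,
                 autozygosity = auto[match(ids, auto$individual), ]),
            class = "hbd_truth")
}

# class index of the truth segment covering each marker, for one individual
marker_segment_class <- function(truth_segments, map) {
  out <- integer(nrow(map))
  for (ch in unique(map$chrom)) {
    m <- map$chrom == ch
    s <- truth_segments[truth_segments$chrom == ch, ]
    s <- s[order(s$start), ]
    idx <- findInterval(map$bp[m] - 1, s$start)  # bp is 1-based, truth 0-based
    if (any(idx < 1 | idx > nrow(s))) {
      abort("internal error: marker not covered by truth tiling")
    }
    out[m] <- s$class[idx]
  }
  out
}

#' Emit genotypes from an HBD mosaic
#'
#' Inside an HBD segment a marker is autozygous with probability `1 - e`
#' (genotype BB with probability `p`, else AA) and an ordinary Hardy-Weinberg
#' draw with probability `e`; outside, genotypes are Hardy-Weinberg
#' (`p^2, 2pq, q^2`). Missing calls are injected at `config$missing_rate`.
#'
#' @param truth An `hbd_truth` from [simulate_hbd_mosaic()].
#' @param map Marker map.
#' @param config A [sim_config()].
#' @return Integer matrix individuals x markers of B-allele dosages (0/1/2,
#'   `NA` = missing), with individual ids as rownames and marker ids as
#'   colnames.
#' @export
emit_genotypes <- function(truth, map, config) {
  stopifnot(inherits(truth, "hbd_truth"))
  K1 <- length(config$class_rates)
  ids <- truth$autozygosity$individual
  n_mark <- nrow(map)
  geno <- matrix(NA_integer_, length(ids), n_mark,
                 dimnames = list(ids, map$marker))
  e <- config$genotype_error
  p <- map$freq
  withr::with_seed(config$seed + 2L, {
    for (i in seq_along(ids)) {
      segs <- truth$segments[truth$segments$individual == ids[i], ]
      cls <- marker_segment_class(segs, map)
      hbd <- cls < K1
      g <- rbinom(n_mark, 2L, p)               # Hardy-Weinberg background
      az <- hbd & (runif(n_mark) >= e)         # autozygous emission
      g[az] <- 2L * (runif(sum(az)) < p[az])
      if (config$missing_rate > 0) {
        g[runif(n_mark) < config$missing_rate] <- NA_integer_
      }
      geno[i, ] <- g
    }
  })
  geno
}

# sample non-overlapping deletion intervals for one individual
place_deletions <- function(config, lens, avoid) {
  chroms <- config$chromosomes
  placed <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  for (ln in lens) {
    ok_chr <- chroms[chroms > ln]
    if (length(ok_chr) == 0) abort("deletion longer than every chromosome")
    for (attempt in 1:200) {
      ch <- sample(names(ok_chr), 1, prob = ok_chr)
      st <- floor(runif(1, 0, chroms[[ch]] - ln))
      en <- st + ln
      clash <- any(placed$chrom == ch & placed$start < en & placed$end > st)
      if (!clash && !is.null(avoid)) {
        a <- avoid[avoid$chrom == ch, ]
        clash <- any(a$start < en & a$end > st)
      }
      if (!clash) {
        placed <- dplyr::bind_rows(placed,
                                   tibble(chrom = ch, start = st, end = en))
        break
      }
      if (attempt == 200) {
        warn("could not place a deletion without overlap; dropping it")
      }
    }
  }
  placed
}

#' Inject hemizygous deletions and generate array intensities
#'
#' Deletions (copy number 1) are placed per individual according to
#' `config$deletion_placement`; inside a deletion each genotype is recoded
#' homozygous for the retained allele (drawn B with probability `p` per
#' marker), which is how array genotyping renders hemizygosity. LRR is drawn
#' `Normal(lrr_del_mean, lrr_del_sd)` inside deletions and
#' `Normal(0, lrr_noise_sd)` elsewhere; BAF is `dosage / 2` plus clipped noise,
#' so deletions concentrate BAF at 0 or 1. A CNV call with copy number 1 is
#' emitted for every injected deletion.
#'
#' @param geno Genotype matrix from [emit_genotypes()].
#' @param truth `hbd_truth` (used to avoid HBD genome when
#'   `deletion_placement = "non-hbd"`).
#' @param map Marker map.
#' @param config A [sim_config()].
#' @return List: `geno` (recoded matrix), `intensity` (tibble `marker`,
#'   `individual`, `lrr`, `baf`), `cnv` (tibble `individual`, `chrom`,
#'   `start`, `end`, `cn`; 0-based half-open), `deletions` (same intervals,
#'   truth bookkeeping).
#' @export
inject_hemizygous_deletions <- function(geno, truth, map, config) {
  K1 <- length(config$class_rates)
  ids <- rownames(geno)
  n_mark <- nrow(map)
  dels <- vector("list", length(ids))
  withr::with_seed(config$seed + 3L, {
    for (i in seq_along(ids)) {
      if (config$n_deletions == 0) {
        dels[[i]] <- tibble(individual = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0))
        next
      }
      lens <- config$deletion_length_law(config$n_deletions)
      avoid <- NULL
      if (config$deletion_placement == "non-hbd") {
        segs <- truth$segments[truth$segments$individual == ids[i], ]
        avoid <- segs[segs$class < K1, c("chrom", "start", "end")]
      }
      placed <- place_deletions(config, lens, avoid)
      placed$individual <- ids[i]
      dels[[i]] <- placed
    }
    dels <- dplyr::bind_rows(dels)

    # recode genotypes and build intensities
    lrr <- matrix(rnorm(length(ids) * n_mark, 0, config$lrr_noise_sd),
                  length(ids), n_mark)
    for (r in seq_len(nrow(dels))) {
      i <- match(dels$individual[r], ids)
      inside <- which(map$chrom == dels$chrom[r] &
                      map$bp - 1 >= dels$start[r] & map$bp - 1 < dels$end[r])
      if (length(inside)) {
        geno[i, inside] <-
          2L * (runif(length(inside)) < map$freq[inside])
        lrr[i, inside] <- rnorm(length(inside), config$lrr_del_mean,
                                config$lrr_del_sd)
      }
    }
    baf <- sweep(geno, 2, 0, "+") / 2 +
      matrix(rnorm(length(ids) * n_mark, 0, config$baf_noise_sd),
             length(ids), n_mark)
    baf <- pmin(pmax(baf, 0), 1)
  })
  intensity <- tibble(
    marker = rep(map$marker, each = length(ids)),
    individual = rep(ids, n_mark),
    lrr = as.vector(lrr),
    baf = as.vector(baf)
  )
  cnv <- dels
  cnv$cn <- rep(1L, nrow(cnv))
  list(geno = geno,
       intensity = intensity,
       cnv = cnv[, c("individual", "chrom", "start", "end", "cn")],
       deletions = dels[, c("individual", "chrom", "start", "end")])
}

#' Simulate a complete dataset
#'
#' Runs the full generator: marker map, HBD mosaic, genotypes, and (if
#' configured) hemizygous deletions with intensities. With a fixed seed the
#' result is fully reproducible.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `data` (an [hbd_data()] genotype
#'   container), `truth` (`hbd_truth`), `intensity`, `cnv`, `deletions`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  map <- simulate_marker_map(config)
  truth <- simulate_hbd_mosaic(config, map)
  geno <- emit_genotypes(truth, map, config)
  inj <- inject_hemizygous_deletions(geno, truth, map, config)
  individuals <- tibble(id = rownames(geno), breed = "SIM")
  structure(list(
    data = hbd_data(inj$geno, map, individuals),
    truth = truth,
    intensity = inj$intensity,
    cnv = inj$cnv,
    deletions = inj$deletions,
    config = config
  ), class = "sim_dataset")
}
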