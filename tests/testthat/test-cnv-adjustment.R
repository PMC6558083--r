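mk_roh <- function(individual, chrom, start, end) {
  tibble::tibble(individual = individual, chrom = chrom, start = start,
                 end = end, n_markers = 5L, class = 1L, length_bp = end - start)
}

test_that("ROH/CNV intersection is half-open interval arithmetic", {
  roh <- mk_roh("i1", "1", 10e6, 20e6)
  # disjoint
  cnv <- tibble::tibble(individual = "i1", chrom = "1", start = 25e6,
                        end = 30e6, cn = 1L)
  expect_equal(nrow(intersect_roh_losses(roh, cnv)), 0)
  # overlap [18, 25) -> [18, 20), 2 Mb
  cnv2 <- tibble::tibble(individual = "i1", chrom = "1", start = 18e6,
                         end = 25e6, cn = 1L)
  lr <- intersect_roh_losses(roh, cnv2)
  expect_equal(lr$start, 18e6)
  expect_equal(lr$end, 20e6)
  expect_equal(lr$end - lr$start, 2e6)
  # duplications never produce loss regions
  cnv3 <- cnv2; cnv3$cn <- 3L
  expect_equal(nrow(intersect_roh_losses(roh, cnv3)), 0)
  # other individuals and chromosomes do not intersect
  cnv4 <- dplyr::bind_rows(
    tibble::tibble(individual = "i2", chrom = "1", start = 18e6, end = 25e6,
                   cn = 1L),
    tibble::tibble(individual = "i1", chrom = "2", start = 18e6, end = 25e6,
                   cn = 0L))
  expect_equal(nrow(intersect_roh_losses(roh, cnv4)), 0)
  # malformed intervals are rejected with the row number
  cnv5 <- tibble::tibble(individual = "i1", chrom = "1", start = 5e6,
                         end = 5e6, cn = 1L)
  expect_error(intersect_roh_losses(roh, cnv5), "row 1")
})

test_that("copy-loss classification thresholds the regional mean LRR", {
  map <- tibble::tibble(chrom = "1", marker = paste0("m", 1:5),
                        bp = c(11, 12, 13, 21, 22) * 1e5)
  region <- tibble::tibble(individual = "i1", chrom = "1", start = 1e6,
                           end = 1.4e6, roh_id = 1L, cnv_id = 1L,
                           roh_length_bp = 3e6)
  intensity <- tibble::tibble(
    marker = rep(paste0("m", 1:5), 2),
    individual = rep(c("i1", "i2"), each = 5),
    lrr = c(-0.6, -0.5, -0.4, 0, 0, 0.1, -0.1, 0, 0, 0),
    baf = 0.5)
  cl <- classify_copy_loss(region, intensity, map)
  expect_equal(cl$n_markers, 3L)
  expect_equal(cl$mean_lrr, -0.5)
  expect_true(cl$flagged)
  # mean 0.0 for the same region in another individual: not flagged
  region2 <- region; region2$individual <- "i2"
  region2$start <- 1e6; region2$end <- 1.3e6 - 1  # markers m1, m2
  cl2 <- classify_copy_loss(region2, intensity, map)
  expect_equal(cl2$mean_lrr, 0)
  expect_false(cl2$flagged)
  # a region with no markers is reported but never flagged
  region3 <- region; region3$start <- 5e6; region3$end <- 6e6
  cl3 <- classify_copy_loss(region3, intensity, map)
  expect_equal(cl3$n_markers, 0L)
  expect_false(cl3$flagged)
})

test_that("lowering the LRR threshold never enlarges the flagged set", {
  set.seed(33)
  map <- tibble::tibble(chrom = "1", marker = paste0("m", 1:50),
                        bp = seq(1e5, 5e6, by = 1e5))
  regions <- tibble::tibble(individual = "i1", chrom = "1",
                            start = seq(0, 4.5e6, by = 5e5),
                            end = seq(5e5, 5e6, by = 5e5),
                            roh_id = 1:10, cnv_id = 1:10,
                            roh_length_bp = 5e6)
  intensity <- tibble::tibble(marker = paste0("m", 1:50), individual = "i1",
                              lrr = rnorm(50, -0.3, 0.3), baf = 0.5)
  f1 <- classify_copy_loss(regions, intensity, map, lrr_threshold = -0.2)
  f2 <- classify_copy_loss(regions, intensity, map, lrr_threshold = -0.4)
  expect_true(all(which(f2$flagged) %in% which(f1$flagged)))
})

test_that("adjustment subtracts merged flagged lengths, clamped at zero", {
  roh_inb <- tibble::tibble(individual = c("i1", "i2"),
                            f_roh = c(0.10, 0.05), f_roh_long = c(0.08, 0.05),
                            denominator_bp = 1e8)
  global_inb <- tibble::tibble(individual = c("i1", "i2"),
                               f_g = c(0.12, 0.06))
  # no flagged regions: adjusted equals raw
  none <- tibble::tibble(individual = character(0), chrom = character(0),
                         start = numeric(0), end = numeric(0),
                         roh_id = integer(0), cnv_id = integer(0),
                         roh_length_bp = numeric(0), n_markers = integer(0),
                         mean_lrr = numeric(0), flagged = logical(0))
  adj0 <- adjust_inbreeding(roh_inb, global_inb, none)
  expect_equal(adj0$f_roh_adj, adj0$f_roh_raw)
  expect_equal(adj0$f_g_adj, adj0$f_g_raw)
  # one flagged 2 Mb region on a 100 Mb denominator: F drops by 0.02
  one <- tibble::tibble(individual = "i1", chrom = "1", start = 10e6,
                        end = 12e6, roh_id = 1L, cnv_id = 1L,
                        roh_length_bp = 5e6, n_markers = 10L,
                        mean_lrr = -0.5, flagged = TRUE)
  adj1 <- adjust_inbreeding(roh_inb, global_inb, one)
  expect_equal(adj1$f_roh_adj[1], 0.10 - 0.02)
  expect_equal(adj1$f_roh_long_adj[1], 0.08 - 0.02)  # host ROH is 5 Mb > 2 Mb
  expect_equal(adj1$f_g_adj[1], 0.12 - 0.02)
  expect_equal(adj1$f_roh_adj[2], 0.05)  # untouched individual
  # flagged region inside a short ROH leaves the long metric alone
  short_host <- one; short_host$roh_length_bp <- 1.5e6
  adj2 <- adjust_inbreeding(roh_inb, global_inb, short_host)
  expect_equal(adj2$f_roh_adj[1], 0.08)
  expect_equal(adj2$f_roh_long_adj[1], 0.08)
  # overlapping flagged regions are merged before subtraction
  two <- dplyr::bind_rows(one, dplyr::mutate(one, start = 11e6, end = 13e6,
                                             cnv_id = 2L))
  adj3 <- adjust_inbreeding(roh_inb, global_inb, two)
  expect_equal(adj3$loss_bp[1], 3e6)  # [10,12) U [11,13) = [10,13)
  expect_equal(adj3$f_roh_adj[1], 0.10 - 0.03)
  # clamped at zero when the loss exceeds the metric
  big <- one; big$end <- one$start + 15e6; big$roh_length_bp <- 20e6
  adj4 <- adjust_inbreeding(roh_inb, global_inb, big)
  expect_equal(adj4$f_roh_adj[1], 0)
  # unknown individuals are rejected
  stray <- one; stray$individual <- "ghost"
  expect_error(adjust_inbreeding(roh_inb, global_inb, stray), "ghost")
})

test_that("adjusted values never exceed raw values on simulated cohorts", {
  cfg <- sim_config(n_individuals = 5,
                    chromosomes = setNames(rep(4e7, 4), paste0("c", 1:4)),
                    marker_density = 25,
                    mixing_proportions = mixing_for_autozygosity(0.15),
                    n_deletions = 2,
                    deletion_length_law = function(n) rexp(n, 1 / 2e6) + 5e5,
                    seed = 303)
  sim <- simulate_dataset(cfg)
  fit <- suppressWarnings(fit_hbd(sim$data))
  roh <- call_roh(fit)
  rm <- roh_metrics(roh, sim$data$map, individuals = rownames(sim$data$geno))
  gi <- global_and_class_inbreeding(fit)$global
  cl <- classify_copy_loss(intersect_roh_losses(roh, sim$cnv),
                           sim$intensity, sim$data$map)
  adj <- adjust_inbreeding(rm, gi, cl)
  expect_true(all(adj$f_roh_adj <= adj$f_roh_raw + 1e-12))
  expect_true(all(adj$f_roh_long_adj <= adj$f_roh_long_raw + 1e-12))
  expect_true(all(adj$f_g_adj <= adj$f_g_raw + 1e-12))
  expect_true(all(adj$f_roh_adj >= 0 & adj$f_g_adj >= 0))
  # conservation: subtracted length equals the merged flagged length
  merged <- mosaicf:::merge_regions(cl[cl$flagged, ])
  total <- sum(merged$end - merged$start)
  expect_equal(sum(adj$loss_bp), total)
})

test_that("evidence reports separate true ROH from hemizygous deletions", {
  cfg <- sim_config(n_individuals = 4,
                    chromosomes = setNames(rep(4e7, 3), paste0("c", 1:3)),
                    marker_density = 25,
                    mixing_proportions = mixing_for_autozygosity(0.2),
                    n_deletions = 2,
                    deletion_length_law = function(n) rep(1e6, n), seed = 304)
  sim <- simulate_dataset(cfg)
  # deletion regions: depressed LRR, BAF at the poles
  ev_del <- region_evidence_report(sim$deletions, sim$intensity, sim$data$map)
  expect_true(all(ev_del$mean_lrr < -0.3))
  expect_true(all(ev_del$baf_near_half < 0.05))
  # true HBD segments without deletions: LRR near zero, BAF off 0.5
  hbd <- sim$truth$segments
  hbd <- hbd[hbd$class < 12 & (hbd$end - hbd$start) > 2e6, ][1:3, ]
  ev_roh <- region_evidence_report(hbd, sim$intensity, sim$data$map)
  expect_true(all(abs(ev_roh$mean_lrr) < 0.15))
  expect_true(all(ev_roh$baf_near_half < 0.2))
  # empty in, empty out
  expect_equal(nrow(region_evidence_report(hbd[0, ], sim$intensity,
                                           sim$data$map)), 0)
})
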