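test_that("default wild-type configuration encodes the study conditions", {
  sch <- channel_scheme()
  cfg <- default_wildtype_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(sum(cfg$ir_rate_per_80gy[sch$group == "snv"]), 36.63)
  # flat radiation signature: every SNV channel carries total/96
  expect_true(all(cfg$ir_rate_per_80gy[sch$group == "snv"] == 36.63 / 96))
  expect_equal(sum(cfg$ir_rate_per_80gy[sch$group == "dnv"]), 1.3)
  expect_equal(sum(cfg$ir_rate_per_80gy[sch$group == "indel"]), 4)
  expect_equal(sum(cfg$ir_rate_per_80gy[sch$group == "sv"]), 1.4)
  expect_equal(cfg$doses_gy, c(0, 20, 40, 60, 80))
  expect_equal(cfg$replicates_per_dose, 3L)
  expect_equal(cfg$cluster_fraction, 0.06)
  expect_equal(cfg$cluster_size_range, c(2L, 3L))
  expect_equal(cfg$cluster_span_range, c(10L, 20L))
  expect_equal(sum(cfg$background_per_genome), 1)
})

test_that("zero rates give zero variants; dose 0 gives background only", {
  cfg <- small_config(seed = 2L,
                      background_per_genome = rep(0, 119),
                      ir_rate_per_80gy = rep(0, 119))
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$variants), 0L)
  expect_true(all(sim$realized == 0L))
  # nonzero radiation rate but dose 0 and no background: still nothing
  cfg2 <- small_config(seed = 2L, doses_gy = 0,
                       background_per_genome = rep(0, 119))
  cfg2$ir_rate_per_80gy <- default_wildtype_config()$ir_rate_per_80gy
  sim2 <- simulate_experiment(cfg2)
  expect_equal(nrow(sim2$variants), 0L)
})

test_that("identical seeds reproduce byte-identical VCF output", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_config(seed = 9L)
  write_experiment(simulate_experiment(cfg), d1)
  write_experiment(simulate_experiment(small_config(seed = 9L)), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the variant set
  d3 <- withr::local_tempdir()
  write_experiment(simulate_experiment(small_config(seed = 10L)), d3)
  vcfs <- grep("vcf$", list.files(d1), value = TRUE)
  expect_false(all(vapply(vcfs, function(f)
    identical(readLines(file.path(d1, f)), readLines(file.path(d3, f))),
    TRUE)))
})

test_that("the classifier recovers the generator's realized counts exactly", {
  sch <- channel_scheme()
  sim <- simulate_experiment(small_config(seed = 21L))
  sp <- spectrum_matrix(sim$variants, sim$samples, sim$genome, sch)
  expect_equal(unname(sp[, seq_len(119L)]), unname(sim$realized))
  expect_true(all(sp[, "unclassified"] == 0L))
})

test_that("per-channel means follow the flat radiation signature", {
  # many 80 Gy genomes: every SNV channel mean within Monte-Carlo error
  # of total/96 (threshold 3.7 accounts for testing 96 channels at once)
  sch <- channel_scheme()
  cfg <- small_config(seed = 31L, doses_gy = 80, replicates_per_dose = 250L,
                      cluster_fraction = 0,
                      background_per_genome = rep(0, 119))
  sim <- simulate_experiment(cfg)
  snv <- which(sch$group == "snv")
  counts <- sim$realized[, snv]
  lambda <- 36.63 / 96
  z <- (colMeans(counts) - lambda) / sqrt(lambda / nrow(counts))
  expect_lt(max(abs(z)), 3.7)
  # aggregate matches the configured total
  expect_lt(abs(mean(rowSums(counts)) - 36.63), 3 * sqrt(36.63 / 250))
})

test_that("empirical totals track background + dose-scaled rates", {
  cfg <- small_config(seed = 41L, replicates_per_dose = 40L,
                      doses_gy = c(0, 40, 80))
  sim <- simulate_experiment(cfg)
  tot_rate <- sum(cfg$ir_rate_per_80gy)
  bg <- sum(cfg$background_per_genome)
  for (d in cfg$doses_gy) {
    ids <- sim$samples$sample_id[sim$samples$dose_gy == d]
    m <- mean(rowSums(sim$realized[ids, , drop = FALSE]))
    mu <- bg + (d / 80) * tot_rate
    expect_lt(abs(m - mu), 3 * sqrt(mu / length(ids)))
  }
})

test_that("cluster placement hits the configured fraction and geometry", {
  cfg <- small_config(seed = 51L, doses_gy = 80, replicates_per_dose = 60L,
                      chrom_lengths = c(cA = 2000000L, cB = 2000000L))
  sim <- simulate_experiment(cfg)
  calls <- detect_clusters(sim$variants, sim$samples, method = "window")
  summ <- summarize_clusters(calls, sim$variants, sim$samples)
  # recovered clustered proportion within 2 percentage points of planted 6%
  expect_lt(abs(summ$prop_clustered - 0.06), 0.02)
  # cluster geometry: sizes 2-3, spans 10-20 bp dominate the calls
  expect_true(summ$size_median %in% 2:3)
  expect_true(summ$span_median >= 10 && summ$span_median <= 20)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(background_per_genome = rep(1, 10)))
  expect_error(sim_config(cluster_fraction = 1.5))
  expect_error(sim_config(cluster_size_range = c(1L, 3L)))
  expect_error(sim_config(genotype_lfc = list(mut = rep(0, 119))),
               "wild-type")
})
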