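test_that("window caller worked examples", {
  cc <- call_clusters_window(data.frame(chrom = "c",
                                        pos = c(100, 600, 1000000)))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$members[[1]], c(100, 600))
  expect_equal(cc$span_bp, 500)
  # chained gaps of 900 bp link transitively into one cluster of 4
  cc2 <- call_clusters_window(data.frame(chrom = "c",
                                         pos = c(1, 901, 1801, 2701)))
  expect_equal(cc2$n, 4L)
  expect_equal(nrow(call_clusters_window(
    data.frame(chrom = character(), pos = integer()))), 0L)
})

test_that("window caller equals the O(n^2) linkage oracle on random instances", {
  set.seed(17)
  for (i in 1:30) {
    n <- sample(2:200, 1)
    pos <- sort(sample.int(50000L, n))
    cc <- call_clusters_window(data.frame(chrom = "c", pos = pos))
    oracle <- linkage_cluster_oracle(pos)
    expect_equal(nrow(cc), length(oracle))
    if (nrow(cc)) expect_equal(cc$members, oracle)
  }
})

test_that("window calls are translation invariant and chromosome bounded", {
  set.seed(23)
  pos <- sort(sample.int(30000L, 60))
  a <- call_clusters_window(data.frame(chrom = "c", pos = pos))
  b <- call_clusters_window(data.frame(chrom = "c", pos = pos + 77777L))
  expect_equal(a$n, b$n)
  expect_equal(a$span_bp, b$span_bp)
  expect_equal(b$start, a$start + 77777L)
  # the same positions on different chromosomes never join
  two <- call_clusters_window(data.frame(
    chrom = c("c1", "c2"), pos = c(100L, 150L)))
  expect_equal(nrow(two), 0L)
})

test_that("HMM caller worked examples", {
  # all gaps far beyond both emission scales: nothing called
  none <- call_clusters_hmm(data.frame(chrom = "c",
                                       pos = c(1e6, 2e6, 3e6)))
  expect_equal(nrow(none), 0L)
  # a 5 bp pair amid megabase gaps is decoded as clustered
  pair <- call_clusters_hmm(data.frame(
    chrom = "c", pos = c(1e6, 2e6, 2000005, 3e6)))
  expect_equal(nrow(pair), 1L)
  expect_equal(pair$n, 2L)
  expect_equal(pair$members[[1]], c(2e6, 2000005))
  expect_error(hmm_params(p_enter = 0), "p_enter")
})

test_that("Viterbi decode equals exhaustive path enumeration for small n", {
  params <- hmm_params()
  set.seed(31)
  for (i in 1:25) {
    n_gaps <- sample(1:11, 1)
    gaps <- sample(c(5L, 20L, 100L, 5000L, 100000L), n_gaps,
                   replace = TRUE)
    mb <- 50000
    expect_equal(radsig:::.viterbi_gaps(gaps, params, mb),
                 viterbi_oracle(gaps, params, mb),
                 label = paste("gaps:", paste(gaps, collapse = ",")))
  }
})

test_that("summaries report planted clustering and scale correctly", {
  sim <- simulate_experiment(small_config(
    seed = 101L, doses_gy = 80, replicates_per_dose = 50L,
    chrom_lengths = c(cA = 2000000L, cB = 2000000L)))
  calls <- detect_clusters(sim$variants, sim$samples)
  summ <- summarize_clusters(calls, sim$variants, sim$samples)
  ps <- attr(summ, "per_sample")
  expect_equal(sum(ps$n_clustered),
               sum(calls$n))
  # no clusters: zero proportion
  empty <- summarize_clusters(
    detect_clusters(sim$variants[0, ], sim$samples),
    sim$variants[0, ], sim$samples)
  expect_equal(empty$prop_clustered, 0)
  expect_equal(empty$n_clusters, 0L)
  # doubling the eligible mutations with unchanged calls halves the
  # clustered proportion
  p1 <- sum(ps$n_clustered) / sum(ps$n_eligible)
  doubled <- rbind(sim$variants, transform(sim$variants, pos = pos + 3e5L))
  summ2 <- summarize_clusters(calls, doubled, sim$samples)
  expect_equal(summ2$prop_clustered, p1 / 2)
})

test_that("pooled mode pools by genotype and generation", {
  # two samples, each with one isolated mutation 400 bp apart: only the
  # pooled analysis links them
  v <- variant_records(c("s1", "s2"), "c", c(1000L, 1400L), c("A", "C"),
                       c("G", "T"), "SNV")
  metas <- sample_sheet(c("s1", "s2"), "g", c(80, 80), 1:2)
  per_sample <- detect_clusters(v, metas)
  expect_equal(nrow(per_sample), 0L)
  pooled <- detect_clusters(v, metas, pooled = TRUE)
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$n, 2L)
})

test_that("the clustering dose model matches the normal equations", {
  # constant response: zero slope; exact line: recovered exactly
  # exact fits trigger lm's perfect-fit warning by construction
  cm0 <- suppressWarnings(
    clustering_dose_model(c(0, 20, 40, 60, 80), rep(0.3, 5)))
  expect_equal(cm0$slope, 0, tolerance = 1e-12)
  cml <- suppressWarnings(
    clustering_dose_model(c(0, 20, 40, 60, 80),
                          0.001 * c(0, 20, 40, 60, 80)))
  expect_equal(cml$slope, 0.001, tolerance = 1e-12)
  expect_equal(cml$sigma2, 0, tolerance = 1e-20)
  set.seed(5)
  d <- rep(c(0, 20, 40, 60, 80), each = 3)
  y <- 0.01 + 0.0005 * d + rnorm(15, 0, 0.01)
  cm <- clustering_dose_model(d, y)
  X <- cbind(1, d)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(cm$intercept, beta[1], tolerance = 1e-10)
  expect_equal(cm$slope, beta[2], tolerance = 1e-10)
  expect_error(clustering_dose_model(c(0, 0, 80), c(1, 2, 3)),
               "3 dose levels")
})

test_that("clustering comparisons use the z-test with FDR control", {
  eq <- compare_clustering(1.2, 0.2, 1.2, 0.2)
  expect_equal(eq$z, 0)
  up <- compare_clustering(6, 0.5, 1.2, 0.2)
  expect_true(up$p < 1e-6 && up$direction == "up")
  summ <- data.frame(genotype = c("wild-type", "a", "b"),
                     clusters_per_80gy = c(1.2, 1.25, 6),
                     clusters_se = c(0.2, 0.2, 0.5))
  tab <- compare_clustering_table(summ)
  expect_false(tab$significant[tab$genotype == "a"])
  expect_true(tab$significant[tab$genotype == "b"])
})

test_that("BED export uses 0-based half-open intervals", {
  cc <- call_clusters_window(data.frame(chrom = "c",
                                        pos = c(100, 600, 1000000)))
  cc$sample_id <- "s1"
  f <- withr::local_tempfile(fileext = ".bed")
  write_clusters_bed(cc, f)
  expect_equal(readLines(f), "c\t99\t600\ts1:n=2")
})
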