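# Helper: simulate an experiment with an extra genotype defined by a
# per-class fold vector, reduced genome for speed.
sim_two_genotypes <- function(seed, lfc_vec, replicates = 4L,
                              rate_scale = 1) {
  cfg <- small_config(seed = seed, replicates_per_dose = replicates)
  cfg$ir_rate_per_80gy <- cfg$ir_rate_per_80gy * rate_scale
  cfg$genotype_lfc[["mutant"]] <- lfc_vec
  simulate_experiment(cfg)
}

test_that("posterior means match an independent grid MLE on a large-count toy", {
  sch <- channel_scheme()
  # comparable counts in every channel so the magnitude-matched priors are
  # a small perturbation; two designated channels carry planted
  # fold-changes
  set.seed(400)
  doses <- rep(c(0, 80), each = 5)
  metas <- sample_sheet(sprintf("s%02d", 1:20),
                        rep(c("wild-type", "mutant"), each = 10),
                        rep(doses, 2), rep(1:10, 2))
  ir_true <- rep(100, 119); ir_true[1] <- 150; ir_true[2] <- 50
  lfc_true <- rep(0, 119); lfc_true[1] <- log(1.5); lfc_true[2] <- log(0.5)
  bg_true <- rep(5, 119)
  tdose <- metas$dose_gy / 80
  rate <- ifelse(metas$genotype == "mutant", 1, 0)
  Y <- t(vapply(seq_len(20), function(s) {
    lam <- bg_true + tdose[s] * ir_true *
      exp(if (metas$genotype[s] == "mutant") lfc_true else 0 * lfc_true)
    rpois(119, lam)
  }, numeric(119)))
  rownames(Y) <- metas$sample_id

  fit <- fit_signature_model(Y, metas, chains = 2, warmup = 400,
                             iter = 400, seed = 8)
  # per channel the model separates into two additive Poisson fits on the
  # 0/1 dose scale; the grid oracle recovers ir and the mutant rate
  for (k in 1:2) {
    wt_rows <- metas$genotype == "wild-type"
    o_wt <- grid_poisson_mle(tdose[wt_rows], Y[wt_rows, k],
                             b_max = 30, r_max = 300)
    o_mu <- grid_poisson_mle(tdose[!wt_rows], Y[!wt_rows, k],
                             b_max = 30, r_max = 300)
    expect_equal(fit$ir_mean[k], o_wt$r, tolerance = 0.05,
                 ignore_attr = TRUE)
    expect_equal(fit$ir_mean[k] * exp(fit$lfc_mean[2, k]), o_mu$r,
                 tolerance = 0.05, ignore_attr = TRUE)
  }
})

test_that("null genotype recovers fold-changes near 1 in every class", {
  # rates scaled up so all four classes are count-rich and sampling noise
  # is small; the planted fold is exactly 1
  sch <- channel_scheme()
  cfg <- small_config(seed = 71L, replicates_per_dose = 4L)
  cfg$ir_rate_per_80gy <- cfg$ir_rate_per_80gy * 10
  cfg$ir_rate_per_80gy[sch$group %in% c("dnv", "mnv")] <- 5  # populate both aggregate channels
  cfg$genotype_lfc[["mutant"]] <- rep(0, 119)
  sim <- simulate_experiment(cfg)
  sp <- spectrum_matrix(sim$variants, sim$samples, sim$genome, sch)
  fit <- fit_signature_model(sp, sim$samples, chains = 2, warmup = 500,
                             iter = 500, seed = 71)
  for (cl in c("snv", "mnv", "indel", "sv")) {
    fc <- class_fold_change(fit, "mutant", cl)
    expect_gt(fc$fold, 0.8)
    expect_lt(fc$fold, 1.25)
  }
})

test_that("wild-type-only fits recover the radiation signature totals", {
  sch <- channel_scheme()
  sim <- simulate_experiment(small_config(seed = 81L,
                                          replicates_per_dose = 4L))
  sp <- spectrum_matrix(sim$variants, sim$samples, sim$genome, sch)
  fit <- fit_signature_model(sp, sim$samples, chains = 2, warmup = 500,
                             iter = 500, seed = 81)
  cls <- reporting_classes(sch)
  truth <- c(snv = 36.63, mnv = 1.3, indel = 4, sv = 1.4)
  for (cl in names(cls)) {
    draws <- rowSums(fit$draws$ir[, cls[[cl]], drop = FALSE])
    expect_lt(abs(mean(draws) - truth[[cl]]), 3 * sd(draws) + 1e-9,
              label = paste("class", cl))
  }
})

test_that("the z-test formula and its tails are exact", {
  zt <- z_test_rates(10, 1, 5, 1)
  expect_equal(zt$z, 5 / sqrt(2), tolerance = 1e-12)
  expect_equal(zt$p, 2 * pnorm(-5 / sqrt(2)), tolerance = 1e-12)
  expect_equal(zt$p, 4.07e-4, tolerance = 0.01)
  z0 <- z_test_rates(5, 1, 5, 1)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  expect_error(z_test_rates(1, 0, 1, 1), "positive standard errors")
})

test_that("BH adjustment equals the textbook step-up on exhaustive small cases", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  set.seed(99)
  for (n in 2:6) {
    base_p <- sort(runif(n))
    for (perm in combinat_perms(n)) {
      p <- base_p[unlist(perm)]
      expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
    }
  }
})

test_that("rate-estimate comparisons apply BH across the family", {
  mk <- function(g, cl, r, se) {
    e <- fit_rate(c(0, 80), c(0, 1), genotype = g, class_label = cl)
    e$per80 <- r; e$se_per80 <- se
    e
  }
  wt <- list(mk("wild-type", "snv", 36.6, 1.1))
  ests <- list(mk("a", "snv", 36.6, 1.1), mk("b", "snv", 80, 5))
  cmp <- compare_rate_estimates(ests, wt)
  expect_equal(cmp$z[1], 0)
  expect_equal(cmp$p[1], 1)
  expect_true(cmp$significant[2])
  expect_true(all(cmp$q >= cmp$p))
})

test_that("profile divergence is zero for identical signatures and detects shifts", {
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(cosine_similarity(c(2, 4), c(1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")

  sch <- channel_scheme()
  # a genuine spectral reshaping: doubling half of the SNV channels moves
  # the signature direction by a cosine distance of ~0.05, well above the
  # posterior-mean noise floor of a matched null fit
  lfc2 <- rep(0, 119); lfc2[which(sch$group == "snv")[1:48]] <- log(2)
  sim <- sim_two_genotypes(91L, lfc2, rate_scale = 3)
  sp <- spectrum_matrix(sim$variants, sim$samples, sim$genome, sch)
  fit <- fit_signature_model(sp, sim$samples, chains = 2, warmup = 500,
                             iter = 500, seed = 91)
  pd <- profile_divergence(fit, "mutant", allow_flagged = TRUE)

  sim0 <- sim_two_genotypes(92L, rep(0, 119), rate_scale = 3)
  sp0 <- spectrum_matrix(sim0$variants, sim0$samples, sim0$genome, sch)
  fit0 <- fit_signature_model(sp0, sim0$samples, chains = 2, warmup = 500,
                              iter = 500, seed = 92)
  pd0 <- profile_divergence(fit0, "mutant", allow_flagged = TRUE)
  expect_gt(pd$point, pd0$point)
})
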