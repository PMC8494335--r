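test_that("channel scheme has the fixed 119-channel structure", {
  sch <- channel_scheme()
  expect_length(sch$labels, 119L)
  expect_equal(anyDuplicated(sch$labels), 0L)
  expect_equal(as.integer(table(sch$group)[c("snv", "dnv", "mnv",
                                             "indel", "sv")]),
               c(96L, 1L, 1L, 14L, 7L))
  # index lookup is a bijection
  expect_equal(unname(sch$index[sch$labels]), seq_len(119L))
})

test_that("SNV classification reads the trinucleotide context and strand", {
  sch <- channel_scheme()
  g <- reference_genome(c(c1 = "AACAT", c2 = "ATGTT"))
  # C>T in A.C.A context
  v <- variant_records("s", "c1", 3L, "C", "T", "SNV")
  expect_equal(sch$labels[classify_variants(v, g, sch)], "A[C>T]A")
  # G>A with T.G.T context on c2 is the reverse-complement representation
  v2 <- variant_records("s", "c2", 3L, "G", "A", "SNV")
  expect_equal(sch$labels[classify_variants(v2, g, sch)], "A[C>T]A")
})

test_that("strand involution: a variant and its reverse-complement map to one channel", {
  sch <- channel_scheme()
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(11)
  for (i in 1:25) {
    tri <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                 collapse = "")
    rc <- paste(rev(comp[strsplit(tri, "")[[1]]]), collapse = "")
    ref <- substr(tri, 2, 2)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    g <- reference_genome(c(f = tri, r = rc))
    vf <- variant_records("s", "f", 2L, ref, alt, "SNV")
    vr <- variant_records("s", "r", 2L, comp[[ref]], comp[[alt]], "SNV")
    expect_equal(classify_variants(vf, g, sch),
                 classify_variants(vr, g, sch))
  }
})

test_that("indel and SV records land in the documented size bins and types", {
  sch <- channel_scheme()
  g <- toy_genome()
  del3 <- variant_records("s", "c1", 50L,
                          ref_base(g, "c1", 50L, 3L), "", "DEL")
  expect_equal(sch$labels[classify_variants(del3, g, sch)], "DEL_2_5")
  del1 <- variant_records("s", "c1", 60L, ref_base(g, "c1", 60L), "", "DEL")
  expect_equal(sch$labels[classify_variants(del1, g, sch)], "DEL_1")
  ins7 <- variant_records("s", "c1", 70L, "", "ACGTACG", "INS")
  expect_equal(sch$labels[classify_variants(ins7, g, sch)], "INS_6_50")
  indel2 <- variant_records("s", "c1", 80L,
                            ref_base(g, "c1", 80L, 2L), "GGG", "INDEL")
  expect_equal(sch$labels[classify_variants(indel2, g, sch)], "INDEL_1_5")
  td <- variant_records("s", "c1", 90L, "", "", "SV", sv_type = "TD",
                        sv_end_chrom = "c1", sv_end = 500L)
  expect_equal(sch$labels[classify_variants(td, g, sch)], "SV_TD")
  dnv_ref <- ref_base(g, "c1", 95L, 2L)
  dnv <- variant_records("s", "c1", 95L, dnv_ref,
                         chartr("ACGT", "TGCA", dnv_ref), "DNV")
  expect_equal(sch$labels[classify_variants(dnv, g, sch)], "DNV")
})

test_that("boundary and N contexts are unclassifiable, never silently dropped", {
  sch <- channel_scheme()
  g <- reference_genome(c(c1 = "CANTA"))
  # first base of the chromosome: no 5' flank
  v1 <- variant_records("s", "c1", 1L, "C", "T", "SNV")
  expect_true(is.na(classify_variants(v1, g, sch)))
  # N in the context window
  v2 <- variant_records("s", "c1", 2L, "A", "G", "SNV")
  expect_true(is.na(classify_variants(v2, g, sch)))
  sp <- count_spectrum(rbind(v1, v2), g, sch, sample_id = "s")
  expect_equal(sum(sp$counts), 0L)
  expect_equal(sp$unclassified, 2L)
})

test_that("reference mismatch is an error", {
  g <- reference_genome(c(c1 = "AACAT"))
  v <- variant_records("s", "c1", 3L, "G", "T", "SNV")
  expect_error(classify_variants(v, g), "reference mismatch")
})

test_that("count_spectrum conserves records and is additive", {
  sch <- channel_scheme()
  g <- toy_genome()
  sim <- simulate_experiment(small_config(seed = 3L))
  id <- sim$samples$sample_id[15]
  v <- sim$variants[sim$variants$sample_id == id, , drop = FALSE]
  sp <- count_spectrum(v, sim$genome, sch)
  expect_equal(sum(sp$counts) + sp$unclassified, nrow(v))
  # duplicating the input doubles every count
  sp2 <- count_spectrum(rbind(v, v), sim$genome, sch, sample_id = id)
  expect_equal(sp2$counts, 2L * sp$counts)
  # empty input gives the zero spectrum
  sp0 <- count_spectrum(v[0, ], sim$genome, sch, sample_id = "none")
  expect_equal(sum(sp0$counts), 0L)
})

test_that("class totals partition the 119 channels as 98 + 14 + 7", {
  sch <- channel_scheme()
  ones <- rep(1, 119)
  expect_equal(class_totals(ones, sch),
               c(substitutions = 98, indels = 14, svs = 7))
  expect_equal(unname(sum(class_totals(ones, sch))), 119)
  expect_equal(class_totals(rep(0, 119), sch),
               c(substitutions = 0, indels = 0, svs = 0))
})
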