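test_that("SCNA group boundaries partition the real line as documented", {
  expect_identical(as.character(assign_scna_group(-0.70)), "deep_loss")
  expect_identical(as.character(assign_scna_group(0.30)), "gain")
  expect_identical(as.character(assign_scna_group(0.0)), "neutral")
  # boundary convention: neutral closed, deep/high strict
  expect_identical(as.character(assign_scna_group(c(-0.65, -0.2, 0.2, 0.65, 0.651))),
                   c("loss", "neutral", "neutral", "gain", "high_gain"))
  expect_error(assign_scna_group(NaN), "non-finite")
  # every finite value maps to exactly one group
  withr::with_seed(1, x <- runif(1000, -2, 2))
  expect_false(anyNA(assign_scna_group(x)))
})

test_that("neutral group selection and medians follow the +-0.2 window", {
  dna <- make_om(matrix(c(0.0, 0.1, 0.5,
                          0.9, 0.9, 0.9), 2, 3, byrow = TRUE),
                 "dna_log2_ratio")
  rna <- make_om(matrix(c(4, 8, 16,
                          4, 8, 16), 2, 3, byrow = TRUE),
                 "rna_abundance", "linear")
  prot <- make_om(matrix(c(0.1, 0.3, 0.5,
                           0, 0, 0), 2, 3, byrow = TRUE),
                  "protein_abundance")
  ds <- align_dataset(dna, rna, prot)
  ref <- define_neutral_group(ds, min_neutral = 2)
  r1 <- ref[ref$gene == "g1", ]
  expect_equal(r1$n_neutral_samples, 2)     # 0.0 and 0.1 only
  expect_equal(r1$neutral_rna, 6)           # median(4, 8) on the linear scale
  expect_equal(r1$neutral_dna, 0.05)
  expect_false(r1$flagged)
  r2 <- ref[ref$gene == "g2", ]
  expect_equal(r2$n_neutral_samples, 0)     # all ratios 0.9: no reference
  expect_true(r2$flagged)
})

test_that("log2 fold changes respect each layer's declared scale", {
  dna <- make_om(matrix(c(0, 0, 1), 1, 3), "dna_log2_ratio")
  rna <- make_om(matrix(c(8, 8, 16), 1, 3), "rna_abundance", "linear")
  prot <- make_om(matrix(c(0.1, 0.1, 0.3), 1, 3), "protein_abundance")
  ds <- align_dataset(dna, rna, prot)
  fc <- compute_log2fc(ds, define_neutral_group(ds, min_neutral = 2))
  s3 <- fc[fc$sample == "s3", ]
  expect_equal(s3$dna_l2fc, 1)
  expect_equal(s3$rna_l2fc, 1)              # log2(16 / 8)
  expect_equal(s3$protein_l2fc, 0.2)        # 0.3 - 0.1 on the log2 scale
  expect_identical(as.character(s3$scna_group), "high_gain")
  s1 <- fc[fc$sample == "s1", ]
  expect_equal(s1$dna_l2fc, 0)
  expect_identical(as.character(s1$scna_group), "neutral")
  # nonpositive linear value is an error, not a silent NaN
  rna_bad <- make_om(matrix(c(-8, 8, 16), 1, 3), "rna_abundance", "linear")
  ds_bad <- align_dataset(dna, rna_bad, prot)
  expect_error(compute_log2fc(ds_bad, define_neutral_group(ds_bad, min_neutral = 2)),
               "nonpositive")
})

test_that("neutral-referenced DNA fold change is robust to a shifted baseline", {
  # same data as above but every DNA ratio shifted by +0.1: fold changes
  # relative to the neutral median must be unchanged
  dna <- make_om(matrix(c(0, 0, 1) + 0.1, 1, 3), "dna_log2_ratio")
  rna <- make_om(matrix(c(8, 8, 16), 1, 3), "rna_abundance", "linear")
  prot <- make_om(matrix(c(0.1, 0.1, 0.3), 1, 3), "protein_abundance")
  ds <- align_dataset(dna, rna, prot)
  fc <- compute_log2fc(ds, define_neutral_group(ds, min_neutral = 2))
  expect_equal(fc$dna_l2fc[fc$sample == "s3"], 1)
})

test_that("low-expression filter removes the configured count with deterministic ties", {
  cfg <- simulation_config(n_genes = 100, n_samples = 20, n_pathways = 10,
                           seed = 2)
  sim <- simulate_proteogenomics(cfg)
  ds <- filter_low_expression(sim$dataset, quantile = 0.10)
  expect_equal(sum(ds$excluded$reason == "low_expression"), 10)
  # quantile 0 removes nothing
  ds0 <- filter_low_expression(sim$dataset, quantile = 0)
  expect_equal(nrow(ds0$excluded), 0)
  expect_error(filter_low_expression(sim$dataset, quantile = 1), "quantile")
  # all-equal RNA: removal is by gene-identifier order
  ds_tie <- sim$dataset
  ds_tie$rna[] <- 1
  ds_tie <- filter_low_expression(ds_tie, quantile = 0.10)
  excl <- sort(ds_tie$excluded$gene)
  expect_identical(excl, sort(rownames(sim$dataset$rna))[1:10])
})

test_that("low-DNA-variance filter uses the strict more-than-70% rule", {
  mk <- function(inside_n) {
    v <- c(rep(0, inside_n), rep(0.5, 10 - inside_n))
    make_om(matrix(v, 1, 10), "dna_log2_ratio")
  }
  rna <- make_om(matrix(8, 1, 10), "rna_abundance", "linear")
  prot <- make_om(matrix(0, 1, 10), "protein_abundance")
  ds8 <- align_dataset(mk(8), rna, prot)
  ds8 <- filter_low_dna_variance(ds8)
  expect_equal(nrow(ds8$excluded), 1)       # 0.8 > 0.7: removed
  ds7 <- align_dataset(mk(7), rna, prot)
  ds7 <- filter_low_dna_variance(ds7)
  expect_equal(nrow(ds7$excluded), 0)       # exactly 0.7: kept
  ds0 <- align_dataset(mk(0), rna, prot)
  ds0 <- filter_low_dna_variance(ds0)
  expect_equal(nrow(ds0$excluded), 0)       # all |ratio| >= 0.05: kept
  expect_error(filter_low_dna_variance(ds0, frac = 0), "frac")
})

test_that("zero-noise, zero-compensation simulation gives rna_l2fc == dna_l2fc", {
  cfg <- noiseless_config(n_genes = 40, n_samples = 30, c_rna = 0, c_prot = 0,
                          seed = 3)
  sim <- simulate_proteogenomics(cfg)
  ref <- define_neutral_group(sim$dataset, min_neutral = 2)
  fc <- compute_log2fc(sim$dataset, ref)
  expect_lt(max(abs(fc$rna_l2fc - fc$dna_l2fc), na.rm = TRUE), 1e-9)
  # neutral samples stay within the window width by construction
  neu <- fc[fc$scna_group == "neutral", ]
  expect_lte(max(abs(neu$dna_l2fc)), 0.4)
})
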