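test_that("compensation score closed forms and sign symmetry hold", {
  expect_equal(compensation_score(1.0, 0.0), 1.0)
  expect_equal(compensation_score(-0.8, -0.3), 0.5)
  expect_equal(compensation_score(0.65, 0.65), 0.0)
  withr::with_seed(7, {
    d <- runif(500, -2, 2)
    d <- d[d != 0]
    x <- rnorm(length(d))
  })
  expect_equal(compensation_score(d, x), compensation_score(-d, -x))
  expect_equal(compensation_score(d, d), rep(0, length(d)))
  expect_equal(compensation_score(d, 0 * d), abs(d))
  expect_error(compensation_score(0, 1), "undefined")
})

test_that("bootstrap median test handles degenerate and shifted samples", {
  r <- bootstrap_median_test(rep(0.5, 30), n_boot = 500, seed = 1)
  expect_equal(r$statistic, 0.5)
  expect_equal(r$p_value, 1 / 501)          # no resampled median can be <= 0
  expect_true(r$ci_low <= r$statistic && r$statistic <= r$ci_high)
  withr::with_seed(1, v <- rnorm(50, mean = 0.3))
  r2 <- bootstrap_median_test(v, n_boot = 2000, seed = 1)
  expect_lt(r2$p_value, 0.05)
  expect_error(bootstrap_median_test(1), "at least 2")
  expect_error(bootstrap_median_test(1:5, n_boot = 10), "n_boot")
})

test_that("bootstrap median p-values center on one-half under a symmetric null", {
  # for any single symmetric-null dataset the p-value is close to uniform,
  # so the sign-symmetry argument pins down its mean, not its value:
  # averaged over datasets it must sit at one half
  ps <- withr::with_seed(42, vapply(1:24, function(i) {
    bootstrap_median_test(rnorm(2000), n_boot = 400, seed = i)$p_value
  }, numeric(1)))
  expect_gt(mean(ps), 0.33)
  expect_lt(mean(ps), 0.67)
})

test_that("bootstrap tests are deterministic under a fixed seed", {
  withr::with_seed(3, v <- rnorm(40, 0.2))
  a <- bootstrap_median_test(v, n_boot = 500, seed = 11)
  b <- bootstrap_median_test(v, n_boot = 500, seed = 11)
  expect_identical(a, b)
  withr::with_seed(4, w <- rnorm(40))
  d1 <- bootstrap_difference_test(v, w, n_boot = 500, seed = 11)
  d2 <- bootstrap_difference_test(v, w, n_boot = 500, seed = 11)
  expect_identical(d1, d2)
})

test_that("difference test statistic is the median difference and is symmetric", {
  d <- bootstrap_difference_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6),
                                 n_boot = 500, seed = 1)
  expect_equal(d$statistic, -0.3)
  withr::with_seed(5, v <- rnorm(200))
  same <- bootstrap_difference_test(v, v, n_boot = 1000, seed = 2)
  expect_equal(same$statistic, 0)
  expect_gt(same$p_value, 0.5)
  expect_error(bootstrap_difference_test(numeric(0), v), "at least 2")
})

test_that("difference test is calibrated when both groups share a distribution", {
  # 60 replicate null datasets; rejection at alpha = 0.05 should be rare
  # but nonzero (binomial check with a generous band)
  rej <- withr::with_seed(8, {
    vapply(1:60, function(i) {
      a <- rnorm(80)
      b <- rnorm(80)
      bootstrap_difference_test(a, b, n_boot = 400, seed = i)$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(rej), 0)
  expect_lte(mean(rej), 0.15)
})

test_that("BH adjustment matches the hand-computed step-up values", {
  # by hand: sorted p (0.01, 0.02, 0.03), n = 3 ->
  # (0.01*3/1, 0.02*3/2, 0.03*3/3) = (0.03, 0.03, 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(1.0), 1.0)
  withr::with_seed(2, p <- sort(runif(50)))
  expect_true(all(diff(fdr_adjust(p)) >= 0))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("group summaries recover the constructed compensation ordering", {
  # complex genes fully protein-compensated, non-complex not at all
  cfg <- noiseless_config(n_genes = 120, n_samples = 60, c_rna = 0,
                          scna_event_rate = 0.4, seed = 21)
  cn <- simulate_copy_number(cfg)
  cn$truth$genes$c_prot <- ifelse(cn$truth$genes$is_complex, 0.9, 0.1)
  ex <- simulate_expression(cn$dna, cn$truth, cfg)
  ds <- align_dataset(cn$dna, ex$rna, ex$protein,
                      gene_annotation = cn$truth$genes[, c("gene", "is_complex",
                                                           "is_ribosomal")])
  fc <- compute_log2fc(ds, define_neutral_group(ds))
  cs <- compute_compensation(fc, gene_annotation = ds$gene_annotation)
  summ <- summarize_group_cs(cs, n_boot = 500, seed = 3, min_cell_size = 10)
  prot <- summ[summ$layer == "protein", ]
  expect_true(all(prot$diff_median > 0))    # complex minus non-complex
  expect_true(all(prot$diff_fdr < 0.005))
  rna <- summ[summ$layer == "rna", ]
  expect_true(all(abs(rna$median_cs) < 1e-9))   # c_rna = 0: no RNA compensation
  # under-sized cells are reported missing, not tested
  small <- summarize_group_cs(cs[1:30, ], n_boot = 500, seed = 3,
                              min_cell_size = 1e4)
  expect_true(all(is.na(small$median_cs)))
})

test_that("tidy and glance expose bootstrap results as tibbles", {
  r <- bootstrap_median_test(c(0.2, 0.4, 0.6, 0.8), n_boot = 200, seed = 1)
  td <- generics::tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("type", "statistic", "ci_low", "ci_high", "p_value"))
  gl <- generics::glance(r)
  expect_equal(gl$n_boot, 200)
})
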