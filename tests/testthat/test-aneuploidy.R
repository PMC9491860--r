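test_that("segment windowing applies length-weighted means within arms", {
  arms <- toy_arms()
  seg <- tibble::tibble(
    sample = "S1",
    chrom = c("chr1", "chr2", "chr2"),
    start = c(0, 0, 1e5),
    end = c(1e6, 1e5, 2e5),
    log2_ratio = c(0.4, 0.0, 1.0)
  )
  w <- segments_to_windows(seg, arms, window_size = 2e5)
  chr1p <- w[w$chrom == "chr1" & w$arm == "p", ]
  expect_true(all(chr1p$log2_ratio == 0.4))          # one segment spans the arm
  chr2w1 <- w[w$chrom == "chr2" & w$window_start == 0, ]
  expect_equal(chr2w1$log2_ratio, 0.5)               # equal halves at 0 and 1
  # chr1q has no segments: all its windows missing
  expect_true(all(is.na(w$log2_ratio[w$chrom == "chr1" & w$arm == "q"])))
  expect_error(segments_to_windows(seg, arms, window_size = 0), "positive")
})

test_that("arm calls use strict +-0.2 thresholds and a coverage floor", {
  arms <- toy_arms()[1, ]
  mk <- function(ratio) tibble::tibble(sample = "S1", chrom = "chr1",
                                       start = 0, end = 1e6,
                                       log2_ratio = ratio)
  call_of <- function(ratio) {
    w <- segments_to_windows(mk(ratio), arms, window_size = 1e5)
    as.character(windows_to_arm_calls(w)$call)
  }
  expect_identical(call_of(0.2), "neutral")           # boundary is strict
  expect_identical(call_of(0.2 + 1e-9), "gain")
  expect_identical(call_of(-0.25), "loss")
  expect_identical(call_of(0.0), "neutral")
  # coverage below the floor gives a missing call
  half <- tibble::tibble(sample = "S1", chrom = "chr1", start = 0, end = 3e5,
                         log2_ratio = 0.5)
  w <- segments_to_windows(half, arms, window_size = 1e5)
  expect_true(is.na(windows_to_arm_calls(w, min_window_frac = 0.5)$call))
})

test_that("aneuploidy scores count non-neutral arms and match simulated truth", {
  calls <- tibble::tibble(
    sample = rep(c("S1", "S2"), each = 3),
    chrom = rep(c("chr1", "chr1", "chr2"), 2),
    arm = rep(c("p", "q", "q"), 2),
    arm_log2_ratio = c(0.5, -0.5, 0, 0, 0, 0),
    call = factor(c("gain", "loss", "neutral", "neutral", "neutral", "neutral"),
                  levels = c("loss", "neutral", "gain"))
  )
  sc <- compute_aneuploidy_score(calls)
  expect_equal(sc$aneuploidy_score[sc$sample == "S1"], 2)
  expect_equal(sc$aneuploidy_score[sc$sample == "S2"], 0)
  expect_equal(sc$n_arms_gained[sc$sample == "S1"], 1)
  # scores are invariant to arm ordering
  sc_perm <- compute_aneuploidy_score(calls[sample(nrow(calls)), ])
  expect_equal(dplyr::arrange(sc_perm, sample), dplyr::arrange(sc, sample))
  # end-to-end recovery on a simulated 39-arm genome
  cfg <- simulation_config(n_genes = 78, n_samples = 25, seed = 6)
  sim <- simulate_proteogenomics(cfg)
  w <- segments_to_windows(sim$segments, sim$arms, window_size = 1e6)
  est <- compute_aneuploidy_score(windows_to_arm_calls(w))
  tr <- sim$truth$samples
  expect_identical(est$aneuploidy_score[match(tr$sample, est$sample)],
                   tr$true_aneuploidy_score)
})

test_that("cell-cycle score averages log2 RNA over the listed genes", {
  rna <- make_om(matrix(c(2, 4, 6, 8), 2, 2, byrow = TRUE),
                 "rna_abundance", "log2", genes = c("MKI67", "CCNB1"))
  sc <- compute_cell_cycle_score(rna, c("MKI67", "CCNB1"))
  expect_equal(unname(sc), c(4, 6))
  expect_warning(sc2 <- compute_cell_cycle_score(rna, c("MKI67", "CCNB1", "XX")),
                 "absent")
  expect_equal(unname(sc2), c(4, 6))
  expect_error(compute_cell_cycle_score(rna, "nope"), "none of the listed")
  # linear RNA is converted to log2 first
  rna_lin <- make_om(matrix(c(4, 16), 1, 2), "rna_abundance", "linear",
                     genes = "MKI67")
  expect_equal(unname(compute_cell_cycle_score(rna_lin, "MKI67")), c(2, 4))
})

test_that("the aneuploidy linear model matches the closed-form OLS oracle", {
  # hand computation: Sxx = 5, Sxy = 6.5, beta = 1.3, SSE = 0.30,
  # SE = sqrt(0.15 / 5), t = 1.3 / sqrt(0.03)
  f <- fit_expression_model(c(0, 1, 2, 4), c(0, 1, 2, 3), gene = "g")
  expect_equal(f$beta_aneuploidy, 1.3, tolerance = 1e-12)
  expect_equal(f$t_value, 1.3 / sqrt(0.03), tolerance = 1e-6)
  expect_equal(f$n_samples, 4L)
  # degenerate: response identical to predictor
  d <- fit_expression_model(c(0, 1, 2, 3), c(0, 1, 2, 3))
  expect_true(d$degenerate)
  expect_identical(d$t_value, Inf)
  expect_error(fit_expression_model(1:5, rep(1, 5)), "constant aneuploidy")
  # an orthogonal covariate leaves the aneuploidy coefficient unchanged
  withr::with_seed(14, {
    x <- rnorm(60)
    z <- rnorm(60)
    z <- residuals(lm(z ~ x))                # exactly orthogonal to x
    y <- 2 * x + rnorm(60)
  })
  plain <- fit_expression_model(y, x)
  adj <- fit_expression_model(y, x, covariates = data.frame(z = z))
  expect_equal(adj$beta_aneuploidy, plain$beta_aneuploidy, tolerance = 1e-9)
})

test_that("null model t-values follow the Student-t reference distribution", {
  n <- 40
  withr::with_seed(15, {
    x <- rnorm(n)
    tvals <- vapply(1:600, function(i) {
      fit_expression_model(rnorm(n), x)$t_value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(tvals, stats::pt, df = n - 2))
  expect_lt(unname(ks$statistic), 0.06)
})

test_that("gene ranking is by descending t with deterministic ties", {
  fits <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         beta_aneuploidy = 1, t_value = c(2, -1, 0.5, 2),
                         p_value = 0.5, n_samples = 10L,
                         degenerate = c(FALSE, FALSE, FALSE, FALSE),
                         covariates = "")
  r <- rank_genes(fits)
  expect_identical(r$gene, c("a", "d", "c", "b"))
  fits$degenerate <- TRUE
  expect_error(rank_genes(fits), "no non-degenerate")
})

test_that("enrichment scores equal brute-force enumeration on short lists", {
  withr::with_seed(16, {
    for (n in 2:8) {
      scores <- sort(round(rnorm(n, sd = 2), 2), decreasing = TRUE)
      genes <- sprintf("g%d", 1:n)
      # every non-trivial subset as a candidate set
      for (mask in 1:(2^n - 2)) {
        in_set <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
        es <- scnareg:::gsea_es(in_set, scores, weight = 1)
        expect_equal(es$es, oracle_es(in_set, scores), tolerance = 1e-12)
      }
    }
  })
})

test_that("preranked enrichment agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(18, {
    genes <- sprintf("g%03d", 1:200)
    scores <- sort(rnorm(200, sd = 2), decreasing = TRUE)
    sets <- lapply(1:10, function(i) sample(genes, 25))
    names(sets) <- sprintf("S%02d", 1:10)
  })
  ranked <- tibble::tibble(gene = genes, t_value = scores)
  mine <- preranked_enrichment(ranked, sets, n_perm = 200, seed = 1)
  ref <- suppressWarnings(fgsea::fgsea(sets, setNames(scores, genes),
                                       scoreType = "std", nPermSimple = 200))
  m <- match(mine$set, ref$pathway)
  expect_equal(mine$es, ref$ES[m], tolerance = 1e-9)
})

test_that("preranked enrichment flags degenerate sets and detects a planted signal", {
  genes <- sprintf("g%03d", 1:100)
  scores <- seq(5, -5, length.out = 100)
  ranked <- tibble::tibble(gene = genes, t_value = scores)
  expect_message(
    res <- preranked_enrichment(ranked, list(all = genes, top = genes[1:10]),
                                n_perm = 200, seed = 2),
    "skipping"
  )
  expect_identical(res$set, "top")
  expect_gt(res$es, 0.8)
  expect_lt(res$p_value, 0.05)
  expect_true(all(res$leading_edge[[1]] %in% genes[1:10]))
  # determinism under a fixed seed
  res2 <- suppressMessages(
    preranked_enrichment(ranked, list(all = genes, top = genes[1:10]),
                         n_perm = 200, seed = 2)
  )
  expect_identical(as.data.frame(res), as.data.frame(res2))
})
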