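test_that("spearman_rho matches the hand-ranked oracle, including ties", {
  expect_equal(spearman_rho(1:3, 1:3, min_pairs = 3), 1.0)
  expect_equal(spearman_rho(1:3, 3:1, min_pairs = 3), -1.0)
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 4), min_pairs = 4),
               oracle_spearman(c(1, 2, 2, 3), c(1, 2, 3, 4)))
  withr::with_seed(10, {
    for (i in 1:200) {
      n <- sample(4:12, 1)
      x <- sample(1:5, n, replace = TRUE) + rnorm(n, sd = 0.01 * rbinom(1, 1, 0.5))
      y <- sample(1:5, n, replace = TRUE)
      if (var(x) == 0 || var(y) == 0) next
      expect_equal(spearman_rho(x, y, min_pairs = 4), oracle_spearman(x, y),
                   tolerance = 1e-12)
      # cross-check against the reference implementation too
      expect_equal(spearman_rho(x, y, min_pairs = 4),
                   suppressWarnings(cor(x, y, method = "spearman")),
                   tolerance = 1e-12)
    }
  })
  expect_error(spearman_rho(1:5, 1:5), "complete pairs")
  expect_warning(out <- spearman_rho(rep(1, 12), 1:12), "constant")
  expect_true(is.na(out))
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  withr::with_seed(11, {
    x <- rnorm(50)
    y <- rnorm(50)
  })
  base <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), base)
  expect_equal(spearman_rho(x, y^3 + 2 * y), base)
})

test_that("regulation profiles recover the generative extremes", {
  # no RNA compensation / full protein compensation with tiny protein
  # noise: DNA-RNA correlation is perfect, RNA-protein near zero
  cfg <- simulation_config(n_genes = 60, n_samples = 40, c_rna = 0, c_prot = 1,
                           scna_noise_sd = 0.02, sigma_rna_range = c(0, 0),
                           kappa_prot_range = c(0.5, 0.5),
                           rna_noise_complex_mult = 1, seed = 13)
  sim <- simulate_proteogenomics(cfg)
  prof <- gene_regulation_profiles(sim$dataset)
  expect_true(all(prof$dr_rho > 0.99))
  expect_lt(abs(median(prof$rp_rho)), 0.3)
  # pan-cancer aggregation is the unweighted mean across tumor types
  two <- tibble::tibble(gene = c("g", "g"), tumor_type = c("A", "B"),
                        dr_rho = c(0.2, 0.6), rp_rho = c(0.1, 0.5),
                        n_dr = c(10L, 90L), n_rp = c(10L, 90L))
  pan <- aggregate_pan_cancer(two)
  expect_equal(pan$dr_rho, 0.4)
  expect_equal(pan$rp_rho, 0.3)
  pan_w <- aggregate_pan_cancer(two, weighted = TRUE)
  expect_equal(pan_w$dr_rho, 0.56)
})

test_that("density slope recovers constructed lines and flags degeneracy", {
  withr::with_seed(20, {
    dr <- runif(10000, -0.5, 1)
    pts <- tibble::tibble(dr_rho = dr, rp_rho = -0.33 * dr + 0.5)
  })
  sl <- density_slope(pts)
  expect_equal(sl$slope, -0.33, tolerance = 0.01)
  expect_equal(sl$rho, -1.0)
  # a flat cloud has slope zero
  flat <- tibble::tibble(dr_rho = dr, rp_rho = 0.4)
  expect_equal(density_slope(flat)$slope, 0)
  # all points identical is degenerate
  one <- tibble::tibble(dr_rho = rep(0.3, 500), rp_rho = rep(0.1, 500))
  expect_error(density_slope(one), "degenerate")
  expect_error(density_slope(pts[1:50, ]), "at least")
})

test_that("regulation groups use opposite-tail quantiles and stay disjoint", {
  pan <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                        dr_rho = (1:100) / 100,
                        rp_rho = 1 - (1:100) / 100)
  gr <- define_regulation_groups(pan, q = 0.35)
  # perfect anti-correlation: group1 is exactly the top-35 dr genes
  expect_setequal(gr$group1, sprintf("g%03d", 66:100))
  expect_setequal(gr$group2, sprintf("g%03d", 1:35))
  expect_length(intersect(gr$group1, gr$group2), 0)
  expect_error(define_regulation_groups(pan, q = 0.5), "q")
  # independent coordinates: expected group size is about q^2 * n
  withr::with_seed(30, pan2 <- tibble::tibble(
    gene = sprintf("g%05d", 1:10000),
    dr_rho = runif(10000), rp_rho = runif(10000)
  ))
  gr2 <- define_regulation_groups(pan2, q = 0.35)
  expect_gt(length(gr2$group1), 0.35^2 * 10000 - 4 * sqrt(0.35^2 * 10000))
  expect_lt(length(gr2$group1), 0.35^2 * 10000 + 4 * sqrt(0.35^2 * 10000))
  expect_length(intersect(gr2$group1, gr2$group2), 0)
})

test_that("pathway aggregation takes medians and reports the association", {
  pan <- tibble::tibble(gene = c("a", "b", "c", "d"),
                        dr_rho = c(0.1, 0.2, 0.3, 0.9),
                        rp_rho = c(0.5, 0.4, 0.6, 0.1))
  sets <- gene_set_collection(list(P1 = c("a", "b", "c"), P2 = c("a", "d")))
  pw <- suppressMessages(pathway_regulation(pan, sets, min_pathway_genes = 2))
  p1 <- pw$pathways[pw$pathways$pathway == "P1", ]
  expect_equal(p1$median_dr_rho, 0.2)
  expect_equal(p1$median_rp_rho, 0.5)
  expect_error(pathway_regulation(pan, sets, min_pathway_genes = 10),
               "minimum size")
  # median robustness: one outlier moves a median at most to the adjacent
  # order statistic
  pan2 <- tibble::tibble(gene = sprintf("g%02d", 1:11),
                         dr_rho = seq(0.1, 0.6, length.out = 11),
                         rp_rho = seq(0.6, 0.1, length.out = 11))
  sets2 <- gene_set_collection(list(P = pan2$gene))
  before <- suppressMessages(pathway_regulation(pan2, sets2))$pathways$median_dr_rho
  pan2$dr_rho[1] <- 50
  after <- suppressMessages(pathway_regulation(pan2, sets2))$pathways$median_dr_rho
  expect_lte(abs(after - before), diff(sort(pan2$dr_rho))[6])
})

test_that("pathway-coupled noise drives the sign of the pathway association", {
  run_coupling <- function(coupling, seed) {
    cfg <- simulation_config(n_genes = 600, n_samples = 70, n_pathways = 30,
                             pathway_coupling = coupling, seed = seed)
    sim <- simulate_proteogenomics(cfg)
    ds <- filter_low_dna_variance(filter_low_expression(sim$dataset))
    pan <- aggregate_pan_cancer(gene_regulation_profiles(ds))
    pathway_regulation(pan, sim$gene_sets,
                       gene_annotation = ds$gene_annotation)
  }
  neg <- run_coupling(-1, 41)
  expect_lt(glance(neg)$spearman_rho, -0.5)
  pos <- run_coupling(+1, 41)
  expect_gt(glance(pos)$spearman_rho, 0.5)
})

test_that("group contrast reuses the bootstrap difference machinery", {
  pan <- withr::with_seed(17, tibble::tibble(
    gene = sprintf("g%02d", 1:40),
    dr_rho = c(rnorm(20, 0.6, 0.05), rnorm(20, 0.2, 0.05)),
    rp_rho = c(rnorm(20, 0.2, 0.05), rnorm(20, 0.6, 0.05))
  ))
  classes <- setNames(rep(c(TRUE, FALSE), each = 20), pan$gene)
  ct <- group_contrast(pan, classes, statistic = "rp_rho", n_boot = 500, seed = 1)
  expect_lt(ct$statistic, 0)
  expect_lt(ct$p_value, 0.05)
  identical_ct <- group_contrast(
    tibble::tibble(gene = pan$gene, dr_rho = rep(0.5, 40),
                   rp_rho = rep(c(0.3, 0.3), 20)),
    classes, statistic = "rp_rho", n_boot = 500, seed = 1
  )
  expect_equal(identical_ct$statistic, 0)
  expect_error(group_contrast(pan[1:5, ], classes, n_boot = 500), "at least")
})

test_that("hypergeometric over-representation matches exact enumeration", {
  universe <- sprintf("u%02d", 1:10)
  ref <- universe[1:4]
  query <- universe[c(1:4, 10)]
  res <- overrepresentation_test(query, list(S = ref), universe)
  # P(overlap >= 4) = C(4,4) * C(6,1) / C(10,5) = 6 / 252
  expect_equal(res$p_value, 6 / 252, tolerance = 1e-12)
  none <- overrepresentation_test(universe[5:6], list(S = universe[1:2]), universe)
  expect_gte(none$p_value, 0.9)
  full <- overrepresentation_test(universe, list(S = ref), universe)
  expect_equal(full$fold_enrichment, 1)
  expect_error(overrepresentation_test("zzz", list(S = ref), universe),
               "subset")
  expect_error(overrepresentation_test("u01", list(S = ref), character(0)),
               "empty universe")
})
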