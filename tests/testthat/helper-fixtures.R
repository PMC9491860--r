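# Shared builders for small in-code fixtures.

make_om <- function(values, layer, scale = "log2",
                    genes = sprintf("g%d", seq_len(nrow(values))),
                    samples = sprintf("s%d", seq_len(ncol(values)))) {
  dimnames(values) <- list(genes, samples)
  omics_matrix(values, layer = layer, scale = scale)
}

# a tiny fully aligned dataset with hand-picked values
tiny_dataset <- function(n_genes = 6, n_samples = 8, seed = 42) {
  withr::with_seed(seed, {
    dna <- matrix(rnorm(n_genes * n_samples, sd = 0.4), n_genes)
    rna <- 2^(3 + 0.8 * dna + matrix(rnorm(n_genes * n_samples, sd = 0.2), n_genes))
    prot <- 0.5 * (log2(rna) - 3) + matrix(rnorm(n_genes * n_samples, sd = 0.2), n_genes)
  })
  align_dataset(
    make_om(dna, "dna_log2_ratio"),
    make_om(rna, "rna_abundance", "linear"),
    make_om(prot, "protein_abundance")
  )
}

# two-arm toy genome for window/call tests
toy_arms <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr1", "chr2"),
    arm = c("p", "q", "q"),
    start = c(0, 1e6, 0),
    end = c(1e6, 2.5e6, 2e6)
  )
}

# zero-noise simulation config used by the closed-form recovery checks
noiseless_config <- function(..., n_pathways = 10, seed = 11) {
  simulation_config(
    n_pathways = n_pathways,
    scna_noise_sd = 0,
    sigma_rna_range = c(0, 0),
    kappa_prot_range = c(0, 0),
    rna_noise_complex_mult = 1,
    seed = seed,
    ...
  )
}

# independent oracle: Spearman rho via explicit average-rank construction
# and the Pearson product-moment formula written out by hand
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# independent oracle: enrichment score by direct enumeration of the
# running sum, step by step; ties in magnitude resolve to the earliest
# extreme (the documented contract), up to accumulation rounding
oracle_es <- function(in_set, scores, weight = 1) {
  n <- length(scores)
  nh <- sum(in_set)
  nr <- sum(abs(scores[in_set])^weight)
  running <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (in_set[i]) abs(scores[i])^weight / nr else -1 / (n - nh)
    running[i] <- acc
  }
  m <- max(abs(running))
  running[which(abs(running) >= m - 1e-12 * max(1, m))[1]]
}
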