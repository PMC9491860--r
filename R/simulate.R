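#' Default chromosome-arm table for simulations
#'
#' A 39-arm genome modeled on the human autosomes: 22 chromosomes with p
#' and q arms, minus the five acrocentric p arms (chromosomes 13, 14, 15,
#' 21, 22) that carry essentially no unique sequence and are conventionally
#' excluded from arm counts. Coordinates are synthetic round numbers
#' (60 Mb p arms, 90 Mb q arms), 0-based half-open.
#'
#' @return An arm definition tibble (`chrom`, `arm`, `start`, `end`).
#' @export
default_arm_table <- function() {
  acrocentric <- c("chr13", "chr14", "chr15", "chr21", "chr22")
  rows <- purrr::map_dfr(1:22, function(i) {
    ch <- paste0("chr", i)
    p <- tibble::tibble(chrom = ch, arm = "p", start = 0, end = 6e7)
    q <- tibble::tibble(chrom = ch, arm = "q", start = 6e7, end = 1.5e8)
    if (ch %in% acrocentric) q else dplyr::bind_rows(p, q)
  })
  validate_arm_table(rows)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic proteogenomic
#' generator. The generative model is, per gene \eqn{g} and sample
#' \eqn{s}, in log2 fold-change space:
#' \deqn{rna = (1 - c_{rna}(g)) \cdot dna + \epsilon,\quad
#'       \epsilon \sim N(0, \sigma_{rna}(g))}
#' \deqn{protein = (1 - c_{prot}(g)) \cdot rna + \eta,\quad
#'       \eta \sim N(0, \sigma_{prot}(g))}
#' where `c_rna`/`c_prot` are per-gene compensation fractions and the
#' noise scales are pathway-indexed. DNA changes are arm-level events:
#' each sample gains or loses whole arms independently.
#'
#' Protein-complex genes default to strong protein-level buffering and
#' weak RNA-level buffering, with tighter RNA noise; non-complex genes the
#' reverse. `pathway_coupling` sets the rank correlation, across pathways,
#' between RNA-noise scale and the relative protein-noise scale, which
#' translates into the sign of the pathway-level association between
#' DNA-RNA and RNA-protein correlations. The default of -0.75 produces
#' the negative coupling characteristic of tumor proteogenomic data.
#'
#' @param n_genes,n_samples,n_tumor_types Problem size; `n_samples` is per
#'   tumor type (default 90, within the 80-110 range typical of tumor
#'   proteogenomic cohorts).
#' @param arm_table Arm definitions (default [default_arm_table()]).
#' @param frac_complex Fraction of protein-complex genes (default 0.35).
#' @param frac_ribosomal Fraction of complex genes flagged ribosomal
#'   (default 0.1).
#' @param scna_event_rate Per-sample expected fraction of arms altered
#'   (default 0.25).
#' @param scna_gain_log2,scna_loss_log2 Arm log2 ratios of a gain / loss
#'   event (defaults log2(3/2) and log2(1/2): one copy gained or lost in a
#'   diploid).
#' @param scna_noise_sd Standard deviation of the per-sample, per-arm
#'   measurement noise on the emitted arm log2 ratio (default 0.05, the
#'   order of array/sequencing-derived ratio noise). The noise is shared
#'   by all genes on the arm and by the segment file, so arm calls remain
#'   exactly recoverable; set to 0 for a noise-free copy-number layer.
#' @param c_rna,c_prot Optional per-gene compensation fractions (scalar or
#'   length `n_genes`); when `NULL` they are drawn from Beta distributions
#'   with class-specific means.
#' @param c_rna_complex,c_rna_noncomplex,c_prot_complex,c_prot_noncomplex
#'   Class means of the compensation fractions.
#' @param c_concentration Concentration of the Beta draws (larger =
#'   tighter around the class mean; default 30).
#' @param n_pathways Number of pathways genes are partitioned into
#'   (default 50).
#' @param sigma_rna_range Range of the pathway RNA-noise scale, log2 units
#'   (default 0.1-0.6).
#' @param kappa_prot_range Range of the pathway protein-noise scale
#'   expressed relative to the RNA signal s.d. (default 0.25-2.5).
#' @param pathway_coupling Rank correlation in `[-1, 1]` between the two
#'   pathway noise scales (default -0.75; see Details).
#' @param rna_noise_complex_mult Multiplier on the RNA noise of complex
#'   genes (default 0.6).
#' @param rna_baseline_log2_mean,rna_baseline_log2_sd Log-normal baseline
#'   RNA abundance (log2 mean 3, s.d. 1.5), so a bottom-quantile
#'   expression filter has real work to do.
#' @param rna_scale Scale on which the RNA matrix is emitted (`"linear"`
#'   default, matching FPKM-style inputs, or `"log2"`).
#' @param purity_range Uniform range of simulated tumor purity.
#' @param genome_doubled_rate Probability a sample is flagged
#'   genome-doubled (default 0).
#' @param seed Integer seed; the full simulation is a deterministic
#'   function of the configuration.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000, n_samples = 90,
                              n_tumor_types = 1,
                              arm_table = default_arm_table(),
                              frac_complex = 0.35, frac_ribosomal = 0.1,
                              scna_event_rate = 0.25,
                              scna_gain_log2 = log2(3 / 2),
                              scna_loss_log2 = log2(1 / 2),
                              scna_noise_sd = 0.05,
                              c_rna = NULL, c_prot = NULL,
                              c_rna_complex = 0.05, c_rna_noncomplex = 0.20,
                              c_prot_complex = 0.60, c_prot_noncomplex = 0.15,
                              c_concentration = 30,
                              n_pathways = 50,
                              sigma_rna_range = c(0.1, 0.6),
                              kappa_prot_range = c(0.25, 2.5),
                              pathway_coupling = -0.75,
                              rna_noise_complex_mult = 0.6,
                              rna_baseline_log2_mean = 3,
                              rna_baseline_log2_sd = 1.5,
                              rna_scale = c("linear", "log2"),
                              purity_range = c(0.5, 1),
                              genome_doubled_rate = 0,
                              seed = 1L) {
  rna_scale <- match.arg(rna_scale)
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              n_tumor_types = as.integer(n_tumor_types),
              arm_table = validate_arm_table(arm_table),
              frac_complex = frac_complex, frac_ribosomal = frac_ribosomal,
              scna_event_rate = scna_event_rate,
              scna_gain_log2 = scna_gain_log2, scna_loss_log2 = scna_loss_log2,
              scna_noise_sd = scna_noise_sd,
              c_rna = c_rna, c_prot = c_prot,
              c_rna_complex = c_rna_complex, c_rna_noncomplex = c_rna_noncomplex,
              c_prot_complex = c_prot_complex,
              c_prot_noncomplex = c_prot_noncomplex,
              c_concentration = c_concentration,
              n_pathways = as.integer(n_pathways),
              sigma_rna_range = sigma_rna_range,
              kappa_prot_range = kappa_prot_range,
              pathway_coupling = pathway_coupling,
              rna_noise_complex_mult = rna_noise_complex_mult,
              rna_baseline_log2_mean = rna_baseline_log2_mean,
              rna_baseline_log2_sd = rna_baseline_log2_sd,
              rna_scale = rna_scale, purity_range = purity_range,
              genome_doubled_rate = genome_doubled_rate,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  fr <- c("frac_complex", "frac_ribosomal", "scna_event_rate",
          "genome_doubled_rate")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must be in [0, 1]."))
  }
  for (f in c("c_rna", "c_prot")) {
    v <- cfg[[f]]
    if (!is.null(v) && (any(v < 0) || any(v > 1))) {
      abort(paste0("`", f, "` fractions must be in [0, 1]."))
    }
    if (!is.null(v) && !length(v) %in% c(1L, cfg$n_genes)) {
      abort(paste0("`", f, "` must be scalar or length n_genes."))
    }
  }
  if (abs(cfg$pathway_coupling) > 1) abort("`pathway_coupling` must be in [-1, 1].")
  if (any(cfg$sigma_rna_range < 0) || any(cfg$kappa_prot_range < 0) ||
      cfg$scna_noise_sd < 0) {
    abort("noise scales must be non-negative.")
  }
  if (cfg$n_genes < cfg$n_pathways) abort("need n_genes >= n_pathways.")
  if (!nrow(cfg$arm_table)) abort("zero arms defined.")
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from a YAML file
#'
#' Scalar fields of [simulation_config()] may be overridden from a flat
#' YAML mapping; the arm table may be given inline as a list of records.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$arm_table)) {
    vals$arm_table <- dplyr::bind_rows(lapply(vals$arm_table, tibble::as_tibble))
  }
  do.call(simulation_config, vals)
}

# deterministic sub-seeds for the independent stages of one simulation
sim_seed <- function(cfg, stage) (cfg$seed * 7L + stage) %% 2147483647L

#' Simulate arm-level copy-number alterations
#'
#' Each sample receives independent Bernoulli arm events (rate
#' `scna_event_rate`); an altered arm takes the gain or loss log2 ratio
#' with equal probability, and every gene on that arm inherits the arm's
#' ratio. Also drawn here are the per-gene ground-truth parameters
#' (pathway, complex membership, compensation fractions, noise scales)
#' consumed by [simulate_expression()].
#'
#' @param config A [simulation_config()].
#' @return List with `segments` (one segment per sample x arm, covering
#'   the arm), `dna` (an [omics_matrix]), and `truth` (list of `genes`,
#'   `arm_events`, `samples` tibbles; `samples$true_aneuploidy_score`
#'   counts arms whose |log2 ratio| exceeds the 0.2 calling threshold).
#' @export
simulate_copy_number <- function(config) {
  cfg <- validate_simulation_config(config)
  arms <- cfg$arm_table
  n_arms <- nrow(arms)
  n_samples_total <- cfg$n_samples * cfg$n_tumor_types
  withr::with_seed(sim_seed(cfg, 1L), {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    samples <- sprintf("S%04d", seq_len(n_samples_total))
    tumor_types <- rep(sprintf("TT%02d", seq_len(cfg$n_tumor_types)),
                       each = cfg$n_samples)

    # genes spread evenly over arms, evenly spaced coordinates within an arm
    gene_arm <- rep(seq_len(n_arms), length.out = cfg$n_genes)
    per_arm_index <- stats::ave(seq_len(cfg$n_genes), gene_arm, FUN = seq_along)
    per_arm_count <- tabulate(gene_arm, nbins = n_arms)
    gstart <- arms$start[gene_arm] +
      floor((per_arm_index - 0.75) / per_arm_count[gene_arm] *
              (arms$end[gene_arm] - arms$start[gene_arm]))
    gene_tb <- tibble::tibble(
      gene = genes, chrom = arms$chrom[gene_arm], arm = arms$arm[gene_arm],
      start = gstart, end = gstart + 1e4,
      pathway = sprintf("PW%03d", rep(seq_len(cfg$n_pathways),
                                      length.out = cfg$n_genes)),
      is_complex = runif(cfg$n_genes) < cfg$frac_complex
    )
    gene_tb$is_ribosomal <- gene_tb$is_complex &
      runif(cfg$n_genes) < cfg$frac_ribosomal

    # compensation fractions: explicit values win, otherwise Beta draws
    # around the class means
    draw_c <- function(given, mean_complex, mean_noncomplex) {
      if (!is.null(given)) return(rep(given, length.out = cfg$n_genes))
      mu <- ifelse(gene_tb$is_complex, mean_complex, mean_noncomplex)
      k <- cfg$c_concentration
      stats::rbeta(cfg$n_genes, mu * k, (1 - mu) * k)
    }
    gene_tb$c_rna <- draw_c(cfg$c_rna, cfg$c_rna_complex, cfg$c_rna_noncomplex)
    gene_tb$c_prot <- draw_c(cfg$c_prot, cfg$c_prot_complex,
                             cfg$c_prot_noncomplex)

    # pathway noise scales: sigma_rna spans its range over pathways;
    # the relative protein-noise scale kappa follows a Gaussian copula
    # with rank correlation pathway_coupling
    npw <- cfg$n_pathways
    u <- (seq_len(npw) - 0.5) / npw
    u <- sample(u)                      # random pathway order
    zc <- qnorm(u)
    rho <- cfg$pathway_coupling
    zs <- rho * zc + sqrt(max(0, 1 - rho^2)) * rnorm(npw)
    s <- pnorm(zs)
    sig_r <- cfg$sigma_rna_range[1] +
      u * diff(cfg$sigma_rna_range)
    kappa <- cfg$kappa_prot_range[1] + s * diff(cfg$kappa_prot_range)
    pw_tb <- tibble::tibble(pathway = sprintf("PW%03d", seq_len(npw)),
                            sigma_rna = sig_r, kappa_prot = kappa)
    gene_tb <- dplyr::left_join(gene_tb, pw_tb, by = "pathway")
    gene_tb$sigma_rna <- gene_tb$sigma_rna *
      ifelse(gene_tb$is_complex, cfg$rna_noise_complex_mult, 1)

    # arm events per sample
    event <- matrix(runif(n_arms * n_samples_total) < cfg$scna_event_rate,
                    nrow = n_arms)
    gain <- matrix(runif(n_arms * n_samples_total) < 0.5, nrow = n_arms)
    ratio <- ifelse(event, ifelse(gain, cfg$scna_gain_log2, cfg$scna_loss_log2), 0)
    if (cfg$scna_noise_sd > 0) {
      ratio <- ratio + matrix(rnorm(n_arms * n_samples_total,
                                    sd = cfg$scna_noise_sd), nrow = n_arms)
    }
    dimnames(ratio) <- list(NULL, samples)

    dna_vals <- ratio[gene_arm, , drop = FALSE]
    rownames(dna_vals) <- genes
    dna <- omics_matrix(dna_vals, layer = "dna_log2_ratio", scale = "log2")

    segments <- tibble::tibble(
      sample = rep(samples, each = n_arms),
      chrom = rep(arms$chrom, times = n_samples_total),
      start = rep(arms$start, times = n_samples_total),
      end = rep(arms$end, times = n_samples_total),
      log2_ratio = as.vector(ratio)
    )
    arm_events <- tibble::tibble(
      sample = rep(samples, each = n_arms),
      chrom = rep(arms$chrom, times = n_samples_total),
      arm = rep(arms$arm, times = n_samples_total),
      log2_ratio = as.vector(ratio),
      event = as.vector(event)
    )
    sample_tb <- tibble::tibble(
      sample = samples, tumor_type = tumor_types,
      purity = runif(n_samples_total, cfg$purity_range[1], cfg$purity_range[2]),
      genome_doubled = runif(n_samples_total) < cfg$genome_doubled_rate,
      true_aneuploidy_score = as.integer(colSums(abs(ratio) > 0.2))
    )
    list(segments = segments, dna = dna,
         truth = list(genes = gene_tb, arm_events = arm_events,
                      samples = sample_tb))
  })
}

#' Simulate RNA and protein abundance from simulated copy number
#'
#' Applies the generative model of [simulation_config()]: RNA log2 fold
#' change attenuates the DNA change by the gene's `c_rna` plus Gaussian
#' pathway noise; the protein log2 fold change attenuates the realized RNA
#' change by `c_prot` plus Gaussian noise whose scale is
#' `kappa_prot * sd(rna signal)` for the gene's pathway. RNA is emitted on
#' the configured scale around a log-normal per-gene baseline; protein is
#' emitted as zero-centered log2 ratios (the native scale of
#' isobaric-label proteomics).
#'
#' @param dna DNA [omics_matrix] from [simulate_copy_number()].
#' @param truth Ground-truth list from [simulate_copy_number()].
#' @param config The same [simulation_config()].
#' @return List with `rna` and `protein` [omics_matrix] objects.
#' @export
simulate_expression <- function(dna, truth, config) {
  cfg <- validate_simulation_config(config)
  g <- truth$genes
  if (!identical(g$gene, rownames(dna))) abort("truth does not match the DNA matrix.")
  n_s <- ncol(dna)
  n_g <- nrow(dna)
  withr::with_seed(sim_seed(cfg, 2L), {
    baseline <- rnorm(n_g, cfg$rna_baseline_log2_mean, cfg$rna_baseline_log2_sd)
    a <- 1 - g$c_rna
    b <- 1 - g$c_prot
    dna_m <- unclass(dna)
    eps <- matrix(rnorm(n_g * n_s), n_g) * g$sigma_rna
    rna_fc <- a * dna_m + eps
    # expected s.d. of the RNA fold change given the arm-event process,
    # used to express the protein noise on a comparable footing
    p_ev <- cfg$scna_event_rate
    m2 <- 0.5 * (cfg$scna_gain_log2^2 + cfg$scna_loss_log2^2)
    m1 <- 0.5 * (cfg$scna_gain_log2 + cfg$scna_loss_log2)
    v_d <- p_ev * m2 - (p_ev * m1)^2 + cfg$scna_noise_sd^2
    sd_rna <- sqrt(a^2 * v_d + g$sigma_rna^2)
    sigma_prot <- g$kappa_prot * sd_rna
    eta <- matrix(rnorm(n_g * n_s), n_g) * sigma_prot
    prot_fc <- b * rna_fc + eta

    rna_log2 <- baseline + rna_fc
    rna_vals <- if (cfg$rna_scale == "linear") 2^rna_log2 else rna_log2
    dimnames(rna_vals) <- dimnames(dna_m)
    dimnames(prot_fc) <- dimnames(dna_m)
    list(
      rna = omics_matrix(rna_vals, layer = "rna_abundance",
                         scale = cfg$rna_scale),
      protein = omics_matrix(prot_fc, layer = "protein_abundance",
                             scale = "log2")
    )
  })
}

#' Simulate a complete proteogenomic study
#'
#' Runs [simulate_copy_number()] and [simulate_expression()] and packages
#' the result as an aligned dataset with gene/sample annotations, the
#' pathway gene sets, and the ground truth.
#'
#' @param config A [simulation_config()].
#' @return An object of class `scnareg_simulation`: list with `dataset`
#'   (a `proteogenomic_dataset`), `segments`, `arms`, `gene_sets`,
#'   `truth`, `config`.
#' @export
simulate_proteogenomics <- function(config = simulation_config()) {
  cfg <- validate_simulation_config(config)
  cn <- simulate_copy_number(cfg)
  expr <- simulate_expression(cn$dna, cn$truth, cfg)
  g <- cn$truth$genes
  gene_ann <- withr::with_seed(sim_seed(cfg, 3L), tibble::tibble(
    gene = g$gene, is_complex = g$is_complex, is_ribosomal = g$is_ribosomal,
    subcellular_location = sample(
      c("nucleus", "cytoplasm", "mitochondria", "ER", "plasma_membrane", "other"),
      nrow(g), replace = TRUE),
    conservation_score = rnorm(nrow(g), mean = 0.09, sd = 0.3) +
      ifelse(g$is_complex, 0.02, 0)
  ))
  gene_ann$subcellular_location[g$is_ribosomal] <- "ribosome"
  sample_ann <- cn$truth$samples[, c("sample", "tumor_type", "purity",
                                     "genome_doubled")]
  sets <- gene_set_collection(split(g$gene, g$pathway),
                              description = paste("simulated pathway",
                                                  sort(unique(g$pathway))))
  dataset <- align_dataset(cn$dna, expr$rna, expr$protein,
                           gene_annotation = gene_ann,
                           sample_annotation = sample_ann)
  structure(list(dataset = dataset, segments = cn$segments,
                 arms = cfg$arm_table, gene_sets = sets, truth = cn$truth,
                 config = cfg),
            class = "scnareg_simulation")
}

#' @export
print.scnareg_simulation <- function(x, ...) {
  cat(sprintf("<scnareg_simulation> %d genes x %d samples, %d pathways, seed %d\n",
              x$config$n_genes, x$config$n_samples * x$config$n_tumor_types,
              x$config$n_pathways, x$config$seed))
  invisible(x)
}

#' Write a simulation to a fixture directory
#'
#' Emits every file the readers of this package (and its command-line
#' interface) consume: the three layer matrices, segments, arm table,
#' gene/sample annotations, pathway GMT, and two ground-truth tables.
#'
#' @param sim An `scnareg_simulation`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture <- function(sim, out_dir) {
  if (is.null(out_dir) || !nzchar(out_dir)) abort("`out_dir` must be a non-empty path.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort("could not create output directory.")
  ds <- sim$dataset
  paths <- c(
    dna = file.path(out_dir, "dna.tsv"),
    rna = file.path(out_dir, "rna.tsv"),
    protein = file.path(out_dir, "protein.tsv"),
    segments = file.path(out_dir, "segments.tsv"),
    arms = file.path(out_dir, "arms.tsv"),
    gene_annotation = file.path(out_dir, "gene_annotation.tsv"),
    sample_annotation = file.path(out_dir, "sample_annotation.tsv"),
    gene_sets = file.path(out_dir, "pathways.gmt"),
    truth_genes = file.path(out_dir, "truth_genes.tsv"),
    truth_samples = file.path(out_dir, "truth_samples.tsv")
  )
  write_omics_matrix(ds$dna, paths["dna"])
  write_omics_matrix(ds$rna, paths["rna"])
  write_omics_matrix(ds$protein, paths["protein"])
  write_segments(sim$segments, paths["segments"])
  readr::write_tsv(sim$arms, paths["arms"], progress = FALSE)
  readr::write_tsv(ds$gene_annotation, paths["gene_annotation"], progress = FALSE)
  readr::write_tsv(ds$sample_annotation, paths["sample_annotation"], progress = FALSE)
  write_gene_sets(sim$gene_sets, paths["gene_sets"])
  readr::write_tsv(sim$truth$genes, paths["truth_genes"], progress = FALSE)
  readr::write_tsv(sim$truth$samples, paths["truth_samples"], progress = FALSE)
  invisible(paths)
}

#' Read a fixture directory back into a dataset
#'
#' Counterpart of [write_fixture()]; reconstructs the aligned dataset and
#' its companions from the files on disk.
#'
#' @param dir Fixture directory.
#' @param rna_scale Scale the RNA matrix was emitted on.
#' @return List with `dataset`, `segments`, `arms`, `gene_sets`.
#' @export
read_fixture <- function(dir, rna_scale = "linear") {
  dna <- read_omics_matrix(file.path(dir, "dna.tsv"), "dna_log2_ratio", "log2")
  rna <- read_omics_matrix(file.path(dir, "rna.tsv"), "rna_abundance", rna_scale)
  protein <- read_omics_matrix(file.path(dir, "protein.tsv"),
                               "protein_abundance", "log2")
  gene_ann <- read_gene_annotation(file.path(dir, "gene_annotation.tsv"))
  sample_ann <- read_sample_annotation(file.path(dir, "sample_annotation.tsv"))
  list(
    dataset = align_dataset(dna, rna, protein, gene_annotation = gene_ann,
                            sample_annotation = sample_ann),
    segments = read_segments(file.path(dir, "segments.tsv")),
    arms = read_arm_table(file.path(dir, "arms.tsv")),
    gene_sets = read_gene_sets(file.path(dir, "pathways.gmt"),
                               min_size = 1, max_size = .Machine$integer.max)
  )
}
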