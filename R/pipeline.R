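#' Run the full analysis pipeline on a simulated study
#'
#' End-to-end driver used by the command-line interface: simulate a
#' proteogenomic study, apply the expression and DNA-variance filters,
#' compute fold changes and compensation summaries, regulation profiles
#' with gene-level and pathway-level associations, aneuploidy scores from
#' the segments, per-gene aneuploidy models and preranked enrichment, and
#' write every stage as a tab-delimited file. All randomness derives from
#' `seed`, so two runs with the same configuration and seed produce
#' byte-identical outputs.
#'
#' @param config A [simulation_config()]; its `seed` is overridden by
#'   `seed` when given.
#' @param out_dir Output directory.
#' @param seed Optional integer seed overriding `config$seed`.
#' @param n_boot Bootstrap resamples for the compensation summaries.
#' @param n_perm Permutations for the preranked enrichment.
#' @param quantile_low_expr Bottom-expression filter fraction.
#' @return Invisibly, a list of the in-memory stage results; the files
#'   written are listed in the `files` element.
#' @export
run_scna_pipeline <- function(config = simulation_config(), out_dir,
                              seed = NULL, n_boot = 2000, n_perm = 500,
                              quantile_low_expr = 0.10) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cfg <- validate_simulation_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- simulate_proteogenomics(cfg)
  ds <- drop_genome_doubled(sim$dataset)
  ds <- filter_low_expression(ds, quantile = quantile_low_expr)

  ref <- define_neutral_group(ds)
  fc <- compute_log2fc(ds, ref)
  cs <- compute_compensation(fc, gene_annotation = ds$gene_annotation)
  cs_summary <- summarize_group_cs(cs, n_boot = n_boot,
                                   seed = sim_seed(cfg, 10L))

  dsr <- filter_low_dna_variance(ds)
  profiles <- gene_regulation_profiles(dsr)
  pan <- aggregate_pan_cancer(profiles)
  slope <- tryCatch(density_slope(pan), error = function(e) NULL)
  pw <- tryCatch(pathway_regulation(pan, sim$gene_sets,
                                    gene_annotation = ds$gene_annotation),
                 error = function(e) NULL)

  windows <- segments_to_windows(sim$segments, sim$arms)
  calls <- windows_to_arm_calls(windows)
  scores <- compute_aneuploidy_score(calls)
  prot_fc <- tidyr::pivot_wider(fc[, c("gene", "sample", "protein_l2fc")],
                                names_from = "sample",
                                values_from = "protein_l2fc")
  prot_m <- as.matrix(prot_fc[, -1])
  rownames(prot_m) <- prot_fc$gene
  covars <- ds$sample_annotation[, intersect(c("sample", "purity", "tumor_type"),
                                             names(ds$sample_annotation))]
  if (cfg$n_tumor_types < 2) covars$tumor_type <- NULL
  fits <- fit_expression_models(prot_m, scores, covariates = covars)
  ranked <- rank_genes(fits)
  enr <- preranked_enrichment(ranked, sim$gene_sets, n_perm = n_perm,
                              seed = sim_seed(cfg, 11L))

  files <- c(
    foldchange = file.path(out_dir, "foldchange.tsv"),
    compensation_summary = file.path(out_dir, "compensation_summary.tsv"),
    regulation_profiles = file.path(out_dir, "regulation_profiles.tsv"),
    pan_profiles = file.path(out_dir, "pan_profiles.tsv"),
    aneuploidy_scores = file.path(out_dir, "aneuploidy_scores.tsv"),
    model_fits = file.path(out_dir, "model_fits.tsv"),
    enrichment = file.path(out_dir, "enrichment.tsv")
  )
  readr::write_tsv(fc, files["foldchange"], progress = FALSE)
  readr::write_tsv(cs_summary, files["compensation_summary"], progress = FALSE)
  readr::write_tsv(profiles, files["regulation_profiles"], progress = FALSE)
  readr::write_tsv(pan, files["pan_profiles"], progress = FALSE)
  readr::write_tsv(scores, files["aneuploidy_scores"], progress = FALSE)
  readr::write_tsv(fits, files["model_fits"], progress = FALSE)
  enr_flat <- tibble::as_tibble(enr)
  enr_flat$leading_edge <- vapply(enr_flat$leading_edge, paste,
                                  character(1), collapse = ",")
  readr::write_tsv(enr_flat, files["enrichment"], progress = FALSE)
  if (!is.null(slope)) {
    readr::write_tsv(glance(slope), file.path(out_dir, "density_slope.tsv"),
                     progress = FALSE)
    files <- c(files, density_slope = file.path(out_dir, "density_slope.tsv"))
  }
  if (!is.null(pw)) {
    readr::write_tsv(pw$pathways, file.path(out_dir, "pathway_regulation.tsv"),
                     progress = FALSE)
    readr::write_tsv(pw$association,
                     file.path(out_dir, "pathway_association.tsv"),
                     progress = FALSE)
    files <- c(files,
               pathway_regulation = file.path(out_dir, "pathway_regulation.tsv"),
               pathway_association = file.path(out_dir, "pathway_association.tsv"))
  }
  invisible(list(simulation = sim, dataset = ds, reference = ref,
                 foldchange = fc, compensation = cs,
                 compensation_summary = cs_summary, profiles = profiles,
                 pan_profiles = pan, density_slope = slope,
                 pathway_regulation = pw, arm_calls = calls,
                 aneuploidy_scores = scores, model_fits = fits,
                 enrichment = enr, files = files))
}
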