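#' Align DNA, RNA and protein matrices into one proteogenomic dataset
#'
#' Restricts the three layers to the genes and samples measured in all of
#' them, the entry requirement for every downstream analysis: a gene counts
#' as present in a layer when it has at least one non-missing value. Gene
#' and sample order is canonicalized (sorted identifiers), so the result is
#' invariant to the input ordering and the operation is idempotent.
#'
#' @param dna,rna,protein [omics_matrix] objects for the
#'   `dna_log2_ratio`, `rna_abundance` and `protein_abundance` layers.
#' @param gene_annotation Optional tibble with one row per gene (see
#'   [read_gene_annotation()]). Restricted to the aligned genes.
#' @param sample_annotation Optional tibble with one row per sample and a
#'   `tumor_type` column. When absent, all samples are assigned the tumor
#'   type `"all"`.
#' @return A `proteogenomic_dataset`: a list with elements `dna`, `rna`,
#'   `protein`, `gene_annotation`, `sample_annotation` and `excluded` (a
#'   per-tumor-type gene exclusion ledger appended to by the filter
#'   functions).
#' @seealso [filter_low_expression()], [filter_low_dna_variance()],
#'   [drop_genome_doubled()]
#' @export
align_dataset <- function(dna, rna, protein,
                          gene_annotation = NULL, sample_annotation = NULL) {
  stopifnot(inherits(dna, "omics_matrix"), inherits(rna, "omics_matrix"),
            inherits(protein, "omics_matrix"))
  if (omx_layer(dna) != "dna_log2_ratio") abort("`dna` must be the dna_log2_ratio layer.")
  if (omx_layer(rna) != "rna_abundance") abort("`rna` must be the rna_abundance layer.")
  if (omx_layer(protein) != "protein_abundance") abort("`protein` must be the protein_abundance layer.")
  if (!nrow(dna) || !nrow(rna) || !nrow(protein)) abort("empty input matrix.")

  present <- function(m) rownames(m)[rowSums(!is.na(m)) > 0]
  genes <- sort(Reduce(intersect, list(present(dna), present(rna), present(protein))))
  samples <- sort(Reduce(intersect, list(colnames(dna), colnames(rna), colnames(protein))))
  if (!length(genes) || !length(samples)) abort("empty intersection of genes or samples across layers.")

  if (is.null(sample_annotation)) {
    sample_annotation <- tibble::tibble(sample = samples, tumor_type = "all")
  } else {
    sample_annotation <- validate_sample_annotation(sample_annotation)
    miss <- setdiff(samples, sample_annotation$sample)
    if (length(miss)) abort(paste0("samples missing from annotation: ",
                                   paste(head(miss, 3), collapse = ", ")))
    sample_annotation <- sample_annotation[match(samples, sample_annotation$sample), ]
  }
  if (!is.null(gene_annotation)) {
    gene_annotation <- validate_gene_annotation(gene_annotation)
    gene_annotation <- gene_annotation[gene_annotation$gene %in% genes, ]
    gene_annotation <- gene_annotation[order(gene_annotation$gene), ]
  }

  structure(list(
    dna = dna[genes, samples],
    rna = rna[genes, samples],
    protein = protein[genes, samples],
    gene_annotation = gene_annotation,
    sample_annotation = sample_annotation,
    excluded = tibble::tibble(gene = character(), tumor_type = character(),
                              reason = character())
  ), class = "proteogenomic_dataset")
}

#' @export
print.proteogenomic_dataset <- function(x, ...) {
  cat(sprintf("<proteogenomic_dataset> %d genes x %d samples, %d tumor type(s)\n",
              nrow(x$dna), ncol(x$dna),
              length(unique(x$sample_annotation$tumor_type))))
  if (nrow(x$excluded)) {
    cat(sprintf("  %d gene x tumor-type exclusions recorded\n", nrow(x$excluded)))
  }
  invisible(x)
}

ds_genes <- function(dataset) rownames(dataset$dna)
ds_samples <- function(dataset) colnames(dataset$dna)

ds_tumor_types <- function(dataset) unique(dataset$sample_annotation$tumor_type)

ds_samples_of_type <- function(dataset, type) {
  dataset$sample_annotation$sample[dataset$sample_annotation$tumor_type == type]
}

# genes retained for a tumor type after the exclusion ledger is applied
ds_kept_genes <- function(dataset, type) {
  excl <- dataset$excluded$gene[dataset$excluded$tumor_type == type]
  setdiff(ds_genes(dataset), excl)
}

#' Remove genome-doubled samples
#'
#' Whole-genome doubling distorts relative copy-number ratios; samples
#' flagged `genome_doubled` in the sample annotation are dropped from all
#' three layers.
#'
#' @param dataset A `proteogenomic_dataset`.
#' @return The dataset restricted to non-doubled samples.
#' @export
drop_genome_doubled <- function(dataset) {
  ann <- dataset$sample_annotation
  if (!"genome_doubled" %in% names(ann)) return(dataset)
  keep <- ann$sample[!isTRUE_vec(ann$genome_doubled)]
  if (!length(keep)) abort("all samples flagged genome-doubled.")
  dataset$dna <- dataset$dna[, keep]
  dataset$rna <- dataset$rna[, keep]
  dataset$protein <- dataset$protein[, keep]
  dataset$sample_annotation <- ann[match(keep, ann$sample), ]
  dataset
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Remove lowly expressed genes per tumor type
#'
#' Within each tumor type, genes whose summary RNA level (by default the
#' median across that tumor type's samples) falls in the bottom `quantile`
#' fraction are recorded in the dataset's exclusion ledger and skipped by
#' that tumor type's downstream analyses. Exactly
#' `floor(quantile * n_genes)` genes are removed per tumor type; ties are
#' broken deterministically by gene identifier.
#'
#' @param dataset A `proteogenomic_dataset`.
#' @param quantile Fraction of genes to remove, in `[0, 1)`. Default 0.10.
#' @param summary `"median"` or `"mean"` summary of RNA level per gene.
#' @return The dataset with an updated exclusion ledger.
#' @export
filter_low_expression <- function(dataset, quantile = 0.10,
                                  summary = c("median", "mean")) {
  summary <- match.arg(summary)
  if (!is.numeric(quantile) || quantile < 0 || quantile >= 1) {
    abort("`quantile` must be in [0, 1).")
  }
  sfun <- if (summary == "median") {
    function(m) apply(m, 1, median, na.rm = TRUE)
  } else {
    function(m) rowMeans(m, na.rm = TRUE)
  }
  new_rows <- purrr::map_dfr(ds_tumor_types(dataset), function(type) {
    sm <- ds_samples_of_type(dataset, type)
    lev <- sfun(dataset$rna[, sm, drop = FALSE])
    k <- floor(quantile * length(lev))
    if (k == 0) return(tibble::tibble(gene = character(), tumor_type = character(),
                                      reason = character()))
    ord <- order(lev, names(lev))
    tibble::tibble(gene = names(lev)[ord[seq_len(k)]], tumor_type = type,
                   reason = "low_expression")
  })
  dataset$excluded <- dplyr::distinct(dplyr::bind_rows(dataset$excluded, new_rows))
  dataset
}

#' Remove genes with near-constant DNA copy number
#'
#' Correlation-based regulation inference is uninformative for genes whose
#' copy number barely varies. Per tumor type, a gene is excluded when
#' strictly more than `frac` of its samples have a DNA log2 ratio strictly
#' inside `(low, high)`.
#'
#' @param dataset A `proteogenomic_dataset`.
#' @param low,high Bounds of the near-neutral DNA window (default
#'   `-0.02`/`0.02`).
#' @param frac Exclusion threshold on the within-window sample fraction
#'   (strict inequality). Default 0.70.
#' @return The dataset with an updated exclusion ledger.
#' @export
filter_low_dna_variance <- function(dataset, low = -0.02, high = 0.02,
                                    frac = 0.70) {
  if (!is.numeric(frac) || frac <= 0 || frac > 1) abort("`frac` must be in (0, 1].")
  if (low >= high) abort("`low` must be below `high`.")
  new_rows <- purrr::map_dfr(ds_tumor_types(dataset), function(type) {
    sm <- ds_samples_of_type(dataset, type)
    m <- dataset$dna[, sm, drop = FALSE]
    inside <- m > low & m < high
    fr <- rowSums(inside, na.rm = TRUE) / rowSums(!is.na(m))
    drop <- names(fr)[!is.na(fr) & fr > frac]
    tibble::tibble(gene = drop, tumor_type = type, reason = "low_dna_variance")
  })
  dataset$excluded <- dplyr::distinct(dplyr::bind_rows(dataset$excluded, new_rows))
  dataset
}
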