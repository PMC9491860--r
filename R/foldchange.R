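#' Assign somatic copy-number alteration groups from DNA log2 fold change
#'
#' Bins a DNA log2 fold change into the five canonical SCNA groups. The
#' boundary convention closes the neutral bin on both sides, matching the
#' neutral-group definition used for the fold-change reference:
#' deep loss `x < -0.65`; loss `-0.65 <= x < -0.2`; neutral
#' `-0.2 <= x <= 0.2`; gain `0.2 < x <= 0.65`; high gain `x > 0.65`.
#'
#' @param dna_l2fc Numeric vector of finite DNA log2 fold changes.
#' @param low,high Neutral bounds (default -0.2 / 0.2).
#' @param deep Deep-loss / high-gain magnitude boundary (default 0.65).
#' @return A factor with levels `deep_loss`, `loss`, `neutral`, `gain`,
#'   `high_gain`.
#' @export
#' @examples
#' assign_scna_group(c(-0.7, -0.3, 0, 0.3, 0.7))
assign_scna_group <- function(dna_l2fc, low = -0.2, high = 0.2, deep = 0.65) {
  if (any(!is.finite(dna_l2fc))) abort("non-finite DNA log2FC.")
  out <- character(length(dna_l2fc))
  out[dna_l2fc < -deep] <- "deep_loss"
  out[dna_l2fc >= -deep & dna_l2fc < low] <- "loss"
  out[dna_l2fc >= low & dna_l2fc <= high] <- "neutral"
  out[dna_l2fc > high & dna_l2fc <= deep] <- "gain"
  out[dna_l2fc > deep] <- "high_gain"
  factor(out, levels = .scna_levels)
}

#' Define the copy-number-neutral reference per gene and tumor type
#'
#' For each gene within each tumor type, the samples whose DNA log2
#' copy-number ratio lies within `[low, high]` form the neutral group; the
#' per-layer medians of that group (on each layer's native scale) are the
#' reference against which fold changes are computed. Genes with fewer than
#' `min_neutral` neutral samples are flagged and excluded from fold-change
#' computation.
#'
#' @param dataset A `proteogenomic_dataset`.
#' @param low,high Neutral window on the DNA log2 ratio, default
#'   `[-0.2, 0.2]`.
#' @param min_neutral Minimum neutral-group size for a usable reference
#'   (default 5; the median over fewer samples is unstable).
#' @return A tibble with columns `gene`, `tumor_type`,
#'   `n_neutral_samples`, `neutral_dna`, `neutral_rna`, `neutral_protein`
#'   and `flagged`.
#' @export
define_neutral_group <- function(dataset, low = -0.2, high = 0.2,
                                 min_neutral = 5) {
  if (low >= high) abort("`low` must be below `high`.")
  purrr::map_dfr(ds_tumor_types(dataset), function(type) {
    sm <- ds_samples_of_type(dataset, type)
    genes <- ds_kept_genes(dataset, type)
    dna <- dataset$dna[genes, sm, drop = FALSE]
    rna <- dataset$rna[genes, sm, drop = FALSE]
    prot <- dataset$protein[genes, sm, drop = FALSE]
    rows <- lapply(seq_along(genes), function(i) {
      d <- dna[i, ]
      neu <- !is.na(d) & d >= low & d <= high
      n <- sum(neu)
      tibble::tibble(
        gene = genes[i], tumor_type = type, n_neutral_samples = n,
        neutral_dna = if (n) median(d[neu]) else NA_real_,
        neutral_rna = if (n) median(rna[i, neu], na.rm = TRUE) else NA_real_,
        neutral_protein = if (n) median(prot[i, neu], na.rm = TRUE) else NA_real_,
        flagged = n < min_neutral
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Compute per-gene, per-sample log2 fold changes on all three layers
#'
#' Fold changes are computed relative to the neutral-group reference from
#' [define_neutral_group()]: for layers on the linear scale,
#' `l2fc = log2(value / neutral median)`; for layers already on the log2
#' scale, `l2fc = value - neutral median`. The DNA fold change is
#' re-referenced to the neutral group's median DNA ratio rather than
#' assumed zero, which keeps the pipeline robust to globally shifted ratio
#' baselines. Each sample is assigned an SCNA group from its DNA fold
#' change.
#'
#' @param dataset A `proteogenomic_dataset`.
#' @param reference Neutral reference tibble from [define_neutral_group()].
#'   Flagged genes (insufficient neutral samples) are skipped.
#' @inheritParams assign_scna_group
#' @return A long tibble: `gene`, `sample`, `tumor_type`, `dna_l2fc`,
#'   `rna_l2fc`, `protein_l2fc`, `scna_group`. Missing expression
#'   propagates to missing fold change.
#' @export
compute_log2fc <- function(dataset, reference, low = -0.2, high = 0.2,
                           deep = 0.65) {
  ref <- reference[!reference$flagged & !is.na(reference$neutral_dna), ]
  rna_scale <- omx_scale(dataset$rna)
  prot_scale <- omx_scale(dataset$protein)
  out <- purrr::map_dfr(ds_tumor_types(dataset), function(type) {
    sm <- ds_samples_of_type(dataset, type)
    reft <- ref[ref$tumor_type == type, ]
    if (!nrow(reft)) return(NULL)
    genes <- reft$gene
    dna <- dataset$dna[genes, sm, drop = FALSE]
    rna <- dataset$rna[genes, sm, drop = FALSE]
    prot <- dataset$protein[genes, sm, drop = FALSE]
    dna_fc <- dna - reft$neutral_dna
    rna_fc <- if (rna_scale == "linear") {
      if (any(!is.na(rna) & rna <= 0)) abort("nonpositive value on a linear-scale layer.")
      if (any(!is.na(reft$neutral_rna) & reft$neutral_rna <= 0)) {
        abort("nonpositive neutral median on a linear-scale layer.")
      }
      log2(rna / reft$neutral_rna)
    } else rna - reft$neutral_rna
    prot_fc <- if (prot_scale == "linear") {
      if (any(!is.na(prot) & prot <= 0)) abort("nonpositive value on a linear-scale layer.")
      log2(prot / reft$neutral_protein)
    } else prot - reft$neutral_protein
    tb <- tibble::tibble(
      gene = rep(genes, times = length(sm)),
      sample = rep(sm, each = length(genes)),
      tumor_type = type,
      dna_l2fc = as.vector(dna_fc),
      rna_l2fc = as.vector(rna_fc),
      protein_l2fc = as.vector(prot_fc)
    )
    tb <- tb[!is.na(tb$dna_l2fc), ]
    tb$scna_group <- assign_scna_group(tb$dna_l2fc, low = low, high = high,
                                       deep = deep)
    tb
  })
  out
}
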