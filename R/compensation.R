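#' Compensation score
#'
#' Quantifies how strongly RNA or protein abundance buffers a DNA
#' copy-number change. For a gene in a sample,
#' `cs = dna_l2fc - expr_l2fc` when `dna_l2fc > 0` and
#' `cs = expr_l2fc - dna_l2fc` when `dna_l2fc < 0`; positive values
#' indicate compensation and the score grows with its degree. The score is
#' undefined at `dna_l2fc == 0` (samples that close to neutral never enter
#' a non-neutral SCNA group), so a zero DNA fold change is an error rather
#' than a silent zero.
#'
#' @param dna_l2fc,expr_l2fc Numeric vectors of DNA and expression (RNA or
#'   protein) log2 fold changes. Recycled to a common length.
#' @return Numeric vector of compensation scores; missing expression gives
#'   a missing score.
#' @export
#' @examples
#' compensation_score(1, 0)       # full compensation of a gain
#' compensation_score(-0.8, -0.3) # partial compensation of a loss
compensation_score <- function(dna_l2fc, expr_l2fc) {
  if (any(!is.finite(dna_l2fc))) abort("non-finite DNA log2FC.")
  if (any(dna_l2fc == 0)) abort("compensation score is undefined at DNA log2FC == 0.")
  ifelse(dna_l2fc > 0, dna_l2fc - expr_l2fc, expr_l2fc - dna_l2fc)
}

#' Per-gene, per-sample compensation table
#'
#' Applies [compensation_score()] to every non-neutral gene-sample
#' observation of a fold-change table, once against the RNA fold change and
#' once against the protein fold change, and attaches gene-class flags used
#' by the group summaries.
#'
#' @param fc_table Fold-change tibble from [compute_log2fc()].
#' @param gene_annotation Optional gene annotation tibble providing
#'   `is_complex` / `is_ribosomal` flags.
#' @return A long tibble: `gene`, `sample`, `tumor_type`, `scna_group`,
#'   `layer` (`"rna"`/`"protein"`), `cs`, plus any gene-class flags.
#' @export
compute_compensation <- function(fc_table, gene_annotation = NULL) {
  tb <- fc_table[fc_table$scna_group != "neutral", ]
  out <- tidyr::pivot_longer(
    tibble::tibble(
      gene = tb$gene, sample = tb$sample, tumor_type = tb$tumor_type,
      scna_group = tb$scna_group,
      rna = compensation_score(tb$dna_l2fc, tb$rna_l2fc),
      protein = compensation_score(tb$dna_l2fc, tb$protein_l2fc)
    ),
    cols = c("rna", "protein"), names_to = "layer", values_to = "cs"
  )
  out <- out[!is.na(out$cs), ]
  if (!is.null(gene_annotation)) {
    keep <- intersect(c("gene", "is_complex", "is_ribosomal"),
                      names(gene_annotation))
    out <- dplyr::left_join(out, gene_annotation[keep], by = "gene")
  }
  out
}

new_boot_result <- function(statistic, ci, p_value, n_boot, seed, n,
                            type, alternative) {
  structure(list(statistic = statistic, ci_low = ci[1], ci_high = ci[2],
                 p_value = p_value, n_boot = n_boot, seed = seed, n = n,
                 type = type, alternative = alternative),
            class = "scnareg_boot")
}

#' @export
print.scnareg_boot <- function(x, ...) {
  cat(sprintf("<bootstrap %s test> statistic = %.4g, 95%% CI [%.4g, %.4g], p = %.3g (n = %s, B = %d)\n",
              x$type, x$statistic, x$ci_low, x$ci_high, x$p_value,
              paste(x$n, collapse = "/"), x$n_boot))
  invisible(x)
}

# resampled medians of `values`, as a length-B vector; vectorized over the
# whole index matrix for speed
boot_medians <- function(values, n_boot) {
  n <- length(values)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  m <- matrix(values[idx], nrow = n, ncol = n_boot)
  half <- n %/% 2L
  if (n %% 2L == 1L) {
    apply(m, 2, function(col) sort.int(col, partial = half + 1L)[half + 1L])
  } else {
    apply(m, 2, function(col) {
      p <- sort.int(col, partial = c(half, half + 1L))
      (p[half] + p[half + 1L]) / 2
    })
  }
}

basic_ci <- function(observed, boot_stats, conf = 0.95) {
  a <- (1 - conf) / 2
  q <- quantile(boot_stats, c(1 - a, a), names = FALSE, type = 7)
  c(2 * observed - q[1], 2 * observed - q[2])
}

#' Bootstrap test for a positive median
#'
#' Resamples `values` with replacement `n_boot` times, records the median
#' of each resample, and tests the null hypothesis that the median is at
#' most zero with the one-tailed Monte-Carlo p-value
#' `(1 + #\{bootstrap medians <= 0\}) / (n_boot + 1)`. The 95% confidence
#' interval uses the basic bootstrap construction
#' `(2m - q_0.975, 2m - q_0.025)` on the bootstrap median distribution.
#'
#' @param values Numeric vector (at least 2 finite values).
#' @param n_boot Number of bootstrap resamples (default 10000, minimum 100).
#' @param seed Optional integer seed making the result reproducible.
#' @param alternative Only `"greater"` (median > 0) is defined.
#' @return An object of class `scnareg_boot` with elements `statistic`
#'   (the observed median), `ci_low`, `ci_high`, `p_value`, `n_boot`,
#'   `seed`, `n`.
#' @export
bootstrap_median_test <- function(values, n_boot = 10000, seed = NULL,
                                  alternative = "greater") {
  alternative <- match.arg(alternative, "greater")
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("need at least 2 finite values.")
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  run <- function() {
    obs <- median(values)
    bm <- boot_medians(values, n_boot)
    p <- (1 + sum(bm <= 0)) / (n_boot + 1)
    new_boot_result(obs, basic_ci(obs, bm), p, n_boot, seed,
                    length(values), "median", alternative)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Bootstrap test for a difference of medians between two groups
#'
#' The statistic is `median(group_a) - median(group_b)`. Each bootstrap
#' replicate resamples both groups independently with replacement. The
#' two-tailed p-value recenters the bootstrap distribution at zero:
#' with deviations `delta_j = stat*_j - stat`,
#' `p = min(1, 2 * min(P*(delta >= stat), P*(delta <= stat)))`, each tail
#' probability carrying the `+1/(B+1)` Monte-Carlo correction.
#'
#' @param group_a,group_b Numeric vectors (at least 2 finite values each).
#' @inheritParams bootstrap_median_test
#' @return An object of class `scnareg_boot` (statistic = median
#'   difference).
#' @export
bootstrap_difference_test <- function(group_a, group_b, n_boot = 10000,
                                      seed = NULL) {
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 finite values.")
  }
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  run <- function() {
    obs <- median(group_a) - median(group_b)
    bd <- boot_medians(group_a, n_boot) - boot_medians(group_b, n_boot)
    delta <- bd - obs
    p_hi <- (1 + sum(delta >= obs)) / (n_boot + 1)
    p_lo <- (1 + sum(delta <= obs)) / (n_boot + 1)
    p <- min(1, 2 * min(p_hi, p_lo))
    new_boot_result(obs, basic_ci(obs, bd), p, n_boot, seed,
                    c(length(group_a), length(group_b)), "median difference",
                    "two.sided")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`
#' (step-up, monotone-enforced, capped at 1).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Group-level compensation summaries with bootstrap inference
#'
#' For every cell of the requested grouping (by default SCNA group within
#' layer), computes the median compensation score, a one-tailed bootstrap
#' test against zero, and -- when complex-membership flags are available --
#' a two-tailed bootstrap test for the complex-vs-non-complex median
#' difference. P-values are FDR-adjusted jointly within each layer (all
#' SCNA groups and tumor types of one layer form one family, mirroring a
#' per-layer figure panel); the median tests and the difference tests form
#' separate families.
#'
#' @param cs_table Compensation table from [compute_compensation()].
#' @param by Character vector of grouping columns (default
#'   `c("layer", "scna_group")`; add `"tumor_type"` for per-type cells,
#'   omit it for a pan-cancer pool).
#' @param n_boot,seed Passed to the bootstrap tests. Cell seeds are derived
#'   deterministically from `seed`.
#' @param min_cell_size Cells with fewer observations are reported with
#'   missing statistics rather than tested (default 20).
#' @param collapse_genes If `TRUE`, collapse each gene to its median score
#'   within the cell before resampling, so the bootstrap treats genes (not
#'   gene-sample observations) as the sampling unit.
#' @return A tibble with one row per cell: `n`, `median_cs`, `ci_low`,
#'   `ci_high`, `p_value`, `fdr`, and (when flags are present)
#'   `diff_median` etc. for the complex-vs-non-complex contrast.
#' @export
summarize_group_cs <- function(cs_table, by = c("layer", "scna_group"),
                               n_boot = 10000, seed = NULL,
                               min_cell_size = 20, collapse_genes = FALSE) {
  miss <- setdiff(by, names(cs_table))
  if (length(miss)) abort(paste0("grouping column(s) not in table: ",
                                 paste(miss, collapse = ", ")))
  has_complex <- "is_complex" %in% names(cs_table)
  cells <- dplyr::group_split(dplyr::group_by(cs_table, dplyr::across(dplyr::all_of(by))))
  rows <- purrr::imap_dfr(cells, function(cell, i) {
    key <- cell[1, by]
    vals <- if (collapse_genes) {
      tapply(cell$cs, cell$gene, median, na.rm = TRUE)
    } else cell$cs
    vals <- vals[is.finite(vals)]
    base <- tibble::tibble(!!!key, n = length(vals))
    cell_seed <- if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    if (length(vals) < min_cell_size) {
      return(dplyr::mutate(base, median_cs = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, p_value = NA_real_))
    }
    bt <- bootstrap_median_test(vals, n_boot = n_boot, seed = cell_seed)
    res <- dplyr::mutate(base, median_cs = bt$statistic, ci_low = bt$ci_low,
                         ci_high = bt$ci_high, p_value = bt$p_value)
    if (has_complex) {
      a <- cell$cs[isTRUE_vec(cell$is_complex)]
      b <- cell$cs[!isTRUE_vec(cell$is_complex) & !is.na(cell$is_complex)]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) >= min_cell_size && length(b) >= min_cell_size) {
        dt <- bootstrap_difference_test(a, b, n_boot = n_boot,
                                        seed = if (is.null(cell_seed)) NULL else cell_seed + 1L)
        res <- dplyr::mutate(res, diff_median = dt$statistic,
                             diff_ci_low = dt$ci_low, diff_ci_high = dt$ci_high,
                             diff_p_value = dt$p_value)
      } else {
        res <- dplyr::mutate(res, diff_median = NA_real_, diff_ci_low = NA_real_,
                             diff_ci_high = NA_real_, diff_p_value = NA_real_)
      }
    }
    res
  })
  fam <- if ("layer" %in% by) rows$layer else rep("all", nrow(rows))
  fdr_by_family <- function(p) {
    out <- rep(NA_real_, length(p))
    ok <- !is.na(p)
    out[ok] <- fdr_adjust(p[ok])
    out
  }
  rows$fdr <- stats::ave(rows$p_value, fam, FUN = fdr_by_family)
  if (has_complex && "diff_p_value" %in% names(rows)) {
    rows$diff_fdr <- stats::ave(rows$diff_p_value, fam, FUN = fdr_by_family)
  }
  rows
}
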