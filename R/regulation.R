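#' Spearman rank correlation with average-rank tie handling
#'
#' Pearson correlation of mean ranks (ties receive the average of the
#' ranks they span), computed after pairwise removal of missing values.
#' Implemented in-repo so tie handling is explicit and testable against a
#' hand-ranked oracle.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_pairs Minimum number of complete pairs required (default 10;
#'   correlations over fewer samples are not informative).
#' @return The rank correlation in `[-1, 1]`; `NA` with a warning when
#'   either vector is constant after pairing (undefined ranks variance).
#' @export
#' @examples
#' spearman_rho(c(1, 2, 2, 3), c(1, 2, 3, 4), min_pairs = 2)
spearman_rho <- function(x, y, min_pairs = 10) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < min_pairs) {
    abort(sprintf("fewer than %d complete pairs.", min_pairs))
  }
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (var(rx) == 0 || var(ry) == 0) {
    warn("constant vector: rank correlation undefined.")
    return(NA_real_)
  }
  cor(rx, ry)
}

# NA-silent variant used in per-gene loops: insufficient pairs or a
# constant vector give NA instead of a condition
spearman_or_na <- function(x, y, min_pairs) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_pairs) return(c(rho = NA_real_, n = n))
  rx <- rank(x[ok], ties.method = "average")
  ry <- rank(y[ok], ties.method = "average")
  if (var(rx) == 0 || var(ry) == 0) return(c(rho = NA_real_, n = n))
  c(rho = cor(rx, ry), n = n)
}

#' Per-gene DNA-RNA and RNA-protein regulation profiles
#'
#' For each gene within each tumor type, computes the Spearman correlation
#' between DNA copy-number ratio and RNA abundance (`dr_rho`; a high value
#' means RNA tracks DNA, i.e. weak RNA-level regulation) and between RNA
#' and protein abundance (`rp_rho`; a high value means protein tracks RNA,
#' i.e. weak protein-level regulation). Genes recorded in the dataset's
#' exclusion ledger for a tumor type (low expression, low DNA variance)
#' are skipped for that type.
#'
#' @param dataset A `proteogenomic_dataset`, typically after
#'   [filter_low_expression()] and [filter_low_dna_variance()].
#' @param min_pairs Minimum complete pairs per correlation (default 10).
#' @return A tibble: `gene`, `tumor_type`, `dr_rho`, `rp_rho`, `n_dr`,
#'   `n_rp`. Genes with no usable correlation in any tumor type are absent.
#' @export
gene_regulation_profiles <- function(dataset, min_pairs = 10) {
  out <- purrr::map_dfr(ds_tumor_types(dataset), function(type) {
    sm <- ds_samples_of_type(dataset, type)
    genes <- ds_kept_genes(dataset, type)
    if (!length(genes)) return(NULL)
    dna <- dataset$dna[genes, sm, drop = FALSE]
    rna <- dataset$rna[genes, sm, drop = FALSE]
    prot <- dataset$protein[genes, sm, drop = FALSE]
    dr <- t(vapply(seq_along(genes),
                   function(i) spearman_or_na(dna[i, ], rna[i, ], min_pairs),
                   c(rho = 0, n = 0)))
    rp <- t(vapply(seq_along(genes),
                   function(i) spearman_or_na(rna[i, ], prot[i, ], min_pairs),
                   c(rho = 0, n = 0)))
    tibble::tibble(gene = genes, tumor_type = type,
                   dr_rho = dr[, "rho"], rp_rho = rp[, "rho"],
                   n_dr = as.integer(dr[, "n"]), n_rp = as.integer(rp[, "n"]))
  })
  out[!(is.na(out$dr_rho) & is.na(out$rp_rho)), ]
}

#' Pan-cancer aggregation of regulation profiles
#'
#' Per gene, the unweighted mean of the per-tumor-type correlation
#' coefficients, taken over the tumor types where the gene has a value;
#' types where a gene failed filters simply do not contribute.
#'
#' @param profiles Tibble from [gene_regulation_profiles()].
#' @param weighted If `TRUE`, weight tumor types by the number of
#'   contributing samples instead (off by default; the unweighted mean is
#'   the canonical aggregate).
#' @return A tibble: `gene`, `dr_rho`, `rp_rho`, `n_types_dr`, `n_types_rp`.
#' @export
aggregate_pan_cancer <- function(profiles, weighted = FALSE) {
  wmean <- function(x, w) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    if (weighted) sum(x[ok] * w[ok]) / sum(w[ok]) else mean(x[ok])
  }
  dplyr::summarise(
    dplyr::group_by(profiles, .data$gene),
    n_types_dr = sum(!is.na(.data$dr_rho)),
    n_types_rp = sum(!is.na(.data$rp_rho)),
    dr_rho = wmean(.data$dr_rho, .data$n_dr),
    rp_rho = wmean(.data$rp_rho, .data$n_rp),
    .groups = "drop"
  )[, c("gene", "dr_rho", "rp_rho", "n_types_dr", "n_types_rp")]
}

#' Density-ridge slope between two correlation profiles
#'
#' Estimates the association between per-gene DNA-RNA (`dr`) and
#' RNA-protein (`rp`) correlations from the ridge of their joint density:
#' a Gaussian kernel density is evaluated on a `grid_size` x `grid_size`
#' grid, the `dr` range is split into `n_bins` windows, and within each
#' window the `rp` coordinate of the maximum-density cell is taken as that
#' window's representative point. The slope of an ordinary least-squares
#' fit and the Spearman correlation over the representative points
#' summarize the association. Windows containing no data points are
#' skipped.
#'
#' @param data Data frame of per-gene values (e.g. from
#'   [aggregate_pan_cancer()]).
#' @param dr,rp Column names holding the two coordinates.
#' @param n_bins Number of windows over the `dr` range (default 40).
#' @param grid_size Kernel density grid resolution per axis (default 100).
#' @param min_points Minimum number of points for a meaningful density
#'   estimate (default 200).
#' @param bandwidth Optional length-2 numeric bandwidth for the kernel
#'   density; defaults to the normal-reference bandwidth of the data.
#' @return An object of class `density_slope`: list with `points` (tibble
#'   of representative `dr`, `rp`), `slope`, `intercept`, `rho`, `n_bins`.
#' @export
density_slope <- function(data, dr = "dr_rho", rp = "rp_rho", n_bins = 40,
                          grid_size = 100, min_points = 200,
                          bandwidth = NULL) {
  x <- data[[dr]]
  y <- data[[rp]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < min_points) {
    abort(sprintf("need at least %d points for density estimation.", min_points))
  }
  if (diff(range(x)) == 0 && diff(range(y)) == 0) abort("degenerate input: all points identical.")
  if (diff(range(x)) == 0) abort("degenerate input: no spread along `dr`.")

  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  has_support <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                          nbins = n_bins) > 0

  if (diff(range(y)) == 0) {
    # flat cloud: the ridge is the constant itself in every supported window
    mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
    pts <- tibble::tibble(dr = mids[has_support], rp = y[1])
  } else {
    h <- bandwidth %||% c(MASS::bandwidth.nrd(x), MASS::bandwidth.nrd(y))
    h[h <= 0] <- 1e-3 * pmax(diff(range(x)), diff(range(y)))
    kde <- MASS::kde2d(x, y, h = h, n = grid_size,
                       lims = c(range(x), range(y)))
    col_bin <- findInterval(kde$x, breaks, rightmost.closed = TRUE)
    col_bin[col_bin < 1] <- 1; col_bin[col_bin > n_bins] <- n_bins
    pts <- purrr::map_dfr(which(has_support), function(b) {
      cols <- which(col_bin == b)
      if (!length(cols)) return(NULL)
      sub <- kde$z[cols, , drop = FALSE]
      idx <- arrayInd(which.max(sub), dim(sub))
      tibble::tibble(dr = kde$x[cols[idx[1]]], rp = kde$y[idx[2]])
    })
  }
  if (nrow(pts) < 3) abort("fewer than 3 supported windows.")
  fit <- lm(rp ~ dr, data = pts)
  rho <- suppressWarnings(spearman_or_na(pts$dr, pts$rp, min_pairs = 3)[["rho"]])
  structure(list(points = pts, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), rho = rho,
                 n_bins = n_bins, n_points = length(x)),
            class = "density_slope")
}

#' @export
print.density_slope <- function(x, ...) {
  cat(sprintf("<density_slope> slope = %.4g, rho = %.4g over %d representative points (%d genes)\n",
              x$slope, x$rho, nrow(x$points), x$n_points))
  invisible(x)
}

#' Classify genes into opposing regulation groups
#'
#' Group 1 collects genes with a high DNA-RNA correlation (top `q`
#' fraction) and a low RNA-protein correlation (bottom `q` fraction):
#' genes predominantly regulated at the protein level. Group 2 is the
#' mirror image: predominantly RNA-level regulation. Quantiles are type-7;
#' genes tied at a cutoff are included when they meet it.
#'
#' @param pan_profiles Per-gene tibble with `dr_rho` and `rp_rho` (e.g.
#'   from [aggregate_pan_cancer()]).
#' @param q Tail fraction in `(0, 0.5)` (default 0.35).
#' @return An object of class `regulation_groups`: list with `group1`,
#'   `group2` (character vectors of genes) and `cutoffs` (realized rho
#'   thresholds).
#' @export
define_regulation_groups <- function(pan_profiles, q = 0.35) {
  if (!is.numeric(q) || q <= 0 || q >= 0.5) abort("`q` must be in (0, 0.5).")
  tb <- pan_profiles[is.finite(pan_profiles$dr_rho) & is.finite(pan_profiles$rp_rho), ]
  if (nrow(tb) < 20) abort("need at least 20 genes with both correlations.")
  dr_hi <- quantile(tb$dr_rho, 1 - q, names = FALSE, type = 7)
  dr_lo <- quantile(tb$dr_rho, q, names = FALSE, type = 7)
  rp_hi <- quantile(tb$rp_rho, 1 - q, names = FALSE, type = 7)
  rp_lo <- quantile(tb$rp_rho, q, names = FALSE, type = 7)
  structure(list(
    group1 = tb$gene[tb$dr_rho >= dr_hi & tb$rp_rho <= rp_lo],
    group2 = tb$gene[tb$dr_rho <= dr_lo & tb$rp_rho >= rp_hi],
    cutoffs = tibble::tibble(
      statistic = c("dr_rho", "dr_rho", "rp_rho", "rp_rho"),
      tail = c("top", "bottom", "top", "bottom"),
      cutoff = c(dr_hi, dr_lo, rp_hi, rp_lo)
    ),
    q = q, n_genes = nrow(tb)
  ), class = "regulation_groups")
}

#' @export
print.regulation_groups <- function(x, ...) {
  cat(sprintf("<regulation_groups> q = %g: group1 (protein-regulated) %d genes, group2 (RNA-regulated) %d genes of %d\n",
              x$q, length(x$group1), length(x$group2), x$n_genes))
  invisible(x)
}

#' Pathway-level aggregation of regulation profiles
#'
#' Each pathway's DNA-RNA and RNA-protein correlation is the median of the
#' per-gene rho values over the pathway members present in the profile
#' table. The association between the two pathway-level vectors is
#' summarized by Spearman and Pearson correlations with their p-values.
#'
#' @param pan_profiles Per-gene tibble with `dr_rho` and `rp_rho`.
#' @param gene_sets A `gene_set_collection` (e.g. from [read_gene_sets()]).
#' @param min_pathway_genes Minimum member genes with profiles for a
#'   pathway to be scored (default 5).
#' @param gene_annotation Optional annotation supplying `is_complex` for
#'   the per-pathway complex-gene fraction.
#' @param genes Optional restriction of the analysis to a gene subset
#'   (e.g. complex-only or non-complex-only robustness checks).
#' @return An object of class `pathway_regulation`: list with `pathways`
#'   (tibble: `pathway`, `median_dr_rho`, `median_rp_rho`, `n_genes`,
#'   optionally `frac_complex`) and `association` (tibble with Spearman
#'   and Pearson rows).
#' @export
pathway_regulation <- function(pan_profiles, gene_sets, min_pathway_genes = 5,
                               gene_annotation = NULL, genes = NULL) {
  tb <- pan_profiles[is.finite(pan_profiles$dr_rho) & is.finite(pan_profiles$rp_rho), ]
  if (!is.null(genes)) tb <- tb[tb$gene %in% genes, ]
  complex_map <- NULL
  if (!is.null(gene_annotation) && "is_complex" %in% names(gene_annotation)) {
    complex_map <- setNames(gene_annotation$is_complex, gene_annotation$gene)
  }
  rows <- purrr::imap_dfr(as.list(gene_sets), function(members, nm) {
    sub <- tb[tb$gene %in% members, ]
    if (nrow(sub) < min_pathway_genes) return(NULL)
    row <- tibble::tibble(pathway = nm,
                          median_dr_rho = median(sub$dr_rho),
                          median_rp_rho = median(sub$rp_rho),
                          n_genes = nrow(sub))
    if (!is.null(complex_map)) {
      row$frac_complex <- mean(isTRUE_vec(complex_map[sub$gene]))
    }
    row
  })
  if (is.null(rows) || !nrow(rows)) abort("no pathway passes the minimum size.")
  if (nrow(rows) >= 3) {
    sp <- suppressWarnings(cor.test(rows$median_dr_rho, rows$median_rp_rho,
                                    method = "spearman", exact = FALSE))
    pe <- cor.test(rows$median_dr_rho, rows$median_rp_rho, method = "pearson")
    assoc <- tibble::tibble(
      method = c("spearman", "pearson"),
      estimate = c(spearman_or_na(rows$median_dr_rho, rows$median_rp_rho,
                                  min_pairs = 3)[["rho"]], unname(pe$estimate)),
      p_value = c(sp$p.value, pe$p.value)
    )
  } else {
    inform("pathway_regulation: fewer than 3 pathways, association not estimated.")
    assoc <- tibble::tibble(method = c("spearman", "pearson"),
                            estimate = NA_real_, p_value = NA_real_)
  }
  structure(list(pathways = rows, association = assoc,
                 n_pathways = nrow(rows)),
            class = "pathway_regulation")
}

#' @export
print.pathway_regulation <- function(x, ...) {
  a <- x$association
  cat(sprintf("<pathway_regulation> %d pathways; DR-RP association: rho = %.3f (p = %.3g), r = %.3f (p = %.3g)\n",
              x$n_pathways, a$estimate[1], a$p_value[1], a$estimate[2], a$p_value[2]))
  invisible(x)
}

#' Bootstrap contrast of a regulation statistic between two gene classes
#'
#' Compares the median of `dr_rho` or `rp_rho` between two gene classes
#' (protein-complex vs non-complex, conservation tertiles, one subcellular
#' location vs the rest, ...) with the two-group bootstrap difference
#' test.
#'
#' @param pan_profiles Per-gene tibble with `dr_rho`/`rp_rho`.
#' @param classes Logical vector named by gene, or two-column data frame
#'   (`gene`, `class` logical): `TRUE` marks class A.
#' @param statistic `"rp_rho"` or `"dr_rho"`.
#' @param min_class_size Minimum genes per class (default 10).
#' @inheritParams bootstrap_median_test
#' @return An object of class `scnareg_boot` (statistic = median(A) -
#'   median(B)).
#' @export
group_contrast <- function(pan_profiles, classes,
                           statistic = c("rp_rho", "dr_rho"),
                           n_boot = 10000, seed = NULL, min_class_size = 10) {
  statistic <- match.arg(statistic)
  if (is.data.frame(classes)) {
    classes <- setNames(as.logical(classes[[2]]), classes[[1]])
  }
  cl <- classes[pan_profiles$gene]
  vals <- pan_profiles[[statistic]]
  a <- vals[isTRUE_vec(cl)]
  b <- vals[!is.na(cl) & !cl]
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < min_class_size || length(b) < min_class_size) {
    abort(sprintf("each class needs at least %d genes with a finite %s.",
                  min_class_size, statistic))
  }
  bootstrap_difference_test(a, b, n_boot = n_boot, seed = seed)
}

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene list and each reference set, within a stated gene universe;
#' p-values are BH-adjusted across the tested sets.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param sets A `gene_set_collection`, named list, or single character
#'   vector of reference genes.
#' @param universe Character vector of all eligible genes.
#' @return A tibble per set: `set`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `fold_enrichment`, `p_value`, `fdr`.
#' @export
overrepresentation_test <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) abort("empty universe.")
  query <- unique(query)
  if (!all(query %in% universe)) abort("query genes must be a subset of the universe.")
  if (is.character(sets)) sets <- list(set = sets)
  rows <- purrr::imap_dfr(as.list(sets), function(ref, nm) {
    ref <- intersect(unique(ref), universe)
    k <- length(intersect(query, ref))
    N <- length(universe); K <- length(ref); n <- length(query)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (K == 0 || n == 0) NA_real_ else (k / n) / (K / N)
    tibble::tibble(set = nm, overlap = k, set_size = K, query_size = n,
                   universe_size = N, fold_enrichment = fe, p_value = p)
  })
  rows$fdr <- fdr_adjust(rows$p_value)
  rows
}
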