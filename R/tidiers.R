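#' Tidy a bootstrap test result
#'
#' @param x An `scnareg_boot` object.
#' @param ... Unused.
#' @return One-row tibble: `statistic`, `ci_low`, `ci_high`, `p_value`.
#' @method tidy scnareg_boot
#' @export
tidy.scnareg_boot <- function(x, ...) {
  tibble::tibble(type = x$type, statistic = x$statistic, ci_low = x$ci_low,
                 ci_high = x$ci_high, p_value = x$p_value)
}

#' @rdname tidy.scnareg_boot
#' @return For `glance`: one-row tibble with the test configuration.
#' @method glance scnareg_boot
#' @export
glance.scnareg_boot <- function(x, ...) {
  tibble::tibble(n_boot = x$n_boot, n = paste(x$n, collapse = "/"),
                 alternative = x$alternative,
                 seed = x$seed %||% NA_integer_)
}

#' Tidy the representative points of a density-slope fit
#'
#' @param x A `density_slope` object.
#' @param ... Unused.
#' @return Tibble of representative `(dr, rp)` points.
#' @method tidy density_slope
#' @export
tidy.density_slope <- function(x, ...) x$points

#' @rdname tidy.density_slope
#' @return For `glance`: one-row tibble with `slope`, `intercept`, `rho`,
#'   `n_bins`, `n_points`.
#' @method glance density_slope
#' @export
glance.density_slope <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, rho = x$rho,
                 n_bins = x$n_bins, n_points = x$n_points)
}

#' Tidy a pathway-level regulation table
#'
#' @param x A `pathway_regulation` object.
#' @param ... Unused.
#' @return The per-pathway tibble of median correlations.
#' @method tidy pathway_regulation
#' @export
tidy.pathway_regulation <- function(x, ...) x$pathways

#' @rdname tidy.pathway_regulation
#' @return For `glance`: one-row tibble with the table-level Spearman and
#'   Pearson association statistics.
#' @method glance pathway_regulation
#' @export
glance.pathway_regulation <- function(x, ...) {
  a <- x$association
  tibble::tibble(
    n_pathways = x$n_pathways,
    spearman_rho = a$estimate[a$method == "spearman"],
    spearman_p = a$p_value[a$method == "spearman"],
    pearson_r = a$estimate[a$method == "pearson"],
    pearson_p = a$p_value[a$method == "pearson"]
  )
}

#' Tidy regulation group membership
#'
#' @param x A `regulation_groups` object.
#' @param ... Unused.
#' @return Long tibble: `gene`, `group`.
#' @method tidy regulation_groups
#' @export
tidy.regulation_groups <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(gene = x$group1, group = "group1"),
    tibble::tibble(gene = x$group2, group = "group2")
  )
}

#' @rdname tidy.regulation_groups
#' @return For `glance`: one-row tibble with group sizes and the realized
#'   cutoffs in wide form.
#' @method glance regulation_groups
#' @export
glance.regulation_groups <- function(x, ...) {
  co <- x$cutoffs
  val <- function(st, tl) co$cutoff[co$statistic == st & co$tail == tl]
  tibble::tibble(q = x$q, n_genes = x$n_genes,
                 n_group1 = length(x$group1), n_group2 = length(x$group2),
                 dr_top_cutoff = val("dr_rho", "top"),
                 dr_bottom_cutoff = val("dr_rho", "bottom"),
                 rp_top_cutoff = val("rp_rho", "top"),
                 rp_bottom_cutoff = val("rp_rho", "bottom"))
}
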