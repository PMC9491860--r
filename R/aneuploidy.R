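#' Project copy-number segments onto fixed-size windows within arms
#'
#' Each chromosome arm is tiled into `window_size`-bp windows (0-based,
#' half-open); every window receives the length-weighted mean log2 ratio
#' of the segments overlapping it. Overlapping segments from one sample
#' are resolved by the same length weighting. Windows with no covering
#' segment are reported as missing.
#'
#' @param segments Segment tibble (see [read_segments()]).
#' @param arms Arm definition tibble (see [read_arm_table()]).
#' @param window_size Window size in base pairs (default 1e5).
#' @return A tibble: `sample`, `chrom`, `arm`, `window_start`,
#'   `window_end`, `log2_ratio` (NA where uncovered).
#' @export
segments_to_windows <- function(segments, arms, window_size = 1e5) {
  if (!is.numeric(window_size) || window_size <= 0) abort("`window_size` must be positive.")
  segments <- validate_segments(segments)
  arms <- validate_arm_table(arms)
  samples <- unique(segments$sample)
  seg_by <- split(segments, segments$sample)
  purrr::map_dfr(samples, function(sm) {
    seg <- seg_by[[sm]]
    purrr::map_dfr(seq_len(nrow(arms)), function(ai) {
      a <- arms[ai, ]
      starts <- seq(a$start, a$end - 1, by = window_size)
      ends <- pmin(starts + window_size, a$end)
      wsum <- numeric(length(starts))
      cov <- numeric(length(starts))
      s <- seg[seg$chrom == a$chrom & seg$end > a$start & seg$start < a$end, ]
      if (nrow(s)) {
        for (k in seq_len(nrow(s))) {
          lo <- max(s$start[k], a$start)
          hi <- min(s$end[k], a$end)
          first <- floor((lo - a$start) / window_size) + 1
          last <- ceiling((hi - a$start) / window_size)
          idx <- first:last
          ow <- pmin(ends[idx], hi) - pmax(starts[idx], lo)
          wsum[idx] <- wsum[idx] + ow * s$log2_ratio[k]
          cov[idx] <- cov[idx] + ow
        }
      }
      tibble::tibble(sample = sm, chrom = a$chrom, arm = a$arm,
                     window_start = starts, window_end = ends,
                     log2_ratio = ifelse(cov > 0, wsum / cov, NA_real_))
    })
  })
}

#' Call arm-level gains and losses from windowed ratios
#'
#' An arm's log2 ratio is the mean of its non-missing windows, provided at
#' least `min_window_frac` of them are covered; the call is a gain when
#' the ratio is strictly above `gain_threshold`, a loss when strictly
#' below `loss_threshold`, and neutral otherwise. Under-covered arms get a
#' missing call.
#'
#' @param windows Tibble from [segments_to_windows()].
#' @param min_window_frac Minimum fraction of covered windows per arm
#'   (default 0.5).
#' @param gain_threshold,loss_threshold Strict call thresholds (default
#'   +0.2 / -0.2).
#' @return A tibble: `sample`, `chrom`, `arm`, `arm_log2_ratio`, `call`
#'   (factor gain/neutral/loss, NA when under-covered).
#' @export
windows_to_arm_calls <- function(windows, min_window_frac = 0.5,
                                 gain_threshold = 0.2, loss_threshold = -0.2) {
  out <- dplyr::summarise(
    dplyr::group_by(windows, .data$sample, .data$chrom, .data$arm),
    frac_covered = mean(!is.na(.data$log2_ratio)),
    arm_log2_ratio = ifelse(.data$frac_covered[1] >= min_window_frac,
                            mean(.data$log2_ratio, na.rm = TRUE), NA_real_),
    .groups = "drop"
  )
  out$call <- factor(
    ifelse(is.na(out$arm_log2_ratio), NA_character_,
           ifelse(out$arm_log2_ratio > gain_threshold, "gain",
                  ifelse(out$arm_log2_ratio < loss_threshold, "loss", "neutral"))),
    levels = c("loss", "neutral", "gain")
  )
  out[, c("sample", "chrom", "arm", "arm_log2_ratio", "call")]
}

#' Per-sample aneuploidy score
#'
#' The aneuploidy score of a sample is the count of chromosome arms called
#' gained or lost; arms with a missing call contribute zero.
#'
#' @param calls Tibble from [windows_to_arm_calls()].
#' @return A tibble: `sample`, `n_arms_gained`, `n_arms_lost`,
#'   `aneuploidy_score`.
#' @export
compute_aneuploidy_score <- function(calls) {
  dplyr::summarise(
    dplyr::group_by(calls, .data$sample),
    n_arms_gained = sum(.data$call == "gain", na.rm = TRUE),
    n_arms_lost = sum(.data$call == "loss", na.rm = TRUE),
    aneuploidy_score = .data$n_arms_gained + .data$n_arms_lost,
    .groups = "drop"
  )
}

#' Cell-cycle activity score from a marker gene list
#'
#' Mean log2 RNA level over a configured list of cell-cycle entry genes,
#' per sample. Listed genes absent from the matrix are reported with a
#' warning; the score is the mean over those present.
#'
#' @param rna An [omics_matrix] of the `rna_abundance` layer.
#' @param gene_list Character vector of marker genes (a curated cell-cycle
#'   entry list; no default is hard-coded).
#' @return Named numeric vector of per-sample scores.
#' @export
compute_cell_cycle_score <- function(rna, gene_list) {
  stopifnot(inherits(rna, "omics_matrix"))
  present <- intersect(gene_list, rownames(rna))
  if (!length(present)) abort("none of the listed genes are present in the matrix.")
  missing <- setdiff(gene_list, present)
  if (length(missing)) {
    warn(sprintf("cell-cycle list: %d gene(s) absent (%s).", length(missing),
                 paste(head(missing, 5), collapse = ", ")))
  }
  m <- rna[present, , drop = FALSE]
  if (omx_scale(rna) == "linear") {
    if (any(!is.na(m) & m <= 0)) abort("nonpositive value on a linear-scale layer.")
    m <- log2(m)
  }
  colMeans(m, na.rm = TRUE)
}

#' Linear model of one gene's expression against aneuploidy
#'
#' Ordinary least squares of `y ~ aneuploidy + covariates`; the t-value of
#' the aneuploidy coefficient summarizes the association with residual
#' degrees of freedom `n - p`. Categorical covariates are expanded to
#' indicator contrasts; samples with any missing value are dropped
#' listwise. A fit with (numerically) zero residual variance is flagged
#' degenerate and its t-value reported as signed infinity.
#'
#' @param y Numeric vector of per-sample expression (or log2FC) for one
#'   gene.
#' @param aneuploidy Numeric vector of per-sample aneuploidy scores.
#' @param covariates Optional data frame of per-sample covariates (purity,
#'   cell-cycle score, cancer type, ...).
#' @param gene Gene identifier carried into the output.
#' @return One-row tibble: `gene`, `beta_aneuploidy`, `t_value`,
#'   `p_value`, `n_samples`, `degenerate`, `covariates`.
#' @export
fit_expression_model <- function(y, aneuploidy, covariates = NULL,
                                 gene = NA_character_) {
  df <- data.frame(.y = y, .aneuploidy = aneuploidy)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$.aneuploidy)) < 2) abort("constant aneuploidy vector.")
  fit <- lm(.y ~ ., data = df)
  p <- fit$rank
  n <- nrow(df)
  if (n <= p + 1) abort("too few samples for the number of parameters.")
  if (!".aneuploidy" %in% names(coef(fit)) || is.na(coef(fit)[".aneuploidy"])) {
    abort("aneuploidy coefficient not estimable (collinear predictors).")
  }
  beta <- unname(coef(fit)[".aneuploidy"])
  rss <- sum(fit$residuals^2)
  tss <- sum((df$.y - mean(df$.y))^2)
  degenerate <- rss <= .Machine$double.eps * max(tss, 1)
  if (degenerate) {
    tval <- sign(beta) * Inf
    pval <- 0
  } else {
    sm <- summary(fit)$coefficients
    tval <- sm[".aneuploidy", "t value"]
    pval <- sm[".aneuploidy", "Pr(>|t|)"]
  }
  tibble::tibble(gene = gene, beta_aneuploidy = beta, t_value = tval,
                 p_value = pval, n_samples = n, degenerate = degenerate,
                 covariates = paste(names(covariates) %||% character(0),
                                    collapse = ","))
}

#' Fit the aneuploidy model for every gene of a matrix
#'
#' Applies [fit_expression_model()] row-wise over a gene-by-sample matrix
#' of expression values (or fold changes), aligning samples by name.
#'
#' @param expr Gene-by-sample numeric matrix (log2-scale values or log2FC).
#' @param scores Tibble from [compute_aneuploidy_score()] or a named
#'   numeric vector of per-sample scores.
#' @param covariates Optional data frame of per-sample covariates with
#'   rownames (or a `sample` column) matching the matrix columns.
#' @param gene_mask Optional character vector of genes to exclude before
#'   fitting (e.g. mitochondrial genes).
#' @return Tibble with one row per fitted gene.
#' @export
fit_expression_models <- function(expr, scores, covariates = NULL,
                                  gene_mask = NULL) {
  if (inherits(scores, "data.frame")) {
    scores <- setNames(scores$aneuploidy_score, scores$sample)
  }
  samples <- intersect(colnames(expr), names(scores))
  if (length(samples) < 3) abort("too few samples shared between matrix and scores.")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if ("sample" %in% names(covariates)) {
      rownames(covariates) <- covariates$sample
      covariates$sample <- NULL
    }
    covariates <- covariates[samples, , drop = FALSE]
  }
  genes <- rownames(expr)
  if (!is.null(gene_mask)) genes <- setdiff(genes, gene_mask)
  sc <- scores[samples]
  purrr::map_dfr(genes, function(g) {
    tryCatch(
      fit_expression_model(expr[g, samples], sc, covariates = covariates,
                           gene = g),
      error = function(e) NULL
    )
  })
}

#' Rank genes by the aneuploidy t-value
#'
#' Descending order by `t_value`; degenerate fits are excluded and ties
#' are broken by gene identifier so the ranking is deterministic.
#'
#' @param fits Tibble from [fit_expression_models()].
#' @return Tibble `gene`, `t_value` in ranking order.
#' @export
rank_genes <- function(fits) {
  ok <- fits[!fits$degenerate & is.finite(fits$t_value), ]
  if (!nrow(ok)) abort("no non-degenerate fits to rank.")
  ok <- ok[order(-ok$t_value, ok$gene), ]
  tibble::tibble(gene = ok$gene, t_value = ok$t_value)
}

# weighted Kolmogorov-Smirnov running-sum enrichment score.
# scores must be sorted in ranking order; returns the signed extreme
# deviation and the position where it is attained.
gsea_es <- function(in_set, scores, weight = 1) {
  n <- length(scores)
  nh <- sum(in_set)
  if (nh == 0 || nh == n) return(NULL)
  w <- abs(scores)^weight
  nr <- sum(w[in_set])
  step <- numeric(n)
  if (nr > 0) {
    step[in_set] <- w[in_set] / nr
  } else {
    step[in_set] <- 1 / nh   # all hit weights zero: fall back to equal steps
  }
  step[!in_set] <- -1 / (n - nh)
  running <- cumsum(step)
  # tie rule: the earliest position attaining the extreme magnitude (up to
  # accumulation rounding) defines the ES
  m <- max(abs(running))
  i <- which(abs(running) >= m - 1e-12 * max(1, m))[1]
  list(es = running[i], at = i, running = running)
}

#' Preranked gene-set enrichment analysis
#'
#' The classical weighted Kolmogorov-Smirnov walk over a ranked gene list:
#' hits advance the running sum by `|score|^weight` (normalized over the
#' set), misses retreat by `1/(N - Nh)`, and the enrichment score (ES) is
#' the signed extreme of the walk. Significance comes from gene-label
#' permutations: for each set, `n_perm` random same-size gene sets provide
#' the null ES distribution; the normalized enrichment score (NES) divides
#' the ES by the mean magnitude of same-sign null scores, the nominal
#' p-value is the same-sign tail fraction, and the FDR q-value compares
#' the observed NES against the pooled null NES distribution, positive and
#' negative sides separately. Sets with no gene in the list (or covering
#' the whole list) are skipped with a message.
#'
#' @param ranked Tibble from [rank_genes()] (columns `gene` and a score
#'   column, by default `t_value`), or a named numeric vector already in
#'   ranking order.
#' @param gene_sets A `gene_set_collection` or named list.
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param weight Exponent on the hit weights (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param seed Optional integer seed for the permutations.
#' @param score_column Score column name when `ranked` is a data frame.
#' @return A tibble of class `scnareg_enrichment`: `set`, `size`, `es`,
#'   `nes`, `p_value`, `fdr`, `leading_edge` (list column).
#' @export
preranked_enrichment <- function(ranked, gene_sets, n_perm = 1000, weight = 1,
                                 seed = NULL, score_column = "t_value") {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene
    scores <- ranked[[score_column]]
  } else {
    genes <- names(ranked)
    scores <- unname(ranked)
  }
  if (any(!is.finite(scores))) abort("ranked scores must be finite.")
  n <- length(genes)
  run <- function() {
    obs <- purrr::imap(as.list(gene_sets), function(members, nm) {
      in_set <- genes %in% members
      r <- gsea_es(in_set, scores, weight)
      if (is.null(r)) {
        inform(sprintf("preranked_enrichment: skipping '%s' (no usable overlap).", nm))
        return(NULL)
      }
      hit_pos <- which(in_set)
      le <- if (r$es >= 0) genes[hit_pos[hit_pos <= r$at]] else genes[hit_pos[hit_pos > r$at]]
      list(set = nm, size = sum(in_set), es = r$es, leading_edge = le)
    })
    obs <- obs[!vapply(obs, is.null, logical(1))]
    if (!length(obs)) abort("no gene set overlaps the ranked list.")

    sizes <- vapply(obs, `[[`, numeric(1), "size")
    perm_by_size <- lapply(unique(sizes), function(k) {
      vapply(seq_len(n_perm), function(j) {
        idx <- sample.int(n, k)
        in_set <- logical(n); in_set[idx] <- TRUE
        gsea_es(in_set, scores, weight)$es
      }, numeric(1))
    })
    names(perm_by_size) <- as.character(unique(sizes))

    res <- purrr::map_dfr(obs, function(o) {
      null_es <- perm_by_size[[as.character(o$size)]]
      same <- if (o$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
      p <- if (length(same)) {
        (1 + sum(abs(same) >= abs(o$es))) / (1 + length(same))
      } else 1 / (1 + n_perm)
      denom <- if (length(same)) mean(abs(same)) else NA_real_
      nes <- if (!is.null(denom) && is.finite(denom) && denom > 0) o$es / denom else NA_real_
      null_nes <- if (is.finite(denom) && denom > 0) {
        pos <- null_es[null_es >= 0]; neg <- null_es[null_es < 0]
        c(if (length(pos)) pos / mean(pos) else numeric(0),
          if (length(neg)) -neg / mean(-neg) * -1 else numeric(0))
      } else numeric(0)
      tibble::tibble(set = o$set, size = o$size, es = o$es, nes = nes,
                     p_value = p, leading_edge = list(o$leading_edge),
                     null_nes = list(null_nes))
    })

    # FDR: positive and negative NES handled separately against the pooled
    # permutation NES distribution
    all_null <- unlist(res$null_nes)
    obs_nes <- res$nes
    res$fdr <- vapply(seq_len(nrow(res)), function(i) {
      nes <- obs_nes[i]
      if (!is.finite(nes)) return(NA_real_)
      if (nes >= 0) {
        null_frac <- mean(all_null[all_null >= 0] >= nes)
        obs_frac <- mean(obs_nes[is.finite(obs_nes) & obs_nes >= 0] >= nes)
      } else {
        null_frac <- mean(all_null[all_null < 0] <= nes)
        obs_frac <- mean(obs_nes[is.finite(obs_nes) & obs_nes < 0] <= nes)
      }
      if (!is.finite(null_frac) || !is.finite(obs_frac) || obs_frac == 0) return(NA_real_)
      min(1, null_frac / obs_frac)
    }, numeric(1))
    res$null_nes <- NULL
    res
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class(out) <- c("scnareg_enrichment", class(out))
  out
}
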