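#' Construct an omics abundance matrix
#'
#' An `omics_matrix` is a numeric gene-by-sample matrix tagged with the
#' molecular layer it measures and the scale its values are on. DNA matrices
#' hold log2 copy-number ratios (the log2 of a gene's copy number over the
#' genome average) and are always on the log2 scale. RNA matrices may be
#' linear (FPKM-like) or log2; protein matrices from isobaric-label
#' proteomics are log2 ratios.
#'
#' @param values Numeric matrix with unique rownames (genes) and unique
#'   colnames (samples). Missing entries (`NA`) are allowed and propagate
#'   through downstream computations; they are never imputed.
#' @param layer One of `"dna_log2_ratio"`, `"rna_abundance"`,
#'   `"protein_abundance"`.
#' @param scale `"linear"` or `"log2"`. The DNA layer must be `"log2"`.
#'
#' @return A numeric matrix of class `omics_matrix` with attributes `layer`
#'   and `scale`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' om <- omics_matrix(m, layer = "dna_log2_ratio", scale = "log2")
#' omx_layer(om)
omics_matrix <- function(values, layer, scale = "log2") {
  layer <- match.arg(layer, .layers)
  scale <- match.arg(scale, .scales)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples)) {
    abort("`values` must have rownames (genes) and colnames (samples).")
  }
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene identifier: ", genes[duplicated(genes)][1]))
  }
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample identifier: ", samples[duplicated(samples)][1]))
  }
  if (layer == "dna_log2_ratio" && scale != "log2") {
    abort("the dna_log2_ratio layer is defined on the log2 scale.")
  }
  structure(values, layer = layer, scale = scale,
            class = c("omics_matrix", class(values)))
}

#' @rdname omics_matrix
#' @param x An `omics_matrix`.
#' @export
omx_layer <- function(x) attr(x, "layer")

#' @rdname omics_matrix
#' @export
omx_scale <- function(x) attr(x, "scale")

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s scale=%s: %d genes x %d samples\n",
              omx_layer(x), omx_scale(x), nrow(x), ncol(x)))
  invisible(x)
}

# subsetting keeps the class and tags as long as the result stays a matrix
#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, layer = omx_layer(x), scale = omx_scale(x),
                     class = class(x))
  }
  out
}

#' Read an abundance matrix from a tab-delimited file
#'
#' The expected format is a header row of sample identifiers and a first
#' column of gene identifiers, as distributed by proteogenomic consortia.
#'
#' @param path Path to a tab-delimited file.
#' @inheritParams omics_matrix
#' @param missing Token encoding a missing value. Default `"NA"`.
#' @return An [omics_matrix].
#' @export
read_omics_matrix <- function(path, layer, scale = "log2", missing = "NA") {
  layer <- match.arg(layer, .layers)
  scale <- match.arg(scale, .scales)
  header <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) abort("malformed header: need a gene column and at least one sample.")
  samples <- header[-1]
  if (anyDuplicated(samples)) {
    abort(paste0("duplicate sample identifier in header: ",
                 samples[duplicated(samples)][1]))
  }
  raw <- readr::read_tsv(path, skip = 1, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  if (nrow(raw) && ncol(raw) != length(header)) {
    abort("malformed file: rows do not match the header width.")
  }
  if (!nrow(raw)) {
    raw <- tibble::as_tibble(matrix(character(0), 0, length(header)),
                             .name_repair = "minimal")
  }
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene: ", genes[duplicated(genes)][1]))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  is_missing <- cells == missing | cells == ""
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !is_missing & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric cell '%s' at gene %s, sample %s",
                  cells[bad][1], genes[idx[1]], samples[idx[2]]))
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(genes, samples)
  omics_matrix(num, layer = layer, scale = scale)
}

#' Write an abundance matrix to a tab-delimited file
#'
#' Values are written with a shortest round-trip decimal representation, so
#' `read_omics_matrix(write_omics_matrix(x))` reproduces `x` bit-exactly,
#' including the missing-value pattern.
#'
#' @param x An [omics_matrix].
#' @param path Output path.
#' @param gene_column Name of the first (gene identifier) column.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, gene_column = "gene") {
  stopifnot(inherits(x, "omics_matrix"))
  tb <- tibble::as_tibble(unclass(x), rownames = gene_column, .name_repair = "minimal")
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}
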