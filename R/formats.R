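#' Read per-sample copy-number segments
#'
#' Reads a SEG-like tab-delimited file with columns `sample`, `chrom`,
#' `start`, `end`, `log2_ratio`. Coordinates are 0-based, half-open
#' `[start, end)`.
#'
#' @param path Path to a tab-delimited segment file.
#' @return A tibble with one row per segment.
#' @export
read_segments <- function(path) {
  seg <- readr::read_tsv(path, col_types = readr::cols(
    sample = readr::col_character(),
    chrom = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double(),
    log2_ratio = readr::col_double()
  ), progress = FALSE)
  validate_segments(seg)
}

validate_segments <- function(seg) {
  need <- c("sample", "chrom", "start", "end", "log2_ratio")
  miss <- setdiff(need, names(seg))
  if (length(miss)) abort(paste0("segment table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(seg$start < 0 | seg$end < 0)) abort("negative segment coordinate.")
  if (any(seg$start >= seg$end)) {
    i <- which(seg$start >= seg$end)[1]
    abort(sprintf("segment with start >= end: %s %s:%g-%g",
                  seg$sample[i], seg$chrom[i], seg$start[i], seg$end[i]))
  }
  tibble::as_tibble(seg[need])
}

#' Write a segment table
#' @param segments A segment tibble as returned by [read_segments()].
#' @param path Output path.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(validate_segments(segments), path, progress = FALSE)
  invisible(path)
}

#' Read a chromosome-arm definition table
#'
#' Columns `chrom`, `arm` (`p`/`q`), `start`, `end`; coordinates 0-based
#' half-open. Arms within one chromosome must not overlap.
#'
#' @param path Path to a tab-delimited arm table.
#' @return A tibble with one row per arm.
#' @export
read_arm_table <- function(path) {
  arms <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    arm = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double()
  ), progress = FALSE)
  validate_arm_table(arms)
}

validate_arm_table <- function(arms) {
  need <- c("chrom", "arm", "start", "end")
  miss <- setdiff(need, names(arms))
  if (length(miss)) abort(paste0("arm table missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!all(arms$arm %in% c("p", "q"))) abort("arm must be 'p' or 'q'.")
  if (any(arms$start < 0)) abort("negative arm coordinate.")
  if (any(arms$start >= arms$end)) abort("arm with start >= end.")
  split_chr <- split(arms, arms$chrom)
  for (ch in split_chr) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1 && any(ch$start[-1] < ch$end[-nrow(ch)])) {
      abort(paste0("overlapping arms on ", ch$chrom[1]))
    }
  }
  tibble::as_tibble(arms[c(need)])
}

#' Read gene sets from a GMT file
#'
#' Standard GMT semantics: one set per line, tab-separated fields
#' `name`, `description`, then member genes. Sets whose size (after
#' de-duplication of members) falls outside `[min_size, max_size]` are
#' dropped, mirroring the conventional 5-500 filter applied before
#' enrichment analyses.
#'
#' @param path Path to a GMT file.
#' @param min_size,max_size Inclusive size bounds for retained sets.
#' @return A named list of character vectors of class
#'   `gene_set_collection`, with a `description` attribute and a
#'   `n_dropped` attribute recording how many sets the size filter removed.
#' @export
read_gene_sets <- function(path, min_size = 5, max_size = 500) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) abort("GMT line with fewer than 3 fields (empty set).")
  nm <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate set name: ", nm[duplicated(nm)][1]))
  }
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  keep <- lengths(sets) >= min_size & lengths(sets) <= max_size
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("read_gene_sets: dropped %d set(s) outside size [%g, %g].",
                   n_dropped, min_size, max_size))
  }
  gene_set_collection(sets[keep], description = desc[keep], n_dropped = n_dropped)
}

gene_set_collection <- function(sets, description = NULL, n_dropped = 0L) {
  if (is.null(description)) description <- rep("", length(sets))
  structure(sets, description = setNames(description, names(sets)),
            n_dropped = n_dropped, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %s\n", length(x),
              if (length(x)) paste0(min(lengths(x)), "-", max(lengths(x))) else "-"))
  invisible(x)
}

#' Write gene sets to a GMT file
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(rep("", length(sets)), names(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[names(sets)[i]]] %||% "", sets[[i]]),
          collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read gene or sample annotation tables
#'
#' Tab-delimited, one record per gene (or sample). The gene table may carry
#' protein-complex membership (`is_complex`), ribosomal membership
#' (`is_ribosomal`), a `subcellular_location` category, a `conservation_score`
#' (phyloP-style) and an `rna_half_life`; only `gene` is required. The sample
#' table requires `sample` and `tumor_type` and may carry `purity` (in
#' `[0, 1]`) and a `genome_doubled` flag.
#'
#' @param path Path to a tab-delimited annotation file.
#' @return A tibble.
#' @export
read_gene_annotation <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        guess_max = Inf)
  validate_gene_annotation(tb)
}

validate_gene_annotation <- function(tb) {
  if (!"gene" %in% names(tb)) abort("gene annotation needs a 'gene' column.")
  if (anyDuplicated(tb$gene)) abort("duplicate gene in annotation.")
  for (fl in c("is_complex", "is_ribosomal")) {
    if (fl %in% names(tb)) tb[[fl]] <- as.logical(tb[[fl]])
  }
  tibble::as_tibble(tb)
}

#' @rdname read_gene_annotation
#' @export
read_sample_annotation <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        guess_max = Inf)
  validate_sample_annotation(tb)
}

validate_sample_annotation <- function(tb) {
  miss <- setdiff(c("sample", "tumor_type"), names(tb))
  if (length(miss)) abort(paste0("sample annotation missing: ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(tb$sample)) abort("duplicate sample in annotation.")
  if ("purity" %in% names(tb)) {
    ok <- is.na(tb$purity) | (tb$purity >= 0 & tb$purity <= 1)
    if (!all(ok)) abort("purity outside [0, 1].")
  }
  if ("genome_doubled" %in% names(tb)) {
    tb$genome_doubled <- as.logical(tb$genome_doubled)
  }
  tibble::as_tibble(tb)
}
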