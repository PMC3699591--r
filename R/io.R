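#' Read a gene-by-sample count table
#'
#' Reads a tab-separated count matrix: one header row of sample ids, gene
#' identifiers in the first column, one column of non-negative integer read
#' counts per sample. Lines starting with `#` are ignored. This is the usual
#' orientation for sequencing count tables: each sample is a column and
#' per-gene counts are in rows.
#'
#' Counts must be integral: fractional values are rejected rather than
#' silently coerced, since they usually indicate an upstream counting error.
#' Set `allow_rounding = TRUE` to round floating-point inputs (e.g. tables
#' produced by estimation tools) to the nearest integer.
#'
#' @param path Path to a TSV file.
#' @param allow_rounding Round non-integral counts instead of failing.
#' @return A tibble with a `gene` character column followed by one integer
#'   column per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t10\t0", "g2\t5\t7"), tf)
#' read_counts(tf)
#' @export
read_counts <- function(path, allow_rounding = FALSE) {
  if (!file.exists(path)) abort(paste0("count file not found: ", path))
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (ncol(tab) < 2L) abort("count table needs a gene-id column plus at least one sample column")
  names(tab)[1] <- "gene"
  validate_counts(tab, allow_rounding = allow_rounding)
}

#' Validate (and canonicalise) a count table
#'
#' Checks the invariants every downstream step relies on: unique non-empty
#' gene and sample identifiers, no missing cells, non-negative integral
#' counts, and at least two genes (the log-ratio transform is undefined for a
#' single component). Errors name the offending gene and sample.
#'
#' @param counts A data frame whose first column (or a column named `gene`)
#'   holds gene ids, with one numeric column per sample; or a numeric matrix
#'   with rownames as gene ids.
#' @inheritParams read_counts
#' @return A validated tibble (`gene` column first).
#' @export
validate_counts <- function(counts, allow_rounding = FALSE) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) abort("count matrix must have gene ids as rownames")
    counts <- dplyr::bind_cols(
      tibble::tibble(gene = rownames(counts)),
      tibble::as_tibble(counts, .name_repair = "minimal")
    )
  }
  counts <- tibble::as_tibble(counts)
  if (!"gene" %in% names(counts)) names(counts)[1] <- "gene"
  counts <- dplyr::relocate(counts, "gene")

  genes <- as.character(counts$gene)
  samples <- setdiff(names(counts), "gene")
  if (length(samples) < 1L) abort("count table has no sample columns")
  if (anyNA(genes) || any(!nzchar(genes))) abort("gene ids must be non-empty")
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene id: ", genes[duplicated(genes)][1]))
  }
  if (anyDuplicated(samples) || any(!nzchar(samples))) abort("sample ids must be unique and non-empty")
  if (length(genes) < 2L) abort("at least two genes are required (the log-ratio transform needs D >= 2)")

  mat <- as.matrix(counts[samples])
  if (!is.numeric(mat)) abort("counts must be numeric")
  bad <- which(is.na(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("invalid count (missing or negative) for gene '%s', sample '%s'",
                  genes[bad[1, 1]], samples[bad[1, 2]]))
  }
  frac <- which(abs(mat - round(mat)) > 1e-8, arr.ind = TRUE)
  if (nrow(frac)) {
    if (!allow_rounding) {
      abort(sprintf("non-integral count for gene '%s', sample '%s' (use allow_rounding = TRUE to round)",
                    genes[frac[1, 1]], samples[frac[1, 2]]))
    }
    mat <- round(mat)
  }
  out <- tibble::as_tibble(mat)
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  dplyr::bind_cols(tibble::tibble(gene = genes), out)
}

# counts tibble -> list(genes, samples, mat, totals)
count_parts <- function(counts) {
  samples <- setdiff(names(counts), "gene")
  mat <- as.matrix(counts[samples])
  rownames(mat) <- counts$gene
  list(genes = counts$gene, samples = samples, mat = mat, totals = colSums(mat))
}

#' Read a two-condition sample assignment
#'
#' Reads a two-column TSV (`sample<TAB>condition`, optional header) mapping
#' each sample to one of exactly two condition labels. Each condition needs
#' at least two samples: the within-condition difference cannot be estimated
#' from a single replicate.
#'
#' @param path Path to the design TSV.
#' @param counts Optional count tibble (from [read_counts()]); when given,
#'   the design is checked against its sample columns.
#' @return A tibble with columns `sample` and `condition`.
#' @export
read_design <- function(path, counts = NULL) {
  if (!file.exists(path)) abort(paste0("design file not found: ", path))
  tab <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tab) != 2L) abort("design file must have two columns: sample and condition")
  names(tab) <- c("sample", "condition")
  if (nrow(tab) && identical(unname(tolower(unlist(tab[1, ]))), c("sample", "condition"))) {
    tab <- tab[-1, ]
  }
  validate_design(tab, counts)
}

#' Validate a two-condition design
#'
#' @param design A data frame with `sample` and `condition` columns, a named
#'   character vector (names = samples), or an unnamed character vector of
#'   labels in count-column order (requires `counts`).
#' @param counts Optional count tibble to check sample ids against.
#' @return A tibble with columns `sample` and `condition`.
#' @export
validate_design <- function(design, counts = NULL) {
  if (is.character(design) || is.factor(design)) {
    nms <- names(design)
    design <- as.character(design)
    if (!is.null(nms) && all(nzchar(nms))) {
      design <- tibble::tibble(sample = nms, condition = unname(design))
    } else if (!is.null(counts)) {
      samples <- setdiff(names(tibble::as_tibble(counts)), "gene")
      if (length(design) != length(samples)) {
        abort("design labels must match the number of sample columns")
      }
      design <- tibble::tibble(sample = samples, condition = design)
    } else {
      abort("an unnamed label vector needs `counts` to supply sample ids")
    }
  }
  design <- tibble::as_tibble(design)
  if (!all(c("sample", "condition") %in% names(design))) {
    abort("design must have `sample` and `condition` columns")
  }
  design <- dplyr::select(design, "sample", "condition")
  design$sample <- as.character(design$sample)
  design$condition <- as.character(design$condition)
  if (anyDuplicated(design$sample)) {
    abort(paste0("sample listed more than once in design: ",
                 design$sample[duplicated(design$sample)][1]))
  }
  if (!is.null(counts)) {
    samples <- setdiff(names(tibble::as_tibble(counts)), "gene")
    missing <- setdiff(samples, design$sample)
    extra <- setdiff(design$sample, samples)
    if (length(extra)) abort(paste0("design sample not in count table: ", extra[1]))
    if (length(missing)) abort(paste0("sample missing from design: ", missing[1]))
  }
  lev <- unique(design$condition)
  if (length(lev) != 2L) {
    abort(sprintf("exactly two conditions are required, found %d (%s)",
                  length(lev), paste(lev, collapse = ", ")))
  }
  n_per <- table(design$condition)
  if (any(n_per < 2L)) {
    abort(sprintf("condition '%s' has %d sample(s); two or more are required per condition",
                  names(n_per)[which.min(n_per)], min(n_per)))
  }
  design
}

#' Write a per-gene result table
#'
#' Writes the result tibble of a fit as TSV. When given a full `ddex` fit the
#' run configuration is echoed as `#` comment lines, so a published table
#' records how it was made. Values round-trip through [read_results()] at full
#' double precision.
#'
#' @param x A `ddex` fit or a result tibble.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_results <- function(x, path) {
  header <- character(0)
  if (inherits(x, "ddex")) {
    cfg <- x$config
    header <- c(
      paste0("# ddex ", as.character(utils::packageVersion("ddex"))),
      paste0("# ", paste(names(cfg), vapply(cfg, function(v) paste(format(v, scientific = FALSE), collapse = ","),
                                            character(1)), sep = "=", collapse = " ")),
      paste0("# conditions: ", paste(x$conditions, collapse = " vs "))
    )
    x <- x$results
  }
  x <- tibble::as_tibble(x)
  if (length(header)) {
    writeLines(header, path)
    readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(x, path)
  }
  invisible(x)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to a result TSV.
#' @return A tibble; `#` comment lines are skipped.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort(paste0("result file not found: ", path))
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    gene = readr::col_character(), .default = readr::col_guess()
  ), progress = FALSE)
  tibble::as_tibble(tab)
}
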