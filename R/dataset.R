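#' Single-cell expression dataset
#'
#' A `bs_dataset` bundles a sparse genes-by-cells count matrix, an optional
#' log-normalized layer of the same shape, and a per-cell metadata table.
#' Counts are non-negative integers; gene and cell identifiers are unique and
#' matched case-sensitively throughout the package.
#'
#' @param counts sparse or dense genes x cells matrix of non-negative integer
#'   counts, with rownames (genes) and colnames (cells)
#' @param meta optional per-cell metadata `data.frame` with a `cell_id`
#'   column; rows are aligned to the columns of `counts` (missing cells get
#'   `NA` fields)
#' @param lognorm optional log-normalized layer, same dimensions as `counts`
#' @return an object of class `bs_dataset` with elements `counts`, `lognorm`
#'   (possibly `NULL`), `meta`, `genes`, `cells`
#' @export
bs_dataset <- function(counts, meta = NULL, lognorm = NULL) {
  counts <- methods::as(as_matrix_like(counts), "CsparseMatrix")
  counts <- methods::as(methods::as(counts, "dMatrix"), "generalMatrix")
  genes <- rownames(counts)
  cells <- colnames(counts)
  if (is.null(genes) && nrow(counts) == 0) genes <- character(0)
  if (is.null(cells) && ncol(counts) == 0) cells <- character(0)
  if (is.null(genes) || is.null(cells))
    stop("counts must carry gene rownames and cell colnames")
  dimnames(counts) <- list(genes, cells)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(cells)) stop("duplicate cell identifiers")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v))))
    stop("counts must be non-negative integers")
  if (is.null(meta)) {
    meta <- data.frame(cell_id = cells, stringsAsFactors = FALSE)
  } else {
    if (!"cell_id" %in% names(meta)) stop("meta must have a cell_id column")
    idx <- match(cells, meta$cell_id)
    meta <- meta[idx, , drop = FALSE]
    meta$cell_id <- cells
    rownames(meta) <- NULL
  }
  if (!is.null(lognorm)) {
    lognorm <- methods::as(methods::as(as_matrix_like(lognorm),
                                       "CsparseMatrix"), "generalMatrix")
    if (!identical(dim(lognorm), dim(counts)))
      stop("lognorm dimensions do not match counts")
    dimnames(lognorm) <- dimnames(counts)
  }
  check_region_values(meta)
  structure(list(counts = counts, lognorm = lognorm, meta = meta,
                 genes = genes, cells = cells),
            class = "bs_dataset")
}

as_matrix_like <- function(m) {
  if (is.matrix(m)) Matrix::Matrix(m, sparse = TRUE) else m
}

check_region_values <- function(meta) {
  for (col in c("region", "truth_region")) {
    if (col %in% names(meta)) {
      bad <- setdiff(unique(stats::na.omit(meta[[col]])), BRAIN_REGIONS)
      if (length(bad))
        stop("invalid region value(s): ", paste(bad, collapse = ", "))
    }
  }
  for (col in c("subregion", "truth_subregion")) {
    if (col %in% names(meta)) {
      bad <- setdiff(unique(stats::na.omit(meta[[col]])), SUBREGIONS)
      if (length(bad))
        stop("invalid subregion value(s): ", paste(bad, collapse = ", "))
    }
  }
  invisible(meta)
}

#' @export
print.bs_dataset <- function(x, ...) {
  cat(sprintf("bs_dataset: %d genes x %d cells%s\n",
              length(x$genes), length(x$cells),
              if (is.null(x$lognorm)) "" else " (log-normalized layer present)"))
  extra <- setdiff(names(x$meta), "cell_id")
  if (length(extra)) cat("meta:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param ds a `bs_dataset`
#' @return integer count
#' @export
n_cells <- function(ds) length(ds$cells)

#' @rdname n_cells
#' @export
n_genes <- function(ds) length(ds$genes)

#' Subset a dataset to selected cells
#'
#' Genes are unchanged; count (and lognorm) columns and metadata rows stay
#' aligned. An all-`FALSE` mask yields a valid 0-cell dataset.
#'
#' @param ds a `bs_dataset`
#' @param mask logical vector of length `n_cells(ds)`, or a character vector
#'   of cell identifiers
#' @return the subsetted `bs_dataset`
#' @export
subset_cells <- function(ds, mask) {
  if (is.character(mask)) {
    missing <- setdiff(mask, ds$cells)
    if (length(missing))
      stop("unknown cell id(s): ", paste(head(missing, 5), collapse = ", "))
    mask <- ds$cells %in% mask
  }
  stopifnot(is.logical(mask), length(mask) == n_cells(ds))
  mask[is.na(mask)] <- FALSE
  out <- ds
  out$counts <- ds$counts[, mask, drop = FALSE]
  if (!is.null(ds$lognorm)) out$lognorm <- ds$lognorm[, mask, drop = FALSE]
  out$meta <- ds$meta[mask, , drop = FALSE]
  rownames(out$meta) <- NULL
  out$cells <- ds$cells[mask]
  out
}

#' Read a CellRanger-style MTX bundle into a dataset
#'
#' Expects `matrix.mtx`, `features.tsv`, `barcodes.tsv` (optionally `.gz`)
#' under `directory`, plus an optional `cells.csv` metadata table keyed by
#' `cell_id`. Cells without a metadata row get `NA` fields.
#'
#' @param directory path to the bundle directory
#' @return a `bs_dataset`
#' @export
read_mtx_dataset <- function(directory) {
  find1 <- function(base) {
    for (f in file.path(directory, c(base, paste0(base, ".gz"))))
      if (file.exists(f)) return(f)
    stop("missing file in MTX bundle: ", base, " (looked in ", directory, ")")
  }
  mtx <- find1("matrix.mtx")
  feat <- find1("features.tsv")
  bar <- find1("barcodes.tsv")
  counts <- Matrix::readMM(mtx)
  first_field <- function(f) {
    lines <- readLines(f)
    vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  }
  features <- first_field(feat)
  barcodes <- first_field(bar)
  if (length(features) != nrow(counts))
    stop(sprintf(
      "integrity error: matrix.mtx declares %d genes but features.tsv has %d lines",
      nrow(counts), length(features)))
  if (length(barcodes) != ncol(counts))
    stop(sprintf(
      "integrity error: matrix.mtx declares %d cells but barcodes.tsv has %d lines",
      ncol(counts), length(barcodes)))
  rownames(counts) <- features
  colnames(counts) <- barcodes
  meta <- NULL
  meta_file <- file.path(directory, "cells.csv")
  if (file.exists(meta_file))
    meta <- read.csv(meta_file, stringsAsFactors = FALSE)
  bs_dataset(counts, meta = meta)
}

#' Write a dataset as a CellRanger-style MTX bundle
#'
#' Writes `matrix.mtx` (counts only; any lognorm layer is recomputable and
#' not serialized), `features.tsv`, `barcodes.tsv` and `cells.csv`.
#' `read_mtx_dataset()` inverts this bit-exactly on counts and metadata.
#'
#' @param ds a `bs_dataset`
#' @param directory output directory (created if absent)
#' @return the directory path, invisibly
#' @export
write_mtx_dataset <- function(ds, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  Matrix::writeMM(ds$counts, file.path(directory, "matrix.mtx"))
  writeLines(ds$genes, file.path(directory, "features.tsv"))
  writeLines(ds$cells, file.path(directory, "barcodes.tsv"))
  write.csv(ds$meta, file.path(directory, "cells.csv"), row.names = FALSE)
  invisible(directory)
}
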