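#' Annotated gene-by-cell count container
#'
#' Bundles a sparse genes x cells count matrix with per-cell annotations
#' (age, tissue, cell type, sample, optional spatial coordinates). All
#' discovery and scoring functions in the package consume this container.
#'
#' @param counts A matrix or sparse Matrix, genes in rows, cells in columns,
#'   nonnegative values. Coerced to `dgCMatrix`.
#' @param genes Character vector of gene symbols, one per row of `counts`.
#' @param cell_meta Data frame with one row per column of `counts`. Required
#'   columns: `cell_id`, `age`, `age_unit` (one of `"months"`, `"years"`,
#'   `"bin_index"`), `sample_id`. Optional: `tissue`, `cell_type`, `x`, `y`.
#' @param layer_kind Either `"raw"` (UMI counts) or `"normalized_log"`.
#'
#' @return An object of class `annotated_counts`: a list with elements
#'   `counts` (dgCMatrix), `genes`, `cells`, `cell_meta` (tibble) and
#'   `layer_kind`.
#' @export
#' @examples
#' m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 3), x = c(2, 1), dims = c(3, 4))
#' meta <- tibble::tibble(
#'   cell_id = paste0("c", 1:4), age = c(3, 3, 24, 24), age_unit = "months",
#'   tissue = "lung", cell_type = "fibroblast", sample_id = "s1"
#' )
#' ac <- annotated_counts(m, paste0("g", 1:3), meta)
#' dim(ac)
annotated_counts <- function(counts, genes, cell_meta, layer_kind = "raw") {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  cell_meta <- as_tibble(cell_meta)
  if (nrow(counts) != length(genes)) {
    abort(sprintf(
      "counts has %d rows but %d gene symbols were given",
      nrow(counts), length(genes)
    ), class = "senesig_dim_error")
  }
  if (ncol(counts) != nrow(cell_meta)) {
    abort(sprintf(
      "counts has %d columns but cell_meta has %d rows",
      ncol(counts), nrow(cell_meta)
    ), class = "senesig_dim_error")
  }
  if (anyDuplicated(genes)) {
    abort("gene symbols must be unique", class = "senesig_data_error")
  }
  if (length(counts@x) && min(counts@x) < 0) {
    abort("counts contain negative values", class = "senesig_data_error")
  }
  required <- c("cell_id", "age", "age_unit", "sample_id")
  missing <- setdiff(required, names(cell_meta))
  if (length(missing)) {
    abort(paste0(
      "cell_meta is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "senesig_schema_error")
  }
  if (anyNA(cell_meta$age) || anyNA(cell_meta$sample_id)) {
    abort("every cell must have an age and a sample_id",
      class = "senesig_data_error"
    )
  }
  if (!all(cell_meta$age_unit %in% c("months", "years", "bin_index"))) {
    abort("age_unit must be one of 'months', 'years', 'bin_index'",
      class = "senesig_schema_error"
    )
  }
  layer_kind <- match.arg(layer_kind, c("raw", "normalized_log"))
  for (col in c("tissue", "cell_type")) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- "unspecified"
  }
  dimnames(counts) <- list(as.character(genes), as.character(cell_meta$cell_id))
  structure(
    list(
      counts = counts,
      genes = as.character(genes),
      cells = as.character(cell_meta$cell_id),
      cell_meta = cell_meta,
      layer_kind = layer_kind
    ),
    class = "annotated_counts"
  )
}

#' @export
dim.annotated_counts <- function(x) dim(x$counts)

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf(
    "<annotated_counts> %d genes x %d cells [%s layer]\n",
    nrow(x$counts), ncol(x$counts), x$layer_kind
  ))
  cat(sprintf(
    "  tissues: %s | cell types: %s | samples: %d\n",
    paste(unique(x$cell_meta$tissue), collapse = ","),
    paste(unique(x$cell_meta$cell_type), collapse = ","),
    length(unique(x$cell_meta$sample_id))
  ))
  invisible(x)
}

#' Subset an annotated_counts object by cells and/or genes
#'
#' @param data An [annotated_counts()] object.
#' @param cells Logical, integer, or character index into the cells.
#' @param genes Logical, integer, or character index into the genes.
#' @return An `annotated_counts` restricted to the selection.
#' @export
subset_cells <- function(data, cells = NULL, genes = NULL) {
  stopifnot(inherits(data, "annotated_counts"))
  ci <- if (is.null(cells)) seq_along(data$cells) else cells
  if (is.character(ci)) ci <- match(ci, data$cells)
  gi <- if (is.null(genes)) seq_along(data$genes) else genes
  if (is.character(gi)) gi <- match(gi, data$genes)
  if (anyNA(ci) || anyNA(gi)) {
    abort("unknown cell or gene identifier in subset", class = "senesig_data_error")
  }
  annotated_counts(
    data$counts[gi, ci, drop = FALSE],
    data$genes[gi],
    data$cell_meta[ci, , drop = FALSE],
    layer_kind = data$layer_kind
  )
}

read_cells_tsv <- function(cells_path) {
  cm <- readr::read_tsv(cells_path, show_col_types = FALSE, progress = FALSE)
  required <- c("cell_id", "age", "age_unit", "tissue", "cell_type", "sample_id")
  missing <- setdiff(required, names(cm))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      cells_path, paste(missing, collapse = ", ")
    ), class = "senesig_schema_error")
  }
  cm
}

#' Read a count matrix with gene and cell sidecar tables
#'
#' Accepts Matrix Market coordinate files (`.mtx`) or dense CSV (gene rows,
#' cell columns; first column gene symbol). Sidecars are headered TSVs:
#' `genes_path` has a `gene` column, `cells_path` has
#' `cell_id, age, age_unit, tissue, cell_type, sample_id` and optional
#' `x, y` spot coordinates.
#'
#' @param matrix_path Path to the `.mtx` or `.csv` matrix.
#' @param genes_path Path to the gene sidecar TSV.
#' @param cells_path Path to the cell sidecar TSV.
#' @param orientation On-disk orientation of the MTX file:
#'   `"genes_by_cells"` or `"cells_by_genes"`. Required — square-ish matrices
#'   cannot be disambiguated from their shape, so no guessing is done.
#' @return An [annotated_counts()] with `layer_kind = "raw"`.
#' @export
read_counts <- function(matrix_path, genes_path, cells_path,
                        orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  gm <- readr::read_tsv(genes_path, show_col_types = FALSE, progress = FALSE)
  if (!"gene" %in% names(gm)) {
    abort(sprintf("%s is missing required column 'gene'", genes_path),
      class = "senesig_schema_error"
    )
  }
  cm <- read_cells_tsv(cells_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
  } else {
    df <- utils::read.csv(matrix_path, check.names = FALSE)
    rn <- df[[1]]
    m <- as(as.matrix(df[, -1, drop = FALSE]), "CsparseMatrix")
    rownames(m) <- rn
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
  }
  if (nrow(m) != nrow(gm)) {
    abort(sprintf(
      "matrix %s has %d gene rows but %s lists %d genes",
      matrix_path, nrow(m), genes_path, nrow(gm)
    ), class = "senesig_dim_error")
  }
  if (ncol(m) != nrow(cm)) {
    abort(sprintf(
      "matrix %s has %d cell columns but %s lists %d cells",
      matrix_path, ncol(m), cells_path, nrow(cm)
    ), class = "senesig_dim_error")
  }
  annotated_counts(m, gm$gene, cm, layer_kind = "raw")
}

#' Write an annotated_counts object as MTX plus sidecar TSVs
#'
#' Inverse of [read_counts()]: writes `matrix.mtx`, `genes.tsv` and
#' `cells.tsv` (genes-by-cells orientation) into `dir`.
#'
#' @param data An [annotated_counts()] object.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(data, dir) {
  stopifnot(inherits(data, "annotated_counts"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  Matrix::writeMM(data$counts, paths[1])
  readr::write_tsv(tibble(gene = data$genes), paths[2], progress = FALSE)
  readr::write_tsv(data$cell_meta, paths[3], progress = FALSE)
  invisible(paths)
}
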