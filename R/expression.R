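# Count-matrix loading and per-population expression summaries.
#
# Orientation convention: cells x genes throughout. MatrixMarket triplets are
# assumed genes x cells (the common single-cell export layout) and transposed
# on load; dense CSV/TSV input is taken as cells x rows directly.

#' Validate and wrap a cells x genes count matrix
#'
#' @param counts matrix or Matrix, cells in rows, genes in columns, with
#'   unique non-empty dimnames and no negative entries.
#' @return a `dgCMatrix` with class attribute `expression_matrix` prepended.
#' @export
expression_matrix <- function(counts) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "dMatrix")
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    abort_validation("expression matrix needs at least 1 cell and 1 gene")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort_validation("expression matrix requires cell and gene names")
  }
  if (anyDuplicated(rownames(counts))) abort_validation("duplicate cell identifiers")
  if (anyDuplicated(colnames(counts))) abort_validation("duplicate gene identifiers")
  if (any(counts@x < 0)) abort_validation("expression matrix contains negative entries")
  counts
}

#' Load a count matrix from MTX or dense text
#'
#' For `format = "mtx"` supply the MatrixMarket file plus barcode (cell) and
#' feature (gene) name files, one name per line (first column used if the
#' files are multi-column, as with 10x-style features.tsv). The MTX is read as
#' genes x cells and transposed. For `format = "dense"` supply a single
#' CSV/TSV with a header of gene names and cell identifiers in the first
#' column. `format = "auto"` picks by file extension.
#'
#' @param matrix_path path to the matrix file.
#' @param cells_path,genes_path name files (MTX only).
#' @param format one of `"auto"`, `"mtx"`, `"dense"`.
#' @return a validated cells x genes sparse matrix.
#' @export
load_counts <- function(matrix_path, cells_path = NULL, genes_path = NULL,
                        format = c("auto", "mtx", "dense")) {
  format <- match.arg(format)
  if (!file.exists(matrix_path)) abort_io("counts file not found: %s", matrix_path)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) "mtx" else "dense"
  }
  if (format == "mtx") {
    if (is.null(cells_path) || is.null(genes_path)) {
      abort_format("MTX input requires cell and gene name files")
    }
    if (!file.exists(cells_path)) abort_io("cell names file not found: %s", cells_path)
    if (!file.exists(genes_path)) abort_io("gene names file not found: %s", genes_path)
    m <- Matrix::readMM(matrix_path)  # genes x cells
    cells <- read_name_column(cells_path)
    genes <- read_name_column(genes_path)
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      abort_format(
        "MTX dimensions (%d genes x %d cells) do not match name files (%d genes, %d cells)",
        nrow(m), ncol(m), length(genes), length(cells))
    }
    m <- Matrix::t(m)
    dimnames(m) <- list(cells, genes)
  } else {
    dt <- data.table::fread(matrix_path, header = TRUE, data.table = FALSE)
    cells <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- cells
  }
  expression_matrix(m)
}

read_name_column <- function(path) {
  dt <- data.table::fread(path, header = FALSE, data.table = FALSE, sep = "\t")
  as.character(dt[[1]])
}

#' Load a cell -> population annotation table
#'
#' Tab-delimited with columns `cell` and `population`. Every annotated cell
#' must exist in the matrix when `counts` is supplied; populations smaller
#' than `min_cells` are flagged with a warning.
#'
#' @param path annotation file path.
#' @param counts optional expression matrix for cross-validation.
#' @param min_cells floor below which a population is flagged (default 20).
#' @return data.frame with columns `cell`, `population`.
#' @export
load_annotation <- function(path, counts = NULL, min_cells = 20L) {
  df <- read_tsv_checked(path, c("cell", "population"), "annotation")
  ann <- data.frame(cell = as.character(df$cell),
                    population = as.character(df$population),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$cell)) abort_validation("duplicate cell in annotation")
  if (nrow(ann) == 0L) abort_validation("annotation is empty")
  if (!is.null(counts)) {
    missing <- setdiff(ann$cell, rownames(counts))
    if (length(missing)) {
      abort_validation("%d annotated cell(s) absent from the matrix (e.g. %s)",
                       length(missing), missing[1])
    }
  }
  sizes <- table(ann$population)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning(sprintf("population(s) below %d cells: %s", min_cells,
                    paste(small, collapse = ", ")), call. = FALSE)
  }
  ann
}

#' Binarize expression values
#'
#' A value of at least one count maps to `+1` (expressed), anything below to
#' `-1`. The rule is applied literally to whatever values are supplied; on
#' normalized (non-integer) data values below 1 are treated as not expressed.
#'
#' @param x non-negative numeric vector.
#' @return integer vector of `+1`/`-1`.
#' @export
binarize <- function(x) {
  if (any(x < 0)) abort_validation("binarize expects non-negative values")
  ifelse(x >= 1, 1L, -1L)
}

#' Summarize one population's expression
#'
#' Computes, for every gene, the number of expressing cells (count >= 1), the
#' expressed-cell fraction, the mean expression over expressing cells only
#' (0 when none express), the any-cell binary state (`+1` iff at least one
#' cell expresses), and a majority-of-cells consensus state (`+1` iff the
#' expressed fraction is at least 0.5) used as the observed activity state in
#' compatibility testing.
#'
#' @param counts cells x genes matrix from [expression_matrix()].
#' @param annotation data.frame with `cell`, `population` columns.
#' @param population population label to profile.
#' @return data.frame of class `population_profile` with one row per gene and
#'   attributes `population` and `n_cells`.
#' @export
profile_population <- function(counts, annotation, population) {
  cells <- annotation$cell[annotation$population == population]
  if (length(cells) == 0L) {
    stop(new_intercom_error(sprintf("unknown population: %s", population),
                            "intercom_key_error"))
  }
  sub <- counts[cells, , drop = FALSE]
  expressed <- sub >= 1
  n_expressing <- Matrix::colSums(expressed)
  total_expressing <- Matrix::colSums(sub * expressed)
  n_cells <- length(cells)
  frac <- n_expressing / n_cells
  prof <- data.frame(
    gene = colnames(sub),
    n_cells = n_cells,
    n_expressing = as.integer(n_expressing),
    expressed_fraction = frac,
    mean_expressing = ifelse(n_expressing > 0, total_expressing / n_expressing, 0),
    binary_state = ifelse(n_expressing >= 1, 1L, -1L),
    consensus_state = ifelse(frac >= 0.5, 1L, -1L),
    stringsAsFactors = FALSE
  )
  rownames(prof) <- prof$gene
  structure(prof, population = population, n_cells = n_cells,
            class = c("population_profile", "data.frame"))
}

#' Split a matrix into per-population submatrices
#'
#' Cells without an annotation are dropped with a warning; the returned
#' submatrices partition the annotated cells.
#'
#' @inheritParams profile_population
#' @return named list of cells x genes matrices, one per population.
#' @export
split_populations <- function(counts, annotation) {
  unannotated <- setdiff(rownames(counts), annotation$cell)
  if (length(unannotated)) {
    warning(sprintf("%d unannotated cell(s) dropped", length(unannotated)),
            call. = FALSE)
  }
  pops <- sort(unique(annotation$population))
  out <- lapply(pops, function(p) {
    counts[annotation$cell[annotation$population == p], , drop = FALSE]
  })
  names(out) <- pops
  out
}
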