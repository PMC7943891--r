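# Reading count matrices and annotations, and the platform-specific cell
# filters applied before any expression-fraction statistic is computed.

#' Single-cell count matrix
#'
#' A sparse gene-by-cell matrix of raw counts together with its platform
#' tag.  Counts from full-length chemistry (SMART-Seq2-like) are read
#' counts; counts from droplet chemistry are UMIs.  The platform decides
#' the default quality-control thresholds (see [default_qc_thresholds()]).
#'
#' @param counts gene-by-cell matrix of non-negative integers (dense or
#'   any Matrix class; stored as `dgCMatrix`).
#' @param genes character vector of gene symbols (rows); no duplicates.
#' @param cells character vector of cell ids (columns); no duplicates.
#' @param platform `"full_length"` or `"umi"`.
#' @return An object of class `cell_matrix` with fields `genes`, `cells`,
#'   `counts` and `platform`.
#' @export
cell_matrix <- function(counts, genes = rownames(counts),
                        cells = colnames(counts),
                        platform = c("full_length", "umi")) {
  platform <- match.arg(platform)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(cells)) {
    stop("gene and cell identifiers are required")
  }
  genes <- as.character(genes)
  cells <- as.character(cells)
  if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but %d genes and %d cells given",
      nrow(counts), ncol(counts), length(genes), length(cells)))
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  if (anyDuplicated(cells)) {
    stop("duplicate cell ids: ",
         paste(unique(cells[duplicated(cells)]), collapse = ", "))
  }
  bad <- which(counts@x < 0 | counts@x != floor(counts@x))[1]
  if (!is.na(bad)) {
    stop(sprintf("counts must be non-negative integers (offending value %g)",
                 counts@x[bad]))
  }
  dimnames(counts) <- list(genes, cells)
  structure(list(genes = genes, cells = cells, counts = counts,
                 platform = platform),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d genes x %d cells, platform = %s, %d nonzero\n",
              length(x$genes), length(x$cells), x$platform,
              length(x$counts@x)))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Read a single-cell count matrix from disk
#'
#' Supports the MatrixMarket layout written by [write_atlas()] (a directory
#' holding `matrix.mtx`, `genes.tsv` and `barcodes.tsv`, 1-based indices)
#' and a dense CSV with genes as rows and cells as columns.
#'
#' @param path directory (for `format = "mtx"`) or CSV file.
#' @param format `"mtx"` or `"csv"`.
#' @param platform platform tag to attach, `"full_length"` or `"umi"`.
#' @return A [cell_matrix()].
#' @export
read_cell_matrix <- function(path, format = c("mtx", "csv"),
                             platform = c("full_length", "umi")) {
  format <- match.arg(format)
  platform <- match.arg(platform)
  if (format == "mtx") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) {
      if (!file.exists(f)) stop("missing file: ", f)
    }
    counts <- Matrix::readMM(mtx)
    genes <- utils::read.table(gf, sep = "\t", header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- if (file.size(bf) > 0) {
      utils::read.table(bf, sep = "\t", header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    } else {
      character(0)
    }
    cell_matrix(counts, genes = genes, cells = barcodes, platform = platform)
  } else {
    tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    cell_matrix(as.matrix(tab), genes = rownames(tab), cells = colnames(tab),
                platform = platform)
  }
}

#' Read a cell annotation table
#'
#' @param path CSV with columns `cell_id`, `cell_type`, `tissue`,
#'   `age_months`, `platform`.
#' @return A data frame with those columns.
#' @export
read_cell_annotation <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cell_annotation(ann)
}

#' @rdname read_cell_annotation
#' @param ann a candidate annotation data frame.
#' @export
validate_cell_annotation <- function(ann) {
  required <- c("cell_id", "cell_type", "tissue", "age_months", "platform")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(ann$cell_id)) {
    stop("duplicate cell ids in annotation")
  }
  if (any(!nzchar(ann$cell_type) | is.na(ann$cell_type))) {
    stop("empty cell_type entries in annotation")
  }
  ann
}

#' Quality-control thresholds for cell filtering
#'
#' Cells are retained when they reach both a minimum total count and a
#' minimum number of detected genes (raw count >= 1).  The platform
#' defaults encode the filters used for the mouse atlas: full-length cells
#' need at least 5,000 counts and 500 detected genes; droplet (UMI) cells
#' need at least 2,500 UMIs and 500 detected genes.  "Fewer than" the
#' threshold removes the cell, so a cell sitting exactly on the threshold
#' is kept.
#'
#' @param min_counts,min_genes non-negative integers.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_counts, min_genes) {
  if (min_counts < 0 || min_genes < 0) {
    stop("thresholds must be non-negative")
  }
  structure(list(min_counts = as.integer(min_counts),
                 min_genes = as.integer(min_genes)),
            class = "qc_thresholds")
}

#' @rdname qc_thresholds
#' @param platform `"full_length"` or `"umi"`.
#' @export
default_qc_thresholds <- function(platform = c("full_length", "umi")) {
  platform <- match.arg(platform)
  if (platform == "full_length") {
    qc_thresholds(5000L, 500L)
  } else {
    qc_thresholds(2500L, 500L)
  }
}

#' Filter cells by total counts and detected genes
#'
#' Retains exactly the cells with total counts >= `min_counts` AND number
#' of detected genes (count >= 1) >= `min_genes`.  The gene list is left
#' unchanged; an empty result is permitted.
#'
#' @param m a [cell_matrix()].
#' @param thresholds a [qc_thresholds()]; defaults to the platform's
#'   standard cut-offs.
#' @return The filtered [cell_matrix()].
#' @export
filter_cells <- function(m, thresholds = default_qc_thresholds(m$platform)) {
  stopifnot(inherits(m, "cell_matrix"), inherits(thresholds, "qc_thresholds"))
  totals <- Matrix::colSums(m$counts)
  detected <- Matrix::colSums(m$counts >= 1)
  keep <- totals >= thresholds$min_counts & detected >= thresholds$min_genes
  cell_matrix(m$counts[, keep, drop = FALSE], genes = m$genes,
              cells = m$cells[keep], platform = m$platform)
}

#' Select cell types by post-QC abundance
#'
#' Returns the cell types whose cell count in the (already filtered)
#' matrix reaches `min_cells`, sorted by descending count and then
#' lexicographically.  The source wording for the abundance rule is
#' ambiguous between "20 or more" and "more than 20" cells; `strict`
#' exposes both readings rather than silently guessing (default:
#' inclusive, >= `min_cells`).
#'
#' @param ann annotation data frame covering all cells of `m`.
#' @param m a [cell_matrix()], normally post-QC.
#' @param min_cells abundance threshold (default 20).
#' @param strict if `TRUE`, require strictly more than `min_cells` cells.
#' @return Character vector of selected cell types.
#' @export
select_cell_types <- function(ann, m, min_cells = 20L, strict = FALSE) {
  stopifnot(inherits(m, "cell_matrix"))
  idx <- match(m$cells, ann$cell_id)
  if (anyNA(idx)) {
    stop("cells missing from annotation: ",
         paste(utils::head(m$cells[is.na(idx)], 10), collapse = ", "))
  }
  counts <- table(ann$cell_type[idx])
  keep <- if (strict) counts > min_cells else counts >= min_cells
  counts <- counts[keep]
  nm <- names(counts)
  nm[order(-as.integer(counts), nm)]
}
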