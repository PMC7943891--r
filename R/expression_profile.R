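# The central statistic: the fraction of cells in each cell type that
# express each gene (raw count >= 1), computed on raw counts before any
# normalisation; plus bulk RPM and profile comparisons.

#' Gene-by-cell-type expressing-fraction profile
#'
#' @param fraction gene-by-type matrix of expressing-cell fractions in
#'   `[0, 1]`.
#' @param n_cells named per-type cell counts used as denominators.
#' @return An object of class `type_profile` with fields `genes`,
#'   `cell_types`, `fraction` and `n_cells`.
#' @export
type_profile <- function(fraction, n_cells) {
  fraction <- as.matrix(fraction)
  if (is.null(rownames(fraction)) || is.null(colnames(fraction))) {
    stop("fraction matrix needs gene rownames and cell-type colnames")
  }
  if (!setequal(names(n_cells), colnames(fraction))) {
    stop("n_cells must be named by the profile's cell types")
  }
  n_cells <- n_cells[colnames(fraction)]
  if (any(fraction < 0) || any(fraction > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  structure(list(genes = rownames(fraction),
                 cell_types = colnames(fraction),
                 fraction = fraction, n_cells = n_cells),
            class = "type_profile")
}

#' @export
print.type_profile <- function(x, ...) {
  cat(sprintf("<type_profile> %d genes x %d cell types (n = %s)\n",
              length(x$genes), length(x$cell_types),
              paste(x$n_cells, collapse = ", ")))
  invisible(x)
}

#' Expressing-cell fraction of each gene in each cell type
#'
#' For every requested cell type `t` and gene `g`,
#' `fraction[g, t] = #\{cells of t with count >= 1 for g\} / #\{cells of t\}`.
#' Computed on raw counts; the matrix should already be quality filtered.
#'
#' @param m a post-QC [cell_matrix()].
#' @param ann annotation data frame covering the matrix's cells.
#' @param types cell types to profile (default: all annotated types with
#'   at least one cell in `m`).
#' @return A [type_profile()].
#' @export
expression_fraction <- function(m, ann, types = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  idx <- match(m$cells, ann$cell_id)
  if (anyNA(idx)) {
    stop("cells missing from annotation: ",
         paste(utils::head(m$cells[is.na(idx)], 10), collapse = ", "))
  }
  cell_type <- ann$cell_type[idx]
  if (is.null(types)) {
    types <- sort(unique(cell_type))
  }
  absent <- setdiff(types, cell_type)
  if (length(absent)) {
    stop("requested cell types with no cells in matrix: ",
         paste(absent, collapse = ", "))
  }
  expressed <- m$counts >= 1
  frac <- vapply(types, function(t) {
    cols <- which(cell_type == t)
    Matrix::rowSums(expressed[, cols, drop = FALSE]) / length(cols)
  }, numeric(length(m$genes)))
  frac <- matrix(frac, nrow = length(m$genes),
                 dimnames = list(m$genes, types))
  n_cells <- vapply(types, function(t) sum(cell_type == t), integer(1))
  type_profile(frac, n_cells)
}

#' Rank cell types by a gene's expressing fraction
#'
#' Descending by fraction; ties are broken by descending cell count and
#' then lexicographically by type name, so the ranking is deterministic.
#'
#' @param p a [type_profile()].
#' @param gene gene symbol present in the profile.
#' @param top_n number of types to return (default: all).
#' @return Data frame with columns `cell_type`, `fraction`, `n_cells`.
#' @export
rank_types_by_gene <- function(p, gene, top_n = Inf) {
  stopifnot(inherits(p, "type_profile"))
  if (!gene %in% p$genes) {
    stop(sprintf("gene '%s' not in profile", gene))
  }
  f <- p$fraction[gene, ]
  ord <- order(-f, -as.numeric(p$n_cells), p$cell_types)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(cell_type = p$cell_types[ord], fraction = unname(f[ord]),
             n_cells = as.integer(p$n_cells[ord]), row.names = NULL)
}

#' Bulk RNA-seq count matrix
#'
#' @param counts non-negative gene-by-sample matrix with dimnames.
#' @param rpm optional same-shape reads-per-million matrix.
#' @return An object of class `bulk_matrix`.
#' @export
bulk_matrix <- function(counts, rpm = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts need gene rownames and sample colnames")
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative")
  }
  structure(list(genes = rownames(counts), samples = colnames(counts),
                 counts = counts, rpm = rpm),
            class = "bulk_matrix")
}

#' Reads per million mapped reads
#'
#' `rpm[g, s] = counts[g, s] / total_counts[s] * 1e6`; every column of the
#' result sums to one million over the genes present.
#'
#' @param b a [bulk_matrix()].
#' @return `b` with its `rpm` field filled in.
#' @export
compute_rpm <- function(b) {
  stopifnot(inherits(b, "bulk_matrix"))
  totals <- colSums(b$counts)
  if (any(totals <= 0)) {
    stop("samples with zero total counts: ",
         paste(b$samples[totals <= 0], collapse = ", "))
  }
  b$rpm <- sweep(b$counts, 2, totals, "/") * 1e6
  b
}

#' Correlate a gene's expressing-fraction pattern between two profiles
#'
#' Pearson (default) or Spearman correlation of the gene's fractions over
#' the intersection of cell types, e.g. to compare ages or platforms.
#'
#' @param pA,pB [type_profile()] objects sharing at least 3 cell types.
#' @param gene gene present in both profiles.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `estimate` (the coefficient, `NA` when undefined),
#'   `undefined` (`TRUE` when either vector has zero variance), `method`
#'   and `cell_types` (the pairing used).
#' @export
compare_profiles <- function(pA, pB, gene,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(pA, "type_profile"), inherits(pB, "type_profile"))
  for (p in list(pA, pB)) {
    if (!gene %in% p$genes) stop(sprintf("gene '%s' not in profile", gene))
  }
  shared <- intersect(pA$cell_types, pB$cell_types)
  if (length(shared) < 3) {
    stop("need at least 3 shared cell types, got ", length(shared))
  }
  a <- pA$fraction[gene, shared]
  b <- pB$fraction[gene, shared]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(estimate = NA_real_, undefined = TRUE, method = method,
                cell_types = shared))
  }
  list(estimate = stats::cor(a, b, method = method), undefined = FALSE,
       method = method, cell_types = shared)
}

#' Write / read an expressing-fraction profile as CSV
#'
#' The fractions go to `path` (genes x types) and the per-type cell
#' counts to a companion file `<path>.n_cells.csv`.
#'
#' @param p a [type_profile()].
#' @param path CSV path.
#' @return `path` invisibly, or the re-read [type_profile()].
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "type_profile"))
  utils::write.csv(as.data.frame(p$fraction), path, row.names = TRUE)
  utils::write.csv(
    data.frame(cell_type = p$cell_types,
               n_cells = as.integer(p$n_cells)),
    paste0(path, ".n_cells.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  frac <- as.matrix(utils::read.csv(path, row.names = 1,
                                    check.names = FALSE))
  nc <- utils::read.csv(paste0(path, ".n_cells.csv"))
  type_profile(frac, stats::setNames(nc$n_cells, nc$cell_type))
}
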