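# Discovery of cell subtypes with divergent receptor expression inside
# low-expressing cell types: log-normalisation, variable-gene selection,
# PCA, shared-nearest-neighbour graph clustering, per-cluster expressing
# fractions, the five-fold divergent-pair rule, and Wilcoxon marker
# screening with Bonferroni correction.

#' Selection rule for cell types entering the subtype analysis
#'
#' A cell type qualifies for a receptor gene when at least `min_cells`
#' cells are profiled, more than `min_expressing_cells` cells express the
#' gene, and the expressing fraction is below `max_fraction` (low bulk
#' expression but enough positives to resolve structure).
#' `min_cluster_fold` is the downstream divergent-pair threshold.
#'
#' @param min_cells minimum profiled cells (default 500).
#' @param min_expressing_cells expressing cells must exceed this (default 50).
#' @param max_fraction expressing fraction must be below this (default 0.2).
#' @param min_cluster_fold fold change defining a divergent cluster pair
#'   (default 5).
#' @return An object of class `subtype_selection_rule`.
#' @export
subtype_selection_rule <- function(min_cells = 500L,
                                   min_expressing_cells = 50L,
                                   max_fraction = 0.2,
                                   min_cluster_fold = 5) {
  vals <- c(min_cells, min_expressing_cells, max_fraction, min_cluster_fold)
  if (any(vals <= 0)) stop("all rule fields must be positive")
  structure(list(min_cells = min_cells,
                 min_expressing_cells = min_expressing_cells,
                 max_fraction = max_fraction,
                 min_cluster_fold = min_cluster_fold),
            class = "subtype_selection_rule")
}

#' Cell types eligible for subtype analysis of a gene
#'
#' @param profile a [type_profile()] carrying per-type cell counts.
#' @param gene receptor gene symbol.
#' @param rule a [subtype_selection_rule()].
#' @return Character vector of qualifying cell types (profile order).
#'   The union over several receptor genes implements an
#'   "either-receptor" selection.
#' @export
eligible_cell_types <- function(profile, gene,
                                rule = subtype_selection_rule()) {
  stopifnot(inherits(profile, "type_profile"))
  if (!gene %in% profile$genes) {
    stop(sprintf("gene '%s' not in profile", gene))
  }
  frac <- profile$fraction[gene, ]
  n <- as.numeric(profile$n_cells)
  expressing <- round(frac * n)
  keep <- n >= rule$min_cells &
    expressing > rule$min_expressing_cells &
    frac < rule$max_fraction
  profile$cell_types[keep]
}

#' Log-normalise a count matrix
#'
#' `value[g, c] = ln(1 + count[g, c] * scale_factor / total_counts[c])`,
#' removing depth differences across cells before clustering.
#'
#' @param m a [cell_matrix()] with no zero-total cells.
#' @param scale_factor depth target (default 10,000).
#' @return An object of class `normalized_matrix` with fields `genes`,
#'   `cells`, `values` (sparse) and `scale_factor`.
#' @export
log_normalize <- function(m, scale_factor = 10000) {
  stopifnot(inherits(m, "cell_matrix"))
  totals <- Matrix::colSums(m$counts)
  if (any(totals <= 0)) {
    stop("cells with zero total counts: ",
         paste(utils::head(m$cells[totals <= 0], 10), collapse = ", "))
  }
  values <- m$counts
  values@x <- log1p(values@x / rep.int(totals, diff(values@p)) * scale_factor)
  structure(list(genes = m$genes, cells = m$cells, values = values,
                 scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' Select highly variable genes (mean/variance-plot style)
#'
#' Gene means and variance-to-mean dispersions are computed on the
#' back-transformed (expm1) normalised values and mapped to the log
#' scale, following the convention the default window was calibrated
#' for: the mean statistic is `log1p(mean(expm1(value)))` and the
#' dispersion statistic is `log(variance / mean)`.  Genes are split into
#' `n_bins` equal-count bins of the mean statistic, the dispersion is
#' z-scored within each bin, and genes are retained when their mean
#' statistic lies in `[mean_low, mean_high]` and their dispersion
#' z-score is at least `dispersion_min`.  Constant genes (zero variance)
#' and degenerate bins (all dispersions equal) score 0 and are never
#' selected.
#'
#' @param nm a [normalized_matrix()] with at least 2 cells.
#' @param mean_low,mean_high window for the log-scale mean statistic
#'   (defaults 0.1 and 8).
#' @param dispersion_min dispersion z-score cut-off (default 1).
#' @param n_bins number of equal-count mean bins (default 20).
#' @return Character vector of variable genes (matrix order).
#' @export
select_variable_genes <- function(nm, mean_low = 0.1, mean_high = 8,
                                  dispersion_min = 1, n_bins = 20L) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (length(nm$cells) < 2) stop("need at least 2 cells")
  back <- nm$values
  back@x <- expm1(back@x)
  mu <- Matrix::rowMeans(back)
  # variance on the back-transformed scale, from sparse moments
  ex2 <- Matrix::rowSums(back^2) / length(nm$cells)
  v <- (ex2 - mu^2) * length(nm$cells) / (length(nm$cells) - 1)
  mean_stat <- log1p(mu)
  disp <- ifelse(mu > 0 & v > 0, log(v / mu), 0)
  bins <- cut(rank(mean_stat, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  z <- numeric(length(mu))
  for (b in unique(bins)) {
    in_bin <- bins == b
    s <- stats::sd(disp[in_bin])
    z[in_bin] <- if (is.na(s) || s == 0) 0 else
      (disp[in_bin] - mean(disp[in_bin])) / s
  }
  z[mu == 0 | v == 0] <- 0
  keep <- mean_stat >= mean_low & mean_stat <= mean_high &
    z >= dispersion_min
  nm$genes[keep]
}

#' Embed cells with PCA and cluster on a shared-nearest-neighbour graph
#'
#' Variable genes are centred and scaled (scaled values capped at
#' `scale_cap`), cells are embedded into the first `n_pcs` principal
#' components, a shared-nearest-neighbour graph is built from the
#' `k_neighbors` nearest cells (Euclidean in PC space, self included)
#' with Jaccard edge weights pruned below `snn_prune`, and communities
#' are found by modularity (Louvain) optimisation at the given
#' `resolution`.  Clusters are relabelled 0, 1, ... by decreasing size.
#' The whole step is deterministic given `seed`.
#'
#' @param nm a [normalized_matrix()].
#' @param variable_genes genes to embed on (at least `n_pcs` of them).
#' @param n_pcs number of principal components (default 15).
#' @param resolution modularity resolution (default 0.5).
#' @param seed integer seed for the community search.
#' @param k_neighbors neighbourhood size (default 20; reduced with a
#'   warning when there are fewer cells).
#' @param scale_cap cap for scaled expression values (default 10).
#' @param snn_prune Jaccard weights below this are dropped (default 1/15).
#' @return An object of class `cluster_assignment` with fields `cells`,
#'   `cluster_id` (0-based, named by cell), `resolution`, `n_clusters`
#'   and `embedding` (the PC scores).
#' @export
embed_and_cluster <- function(nm, variable_genes, n_pcs = 15L,
                              resolution = 0.5, seed = 0L,
                              k_neighbors = 20L, scale_cap = 10,
                              snn_prune = 1 / 15) {
  stopifnot(inherits(nm, "normalized_matrix"))
  variable_genes <- intersect(variable_genes, nm$genes)
  if (length(variable_genes) < n_pcs) {
    stop(sprintf("need at least n_pcs = %d variable genes, got %d",
                 n_pcs, length(variable_genes)))
  }
  n <- length(nm$cells)
  x <- as.matrix(nm$values[variable_genes, , drop = FALSE])
  xs <- t(scale(t(x)))
  xs[is.na(xs)] <- 0
  xs[xs > scale_cap] <- scale_cap
  pc <- stats::prcomp(t(xs), center = FALSE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$x))
  emb <- pc$x[, seq_len(n_pcs), drop = FALSE]
  if (k_neighbors > n) {
    warning(sprintf("k reduced from %d to %d (only %d cells)",
                    k_neighbors, n - 1L, n))
    k_neighbors <- n - 1L
  }
  d <- as.matrix(stats::dist(emb))
  nn <- apply(d, 1L, function(row) order(row)[seq_len(k_neighbors)])
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(nn), x = 1, dims = c(n, n))
  C <- methods::as(methods::as(Matrix::tcrossprod(A), "generalMatrix"),
                   "CsparseMatrix")
  C@x <- C@x / (2 * k_neighbors - C@x)  # Jaccard: |I| / (|A| + |B| - |I|)
  C@x[C@x < snn_prune] <- 0
  Matrix::diag(C) <- 0
  C <- Matrix::drop0(C)
  g <- igraph::graph_from_adjacency_matrix(C, mode = "undirected",
                                           weighted = TRUE)
  .set_seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- as.integer(igraph::membership(comm))
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cluster_id <- relabel[as.character(memb)]
  names(cluster_id) <- nm$cells
  rownames(emb) <- nm$cells
  structure(list(cells = nm$cells, cluster_id = cluster_id,
                 resolution = resolution,
                 n_clusters = length(sizes), embedding = emb),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells in %d clusters (resolution %g)\n",
              length(x$cells), x$n_clusters, x$resolution))
  print(table(cluster = x$cluster_id))
  invisible(x)
}

#' Expressing fraction of a gene per cell cluster
#'
#' @param m the [cell_matrix()] the clusters were derived from.
#' @param ca a [cluster_assignment()] over (a subset of) its cells.
#' @param gene gene symbol.
#' @return Named numeric vector of expressing fractions, one per cluster
#'   id.
#' @export
cluster_fractions <- function(m, ca, gene) {
  stopifnot(inherits(m, "cell_matrix"), inherits(ca, "cluster_assignment"))
  if (!gene %in% m$genes) stop(sprintf("gene '%s' not in matrix", gene))
  if (!all(ca$cells %in% m$cells)) {
    stop("cluster assignment covers cells absent from the matrix")
  }
  expressed <- as.vector(m$counts[gene, ca$cells] >= 1)
  tapply(expressed, ca$cluster_id, mean)
}

#' Pick the cluster pair with the largest fold change in expressing
#' fraction
#'
#' Considers all cluster pairs; the fold change is `high / low`.  Pairs
#' whose low fraction is zero (and high fraction positive) count as
#' infinite fold and rank above every finite fold, tie-broken by the
#' larger numerator.  Returns the maximising pair when its fold exceeds
#' `min_fold` ("more than a five-fold change"), otherwise `NULL`.
#'
#' @param fractions named per-cluster fractions from
#'   [cluster_fractions()].
#' @param min_fold threshold the best fold must exceed (default 5).
#' @return `NULL`, or a list with `cluster_hi`, `cluster_lo`, `fold`
#'   (possibly `Inf`) and `fractions`.
#' @export
select_divergent_pair <- function(fractions, min_fold = 5) {
  if (length(fractions) < 2) {
    return(NULL)
  }
  ids <- names(fractions)
  best <- NULL
  for (a in seq_along(fractions)) {
    for (b in seq_along(fractions)) {
      if (a == b) next
      hi <- fractions[a]
      lo <- fractions[b]
      if (hi <= lo || hi == 0) next
      fold <- if (lo == 0) Inf else hi / lo
      if (fold <= min_fold) next
      cand <- list(cluster_hi = ids[a], cluster_lo = ids[b], fold = fold,
                   numerator = unname(hi))
      if (is.null(best) ||
          fold > best$fold ||
          (is.infinite(fold) && is.infinite(best$fold) &&
           cand$numerator > best$numerator)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(NULL)
  }
  list(cluster_hi = best$cluster_hi, cluster_lo = best$cluster_lo,
       fold = unname(best$fold), fractions = fractions)
}

# The exact retention rule for marker records; split out so the
# boundaries are testable in isolation.
.marker_passes <- function(log2_fold_change, pct_in, pct_out, p_adjusted,
                           fold_min = 2, pct_min = 0.2, p_adj_max = 0.05) {
  abs(log2_fold_change) >= log2(fold_min) &
    pmax(pct_in, pct_out) >= pct_min &
    p_adjusted <= p_adj_max
}

#' Marker genes per cluster (Wilcoxon rank-sum screen)
#'
#' Each cluster is compared against all other cells with a two-sided
#' Wilcoxon rank-sum test on the normalised values (normal approximation
#' with continuity and tie correction).  Fold change is the ratio of
#' back-transformed mean expressions with a pseudocount of 1.  P-values
#' are Bonferroni-corrected by the total number of genes in the matrix,
#' and only records with at least a two-fold change, a detectable
#' percentage of at least `pct_min` in one of the two groups, and
#' adjusted p <= `p_adj_max` are retained.  Clusters with fewer than 3
#' cells are skipped with a warning.
#'
#' @param nm a [normalized_matrix()].
#' @param ca a [cluster_assignment()] over its cells.
#' @param fold_min minimum fold change (default 2).
#' @param pct_min minimum detectable percentage (default 0.2).
#' @param p_adj_max adjusted p-value cut-off (default 0.05).
#' @return Data frame of marker records: `cluster_id`, `gene`,
#'   `log2_fold_change`, `pct_in`, `pct_out`, `p_raw`, `p_adjusted`.
#' @export
find_markers <- function(nm, ca, fold_min = 2, pct_min = 0.2,
                         p_adj_max = 0.05) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(ca, "cluster_assignment"))
  values <- nm$values[, ca$cells, drop = FALSE]
  n_genes_total <- length(nm$genes)
  back <- values
  back@x <- expm1(back@x)
  out <- list()
  for (cl in sort(unique(ca$cluster_id))) {
    in_cl <- ca$cluster_id == cl
    if (sum(in_cl) < 3) {
      warning(sprintf("cluster %s has fewer than 3 cells; skipped", cl))
      next
    }
    pct_in <- Matrix::rowMeans(values[, in_cl, drop = FALSE] > 0)
    pct_out <- Matrix::rowMeans(values[, !in_cl, drop = FALSE] > 0)
    mean_in <- Matrix::rowMeans(back[, in_cl, drop = FALSE])
    mean_out <- Matrix::rowMeans(back[, !in_cl, drop = FALSE])
    l2fc <- log2((mean_in + 1) / (mean_out + 1))
    # only genes that could survive the filters are worth testing
    candidate <- which(pmax(pct_in, pct_out) >= pct_min &
                         abs(l2fc) >= log2(fold_min))
    if (!length(candidate)) next
    dense <- as.matrix(values[candidate, , drop = FALSE])
    p_raw <- vapply(seq_along(candidate), function(r) {
      stats::wilcox.test(dense[r, in_cl], dense[r, !in_cl],
                         exact = FALSE, correct = TRUE)$p.value
    }, numeric(1))
    p_adj <- pmin(1, p_raw * n_genes_total)
    rec <- data.frame(
      cluster_id = as.integer(cl), gene = nm$genes[candidate],
      log2_fold_change = l2fc[candidate],
      pct_in = pct_in[candidate], pct_out = pct_out[candidate],
      p_raw = p_raw, p_adjusted = p_adj, stringsAsFactors = FALSE)
    rec <- rec[.marker_passes(rec$log2_fold_change, rec$pct_in,
                              rec$pct_out, rec$p_adjusted,
                              fold_min, pct_min, p_adj_max), ,
               drop = FALSE]
    out[[length(out) + 1L]] <- rec
  }
  if (!length(out)) {
    return(data.frame(cluster_id = integer(0), gene = character(0),
                      log2_fold_change = numeric(0), pct_in = numeric(0),
                      pct_out = numeric(0), p_raw = numeric(0),
                      p_adjusted = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sequencing depth of the cells in two clusters
#'
#' Reports the per-cell total counts for each of the two clusters and
#' their medians; no test is applied (depth comparability is judged by
#' inspection).
#'
#' @param m the [cell_matrix()].
#' @param ca a [cluster_assignment()].
#' @param clusters length-2 vector of cluster ids.
#' @return List with `depths` (two named vectors of totals) and
#'   `medians`.
#' @export
cluster_depths <- function(m, ca, clusters) {
  stopifnot(inherits(m, "cell_matrix"), inherits(ca, "cluster_assignment"))
  clusters <- as.character(clusters)
  if (length(clusters) != 2) stop("clusters must name exactly two clusters")
  present <- as.character(unique(ca$cluster_id))
  missing <- setdiff(clusters, present)
  if (length(missing)) {
    stop("clusters not in assignment: ", paste(missing, collapse = ", "))
  }
  cells_in <- lapply(clusters, function(cl) {
    cells <- ca$cells[as.character(ca$cluster_id) == cl]
    cells <- intersect(cells, m$cells)
    if (!length(cells)) {
      stop(sprintf("cluster %s has no cells in the matrix", cl))
    }
    cells
  })
  depths <- lapply(cells_in, function(cells) {
    Matrix::colSums(m$counts[, cells, drop = FALSE])
  })
  names(depths) <- clusters
  list(depths = depths, medians = vapply(depths, stats::median, numeric(1)))
}

#' Run the full subtype-discovery chain for one cell type and gene
#'
#' Convenience wrapper: subset the matrix to the cell type, log-normalise,
#' select variable genes, embed and cluster, compute per-cluster
#' expressing fractions for the receptor gene, pick the divergent cluster
#' pair, and (optionally) screen for markers.
#'
#' @param m a post-QC [cell_matrix()].
#' @param ann annotation covering its cells.
#' @param cell_type the parent cell type to analyse.
#' @param gene receptor gene of interest.
#' @param n_pcs,resolution,seed,k_neighbors passed to
#'   [embed_and_cluster()].
#' @param min_fold divergent-pair threshold (default 5).
#' @param markers whether to run the marker screen (default `TRUE`).
#' @return List with `normalized`, `variable_genes`, `clusters`,
#'   `fractions`, `divergent_pair` (or `NULL`) and `markers`.
#' @export
run_subtype_analysis <- function(m, ann, cell_type, gene, n_pcs = 15L,
                                 resolution = 0.5, seed = 0L,
                                 k_neighbors = 20L, min_fold = 5,
                                 markers = TRUE) {
  stopifnot(inherits(m, "cell_matrix"))
  keep <- m$cells %in% ann$cell_id[ann$cell_type == cell_type]
  if (!any(keep)) stop(sprintf("no cells of type '%s'", cell_type))
  sub <- cell_matrix(m$counts[, keep, drop = FALSE], genes = m$genes,
                     cells = m$cells[keep], platform = m$platform)
  nm <- log_normalize(sub)
  hvg <- select_variable_genes(nm)
  ca <- embed_and_cluster(nm, hvg, n_pcs = n_pcs, resolution = resolution,
                          seed = seed, k_neighbors = k_neighbors)
  fr <- cluster_fractions(sub, ca, gene)
  pair <- select_divergent_pair(fr, min_fold = min_fold)
  mk <- if (markers) find_markers(nm, ca) else NULL
  list(normalized = nm, variable_genes = hvg, clusters = ca,
       fractions = fr, divergent_pair = pair, markers = mk)
}
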