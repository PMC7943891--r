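# Decomposing bulk-tissue DEG lists into cell-type-specific groups:
# look up each gene's expressing-fraction profile over a fixed cell-type
# microenvironment, cluster the genes by Ward.D2 on Euclidean distances,
# cut the tree, and test each group against gene-set collections with
# the hypergeometric upper tail.

#' A tissue microenvironment: an ordered set of cell types
#'
#' @param name label for the environment.
#' @param cell_types ordered character vector of at least two cell types.
#' @return An object of class `microenvironment`.
#' @export
microenvironment <- function(name, cell_types) {
  cell_types <- as.character(cell_types)
  if (length(cell_types) < 2) {
    stop("a microenvironment needs at least 2 cell types")
  }
  if (anyDuplicated(cell_types)) stop("duplicate cell types")
  structure(list(name = name, cell_types = cell_types),
            class = "microenvironment")
}

#' The ten-cell-type liver microenvironment
#'
#' The canonical liver panel: immune types, hepatocytes, sinusoidal
#' endothelium, fibroblasts, and pancreatic stellate cells standing in
#' for hepatic stellate cells (which are absent from the source atlas but
#' functionally close).
#'
#' @return A [microenvironment()] of ten liver-resident cell types.
#' @export
liver_microenvironment <- function() {
  microenvironment("liver", c(
    "natural killer cell", "B cell", "T cell", "neutrophil",
    "macrophage", "Kupffer cell", "hepatocyte",
    "endothelial cell of hepatic sinusoid", "fibroblast",
    "pancreatic stellate cell"))
}

#' Load a microenvironment from YAML
#'
#' @param path YAML file with fields `name` and `cell_types` (ordered
#'   list).
#' @return A [microenvironment()].
#' @export
microenvironment_from_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  microenvironment(spec$name, unlist(spec$cell_types))
}

#' Expression-fraction rows of a gene list over a microenvironment
#'
#' Rows are the input genes found in the profile, columns follow the
#' environment's type order.  Genes absent from the profile are dropped
#' and reported via the `"dropped"` attribute; losing more than half the
#' list is an error unless `allow_sparse = TRUE`.
#'
#' @param profile a [type_profile()] containing the environment's types.
#' @param env a [microenvironment()].
#' @param genes character vector of DEG symbols.
#' @param allow_sparse tolerate > 50% of the list missing.
#' @return Numeric matrix (genes x environment types) with attribute
#'   `dropped`.
#' @export
microenvironment_profile <- function(profile, env, genes,
                                     allow_sparse = FALSE) {
  stopifnot(inherits(profile, "type_profile"),
            inherits(env, "microenvironment"))
  missing_types <- setdiff(env$cell_types, profile$cell_types)
  if (length(missing_types)) {
    stop("environment types absent from profile: ",
         paste(missing_types, collapse = ", "))
  }
  genes <- unique(as.character(genes))
  found <- genes[genes %in% profile$genes]
  dropped <- setdiff(genes, found)
  if (length(dropped) > length(genes) / 2 && !allow_sparse) {
    stop(sprintf(
      "%d of %d input genes missing from profile (pass allow_sparse to continue)",
      length(dropped), length(genes)))
  }
  mat <- profile$fraction[found, env$cell_types, drop = FALSE]
  attr(mat, "dropped") <- dropped
  mat
}

#' Ward.D2 hierarchical clustering of gene profiles cut into k groups
#'
#' Agglomerates rows with Euclidean distances under the Ward.D2 linkage
#' (the Lance-Williams update applied to the distances themselves, not
#' their squares, so merge heights equal the square root of twice the
#' within-cluster variance increase).  The tree is cut into `k` groups
#' and group ids are renumbered 1..k by first appearance in the
#' dendrogram leaf order, which matches how groups read off a sorted
#' heatmap.
#'
#' @param mat numeric matrix with gene rownames (duplicate rows allowed).
#' @param k number of groups, `1 <= k <= nrow(mat)`.
#' @return An object of class `gene_grouping`: `genes` (in leaf order),
#'   `group_id` (named integer vector over all genes), `tree` (the
#'   `hclust` object), `heights`, and `k`.
#' @export
ward_d2_cluster <- function(mat, k) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("matrix needs gene rownames")
  if (k < 1 || k > nrow(mat)) {
    stop(sprintf("k must be in 1..%d, got %g", nrow(mat), k))
  }
  if (nrow(mat) == 1) {
    return(structure(list(genes = rownames(mat),
                          group_id = stats::setNames(1L, rownames(mat)),
                          tree = NULL, heights = numeric(0), k = 1L),
                     class = "gene_grouping"))
  }
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  leaf_genes <- hc$labels[hc$order]
  first_seen <- unique(raw[leaf_genes])
  relabel <- stats::setNames(seq_along(first_seen), first_seen)
  group_id <- stats::setNames(as.integer(relabel[as.character(raw)]),
                              names(raw))
  structure(list(genes = leaf_genes, group_id = group_id, tree = hc,
                 heights = hc$height, k = as.integer(k)),
            class = "gene_grouping")
}

#' @export
print.gene_grouping <- function(x, ...) {
  cat(sprintf("<gene_grouping> %d genes in %d groups\n",
              length(x$genes), x$k))
  print(table(group = x$group_id))
  invisible(x)
}

#' Heatmap-ready table for a grouping
#'
#' @param grouping a [gene_grouping()].
#' @param mat the matrix it was built from.
#' @return Data frame with `gene`, `group`, `leaf_order` and one column
#'   per cell type, rows sorted by leaf order.
#' @export
grouping_table <- function(grouping, mat) {
  genes <- grouping$genes
  data.frame(gene = genes,
             group = unname(grouping$group_id[genes]),
             leaf_order = seq_along(genes),
             as.data.frame(mat[genes, , drop = FALSE],
                           check.names = FALSE),
             row.names = NULL, check.names = FALSE)
}

#' Decompose up- and down-regulated DEG lists onto a microenvironment
#'
#' Runs [microenvironment_profile()] and [ward_d2_cluster()] on each list
#' and emits the genes sorted by grouping with their fraction rows, ready
#' for heatmap display.
#'
#' @param up,down character vectors of DEG symbols.
#' @param profile a [type_profile()].
#' @param env a [microenvironment()].
#' @param k_up,k_down tree-cut group counts (defaults 7 and 2, matching
#'   the long-term liver analysis for the up list; pick per dataset).
#' @param allow_sparse passed through to [microenvironment_profile()].
#' @return List with `up`, `down` (each: `grouping`, `matrix`, `table`,
#'   `dropped`).
#' @export
decompose_degs <- function(up, down, profile, env, k_up = 7L, k_down = 4L,
                           allow_sparse = FALSE) {
  one <- function(genes, k) {
    mat <- microenvironment_profile(profile, env, genes,
                                    allow_sparse = allow_sparse)
    if (nrow(mat) == 0) stop("no input genes found in profile")
    grouping <- ward_d2_cluster(mat, k = min(k, nrow(mat)))
    list(grouping = grouping, matrix = mat,
         table = grouping_table(grouping, mat),
         dropped = attr(mat, "dropped"))
  }
  list(up = one(up, k_up), down = one(down, k_down))
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (one set per line: name, description, genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric enrichment of gene groups against gene sets
#'
#' For each (group, set) pair the overlap is tested with the same
#' upper-tail hypergeometric statistic used for co-expression
#' ([hypergeom_coexpression_p()]), with the population being the gene
#' universe, successes the set's genes in the universe, and draws the
#' group.  P-values are Bonferroni-corrected across sets within each
#' group; records with adjusted p < 0.05 are flagged significant.
#'
#' @param grouping a [gene_grouping()].
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector containing every group gene.
#' @return Data frame of records: `group_id`, `gene_set_name`, `overlap`,
#'   `set_size`, `group_size`, `universe_size`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
enrich_groups <- function(grouping, gene_sets, universe) {
  stopifnot(inherits(grouping, "gene_grouping"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty gene universe")
  if (!length(gene_sets)) stop("empty gene-set collection")
  outside <- setdiff(names(grouping$group_id), universe)
  if (length(outside)) {
    stop("group genes outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "))
  }
  n <- length(universe)
  rows <- list()
  for (grp in sort(unique(grouping$group_id))) {
    grp_genes <- names(grouping$group_id)[grouping$group_id == grp]
    for (set_name in names(gene_sets)) {
      set_genes <- intersect(gene_sets[[set_name]], universe)
      m <- length(set_genes)
      k <- length(grp_genes)
      x <- length(intersect(set_genes, grp_genes))
      p <- if (m == 0) 1 else hypergeom_coexpression_p(n, m, k, x)
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = grp, gene_set_name = set_name, overlap = x,
        set_size = m, group_size = k, universe_size = n, p_raw = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (grp in unique(out$group_id)) {
    sel <- out$group_id == grp
    out$p_adjusted[sel] <- pmin(1, out$p_raw[sel] * sum(sel))
  }
  out$significant <- out$p_adjusted < 0.05
  rownames(out) <- NULL
  out
}
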