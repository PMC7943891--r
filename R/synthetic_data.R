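# Synthetic single-cell atlases and bulk experiments with known ground
# truth.  Detection (count >= 1) is modelled separately from depth: a gene
# is detected in a cell with a planted per-type probability, and detected
# entries receive 1 + negative-binomial extra counts.  This decouples the
# expressing-cell fraction -- the statistic every downstream stage
# consumes -- from sequencing depth.

# Library-depth scale by platform; droplet libraries are shallower but the
# detection model is identical (platforms differ in depth/sensitivity, not
# chemistry).
.platform_depth_scale <- c(full_length = 1, umi = 0.4)

#' Configuration of a synthetic single-cell atlas
#'
#' @param n_genes number of genes in the universe.
#' @param cell_types named integer vector: cells per cell type.
#' @param detection_prob gene-by-type matrix of detection probabilities in
#'   `[0, 1]`; rownames (if present) become gene symbols.
#' @param mean_count mean raw count of a detected gene-cell pair (scalar or
#'   per gene, >= 1); scaled by platform depth.
#' @param dispersion negative-binomial shape of counts given detection.
#' @param subtype_spec optional planted subtype structure inside one parent
#'   type: `list(parent =, proportions = c(p1, p2), markers = list(chr,
#'   chr), detection_override = list(named numeric, named numeric))`.  The
#'   overrides replace the parent's detection probability for the named
#'   genes in cells of each subtype.
#' @param dependence_spec optional list of planted pairwise dependences,
#'   each `list(gene_a =, gene_b =, type =, joint =)` giving the joint
#'   detection probability of the pair in that type (a bivariate Bernoulli
#'   with the type's marginals).
#' @param platform `"full_length"` or `"umi"`.
#' @param seed integer global seed; every cell type is drawn from its own
#'   substream derived from it (see [substream_seed()]).
#' @param genes optional explicit gene symbols.
#' @return A validated object of class `atlas_config`.
#' @export
atlas_config <- function(n_genes, cell_types, detection_prob,
                         mean_count = 3, dispersion = 1,
                         subtype_spec = NULL, dependence_spec = NULL,
                         platform = c("full_length", "umi"), seed = 1L,
                         genes = NULL) {
  platform <- match.arg(platform)
  if (is.null(genes)) {
    genes <- rownames(detection_prob)
  }
  if (is.null(genes)) {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
  }
  cfg <- structure(list(
    n_genes = as.integer(n_genes), genes = as.character(genes),
    cell_types = cell_types, detection_prob = as.matrix(detection_prob),
    mean_count = mean_count, dispersion = dispersion,
    subtype_spec = subtype_spec, dependence_spec = dependence_spec,
    platform = platform, seed = as.integer(seed)), class = "atlas_config")
  validate_atlas_config(cfg)
}

#' @rdname atlas_config
#' @param config candidate configuration.
#' @export
validate_atlas_config <- function(config) {
  c0 <- .config_stop
  if (length(config$n_genes) != 1L || is.na(config$n_genes) ||
      config$n_genes < 1L) {
    c0("n_genes", "must be a positive integer")
  }
  ct <- config$cell_types
  if (is.null(names(ct)) || any(!nzchar(names(ct))) ||
      anyDuplicated(names(ct))) {
    c0("cell_types", "must be a uniquely named vector of cell counts")
  }
  if (any(ct < 1) || any(ct != floor(ct))) {
    c0("cell_types", "cell counts must be positive integers")
  }
  if (length(config$genes) != config$n_genes ||
      anyDuplicated(config$genes)) {
    c0("genes", "must be n_genes unique symbols")
  }
  dp <- config$detection_prob
  if (!is.matrix(dp) || nrow(dp) != config$n_genes ||
      ncol(dp) != length(ct)) {
    c0("detection_prob", "must be an n_genes x n_types matrix")
  }
  if (any(is.na(dp)) || any(dp < 0) || any(dp > 1)) {
    c0("detection_prob", "probabilities must lie in [0, 1]")
  }
  if (any(config$mean_count < 1)) {
    c0("mean_count", "mean count given detection must be >= 1")
  }
  if (!length(config$mean_count) %in% c(1L, config$n_genes)) {
    c0("mean_count", "must be scalar or one value per gene")
  }
  if (config$dispersion <= 0) {
    c0("dispersion", "must be positive")
  }
  ss <- config$subtype_spec
  if (!is.null(ss)) {
    if (!ss$parent %in% names(ct)) {
      c0("subtype_spec", sprintf("parent '%s' is not a cell type", ss$parent))
    }
    if (length(ss$proportions) != 2L ||
        abs(sum(ss$proportions) - 1) > 1e-8 || any(ss$proportions <= 0)) {
      c0("subtype_spec", "proportions must be two positives summing to 1")
    }
    planted <- unique(c(unlist(ss$markers),
                        unlist(lapply(ss$detection_override, names))))
    missing <- setdiff(planted, config$genes)
    if (length(missing)) {
      c0("subtype_spec", paste("genes not in gene universe:",
                               paste(missing, collapse = ", ")))
    }
    for (ov in ss$detection_override) {
      if (length(ov) && (any(ov < 0) || any(ov > 1))) {
        c0("subtype_spec", "detection_override probabilities must be in [0, 1]")
      }
    }
  }
  for (dep in config$dependence_spec) {
    for (g in c(dep$gene_a, dep$gene_b)) {
      if (!g %in% config$genes) {
        c0("dependence_spec", sprintf("gene '%s' not in gene universe", g))
      }
    }
    if (!dep$type %in% names(ct)) {
      c0("dependence_spec", sprintf("type '%s' is not a cell type", dep$type))
    }
    rownames(dp) <- config$genes
    pa <- dp[dep$gene_a, dep$type]
    pb <- dp[dep$gene_b, dep$type]
    if (dep$joint > min(pa, pb) + 1e-12) {
      c0("dependence_spec", "joint probability exceeds a marginal")
    }
    if (pa + pb - dep$joint > 1 + 1e-12) {
      c0("dependence_spec", "implied cell probabilities exceed 1")
    }
  }
  config
}

# Per-cell detection probability matrix for one type, with subtype
# overrides applied; also returns the subtype label per cell.
.type_detection_matrix <- function(config, type, n_c) {
  genes <- config$genes
  dp <- config$detection_prob
  rownames(dp) <- genes
  P <- matrix(dp[, type], nrow = config$n_genes, ncol = n_c,
              dimnames = list(genes, NULL))
  subtype <- NULL
  ss <- config$subtype_spec
  if (!is.null(ss) && identical(ss$parent, type)) {
    n1 <- round(ss$proportions[1] * n_c)
    subtype <- rep(c(1L, 2L), c(n1, n_c - n1))
    for (s in 1:2) {
      ov <- ss$detection_override[[s]]
      if (length(ov)) {
        P[names(ov), subtype == s] <- rep(ov, sum(subtype == s))
      }
    }
  }
  list(P = P, subtype = subtype)
}

#' Generate a synthetic single-cell atlas
#'
#' Cells of each type are drawn from a dedicated substream in this order:
#' (1) per-cell detection indicators `u < P` from a single
#' `runif(n_genes * n_cells)` matrix (genes vary fastest); (2) for each
#' planted dependence in the type, one `runif(n_cells)` vector re-draws
#' the pair's indicators from the bivariate Bernoulli; (3) detected
#' entries receive `1 + rnbinom(mu = depth * mean_count - 1, size =
#' dispersion)` counts in column-major order.  Identical seeds therefore
#' give bit-identical atlases, and the documented order lets tests
#' re-simulate any stage independently.
#'
#' @param config an [atlas_config()].
#' @return A list with elements `matrix` (a [cell_matrix()]),
#'   `annotation` (cell metadata data frame) and `truth` (all planted
#'   parameters, including per-cell subtype labels when planted).
#' @export
generate_atlas <- function(config) {
  config <- validate_atlas_config(config)
  genes <- config$genes
  G <- config$n_genes
  scale <- .platform_depth_scale[[config$platform]]
  mu_extra <- pmax(config$mean_count * scale - 1, 0)
  if (length(mu_extra) == 1L) mu_extra <- rep(mu_extra, G)
  dp <- config$detection_prob
  rownames(dp) <- genes

  blocks <- list()
  cells_all <- character(0)
  types_all <- character(0)
  subtype_truth <- NULL
  for (type in names(config$cell_types)) {
    n_c <- as.integer(config$cell_types[[type]])
    .set_seed(substream_seed(config$seed, paste0("type:", type)))
    td <- .type_detection_matrix(config, type, n_c)
    u <- matrix(stats::runif(G * n_c), nrow = G)
    det <- u < td$P
    for (dep in config$dependence_spec) {
      if (!identical(dep$type, type)) next
      pa <- dp[dep$gene_a, type]
      pb <- dp[dep$gene_b, type]
      v <- stats::runif(n_c)
      det[match(dep$gene_a, genes), ] <- v < pa
      det[match(dep$gene_b, genes), ] <-
        v < dep$joint | (v >= pa & v < pa + pb - dep$joint)
    }
    idx <- which(det)
    gi <- (idx - 1L) %% G + 1L
    extra <- stats::rnbinom(length(idx), size = config$dispersion,
                            mu = mu_extra[gi])
    counts <- Matrix::sparseMatrix(
      i = gi, j = (idx - 1L) %/% G + 1L, x = 1 + extra, dims = c(G, n_c))
    ids <- sprintf("%s_c%04d", gsub("[^A-Za-z0-9]+", "_", type),
                   seq_len(n_c))
    blocks[[type]] <- counts
    cells_all <- c(cells_all, ids)
    types_all <- c(types_all, rep(type, n_c))
    if (!is.null(td$subtype)) {
      subtype_truth <- data.frame(cell_id = ids, parent = type,
                                  subtype = td$subtype)
    }
  }
  counts <- do.call(cbind, blocks)
  m <- cell_matrix(counts, genes = genes, cells = cells_all,
                   platform = config$platform)
  annotation <- data.frame(
    cell_id = cells_all, cell_type = types_all, tissue = "synthetic",
    age_months = 3, platform = config$platform,
    stringsAsFactors = FALSE)
  truth <- list(
    detection_prob = dp, mean_count = config$mean_count,
    dispersion = config$dispersion, platform = config$platform,
    depth_scale = scale, seed = config$seed,
    subtype_spec = config$subtype_spec, subtypes = subtype_truth,
    dependence_spec = config$dependence_spec)
  list(matrix = m, annotation = annotation, truth = truth)
}

#' Write a synthetic atlas to disk
#'
#' Writes `matrix.mtx` (MatrixMarket, 1-based indices), `genes.tsv`,
#' `barcodes.tsv`, `annotation.csv` and `truth.json` into `dir`.
#'
#' @param atlas result of [generate_atlas()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- atlas$matrix
  Matrix::writeMM(m$counts, file.path(dir, "matrix.mtx"))
  writeLines(m$genes, file.path(dir, "genes.tsv"))
  writeLines(m$cells, file.path(dir, "barcodes.tsv"))
  utils::write.csv(atlas$annotation, file.path(dir, "annotation.csv"),
                   row.names = FALSE)
  truth <- atlas$truth
  truth$detection_prob <- NULL  # matrix kept out of the JSON summary
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Configuration of a synthetic bulk treated/control experiment
#'
#' Control sample means are proportional to the mixture of the cell-type
#' expression-fraction profiles weighted by `mixing_weights`; treated
#' samples multiply the planted genes' means by their effect multipliers.
#' Counts are negative-binomial draws.
#'
#' @param profile a [type_profile()] reference (expressing fractions per
#'   cell type).
#' @param mixing_weights named non-negative weights over the profile's
#'   types, summing to 1.
#' @param n_treated,n_control sample counts per arm.
#' @param planted_up,planted_down data frames with columns `gene`,
#'   `multiplier` (> 0) and optionally `target_type`; the lists must be
#'   disjoint and all genes present in the profile.
#' @param library_size expected total counts per sample.
#' @param dispersion negative-binomial shape of the counts.
#' @param seed integer seed (a dedicated substream is derived from it).
#' @return A validated object of class `bulk_config`.
#' @export
bulk_config <- function(profile, mixing_weights, n_treated, n_control,
                        planted_up = NULL, planted_down = NULL,
                        library_size = 1e6, dispersion = 20, seed = 1L) {
  cfg <- structure(list(
    profile = profile, mixing_weights = mixing_weights,
    n_treated = as.integer(n_treated), n_control = as.integer(n_control),
    planted_up = planted_up, planted_down = planted_down,
    library_size = library_size, dispersion = dispersion,
    seed = as.integer(seed)), class = "bulk_config")
  validate_bulk_config(cfg)
}

#' @rdname bulk_config
#' @param config candidate configuration.
#' @export
validate_bulk_config <- function(config) {
  c0 <- .config_stop
  p <- config$profile
  if (!inherits(p, "type_profile")) {
    c0("profile", "must be a type_profile")
  }
  w <- config$mixing_weights
  if (is.null(names(w)) || !all(names(w) %in% p$cell_types)) {
    c0("mixing_weights", "must be named by the profile's cell types")
  }
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    c0("mixing_weights", "must be non-negative and sum to 1")
  }
  for (field in c("planted_up", "planted_down")) {
    pl <- config[[field]]
    if (is.null(pl)) next
    if (!all(c("gene", "multiplier") %in% names(pl))) {
      c0(field, "needs columns gene and multiplier")
    }
    if (any(pl$multiplier <= 0)) {
      c0(field, "effect multipliers must be > 0")
    }
    missing <- setdiff(pl$gene, p$genes)
    if (length(missing)) {
      c0(field, paste("genes absent from reference profile:",
                      paste(missing, collapse = ", ")))
    }
  }
  overlap <- intersect(config$planted_up$gene, config$planted_down$gene)
  if (length(overlap)) {
    c0("planted_up/planted_down",
       paste("lists must be disjoint; shared:", paste(overlap, collapse = ", ")))
  }
  if (config$n_treated < 1 || config$n_control < 1) {
    c0("n_treated/n_control", "need at least one sample per arm")
  }
  if (config$library_size <= 0) c0("library_size", "must be positive")
  if (config$dispersion <= 0) c0("dispersion", "must be positive")
  config
}

#' Generate a synthetic bulk treated/control experiment
#'
#' Samples are drawn column by column (controls first, then treated) from
#' a substream of the configured seed.
#'
#' @param config a [bulk_config()].
#' @return A list with `bulk` (a [bulk_matrix()] tagged with a `condition`
#'   factor) and `truth` (planted gene lists and the exact per-arm mean
#'   vectors).
#' @export
generate_bulk <- function(config) {
  config <- validate_bulk_config(config)
  p <- config$profile
  w <- numeric(length(p$cell_types))
  names(w) <- p$cell_types
  w[names(config$mixing_weights)] <- config$mixing_weights
  mix <- as.vector(p$fraction %*% w)
  if (sum(mix) <= 0) {
    stop("mixture profile is identically zero")
  }
  mu_control <- config$library_size * mix / sum(mix)
  names(mu_control) <- p$genes
  mu_treated <- mu_control
  for (pl in list(config$planted_up, config$planted_down)) {
    if (!is.null(pl)) {
      mu_treated[pl$gene] <- mu_treated[pl$gene] * pl$multiplier
    }
  }
  .set_seed(substream_seed(config$seed, "bulk"))
  n_g <- length(p$genes)
  draw <- function(mu, n, tag) {
    cols <- vapply(seq_len(n), function(j) {
      stats::rnbinom(n_g, size = config$dispersion, mu = mu)
    }, numeric(n_g))
    colnames(cols) <- sprintf("%s_%d", tag, seq_len(n))
    cols
  }
  counts <- cbind(draw(mu_control, config$n_control, "control"),
                  draw(mu_treated, config$n_treated, "treated"))
  rownames(counts) <- p$genes
  bulk <- bulk_matrix(counts)
  bulk$condition <- factor(rep(c("control", "treated"),
                               c(config$n_control, config$n_treated)),
                           levels = c("control", "treated"))
  truth <- list(planted_up = config$planted_up,
                planted_down = config$planted_down,
                mu_control = mu_control, mu_treated = mu_treated,
                seed = config$seed)
  list(bulk = bulk, truth = truth)
}
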