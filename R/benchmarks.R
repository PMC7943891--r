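# Canonical synthetic study conditions used by the analysis scripts and
# the acceptance checks.  These encode, once, the regimes the pipeline is
# meant to operate in: a low-expressing parent type hiding two subtypes
# with a >= 5-fold receptor-fraction gap, an independent/dependent gene
# pair at realistic detection levels, and a liver-like microenvironment
# with cell-type-specific gene programs feeding a treated/control bulk
# experiment.

#' Two-subtype benchmark configuration
#'
#' One parent cell type ("myeloid cell", 800 cells in two equal
#' subtypes) whose receptor gene `Thra` is detected in 20% of subtype-1
#' cells but only 2% of subtype-2 cells -- a ten-fold gap the divergent-
#' pair rule (fold > 5) must flag.  Each subtype carries 30 planted
#' marker genes (detection 0.85 in its own subtype, 0.02 in the other,
#' mean count 8 when detected).  The background is a ladder of 1,000
#' genes whose detection probabilities sweep 0.05-0.95 and whose mean
#' counts follow the usual single-cell detection-expression trend
#' (`mean = 1 + 6 p`), so the bimodal markers sit above the
#' variance-to-mean trend of their mean-expression bin -- the regime the
#' dispersion z-score is designed to flag.
#'
#' @param seed integer seed.
#' @param n_per_subtype cells per subtype (default 400).
#' @param n_markers planted markers per subtype (default 30).
#' @param n_background background genes (default 1000).
#' @return An [atlas_config()].
#' @export
subtype_benchmark_config <- function(seed = 1L, n_per_subtype = 400L,
                                     n_markers = 30L,
                                     n_background = 1000L) {
  mk1 <- sprintf("mkA_%02d", seq_len(n_markers))
  mk2 <- sprintf("mkB_%02d", seq_len(n_markers))
  bg <- sprintf("bg_%04d", seq_len(n_background))
  genes <- c("Thra", mk1, mk2, bg)
  dp <- matrix(0, nrow = length(genes), ncol = 1,
               dimnames = list(genes, "myeloid cell"))
  dp["Thra", ] <- 0.11  # parent-level marginal; subtypes override below
  dp[c(mk1, mk2), ] <- 0.02
  dp[bg, ] <- seq(0.05, 0.95, length.out = n_background)
  mean_count <- stats::setNames(1 + 6 * dp[, 1], genes)
  mean_count[c(mk1, mk2)] <- 8
  mean_count["Thra"] <- 3
  atlas_config(
    n_genes = length(genes),
    cell_types = c("myeloid cell" = 2L * n_per_subtype),
    detection_prob = dp,
    mean_count = unname(mean_count), dispersion = 1,
    subtype_spec = list(
      parent = "myeloid cell",
      proportions = c(0.5, 0.5),
      markers = list(mk1, mk2),
      detection_override = list(
        stats::setNames(c(0.20, rep(0.85, n_markers)), c("Thra", mk1)),
        stats::setNames(c(0.02, rep(0.85, n_markers)), c("Thra", mk2)))),
    platform = "full_length", seed = seed)
}

#' Gene-pair benchmark configuration
#'
#' A single 300-cell type with two genes at detection 0.3 each, either
#' independent (`joint = NULL`, the null of the co-expression test) or
#' with a planted joint detection probability (e.g. 0.25, well above the
#' 0.09 expected under independence).
#'
#' @param seed integer seed.
#' @param n_cells cells in the type (default 300).
#' @param marginal per-gene detection probability (default 0.3).
#' @param joint planted joint probability, or `NULL` for independence.
#' @return An [atlas_config()] over genes `geneA`, `geneB`.
#' @export
pair_benchmark_config <- function(seed = 1L, n_cells = 300L,
                                  marginal = 0.3, joint = NULL) {
  genes <- c("geneA", "geneB")
  dp <- matrix(marginal, nrow = 2, ncol = 1,
               dimnames = list(genes, "test type"))
  dep <- if (is.null(joint)) NULL else
    list(list(gene_a = "geneA", gene_b = "geneB", type = "test type",
              joint = joint))
  atlas_config(n_genes = 2L, cell_types = c("test type" = n_cells),
               detection_prob = dp, mean_count = 2, dispersion = 1,
               dependence_spec = dep, platform = "full_length",
               seed = seed)
}

#' Liver-like microenvironment benchmark
#'
#' A 200-gene atlas over the ten liver cell types of
#' [liver_microenvironment()]: 40 hepatocyte-specific genes (detection
#' 0.8 in hepatocytes, 0.02 elsewhere), 40 immune-specific genes (0.7 in
#' the six immune types, 0.02 elsewhere), 80 broadly expressed genes
#' (0.5 everywhere) and 40 weakly expressed genes (0.05 everywhere),
#' with 60 cells per type.
#'
#' @param seed integer seed.
#' @param cells_per_type cells per cell type (default 60).
#' @return An [atlas_config()].
#' @export
liver_benchmark_config <- function(seed = 1L, cells_per_type = 60L) {
  env <- liver_microenvironment()
  types <- env$cell_types
  immune <- c("natural killer cell", "B cell", "T cell", "neutrophil",
              "macrophage", "Kupffer cell")
  hep <- sprintf("hep_%02d", 1:40)
  imm <- sprintf("imm_%02d", 1:40)
  broad <- sprintf("broad_%02d", 1:80)
  low <- sprintf("low_%02d", 1:40)
  genes <- c(hep, imm, broad, low)
  dp <- matrix(0.02, nrow = length(genes), ncol = length(types),
               dimnames = list(genes, types))
  dp[hep, "hepatocyte"] <- 0.8
  dp[imm, immune] <- 0.7
  dp[broad, ] <- 0.5
  dp[low, ] <- 0.05
  atlas_config(n_genes = length(genes),
               cell_types = stats::setNames(rep(cells_per_type,
                                                length(types)), types),
               detection_prob = dp, mean_count = 3, dispersion = 1,
               platform = "full_length", seed = seed)
}

#' Bulk treated/control benchmark over the liver microenvironment
#'
#' Mixes the reference profile with hepatocyte-dominated weights
#' (hepatocytes 0.55, the rest spread over the other nine types) and
#' plants an up-regulated list (20 hepatocyte-specific plus 10 broad
#' genes, multiplier 6) and a down-regulated list (20 immune-specific
#' plus 10 broad genes, multiplier 0.2), four treated and four control
#' samples.
#'
#' @param profile a [type_profile()] of the liver benchmark atlas.
#' @param seed integer seed.
#' @return A [bulk_config()].
#' @export
liver_bulk_benchmark_config <- function(profile, seed = 1L) {
  weights <- c(
    "hepatocyte" = 0.55, "endothelial cell of hepatic sinusoid" = 0.10,
    "Kupffer cell" = 0.08, "macrophage" = 0.05, "T cell" = 0.05,
    "B cell" = 0.04, "neutrophil" = 0.04, "natural killer cell" = 0.03,
    "fibroblast" = 0.03, "pancreatic stellate cell" = 0.03)
  planted_up <- data.frame(
    gene = c(sprintf("hep_%02d", 1:20), sprintf("broad_%02d", 1:10)),
    multiplier = 6,
    target_type = c(rep("hepatocyte", 20), rep("broad", 10)))
  planted_down <- data.frame(
    gene = c(sprintf("imm_%02d", 1:20), sprintf("broad_%02d", 11:20)),
    multiplier = 0.2,
    target_type = c(rep("immune", 20), rep("broad", 10)))
  bulk_config(profile, weights, n_treated = 4L, n_control = 4L,
              planted_up = planted_up, planted_down = planted_down,
              library_size = 1e6, dispersion = 20, seed = seed)
}
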