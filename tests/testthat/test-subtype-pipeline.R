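test_that("eligibility rule is evaluated exactly", {
  types <- c("too small", "good", "too high", "too few expr")
  frac <- matrix(c(0.1, 0.19, 0.25, 0.05), nrow = 1,
                 dimnames = list("Thra", types))
  p <- type_profile(frac, c("too small" = 499, "good" = 600,
                            "too high" = 600, "too few expr" = 600))
  # 600 * 0.19 = 114 expressing > 50; 600 * 0.05 = 30 expressing <= 50
  expect_identical(eligible_cell_types(p, "Thra"), "good")
  expect_error(eligible_cell_types(p, "Thrb"), "Thrb")

  # boundary: fraction exactly 0.2 is not "less than 0.2"
  p2 <- type_profile(matrix(0.2, 1, 1, dimnames = list("Thra", "t")),
                     c(t = 1000))
  expect_length(eligible_cell_types(p2, "Thra"), 0)
})

test_that("log-normalisation matches elementwise recomputation", {
  # cell with total 10,000 and a count of 1 gives exactly ln(2)
  mat <- rbind(a = c(1, 0), b = c(9999, 5))
  m <- fixture_cell_matrix(mat)
  nm <- log_normalize(m)
  expect_equal(nm$values["a", "c1"], log(2))
  expect_equal(nm$values["a", "c2"], 0)  # zero counts stay zero
  expect_equal(nm$values["b", "c2"], log1p(10000))

  set.seed(4)
  big <- fixture_cell_matrix(matrix(rpois(50 * 20, 2) , 50, 20))
  totals <- colSums(as.matrix(big$counts))
  expect_true(all(totals > 0))
  nmb <- log_normalize(big)
  manual <- log1p(sweep(as.matrix(big$counts), 2, totals, "/") * 10000)
  expect_equal(as.matrix(nmb$values), manual)

  zero_cell <- fixture_cell_matrix(cbind(c1 = c(1, 2), c2 = c(0, 0)))
  expect_error(log_normalize(zero_cell), "c2")
})

test_that("variable-gene selection recovers planted high-dispersion genes", {
  # 2,000 flat genes (count exactly 1 in every cell, hence zero
  # dispersion beyond depth) and 30 planted bursty genes
  n_bg <- 2000L
  planted <- sprintf("hv_%02d", 1:30)
  genes <- c(planted, sprintf("flat_%04d", seq_len(n_bg)))
  dp <- matrix(c(rep(0.3, 30), rep(1, n_bg)), ncol = 1,
               dimnames = list(genes, "t"))
  mean_count <- c(rep(12, 30), rep(1, n_bg))
  cfg <- atlas_config(length(genes), c(t = 400L), dp,
                      mean_count = mean_count, dispersion = 1, seed = 21)
  atl <- generate_atlas(cfg)
  hvg <- select_variable_genes(log_normalize(atl$matrix))
  expect_gte(sum(planted %in% hvg), 30)
  expect_lte(sum(!hvg %in% planted), 5)

  # a constant gene can never be selected
  const <- fixture_cell_matrix(rbind(same = rep(5, 10),
                                     vary = c(1:5, 20, 40, 1, 1, 90)))
  expect_false("same" %in% select_variable_genes(log_normalize(const),
                                                 n_bins = 2))
})

test_that("clustering recovers planted subtypes and is deterministic", {
  atl <- generate_atlas(subtype_benchmark_config(seed = 13))
  nm <- log_normalize(atl$matrix)
  hvg <- select_variable_genes(nm)
  ca1 <- embed_and_cluster(nm, hvg, seed = 1)
  ca2 <- embed_and_cluster(nm, hvg, seed = 1)
  expect_identical(ca1$cluster_id, ca2$cluster_id)

  truth <- atl$truth$subtypes
  ari <- adjusted_rand_index(truth$subtype,
                             ca1$cluster_id[truth$cell_id])
  expect_gte(ari, 0.95)

  # cluster ids are 0..k-1 in decreasing size order
  sizes <- as.integer(table(ca1$cluster_id))
  expect_identical(sort(unique(as.integer(ca1$cluster_id))),
                   seq_along(sizes) - 1L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("agreement with an independent partition score", {
  skip_if_not_installed("mclust")
  set.seed(30)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
})

test_that("a homogeneous population yields at most two clusters", {
  for (s in 1:5) {
    cfg <- subtype_benchmark_config(seed = 100 + s, n_per_subtype = 200L)
    cfg$subtype_spec <- NULL  # strip the planted structure
    atl <- generate_atlas(cfg)
    nm <- log_normalize(atl$matrix)
    hvg <- select_variable_genes(nm)
    ca <- embed_and_cluster(nm, hvg, seed = 1)
    expect_lte(ca$n_clusters, 2)
  }
})

test_that("cluster fractions recover planted values and average exactly", {
  atl <- generate_atlas(subtype_benchmark_config(seed = 17))
  nm <- log_normalize(atl$matrix)
  ca <- embed_and_cluster(nm, select_variable_genes(nm), seed = 1)
  fr <- cluster_fractions(atl$matrix, ca, "Thra")

  # size-weighted mean of cluster fractions equals the parent fraction
  sizes <- table(ca$cluster_id)[names(fr)]
  parent <- sum(fr * as.numeric(sizes)) / sum(sizes)
  whole <- mean(atl$matrix$counts["Thra", ] >= 1)
  expect_equal(parent, whole)

  # planted 0.20 / 0.02 recovered within 3 binomial SE per cluster
  truth <- atl$truth$subtypes
  for (cl in names(fr)) {
    cells <- ca$cells[as.character(ca$cluster_id) == cl]
    sub <- unique(truth$subtype[match(cells, truth$cell_id)])
    expect_length(sub, 1)  # clusters align with planted subtypes here
    p <- c(0.20, 0.02)[sub]
    expect_lt(abs(fr[[cl]] - p), 3 * sqrt(p * (1 - p) / length(cells)))
  }

  none <- cluster_fractions(atl$matrix, ca, "mkA_01")
  expect_true(all(none >= 0))
})

test_that("divergent-pair selection follows the fold ordering rules", {
  pair <- select_divergent_pair(c(`0` = 0.20, `6` = 0.019))
  expect_equal(pair$cluster_hi, "0")
  expect_equal(pair$cluster_lo, "6")
  expect_equal(pair$fold, 0.20 / 0.019)  # ~10.5, above 5

  expect_null(select_divergent_pair(c(`0` = 0.10, `1` = 0.05)))

  # zero-denominator pairs rank above any finite fold
  pair0 <- select_divergent_pair(c(`0` = 0.3, `1` = 0.0, `2` = 0.1))
  expect_equal(pair0$cluster_hi, "0")
  expect_equal(pair0$cluster_lo, "1")
  expect_true(is.infinite(pair0$fold))

  # infinite folds tie-break on the larger numerator
  pair1 <- select_divergent_pair(c(`0` = 0.2, `1` = 0.0, `2` = 0.4))
  expect_equal(pair1$cluster_hi, "2")

  expect_null(select_divergent_pair(c(`0` = 0.5)))
  expect_null(select_divergent_pair(c(`0` = 0, `1` = 0)))
})

test_that("marker screen filters sit exactly on the stated boundaries", {
  passes <- thyrotrace:::.marker_passes
  expect_true(passes(1, 0.5, 0.01, 0.04))
  expect_false(passes(log2(1.99), 0.5, 0.01, 0.04))  # fold below 2
  expect_false(passes(1, 0.19, 0.19, 0.04))          # pct below 0.2
  expect_false(passes(1, 0.5, 0.01, 0.051))          # p_adj above 0.05
  expect_true(passes(-1, 0.01, 0.5, 0.05))           # down-markers count
})

test_that("marker screen finds planted markers and skips null genes", {
  atl <- generate_atlas(subtype_benchmark_config(seed = 19))
  nm <- log_normalize(atl$matrix)
  ca <- embed_and_cluster(nm, select_variable_genes(nm), seed = 1)
  mk <- find_markers(nm, ca)
  planted <- unique(c(sprintf("mkA_%02d", 1:30), sprintf("mkB_%02d", 1:30)))
  expect_gte(sum(planted %in% mk$gene), 0.9 * length(planted))
  # background ladder genes are distributionally identical across
  # clusters and must not appear
  expect_lte(sum(grepl("^bg_", mk$gene)), 2)
  expect_true(all(mk$p_adjusted <= 0.05))
  expect_true(all(abs(mk$log2_fold_change) >= 1))
})

test_that("rank-sum p-values match exact enumeration at small n", {
  # tie-free fixture: integer counts whose per-cell depths differ, so
  # the normalised target values are all distinct
  g <- c(5:16, 30:41)
  filler <- 100 + seq_len(24) * 3
  counts <- rbind(target = g, filler = filler)
  norm_vals <- g / (g + filler)
  stopifnot(!anyDuplicated(norm_vals))
  m <- fixture_cell_matrix(counts)
  nm <- log_normalize(m)
  ca <- structure(list(
    cells = m$cells,
    cluster_id = setNames(rep(c(0L, 1L), each = 12), m$cells),
    resolution = 0.5, n_clusters = 2L), class = "cluster_assignment")
  mk <- find_markers(nm, ca, p_adj_max = 1)
  row <- mk[mk$gene == "target" & mk$cluster_id == 0, ]
  expect_equal(nrow(row), 1)
  x <- as.numeric(nm$values["target", 1:12])
  y <- as.numeric(nm$values["target", 13:24])
  exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(row$p_raw, exact, tolerance = 0.05)
})

test_that("cluster depths report comparable medians for equal-depth subtypes", {
  atl <- generate_atlas(subtype_benchmark_config(seed = 29))
  nm <- log_normalize(atl$matrix)
  ca <- embed_and_cluster(nm, select_variable_genes(nm), seed = 1)
  cd <- cluster_depths(atl$matrix, ca, c("0", "1"))
  expect_length(cd$depths, 2)
  ratio <- cd$medians[[1]] / cd$medians[[2]]
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)

  same <- cluster_depths(atl$matrix, ca, c("0", "0"))
  expect_equal(same$medians[[1]], same$medians[[2]])

  expect_error(cluster_depths(atl$matrix, ca, c("0", "99")), "99")
})
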