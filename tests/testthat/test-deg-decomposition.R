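make_liver_profile <- function(seed = 6) {
  atl <- generate_atlas(liver_benchmark_config(seed = seed,
                                               cells_per_type = 40L))
  expression_fraction(atl$matrix, atl$annotation)
}

test_that("microenvironment profiles are direct lookups with drop reports", {
  prof <- make_liver_profile()
  env <- liver_microenvironment()
  genes <- c("hep_01", "imm_03", "broad_10")
  mat <- microenvironment_profile(prof, env, genes)
  expect_identical(rownames(mat), genes)
  expect_identical(colnames(mat), env$cell_types)
  expect_equal(mat["hep_01", ], prof$fraction["hep_01", env$cell_types])
  expect_length(attr(mat, "dropped"), 0)

  with_unknown <- c(genes, "ghost1", "ghost2", "ghost3")
  mat2 <- microenvironment_profile(prof, env, with_unknown)
  expect_identical(attr(mat2, "dropped"), c("ghost1", "ghost2", "ghost3"))

  mostly_missing <- c("hep_01", sprintf("ghost%d", 1:5))
  expect_error(microenvironment_profile(prof, env, mostly_missing),
               "allow_sparse")
  expect_silent(microenvironment_profile(prof, env, mostly_missing,
                                         allow_sparse = TRUE))

  bad_env <- microenvironment("x", c("hepatocyte", "unicorn cell"))
  expect_error(microenvironment_profile(prof, bad_env, genes),
               "unicorn cell")
})

test_that("ward.D2 grouping matches the naive objective-recomputing oracle", {
  set.seed(33)
  for (trial in 1:12) {
    n <- sample(3:8, 1)
    X <- matrix(runif(n * 4), n, 4,
                dimnames = list(sprintf("g%d", 1:n), NULL))
    hc <- ward_d2_cluster(X, k = 2)$tree
    naive <- ward_d2_naive(X)
    steps <- hclust_merge_sets(hc)
    for (s in seq_along(steps)) {
      expect_true(same_merge(steps[[s]], naive$merges[[s]]))
    }
    expect_equal(hc$height, naive$heights, tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone agglomeration
  }
})

test_that("grouping ids follow leaf order and k boundaries hold", {
  set.seed(34)
  X <- matrix(runif(40), 10, 4,
              dimnames = list(sprintf("g%d", 1:10), NULL))
  g1 <- ward_d2_cluster(X, k = 1)
  expect_equal(unname(unique(g1$group_id)), 1L)

  g3 <- ward_d2_cluster(X, k = 3)
  # ids are 1..3 renumbered by first appearance along the dendrogram
  first_seen <- g3$group_id[g3$genes]
  expect_identical(unique(unname(first_seen)), c(1L, 2L, 3L))

  gk <- ward_d2_cluster(X, k = 10)
  expect_equal(length(unique(gk$group_id)), 10)

  expect_error(ward_d2_cluster(X, k = 11), "k must be")
  expect_error(ward_d2_cluster(X, k = 0), "k must be")

  # duplicate rows are permitted (zero distances)
  Xd <- rbind(X, g11 = X[1, ])
  expect_silent(ward_d2_cluster(Xd, k = 2))
})

test_that("grouping is invariant to input gene order", {
  prof <- make_liver_profile()
  env <- liver_microenvironment()
  genes <- c(sprintf("hep_%02d", 1:10), sprintf("imm_%02d", 1:10))
  mat <- microenvironment_profile(prof, env, genes)
  g <- ward_d2_cluster(mat, k = 2)
  set.seed(35)
  for (i in 1:5) {
    perm <- sample(nrow(mat))
    gp <- ward_d2_cluster(mat[perm, ], k = 2)
    common <- rownames(mat)
    expect_equal(adjusted_rand_index(g$group_id[common],
                                     gp$group_id[common]), 1)
  }
})

test_that("planted cell-type-specific blocks are recovered exactly", {
  prof <- make_liver_profile()
  env <- liver_microenvironment()
  up <- c(sprintf("hep_%02d", 1:15), sprintf("imm_%02d", 1:15))
  g <- ward_d2_cluster(microenvironment_profile(prof, env, up), k = 2)
  planted <- rep(1:2, each = 15)
  expect_equal(adjusted_rand_index(g$group_id[up], planted), 1)
})

test_that("decomposition splits DEG lists and is deterministic", {
  prof <- make_liver_profile()
  env <- liver_microenvironment()
  up <- c(sprintf("hep_%02d", 1:12), sprintf("broad_%02d", 1:8))
  down <- c(sprintf("imm_%02d", 1:12), sprintf("broad_%02d", 11:18))
  dec <- decompose_degs(up, down, prof, env, k_up = 2, k_down = 2)

  up_groups <- dec$up$grouping$group_id
  hep_group <- unique(up_groups[sprintf("hep_%02d", 1:12)])
  expect_length(hep_group, 1)
  expect_false(any(up_groups[sprintf("broad_%02d", 1:8)] == hep_group))

  down_groups <- dec$down$grouping$group_id
  imm_group <- unique(down_groups[sprintf("imm_%02d", 1:12)])
  expect_length(imm_group, 1)

  # identical lists give identical groupings
  dec2 <- decompose_degs(up, up, prof, env, k_up = 2, k_down = 2)
  expect_identical(dec2$up$grouping$group_id, dec2$down$grouping$group_id)

  # maximal cut: every gene its own group
  deck <- decompose_degs(up, down, prof, env, k_up = length(up), k_down = 2)
  expect_equal(length(unique(deck$up$grouping$group_id)), length(up))

  # heatmap table rows follow leaf order
  tab <- dec$up$table
  expect_identical(tab$gene, dec$up$grouping$genes)
  expect_identical(tab$leaf_order, seq_len(nrow(tab)))
})

test_that("group enrichment reproduces the exact hypergeometric tail", {
  grouping <- structure(list(
    genes = sprintf("g%02d", 1:40),
    group_id = setNames(rep(1:2, each = 20), sprintf("g%02d", 1:40)),
    tree = NULL, heights = numeric(0), k = 2L), class = "gene_grouping")
  universe <- sprintf("g%02d", 1:80)
  sets <- list(setA = sprintf("g%02d", 1:20),     # exactly group 1
               setB = sprintf("g%02d", 60:80),    # disjoint from groups
               setC = sprintf("g%02d", 15:30))
  res <- enrich_groups(grouping, sets, universe)
  expect_equal(nrow(res), 6)

  rA1 <- res[res$group_id == 1 & res$gene_set_name == "setA", ]
  expect_equal(rA1$overlap, 20)
  brute <- choose(20, 20) * choose(60, 0) / choose(80, 20)
  expect_equal(rA1$p_raw, brute, tolerance = 1e-12)
  expect_equal(rA1$p_raw, min(res$p_raw))

  rB <- res[res$gene_set_name == "setB", ]
  expect_true(all(rB$overlap == 0))
  expect_true(all(rB$p_raw == 1))

  # Bonferroni is per group across sets
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 3))

  expect_error(enrich_groups(grouping, sets, character(0)), "universe")
  expect_error(enrich_groups(grouping, list(), universe), "gene-set")
  expect_error(enrich_groups(grouping, sets, universe[1:10]), "outside")
})

test_that("planted enrichment survives Bonferroni over many sets", {
  # group of 30 genes, 25 drawn from one 40-gene set, universe of 2,000
  universe <- sprintf("u%04d", 1:2000)
  special <- universe[1:40]
  group_genes <- c(special[1:25], universe[1000:1004])
  grouping <- structure(list(
    genes = group_genes,
    group_id = setNames(rep(1L, 30), group_genes),
    tree = NULL, heights = numeric(0), k = 1L), class = "gene_grouping")
  set.seed(36)
  decoys <- lapply(1:49, function(i) sample(universe, 40))
  names(decoys) <- sprintf("decoy%02d", 1:49)
  sets <- c(list(planted = special), decoys)
  res <- enrich_groups(grouping, sets, universe)
  planted_row <- res[res$gene_set_name == "planted", ]
  expect_true(planted_row$significant)
  direct <- hypergeom_coexpression_p(2000, 40, 30, 25)
  expect_equal(planted_row$p_raw, direct)
  expect_equal(which.min(res$p_raw),
               which(res$gene_set_name == "planted"))
})

test_that("GMT collections and microenvironment YAML round-trip", {
  gmt <- file.path(tempdir(), "sets.gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4\tg5"), gmt)
  sets <- read_gmt(gmt)
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(sets$setB, c("g4", "g5"))

  yml <- file.path(tempdir(), "env.yaml")
  writeLines(c("name: liver", "cell_types:", "  - hepatocyte",
               "  - Kupffer cell", "  - fibroblast"), yml)
  env <- microenvironment_from_yaml(yml)
  expect_identical(env$cell_types, c("hepatocyte", "Kupffer cell",
                                     "fibroblast"))
})
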