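#!/usr/bin/env Rscript
# Step 1 — simulate the study's three synthetic datasets with known
# ground truth:
#   (a) a "myeloid cell" atlas hiding two subtypes whose receptor gene
#       Thra is detected in 20% vs 2% of cells,
#   (b) a gene-pair atlas with a planted co-detection dependence
#       (marginals 0.3/0.3, joint 0.25 in 300 cells),
#   (c) a ten-cell-type liver-like atlas plus a treated/control bulk
#       experiment with planted up- (hepatocyte-specific) and down-
#       (immune-specific) regulated genes.
# Everything downstream reads these from results/data/.

library(thyrotrace)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating subtype benchmark atlas (800 myeloid cells) ...")
subtype_atlas <- generate_atlas(subtype_benchmark_config(seed = seed))
write_atlas(subtype_atlas, file.path(out, "subtype_atlas"))

message("simulating dependent gene-pair atlas (300 cells) ...")
pair_atlas <- generate_atlas(pair_benchmark_config(seed = seed,
                                                   joint = 0.25))
write_atlas(pair_atlas, file.path(out, "pair_atlas"))

message("simulating liver microenvironment atlas (10 types x 60 cells) ...")
liver_atlas <- generate_atlas(liver_benchmark_config(seed = seed))
write_atlas(liver_atlas, file.path(out, "liver_atlas"))

message("simulating T3-like bulk experiment (4 treated vs 4 control) ...")
liver_profile <- expression_fraction(liver_atlas$matrix,
                                     liver_atlas$annotation)
bulk_cfg <- liver_bulk_benchmark_config(liver_profile, seed = seed)
bulk <- generate_bulk(bulk_cfg)
write.csv(bulk$bulk$counts, file.path(out, "bulk_counts.csv"))
writeLines(bulk_cfg$planted_up$gene, file.path(out, "degs_up.txt"))
writeLines(bulk_cfg$planted_down$gene, file.path(out, "degs_down.txt"))

message(sprintf(
  "done: %d + %d + %d cells simulated; bulk has %d genes x %d samples",
  ncol(subtype_atlas$matrix$counts), ncol(pair_atlas$matrix$counts),
  ncol(liver_atlas$matrix$counts), nrow(bulk$bulk$counts),
  ncol(bulk$bulk$counts)))
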