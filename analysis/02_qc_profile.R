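#!/usr/bin/env Rscript
# Step 2 — ingest the simulated atlases from disk, apply cell QC and the
# cell-type abundance filter, and compute the central statistic: the
# fraction of cells in each cell type expressing each gene.  The QC
# thresholds scale with the synthetic library depth (the defaults encode
# the full-size atlas cut-offs of 5,000 counts / 500 genes for
# full-length libraries, which would remove every cell of a 1,000-gene
# simulation).

library(thyrotrace)

data_dir <- "results/data"
out <- "results"

atlas <- read_cell_matrix(file.path(data_dir, "liver_atlas"),
                          format = "mtx", platform = "full_length")
ann <- read_cell_annotation(file.path(data_dir, "liver_atlas",
                                      "annotation.csv"))

qc <- qc_thresholds(min_counts = 60, min_genes = 25)
filtered <- filter_cells(atlas, qc)
message(sprintf("QC: kept %d of %d cells (>= %d counts, >= %d genes)",
                length(filtered$cells), length(atlas$cells),
                qc$min_counts, qc$min_genes))

types <- select_cell_types(ann, filtered, min_cells = 20)
message(sprintf("cell types with >= 20 cells after QC: %d", length(types)))

profile <- expression_fraction(filtered, ann, types)
write_profile(profile, file.path(out, "liver_profile.csv"))

# rank the cell types by hepatocyte-specific and immune-specific example
# genes, the way one ranks types by receptor expression
for (gene in c("hep_01", "imm_01", "broad_01")) {
  ranking <- rank_types_by_gene(profile, gene, top_n = 5)
  message(sprintf("top types for %s: %s", gene,
                  paste(sprintf("%s (%.2f)", ranking$cell_type,
                                ranking$fraction), collapse = ", ")))
}

# bulk RPM for the treated/control experiment
bulk <- bulk_matrix(as.matrix(read.csv(file.path(data_dir,
                                                 "bulk_counts.csv"),
                                       row.names = 1,
                                       check.names = FALSE)))
bulk <- compute_rpm(bulk)
write.csv(bulk$rpm, file.path(out, "bulk_rpm.csv"))
message(sprintf("bulk RPM written for %d samples (columns sum to 1e6)",
                length(bulk$samples)))
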