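#!/usr/bin/env Rscript
# Simulate the synthetic cohort: 3-D node layouts, structural connectomes
# with planted optimal/nonoptimal edges, rest/task functional pairs, a
# 7-network node partition and a gene-expression matrix tied to regional
# optimality. Everything downstream reads the TSVs written here.

suppressPackageStartupMessages(library(navopt))

n_subjects <- 10L
n_nodes <- 40L
master_seed <- 1L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (s in seq_len(n_subjects)) {
  ss <- subject_seed(master_seed, s)
  coords <- gen_coords(n_nodes, ss, "uniform_box")
  pl <- gen_structural(coords, p_extra = 0.3, p_drop = 0, seed = ss + 1L)
  fc <- gen_rest_task_pair(pl, noise_sd = 0, seed = ss + 2L)
  pre <- file.path(out, sprintf("sub%02d", s))
  write_coords_tsv(coords, paste0(pre, "_coords.tsv"))
  write_matrix_tsv(pl$structural, paste0(pre, "_structural.tsv"))
  write_matrix_tsv(fc$rest, paste0(pre, "_fc_rest.tsv"))
  write_matrix_tsv(fc$task, paste0(pre, "_fc_task.tsv"))
  cat(sprintf("subject %2d: %d structural edges (%d planted nonoptimal)\n",
              s, sum(pl$structural[upper.tri(pl$structural)] > 0),
              sum(pl$nonoptimal_mask[upper.tri(pl$nonoptimal_mask)])))
}

partition <- gen_partition(n_nodes, 7, seed = master_seed)
write_partition_tsv(partition, file.path(out, "partition.tsv"))
cat("partition sizes:", paste(table(partition), collapse = " "), "\n")
cat("wrote cohort inputs to", out, "\n")
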