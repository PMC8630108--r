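#!/usr/bin/env Rscript
# Stage 5 — ligand-receptor interaction testing and the cell-type network.
#
# Per-sample permutation tests over the BME cell types of the default
# cohort (planted: IL18 -> IL18R1/IL18RAP from TAM to NK cells and
# MIF -> CD74 from TAM to T cells), then cohort-level mean significant
# interaction counts, summed strengths, and the top-4 partner network.

library(cnasig)
cohort <- readRDS("scratch/sim/default_cohort.rds")
lr <- read_lr_pairs(default_lr_path())

norm <- normalize_log(qc_filter(cohort$em))
meta <- qc_filter(cohort$em)$cell_meta
bme <- rownames(meta)[meta$compartment == "bme"]
samples <- sort(unique(meta[bme, "sample_id"]))
results <- lapply(seq_along(samples), function(i) {
  message("sample ", samples[i])
  cells <- bme[meta[bme, "sample_id"] == samples[i]]
  test_interactions(norm[cells, ], meta[cells, "cell_type"], lr,
                    n_perm = 1000, seed = 100 + i)
})
names(results) <- samples

counts <- count_interactions(results)
strengths <- interaction_strength(results)
net <- build_network(strengths, k = 4)

write.table(counts, "results/interaction_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(strengths, "results/interaction_strengths.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(net$edges, "results/network_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(net$nodes, "results/network_nodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("mean significant interactions per type pair:")
print(counts[order(-counts$mean_count), ][1:6, ])
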