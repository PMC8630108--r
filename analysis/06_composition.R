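#!/usr/bin/env Rscript
# Stage 6 — BME cell-type composition and group comparison.
#
# Computes per-sample cell-type fractions (dropping types under 5 cells
# per sample) and compares them between the +1q groups derived from the
# CNA analysis. The generator plants no compositional difference between
# groups, so this stage doubles as a null check: no type should reach
# Bonferroni significance.

library(cnasig)
cohort <- readRDS("scratch/sim/default_cohort.rds")
qc <- qc_filter(cohort$em)
meta <- qc$cell_meta
bme <- rownames(meta)[meta$compartment == "bme"]

fractions <- compute_fractions(meta[bme, "cell_type"],
                               meta[bme, "sample_id"])
write.table(fractions, "results/cell_type_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- cohort$truth$oneq_fractions
groups <- setNames(as.character(classify_1q_group(truth$oneq_fraction)),
                   truth$sample_id)
cmp <- compare_fractions(fractions, groups, "ND_rare", "dominant")
write.table(cmp, "results/composition_compare.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(cmp)
message("significant types at Bonferroni 0.05: ",
        sum(cmp$p_bonferroni < 0.05, na.rm = TRUE), " (0 planted)")
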