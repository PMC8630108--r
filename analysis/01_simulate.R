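#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohorts.
#
# Three synthetic datasets with planted ground truth drive the analysis:
#  * a single-patient subclone fixture (3 major clones at 0.5/0.3/0.2 with
#    arm-level single-copy gains/losses, plus a 30-cell minor clone under
#    the 40-cell reporting floor),
#  * a 10-patient cohort whose +1q clone fractions span 0 to 1 across the
#    not-detected/rare, subclonal and dominant groups, sampled pre and
#    post treatment, with BME cell types and planted ligand-receptor
#    co-expression,
#  * a 10-patient all-subclonal cohort used to derive the +1q signature.
#
# Heavy objects are cached under scratch/ (not part of the deliverable);
# small truth tables go to results/.

library(cnasig)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

message("simulating subclone fixture ...")
fix <- simulate_cohort(subclone_fixture_config(seed = 42))
saveRDS(fix, "scratch/sim/subclone_fixture.rds")

message("simulating default cohort (with BME) ...")
cohort <- simulate_cohort(default_cohort_config(
  seed = 1, n_bme = 80, lr_pairs = read_lr_pairs(default_lr_path())))
saveRDS(cohort, "scratch/sim/default_cohort.rds")

message("simulating signature cohort ...")
sigc <- simulate_cohort(signature_cohort_config(seed = 11))
saveRDS(sigc, "scratch/sim/signature_cohort.rds")

write.table(cohort$truth$oneq_fractions, "results/truth_oneq_fractions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cohort$truth$subclones, "results/truth_subclones.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# a 10x-style on-disk bundle of the fixture, exercising the readers
make_default_fixtures("scratch/sim/fixture_10x", subclone_fixture_config(seed = 42))

message("done: ", nrow(cohort$em$counts), " cohort cells, ",
        nrow(fix$em$counts), " fixture cells")
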