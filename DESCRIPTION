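Package: cnasig
Title: Subclone-Resolved Copy-Number and Signature Analysis for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers copy-number alteration (CNA) profiles of tumor cells from
    single-cell RNA-seq expression against a normal reference, partitions cells
    into CNA subclones by dendrogram cutting, derives recurrence-filtered
    arm-restricted expression signatures (such as a chromosome 1q-gain
    signature in multiple myeloma) from matched-clone differential expression,
    scores cells with expression-bin-matched control genes, quantifies clonal
    dynamics under treatment with a clone-stability score, and tests
    ligand-receptor cell-type interactions with a label-permutation null.
    Ships a negative-binomial cohort simulator that plants known subclones,
    dosage effects, marker genes and ligand-receptor co-expression so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
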