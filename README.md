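# cnasig

Subclone-resolved copy-number and expression-signature analysis for tumor
single-cell RNA-seq, written for the analysis pattern used in
relapsed/refractory multiple myeloma (RRMM): infer copy-number alterations
(CNAs) per cell from expression, partition tumor cells into genetic
subclones, derive a chromosome-1q-gain expression signature from
matched-clone differential expression, score cells for it, follow clonal
dynamics through treatment, and test ligand–receptor interactions between
bone-marrow-microenvironment (BME) cell types. It is aimed at
computational biologists who want these steps as plain, tested R functions
rather than a stack of interactive notebooks.

Patient-level myeloma scRNA-seq is access-restricted, so the package
includes a negative-binomial cohort simulator that plants known subclones,
dosage effects, cell types and ligand–receptor co-expression; every
claim about the pipeline is tested against that planted truth.

## The statistics at the core

* **CNA signal.** For log-normalized expression `v = ln(x/total · 1e4 + 1)`,
  the per-cell CNA profile is the reference-centred, depth-regressed,
  ±3 SD-clipped residual, moving-averaged over 101 genes within each
  chromosome and recentred on the cell median. A single-copy gain shifts
  an arm's signal by about `ln 1.5 ≈ 0.405` times the responding fraction
  of its genes.
* **Subclones.** Ward clustering on profiles from even-indexed genes,
  then clusters are merged while indistinguishable: two clusters are
  distinct subclones only if some chromosome arm shows a state contrast
  on the held-out odd-indexed genes (|Δ| > 0.15 ≈ half a single-copy
  shift, > 5 SE), so the test is free of the selection bias of testing on
  the clustering features. Clusters under 40 cells are absorbed into
  their nearest relative.
* **Clone stability.** For pre/post clone fractions,
  `score = mean_i [ min(f_pre,i, f_post,i) / max(f_pre,i, f_post,i) ]`
  over the union of clones; 1 = unchanged composition, 0 = turnover.
* **Signature.** Genes significantly upregulated (two-sided Wilcoxon,
  Bonferroni p < 0.05, logFC > 0.1) in the +1q clone versus its closest
  1q-neutral relative in ≥ 5 of 10 patients, located on 1q,
  non-mitochondrial.
* **Module score.** Mean signature expression minus the mean of 100
  expression-bin-matched control genes per signature gene (24 bins), so a
  random gene set scores ~0. PPV of `score ≥ t` calls is evaluated
  against the CNA-derived truth.
* **Interactions.** CellPhoneDB-style: statistic = ½(mean ligand complex
  in sender + mean receptor complex in receiver), complexes as subunit
  minima, null from 1,000 cell-type label permutations,
  `p = (1 + #{perm ≥ obs})/(n_perm + 1)`; cohort summaries average
  significant counts and sum strengths over patients, and each cell type
  connects to its top-4 partners in the network.

## Worked example

Simulate one patient with three subclones (fractions 0.5/0.3/0.2, one
arm-level single-copy event each, plus a 30-cell minor clone below the
40-cell floor), recover them, and classify the sample's +1q group:

```r
library(cnasig)

sim  <- simulate_cohort(subclone_fixture_config(seed = 42))
qc   <- qc_filter(sim$em)
norm <- normalize_log(qc)
ref  <- rownames(qc$cell_meta)[qc$cell_meta$compartment == "reference"]

cna <- infer_cna_profiles(norm, sim$gene_order, ref)
sub <- call_region_state(call_subclones(cna), "1q")
sub
#> SubcloneSet: 3 subclones over 2000 cells (min 40 cells/clone)
#>
#>  S1  S2  S3
#> 987 602 411

frac <- fraction_aberrant_cells(sub, "1q")
frac
#> [1] 0.4935
classify_1q_group(frac)
#> [1] subclonal
#> Levels: ND_rare subclonal dominant
```

The three major clones come back near their planted sizes of 985/591/394
(the 30-cell minor clone is absorbed into its closest relative), the
called +1q cell fraction 0.4935 sits within one percent of the planted
0.4925, and the sample lands in the subclonal band (10–80%).

`run_pipeline(out_dir, seed)` chains every stage — QC, CNA subclones per
patient, matched-clone DE, signature derivation and scoring,
score-versus-fraction correlation, PPV, interactions, composition — on
the default ten-patient cohort and writes TSV/JSON outputs. The numbered
scripts under `analysis/` run the same stages as a narrative and drop
small summary tables in `results/`.

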