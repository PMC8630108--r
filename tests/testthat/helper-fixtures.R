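# Shared fixtures and independent oracles. Heavy simulated cohorts are
# cached so several test files can reuse one realisation.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# adjusted Rand index, written from the contingency-table definition so it
# is independent of any clustering code under test
adj_rand_index <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  n <- length(a)
  expected <- s(rowSums(tab)) * s(colSums(tab)) / choose(n, 2)
  (s(tab) - expected) /
    ((s(rowSums(tab)) + s(colSums(tab))) / 2 - expected)
}

# deterministic small count matrix wrapped as an ExpressionMatrix
toy_counts <- function(n_cells, n_genes, seed = 1, mu = 2,
                       gene_names = sprintf("G%03d", seq_len(n_genes))) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_cells * n_genes, mu = mu, size = 2),
                n_cells, n_genes,
                dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                                gene_names))
    m
  })
}

# subclone-recovery fixture: 3 major clones + 30-cell minor clone
subclone_fixture <- function() cached("subclone_fixture", {
  cfg <- subclone_fixture_config(seed = 42)
  sim <- simulate_cohort(cfg)
  qc <- qc_filter(sim$em)
  norm <- normalize_log(qc)
  ref <- rownames(qc$cell_meta)[qc$cell_meta$compartment == "reference"]
  cna <- infer_cna_profiles(norm, sim$gene_order, ref)
  sub <- call_region_state(call_subclones(cna), "1q")
  list(sim = sim, qc = qc, norm = norm, ref = ref, cna = cna, sub = sub)
})

# ten-patient cohort with subclonal +1q clones in every patient
signature_fixture <- function() cached("signature_fixture", {
  cfg <- signature_cohort_config(seed = 11)
  sim <- simulate_cohort(cfg)
  qc <- qc_filter(sim$em)
  norm <- normalize_log(qc)
  meta <- qc$cell_meta
  patients <- sort(unique(meta$patient_id[meta$compartment == "tumor"]))
  per_patient <- lapply(patients, function(p)
    analyze_patient(norm, sim$gene_order, meta, p))
  names(per_patient) <- patients
  de <- Filter(Negate(is.null), lapply(per_patient, `[[`, "de"))
  sig <- derive_signature(de, min_recurrence = 5, order = sim$gene_order)
  list(sim = sim, qc = qc, norm = norm, meta = meta,
       per_patient = per_patient, de = de, sig = sig)
})

# full-pipeline default cohort (fractions spanning 0..1), tumor arm only
default_analysis <- function() cached("default_analysis", {
  run_pipeline(out_dir = NULL, seed = 5,
               cfg = default_cohort_config(seed = 5), verbose = FALSE)
})

# small simulated dataset with BME cell types and planted LR interactions
interaction_fixture <- function() cached("interaction_fixture", {
  lr <- read_lr_pairs(default_lr_path())
  pat <- sim_patient("P1", list(sim_subclone("c1", c(pre = 1))),
                     n_tumor = c(pre = 50), n_reference = 40, n_bme = 300)
  cfg <- sim_config(seed = 21, patients = list(pat), n_genes = 1200,
                    oneq_genes = 80, oneq_responsive = 40,
                    bme_types = list(Tcell = list(n_markers = 12, fold = 4),
                                     NK = list(n_markers = 12, fold = 4),
                                     TAM = list(n_markers = 12, fold = 4)),
                    lr_pairs = lr,
                    lr_planted = list(list(pair_id = "IL18_IL18R",
                                           sender = "TAM", receiver = "NK",
                                           fold = 4)))
  sim <- simulate_cohort(cfg)
  norm <- normalize_log(sim$em)
  bme <- rownames(sim$em$cell_meta)[sim$em$cell_meta$compartment == "bme"]
  list(sim = sim, norm = norm, bme = bme, lr = lr,
       labels = sim$em$cell_meta[bme, "cell_type"])
})
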