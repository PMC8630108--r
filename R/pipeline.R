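#' Subclone and +1q analysis of one patient
#'
#' Runs the per-patient arm of the pipeline: CNA profile inference of the
#' patient's tumor cells against the pooled normal reference, subclone
#' calling, 1q state calls, per-sample +1q fractions and group labels,
#' pre/post clone-stability, and matched-clone differential expression
#' (largest 1q-gained clone versus its closest 1q-neutral relative).
#'
#' @param norm cells x genes log-normalized matrix (whole cohort).
#' @param order a `GeneOrder`.
#' @param cell_meta per-cell metadata with `patient_id`, `timepoint`,
#'   `compartment` (tumor cells analysed, reference cells define neutral).
#' @param patient patient id.
#' @param arm arm of interest.
#' @param min_cells minimum cells per subclone.
#' @param window CNA smoothing window (genes).
#' @param de_alpha,de_min_logfc thresholds for the matched-clone DE.
#' @param state_thresh arm-state threshold on the subclone mean signal:
#'   half the expected single-copy dosage shift, consistent with the
#'   effect floor the subclone caller uses to separate clones (the
#'   standalone [call_region_state()] default of 3 reference SDs is more
#'   conservative and sits near the dosage-1.5 shift itself).
#' @return list: `sub` (SubcloneSet with states), `samples` (data.frame per
#'   timepoint: sample_id, cna_fraction, group), `stability` (score or NA),
#'   `clone_fracs` (per-timepoint fraction maps), `de` (DETable or NULL),
#'   `matched` (target/comparator ids or NULL).
#' @export
analyze_patient <- function(norm, order, cell_meta, patient, arm = "1q",
                            min_cells = 40, window = 101,
                            de_alpha = 0.05, de_min_logfc = 0.1,
                            state_thresh = 0.15) {
  stopifnot(all(rownames(cell_meta) == rownames(norm)))
  tumor <- rownames(cell_meta)[cell_meta$patient_id == patient &
                               cell_meta$compartment == "tumor"]
  ref <- rownames(cell_meta)[cell_meta$compartment == "reference"]
  cna <- infer_cna_profiles(norm[c(tumor, ref), , drop = FALSE], order,
                            reference_cells = ref, window = window)
  sub <- call_subclones(cna, min_cells = min_cells)
  sub <- call_region_state(sub, arm = arm, gain_thresh = state_thresh,
                           loss_thresh = -state_thresh)
  state <- sub$states[[arm]]
  gained <- names(state)[state == "gain"]

  tps <- unique(cell_meta[tumor, "timepoint"])
  samples <- do.call(rbind, lapply(tps, function(tp) {
    cells <- tumor[cell_meta[tumor, "timepoint"] == tp]
    frac <- mean(sub$labels[cells] %in% gained)
    data.frame(patient_id = patient, timepoint = tp,
               sample_id = paste0(patient, "_", tp),
               n_tumor = length(cells), cna_fraction = frac,
               group = as.character(classify_1q_group(frac)),
               stringsAsFactors = FALSE)
  }))

  clone_fracs <- lapply(tps, function(tp) {
    cells <- tumor[cell_meta[tumor, "timepoint"] == tp]
    tab <- table(sub$labels[cells])
    as.numeric(tab) / length(cells) -> fr
    names(fr) <- names(tab)
    fr
  })
  names(clone_fracs) <- tps
  stability <- if (all(c("pre", "post") %in% tps))
    clone_stability_score(clone_fracs$pre, clone_fracs$post) else NA_real_

  de <- NULL; matched <- NULL
  if (length(gained) && length(setdiff(levels(sub$labels), gained))) {
    target <- gained[which.max(sub$n_cells[match(gained, levels(sub$labels))])]
    comparator <- match_closest_clone(sub, target, exclude_arm = arm)
    cells_a <- names(sub$labels)[sub$labels == target]
    cells_b <- names(sub$labels)[sub$labels == comparator]
    de <- differential_expression(norm, cells_a, cells_b,
                                  alpha = de_alpha, min_logfc = de_min_logfc)
    matched <- list(target = target, comparator = comparator)
  }
  list(sub = sub, samples = samples, stability = stability,
       clone_fracs = clone_fracs, de = de, matched = matched)
}

#' Run the full pipeline on a simulated cohort
#'
#' Chains every stage under a single seed: cohort simulation, QC,
#' log-normalization, per-patient CNA subclone analysis, matched-clone DE
#' and recurrence-filtered arm signature, bin-matched module scoring with
#' PPV and score-versus-fraction correlation, ligand-receptor interaction
#' testing with the cohort network, and cell-type composition comparisons.
#' Identical seed and config give byte-identical outputs.
#'
#' @param out_dir directory for the stage outputs (TSV/JSON); NULL skips
#'   writing.
#' @param seed global seed; stage seeds are derived from it.
#' @param cfg simulation config; default [default_cohort_config()] with BME
#'   cells and planted interactions.
#' @param arm arm of interest.
#' @param min_recurrence recurrence floor for the signature; NULL (default)
#'   uses the majority of contributing patients, capped at 5 — the
#'   5-of-10 convention generalized to cohorts where fewer patients carry
#'   a subclonal comparison.
#' @param score_threshold signature-score cutoff for the PPV evaluation.
#' @param n_perm interaction-test permutations.
#' @param verbose print per-stage progress.
#' @return invisibly, a list with every stage result (`sim`, `qc`, `norm`,
#'   `patients`, `signature`, `scores`, `sample_summary`, `correlation`,
#'   `ppv`, `interactions`, `counts`, `strengths`, `network`, `fractions`,
#'   `composition`).
#' @export
run_pipeline <- function(out_dir = NULL, seed = 1L, cfg = NULL, arm = "1q",
                         min_recurrence = NULL, score_threshold = 0.2,
                         n_perm = 1000, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cfg))
    cfg <- default_cohort_config(seed = seed, n_bme = 80,
                                 lr_pairs = read_lr_pairs(default_lr_path()))
  else if (!is.null(seed)) cfg$seed <- as.integer(seed)

  say("simulating cohort (seed %d)", cfg$seed)
  sim <- simulate_cohort(cfg)
  say("QC on %d cells x %d genes", nrow(sim$em$counts), ncol(sim$em$counts))
  qc <- qc_filter(sim$em)
  norm <- normalize_log(qc)
  meta <- qc$cell_meta
  say("retained %d cells", nrow(norm))

  patients <- sort(unique(meta$patient_id[meta$compartment == "tumor"]))
  per_patient <- lapply(patients, function(p) {
    say("CNA subclones: patient %s", p)
    analyze_patient(norm, sim$gene_order, meta, p, arm = arm)
  })
  names(per_patient) <- patients

  de_tables <- Filter(Negate(is.null), lapply(per_patient, `[[`, "de"))
  if (is.null(min_recurrence))
    min_recurrence <- min(5L, max(2L, ceiling(length(de_tables) / 2)))
  say("deriving %s signature from %d matched-clone comparisons (recurrence >= %d)",
      arm, length(de_tables), min_recurrence)
  signature <- derive_signature(de_tables, min_recurrence = min_recurrence,
                                order = sim$gene_order, arm = arm)

  tumor_cells <- rownames(meta)[meta$compartment == "tumor"]
  scores <- NULL; correlation <- NA_real_; ppv <- NULL
  sample_summary <- do.call(rbind, lapply(per_patient, `[[`, "samples"))
  rownames(sample_summary) <- NULL
  sample_summary$mean_score <- NA_real_
  if (nrow(signature) > 0) {
    say("scoring %d cells on %d signature genes",
        length(tumor_cells), nrow(signature))
    scores <- score_signature(norm[tumor_cells, , drop = FALSE], signature,
                              seed = cfg$seed + 1L)
    sample_of <- meta[tumor_cells, "sample_id"]
    mean_scores <- tapply(scores, sample_of, mean)
    sample_summary$mean_score <-
      as.numeric(mean_scores[sample_summary$sample_id])
    correlation <- score_fraction_correlation(sample_summary$mean_score,
                                              sample_summary$cna_fraction)
    truth <- unlist(unname(lapply(per_patient, function(pp) {
      st <- pp$sub$states[[arm]]
      gained <- names(st)[st == "gain"]
      setNames(pp$sub$labels %in% gained, names(pp$sub$labels))
    })))
    ppv <- evaluate_ppv(scores, truth[tumor_cells], score_threshold)
  }

  interactions <- list(); counts <- NULL; strengths <- NULL; network <- NULL
  bme <- rownames(meta)[meta$compartment == "bme"]
  if (length(bme) && !is.null(cfg$lr_pairs)) {
    say("interaction testing over %d BME cells", length(bme))
    samples <- sort(unique(meta[bme, "sample_id"]))
    interactions <- lapply(seq_along(samples), function(i) {
      cells <- bme[meta[bme, "sample_id"] == samples[i]]
      test_interactions(norm[cells, , drop = FALSE],
                        meta[cells, "cell_type"], cfg$lr_pairs,
                        n_perm = n_perm, seed = cfg$seed + 100L + i)
    })
    names(interactions) <- samples
    counts <- count_interactions(interactions)
    strengths <- interaction_strength(interactions)
    network <- build_network(strengths, k = 4)
  }

  fractions <- NULL; composition <- NULL
  if (length(bme)) {
    fractions <- compute_fractions(meta[bme, "cell_type"],
                                   meta[bme, "sample_id"])
    groups <- setNames(sample_summary$group, sample_summary$sample_id)
    if (sum(groups == "ND_rare") >= 3 && sum(groups == "dominant") >= 3)
      composition <- compare_fractions(fractions, groups,
                                       "ND_rare", "dominant")
  }

  res <- list(sim = sim, qc = qc, norm = norm, per_patient = per_patient,
              signature = signature, scores = scores,
              sample_summary = sample_summary, correlation = correlation,
              ppv = ppv, interactions = interactions, counts = counts,
              strengths = strengths, network = network,
              fractions = fractions, composition = composition,
              seed = cfg$seed)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) write.table(df, file.path(out_dir, name),
                                        sep = "\t", quote = FALSE,
                                        row.names = FALSE)
  labels <- do.call(rbind, lapply(names(res$per_patient), function(p) {
    s <- res$per_patient[[p]]$sub
    data.frame(cell_id = names(s$labels), patient_id = p,
               subclone = as.character(s$labels), stringsAsFactors = FALSE)
  }))
  tsv(labels, "subclone_labels.tsv")

  states <- do.call(rbind, lapply(names(res$per_patient), function(p) {
    st <- res$per_patient[[p]]$sub$states[["1q"]]
    if (is.null(st)) st <- res$per_patient[[p]]$sub$states[[1]]
    data.frame(patient_id = p, subclone = names(st), state = as.character(st),
               arm_mean = as.numeric(attr(st, "arm_mean")),
               stringsAsFactors = FALSE)
  }))
  tsv(states, "arm_states.tsv")

  fr <- do.call(rbind, lapply(names(res$per_patient), function(p) {
    cf <- res$per_patient[[p]]$clone_fracs
    do.call(rbind, lapply(names(cf), function(tp)
      data.frame(patient_id = p, timepoint = tp, subclone = names(cf[[tp]]),
                 fraction = as.numeric(cf[[tp]]), stringsAsFactors = FALSE)))
  }))
  tsv(fr, "clone_fractions.tsv")

  stab <- data.frame(patient_id = names(res$per_patient),
                     stability = vapply(res$per_patient, `[[`,
                                        numeric(1), "stability"))
  tsv(stab, "clone_stability.tsv")
  tsv(res$sample_summary, "sample_summary.tsv")
  tsv(as.data.frame(res$signature), "signature_genes.tsv")
  if (!is.null(res$scores))
    tsv(data.frame(cell_id = names(res$scores),
                   score = as.numeric(res$scores)), "signature_scores.tsv")
  if (length(res$interactions)) {
    all_int <- do.call(rbind, lapply(names(res$interactions), function(s)
      cbind(sample_id = s, res$interactions[[s]])))
    tsv(all_int, "interactions.tsv")
    tsv(res$counts, "interaction_counts.tsv")
    tsv(res$strengths, "interaction_strengths.tsv")
    tsv(res$network$edges, "network_edges.tsv")
    tsv(res$network$nodes, "network_nodes.tsv")
  }
  if (!is.null(res$fractions)) tsv(res$fractions, "cell_type_fractions.tsv")
  if (!is.null(res$composition)) tsv(res$composition, "composition_compare.tsv")

  summary <- list(
    seed = res$seed,
    n_cells_qc = nrow(res$norm),
    n_signature_genes = nrow(res$signature),
    score_fraction_r = as.numeric(res$correlation),
    ppv = if (!is.null(res$ppv)) res$ppv$ppv else NA,
    mean_stability = mean(stab$stability, na.rm = TRUE))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
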