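#' @importFrom stats rlnorm rnbinom rbeta runif rnorm
NULL

#' Subclone specification for the cohort simulator
#'
#' @param name subclone label, unique within a patient.
#' @param fraction named numeric vector of clone fractions per timepoint
#'   (e.g. `c(pre = 0.7, post = 0.4)`); fractions over a patient's subclones
#'   must sum to 1 at every timepoint.
#' @param events list of CNA events, each `list(arm =, copy =)` or
#'   `list(chrom =, copy =)` with `copy` in 1:4 (2 = neutral).
#' @export
sim_subclone <- function(name, fraction, events = list()) {
  stopifnot(is.character(name), is.numeric(fraction), !is.null(names(fraction)))
  for (ev in events) stopifnot(ev$copy %in% 1:4)
  list(name = name, fraction = fraction, events = events)
}

#' Patient specification for the cohort simulator
#'
#' @param name patient id.
#' @param subclones list of [sim_subclone()] entries.
#' @param n_tumor named vector: tumor cells per timepoint.
#' @param n_reference normal plasma cells (genomically neutral), pooled into
#'   the cohort reference.
#' @param n_bme named vector: bone-marrow-microenvironment cells per cell
#'   type per timepoint (every configured BME type gets this many cells),
#'   or a single number applied to all timepoints.
#' @export
sim_patient <- function(name, subclones, n_tumor, n_reference = 100,
                        n_bme = 0) {
  fr <- do.call(rbind, lapply(subclones, `[[`, "fraction"))
  if (any(abs(colSums(fr) - 1) > 1e-9))
    stop(sprintf("patient %s: subclone fractions do not sum to 1", name))
  list(name = name, subclones = subclones, n_tumor = n_tumor,
       n_reference = n_reference, n_bme = n_bme)
}

#' Cohort simulator configuration
#'
#' Defines a toy genome (22 autosomes with declared arm boundaries plus a
#' mitochondrial contig), per-gene negative-binomial expression parameters,
#' tumor subclones with copy-number dosage effects, BME cell types with
#' marker genes, and planted ligand-receptor co-expression.
#'
#' Counts for cell c, gene g are drawn
#' `NB(mean = base_mean_g * dosage * marker_shift * lib_c, size = dispersion)`
#' where `dosage = 1 + response_g * (copy/2 - 1)` so a neutral region leaves
#' expression unchanged and a single-copy gain at full response scales the
#' mean by 1.5.
#'
#' @param seed integer RNG seed; the same config and seed reproduce the
#'   dataset bit-identically.
#' @param patients list of [sim_patient()].
#' @param n_genes autosomal panel size.
#' @param n_mito mitochondrial genes (named `MT-*`, high expression).
#' @param oneq_genes genes placed on chromosome arm 1q.
#' @param oneq_responsive how many 1q genes are guaranteed well-expressed
#'   so arm dosage is detectable; recorded as truth. Mirrors the fact that
#'   recurrent 1q signature genes are strongly expressed dosage responders.
#' @param responsive_floor base-mean floor applied to the responsive 1q
#'   genes (default 2 counts per cell before library scaling).
#' @param base_meanlog,base_sdlog log-normal base-mean distribution.
#' @param dispersion NB size parameter (scalar).
#' @param lib_sdlog log-normal spread of per-cell library-size factors.
#' @param dosage_response either 1 (all genes respond fully to copy number)
#'   or `list(a =, b =)` Beta parameters for per-gene attenuation.
#' @param bme_types named list of BME cell types: each
#'   `list(n_markers =, fold =)`; marker genes are drawn from non-chr1
#'   autosomal genes, disjoint across types.
#' @param lr_pairs optional ligand-receptor pair table as returned by
#'   [read_lr_pairs()]; its gene symbols are grafted onto non-chr1 panel
#'   slots so the pairs resolve against the simulated matrix.
#' @param lr_planted list of planted interactions:
#'   `list(pair_id =, sender =, receiver =, fold =)` referencing BME types.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, patients, n_genes = 2000, n_mito = 8,
                       oneq_genes = 120, oneq_responsive = 100,
                       responsive_floor = 2, base_meanlog = 0,
                       base_sdlog = 1, dispersion = 2, lib_sdlog = 0.3,
                       dosage_response = 1, bme_types = list(),
                       lr_pairs = NULL, lr_planted = list()) {
  structure(list(seed = as.integer(seed), patients = patients,
                 n_genes = n_genes, n_mito = n_mito,
                 oneq_genes = oneq_genes, oneq_responsive = oneq_responsive,
                 responsive_floor = responsive_floor,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 dispersion = dispersion, lib_sdlog = lib_sdlog,
                 dosage_response = dosage_response, bme_types = bme_types,
                 lr_pairs = lr_pairs, lr_planted = lr_planted),
            class = "SimConfig")
}

# Toy genome: chr1 gets a fixed 1q block; remaining autosomes share the rest.
# Positions only need ordering and arm membership, so genes sit on a 10-kb
# grid with the p/q boundary between the allotted p and q gene counts.
build_gene_panel <- function(cfg) {
  n_auto <- cfg$n_genes
  chr1_p <- 80
  rest <- n_auto - chr1_p - cfg$oneq_genes
  per_chrom <- rep(rest %/% 21, 21)
  per_chrom[seq_len(rest %% 21)] <- per_chrom[seq_len(rest %% 21)] + 1L
  counts <- c(chr1_p + cfg$oneq_genes, per_chrom)
  p_frac <- c(NA, ifelse(2:22 >= 13, 0.2, 0.4))  # chr1 handled explicitly

  rows <- list()
  gi <- 0L
  for (ch in 1:22) {
    n <- counts[ch]
    n_p <- if (ch == 1) chr1_p else max(1L, round(p_frac[ch] * n))
    ids <- sprintf("G%04d", gi + seq_len(n))
    gi <- gi + n
    start <- seq_len(n) * 10000
    rows[[ch]] <- data.frame(gene = ids, chrom = as.character(ch),
                             start = start, end = start + 5000,
                             n_p = n_p, stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, rows)
  arms <- do.call(rbind, lapply(1:22, function(ch) {
    n_p <- rows[[ch]]$n_p[1]
    data.frame(chrom = as.character(ch),
               arm = c("p", "q"),
               boundary = c((n_p + 0.5) * 10000, .Machine$integer.max),
               stringsAsFactors = FALSE)
  }))
  if (cfg$n_mito > 0) {
    mt <- data.frame(gene = paste0("MT-G", seq_len(cfg$n_mito)),
                     chrom = "MT", start = seq_len(cfg$n_mito) * 100,
                     end = seq_len(cfg$n_mito) * 100 + 50, n_p = 0,
                     stringsAsFactors = FALSE)
    panel <- rbind(panel, mt)
  }
  panel$n_p <- NULL
  list(order = gene_order(panel, arms), arms = arms)
}

# deterministic largest-remainder rounding of n into parts proportional to p
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  k <- floor(raw)
  extra <- order(raw - k, decreasing = TRUE)
  short <- n - sum(k)
  if (short > 0) k[extra[seq_len(short)]] <- k[extra[seq_len(short)]] + 1
  as.integer(k)
}

#' Simulate a cohort with planted ground truth
#'
#' @param cfg a [sim_config()].
#' @return a `SimulatedDataset` list: `em` (an [expression_matrix()] with
#'   per-cell `patient_id`, `timepoint`, `fraction`, `compartment`,
#'   `cell_type`, `sample_id` metadata), `gene_order`, `arms`, and `truth`
#'   (per-cell subclone labels, per-subclone CNA events, per-sample +1q
#'   fractions, responsive 1q genes, marker genes, planted interactions).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  withr::with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  genome <- build_gene_panel(cfg)
  go <- genome$order
  n_genes <- nrow(go)
  genes <- go$gene
  is_mito <- go$chrom == "MT"

  base_mean <- rlnorm(n_genes, cfg$base_meanlog, cfg$base_sdlog)
  names(base_mean) <- genes
  base_mean[is_mito] <- 5
  oneq <- genes[!is.na(go$arm) & go$arm == "1q"]
  responsive <- sort(sample(oneq, min(cfg$oneq_responsive, length(oneq))))
  base_mean[responsive] <- pmax(base_mean[responsive], cfg$responsive_floor)

  response <- if (is.list(cfg$dosage_response))
    rbeta(n_genes, cfg$dosage_response$a, cfg$dosage_response$b)
  else rep(cfg$dosage_response, n_genes)
  names(response) <- genes

  # graft LR gene symbols onto well-expressed non-chr1, non-mito slots
  lr_genes <- character(0)
  if (!is.null(cfg$lr_pairs)) {
    lr_genes <- unique(unlist(c(cfg$lr_pairs$ligand, cfg$lr_pairs$receptor)))
    host <- sample(genes[go$chrom != "1" & !is_mito], length(lr_genes))
    genes[match(host, genes)] <- lr_genes
    go$gene <- genes
    rownames(go) <- genes
    names(base_mean) <- names(response) <- genes
    base_mean[lr_genes] <- pmax(base_mean[lr_genes], 1)
  }

  # marker genes per BME type: disjoint, non-chr1, non-mito, not LR genes
  marker_pool <- setdiff(genes[go$chrom != "1" & !is_mito], lr_genes)
  markers <- list()
  for (ty in names(cfg$bme_types)) {
    m <- sample(marker_pool, cfg$bme_types[[ty]]$n_markers)
    markers[[ty]] <- m
    marker_pool <- setdiff(marker_pool, m)
    base_mean[m] <- pmax(base_mean[m], 0.5)
  }

  dosage_mult <- function(events) {
    mult <- rep(1, n_genes)
    for (ev in events) {
      sel <- if (!is.null(ev$arm)) !is.na(go$arm) & go$arm == ev$arm
             else go$chrom == as.character(ev$chrom)
      mult[sel] <- 1 + response[sel] * (ev$copy / 2 - 1)
    }
    mult
  }

  draw_block <- function(n_cells, mu_gene, prefix) {
    lib <- rlnorm(n_cells, 0, cfg$lib_sdlog)
    mu <- outer(lib, mu_gene)
    x <- rnbinom(length(mu), size = cfg$dispersion, mu = as.vector(mu))
    m <- matrix(x, nrow = n_cells, ncol = n_genes,
                dimnames = list(sprintf("%s_c%04d", prefix, seq_len(n_cells)),
                                genes))
    as(as(m, "CsparseMatrix"), "generalMatrix")
  }

  blocks <- list(); meta <- list(); truth_cells <- list()
  truth_subclones <- list(); truth_oneq <- list()

  for (pat in cfg$patients) {
    tps <- names(pat$n_tumor)
    for (tp in tps) {
      n_tum <- pat$n_tumor[[tp]]
      fr <- vapply(pat$subclones, function(s) s$fraction[[tp]], numeric(1))
      ns <- apportion(n_tum, fr)
      oneq_cells <- 0L
      for (j in seq_along(pat$subclones)) {
        sc <- pat$subclones[[j]]
        if (ns[j] == 0) next
        mu <- base_mean * dosage_mult(sc$events)
        pre <- sprintf("%s_%s_%s", pat$name, tp, sc$name)
        blocks[[pre]] <- draw_block(ns[j], mu, pre)
        gained_1q <- any(vapply(sc$events, function(ev)
          identical(ev$arm, "1q") && ev$copy > 2, logical(1)))
        if (gained_1q) oneq_cells <- oneq_cells + ns[j]
        meta[[pre]] <- data.frame(
          patient_id = pat$name, timepoint = tp, fraction = "CD138pos",
          compartment = "tumor", cell_type = "tumor",
          sample_id = paste0(pat$name, "_", tp),
          subclone = sc$name, stringsAsFactors = FALSE)
        truth_subclones[[paste0(pre, "_t")]] <- data.frame(
          patient_id = pat$name, timepoint = tp, subclone = sc$name,
          n_cells = ns[j], fraction = fr[j], oneq_gain = gained_1q,
          events = paste(vapply(sc$events, function(ev)
            sprintf("%s:%d", if (!is.null(ev$arm)) ev$arm else
                    paste0("chr", ev$chrom), ev$copy), character(1)),
            collapse = ";"),
          stringsAsFactors = FALSE)
      }
      truth_oneq[[paste0(pat$name, tp)]] <- data.frame(
        patient_id = pat$name, timepoint = tp,
        sample_id = paste0(pat$name, "_", tp),
        oneq_fraction = oneq_cells / n_tum, stringsAsFactors = FALSE)

      # BME cells for this sample
      n_bme <- if (length(pat$n_bme) > 1) pat$n_bme[[tp]] else pat$n_bme
      if (n_bme > 0 && length(cfg$bme_types) > 0) {
        for (ty in names(cfg$bme_types)) {
          mu <- base_mean
          mu[markers[[ty]]] <- mu[markers[[ty]]] * cfg$bme_types[[ty]]$fold
          for (pl in cfg$lr_planted) {
            pr <- cfg$lr_pairs[cfg$lr_pairs$pair_id == pl$pair_id, ]
            if (!nrow(pr)) next
            if (identical(pl$sender, ty))
              mu[pr$ligand[[1]]] <- mu[pr$ligand[[1]]] * pl$fold
            if (identical(pl$receiver, ty))
              mu[pr$receptor[[1]]] <- mu[pr$receptor[[1]]] * pl$fold
          }
          pre <- sprintf("%s_%s_%s", pat$name, tp, ty)
          blocks[[pre]] <- draw_block(n_bme, mu, pre)
          meta[[pre]] <- data.frame(
            patient_id = pat$name, timepoint = tp, fraction = "CD138neg",
            compartment = "bme", cell_type = ty,
            sample_id = paste0(pat$name, "_", tp),
            subclone = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
    if (pat$n_reference > 0) {
      pre <- sprintf("%s_ref", pat$name)
      blocks[[pre]] <- draw_block(pat$n_reference, base_mean, pre)
      meta[[pre]] <- data.frame(
        patient_id = pat$name, timepoint = "pre", fraction = "CD138pos",
        compartment = "reference", cell_type = "nPC",
        sample_id = paste0(pat$name, "_ref"),
        subclone = NA_character_, stringsAsFactors = FALSE)
    }
  }

  counts <- do.call(rbind, blocks)
  cell_meta <- do.call(rbind, lapply(names(blocks), function(b) {
    df <- meta[[b]][rep(1, nrow(blocks[[b]])), , drop = FALSE]
    rownames(df) <- rownames(blocks[[b]])
    df
  }))
  em <- expression_matrix(counts, cell_meta = cell_meta,
                          gene_meta = data.frame(mito = is_mito,
                                                 row.names = genes))
  structure(list(
    em = em, gene_order = go, arms = genome$arms,
    truth = list(
      cells = data.frame(cell_id = rownames(counts),
                         subclone = cell_meta$subclone,
                         cell_type = cell_meta$cell_type,
                         stringsAsFactors = FALSE),
      subclones = do.call(rbind, truth_subclones),
      oneq_fractions = do.call(rbind, truth_oneq),
      responsive_1q = responsive,
      gene_params = data.frame(gene = genes, base_mean = unname(base_mean),
                               response = unname(response),
                               row.names = genes, stringsAsFactors = FALSE),
      markers = markers,
      lr_planted = cfg$lr_planted),
    config = cfg), class = "SimulatedDataset")
}

#' Default cohort configuration
#'
#' Ten patients sampled pre and post treatment whose planted +1q clone
#' fractions span 0 to 1 across the three clinical groups (not-detected/rare
#' < 10 percent, subclonal 10-80 percent, dominant > 80 percent), each
#' patient carrying a private non-1q CNA so subclones differ beyond 1q.
#' Three BME cell types with marker genes and planted ligand-receptor
#' interactions are included.
#'
#' @param seed RNG seed.
#' @param n_tumor tumor cells per patient per timepoint.
#' @param n_reference reference normal plasma cells per patient.
#' @param n_bme BME cells per type per sample (0 disables BME simulation).
#' @param lr_pairs LR pair table; defaults to the packaged fixture when BME
#'   cells are simulated.
#' @param pre_frac planted +1q clone fractions pre-treatment, one per
#'   patient.
#' @param post_shift added to `pre_frac` (capped at 1) for the
#'   post-treatment fractions; clones expand or stay, as observed for +1q.
#' @export
default_cohort_config <- function(seed = 1L, n_tumor = 300,
                                  n_reference = 60, n_bme = 0,
                                  lr_pairs = NULL,
                                  pre_frac = c(0, 0.05, 0.12, 0.2, 0.35,
                                               0.5, 0.65, 0.8, 0.9, 1.0),
                                  post_shift = c(0, 0, 0.1, 0.15, 0.2,
                                                 0.2, 0.15, 0.1, 0.05, 0)) {
  post_frac <- pmin(1, pre_frac + post_shift)
  other_chrom <- c(3, 5, 7, 8, 9, 11, 13, 16, 19, 21)
  private_chrom <- c(4, 6, 10, 12, 14, 15, 17, 18, 20, 22)
  patients <- lapply(seq_along(pre_frac), function(i) {
    f1 <- c(pre = pre_frac[i], post = post_frac[i])
    subs <- list(
      sim_subclone("neutral", fraction = 1 - f1,
                   events = list(list(chrom = other_chrom[i], copy = 3))),
      # the +1q clone carries a private off-1q co-event, as expanding
      # subclones accumulate them; its dosage genes exercise the
      # signature's arm-location filter
      sim_subclone("oneq", fraction = f1,
                   events = list(list(arm = "1q", copy = 3),
                                 list(chrom = other_chrom[i], copy = 3),
                                 list(chrom = private_chrom[i], copy = 3))))
    # drop zero-fraction clones at both timepoints
    subs <- Filter(function(s) any(s$fraction > 0), subs)
    if (all(f1 == 1)) subs <- subs[vapply(subs, function(s)
      s$name == "oneq", logical(1))]
    sim_patient(sprintf("P%02d", i), subs,
                n_tumor = c(pre = n_tumor, post = n_tumor),
                n_reference = n_reference, n_bme = n_bme)
  })
  bme <- if (n_bme > 0) list(
    Tcell = list(n_markers = 15, fold = 4),
    NK = list(n_markers = 15, fold = 4),
    TAM = list(n_markers = 15, fold = 4)) else list()
  planted <- list()
  if (n_bme > 0) {
    if (is.null(lr_pairs)) lr_pairs <- read_lr_pairs(default_lr_path())
    planted <- list(
      list(pair_id = "IL18_IL18R", sender = "TAM", receiver = "NK", fold = 4),
      list(pair_id = "MIF_CD74", sender = "TAM", receiver = "Tcell", fold = 4))
  }
  sim_config(seed = seed, patients = patients, bme_types = bme,
             lr_pairs = lr_pairs, lr_planted = planted)
}

#' Subclone-recovery fixture configuration
#'
#' One patient, one timepoint, 2,000 tumor cells in three major clones at
#' fractions 0.5/0.3/0.2 differing by arm-level single-copy gains (dosage
#' 1.5), plus a planted 30-cell minor clone (below the 40-cell floor, so a
#' correct caller absorbs it), and 300 reference cells.
#'
#' @param seed RNG seed.
#' @param n_tumor tumor cells.
#' @param n_reference reference cells.
#' @export
subclone_fixture_config <- function(seed = 1L, n_tumor = 2000,
                                    n_reference = 300) {
  f_minor <- 30 / n_tumor
  f <- (1 - f_minor) * c(0.5, 0.3, 0.2)
  trunk <- list(list(arm = "9q", copy = 3))  # shared truncal gain
  pat <- sim_patient("P01", list(
    sim_subclone("clone1", c(pre = f[1]),
                 events = c(trunk, list(list(arm = "1q", copy = 3),
                                        list(arm = "3q", copy = 3)))),
    sim_subclone("clone2", c(pre = f[2]),
                 events = c(trunk, list(list(arm = "5q", copy = 3),
                                        list(arm = "13q", copy = 1)))),
    sim_subclone("clone3", c(pre = f[3]),
                 events = c(trunk, list(list(arm = "8q", copy = 1),
                                        list(arm = "16q", copy = 3)))),
    sim_subclone("minor", c(pre = f_minor),
                 events = c(trunk, list(list(arm = "11q", copy = 3))))),
    n_tumor = c(pre = n_tumor), n_reference = n_reference)
  sim_config(seed = seed, patients = list(pat))
}

#' Signature-recovery cohort configuration
#'
#' Ten patients whose +1q clone is subclonal at every timepoint (fractions
#' 0.25-0.55 pre, expanding post), so every patient contributes a
#' matched-clone comparison; each patient carries a private non-1q gain so
#' the closest 1q-neutral relative is non-trivial.
#'
#' @param seed RNG seed.
#' @param n_tumor tumor cells per patient per timepoint.
#' @param n_reference reference cells per patient.
#' @export
signature_cohort_config <- function(seed = 1L, n_tumor = 500,
                                    n_reference = 60) {
  default_cohort_config(seed = seed, n_tumor = n_tumor,
                        n_reference = n_reference,
                        pre_frac = seq(0.25, 0.55, length.out = 10),
                        post_shift = rep(0.1, 10))
}

#' Path of the packaged ligand-receptor pair fixture
#' @export
default_lr_path <- function() {
  system.file("extdata", "lr_pairs.csv", package = "cnasig", mustWork = TRUE)
}

#' Write the default simulated cohort to disk
#'
#' Writes the MTX/barcodes/features triplet, the cell-metadata TSV, the
#' gene-order and arm-boundary files, and the ground-truth tables used by
#' the test-suite and the analysis scripts.
#'
#' @param out_dir writable directory.
#' @param cfg simulation config (defaults to [default_cohort_config()]).
#' @return invisibly, a named list of the written paths.
#' @export
make_default_fixtures <- function(out_dir, cfg = default_cohort_config()) {
  sim <- simulate_cohort(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(sim$em, out_dir)
  meta <- cbind(cell_id = rownames(sim$em$counts), sim$em$cell_meta)
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list(
    matrix = file.path(out_dir, "matrix.mtx"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    features = file.path(out_dir, "features.tsv"),
    cell_meta = tsv(meta, "cell_meta.tsv"),
    truth_subclones = tsv(sim$truth$subclones, "truth_subclones.tsv"),
    truth_oneq = tsv(sim$truth$oneq_fractions, "truth_oneq_fractions.tsv"),
    gene_order = file.path(out_dir, "gene_order.tsv"),
    arms = file.path(out_dir, "arm_boundaries.tsv"))
  write_gene_order(sim$gene_order, paths$gene_order, paths$arms, sim$arms)
  invisible(paths)
}
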