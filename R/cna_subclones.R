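#' @importFrom stats hclust cutree dist as.dendrogram
NULL

#' Infer per-cell CNA profiles from expression
#'
#' Expression-based copy-number inference against a normal reference in the
#' style of moving-average CNA tools: lowly expressed genes are dropped, each
#' gene is centred on the reference mean, residuals are clipped, a
#' genome-ordered moving average smooths per-cell signal within chromosomes,
#' and each cell is recentred on its median. Neutral regions end up near 0,
#' a single-copy gain near `log(1.5)` times the responding fraction.
#'
#' @param norm cells x genes log-normalized matrix ([normalize_log()]).
#' @param order a `GeneOrder` covering (a superset of) the genes.
#' @param reference_cells character ids of normal cells (>= 30 required).
#' @param mean_cutoff genes with mean normalized expression below this across
#'   all cells are dropped before smoothing.
#' @param window odd moving-average span in genes; shrinks symmetrically at
#'   chromosome ends and never crosses a chromosome boundary.
#' @param clip_sd residuals clipped to this many reference SDs per gene.
#' @param regress_depth regress out a per-cell library-complexity covariate
#'   (the cell's mean normalized expression over retained genes) with
#'   per-gene slopes fitted on the reference cells. Log-normalization
#'   leaves a depth-dependent detection artifact that is correlated across
#'   genes and otherwise dominates cell-cell distances.
#' @param exclude_chroms chromosomes excluded from the profile (the
#'   mitochondrial contig by default).
#' @return a `CNAProfileMatrix`: list with `signal` (cells x retained genes,
#'   genome-ordered), `genes` (retained rows of `order`), `window`,
#'   `reference_ids`.
#' @export
infer_cna_profiles <- function(norm, order, reference_cells,
                               mean_cutoff = 0.1, window = 101,
                               clip_sd = 3, regress_depth = TRUE,
                               exclude_chroms = "MT") {
  stopifnot(window %% 2 == 1)
  if (length(reference_cells) < 30)
    stop(sprintf("need >= 30 reference cells, got %d", length(reference_cells)))
  if (!all(reference_cells %in% rownames(norm)))
    stop("reference cells missing from the matrix")
  order <- order[order$gene %in% colnames(norm) &
                 !(order$chrom %in% exclude_chroms), , drop = FALSE]
  x <- as.matrix(norm[, order$gene, drop = FALSE])

  keep <- colMeans(x) >= mean_cutoff
  if (sum(keep) < 2 * window)
    stop(sprintf("only %d genes pass mean_cutoff; need >= %d",
                 sum(keep), 2 * window))
  x <- x[, keep, drop = FALSE]
  order <- order[keep, , drop = FALSE]

  ref <- x[reference_cells, , drop = FALSE]
  mu <- colMeans(ref)
  x <- sweep(x, 2, mu)
  if (regress_depth) {
    v <- rowMeans(x)
    vc <- v - mean(v[reference_cells])
    design <- cbind(1, vc, vc^2)
    fit <- design[reference_cells, , drop = FALSE]
    beta <- solve(crossprod(fit),
                  crossprod(fit, x[reference_cells, , drop = FALSE]))
    x <- x - design %*% beta
    # the intercept row restores exact zero reference means per gene
  }
  ref <- x[reference_cells, , drop = FALSE]
  sd_ref <- apply(ref, 2, sd)
  sd_ref[sd_ref == 0] <- mean(sd_ref[sd_ref > 0])
  lim <- clip_sd * sd_ref
  x <- pmin(pmax(x, rep(-lim, each = nrow(x))), rep(lim, each = nrow(x)))

  res <- x
  x <- smooth_by_chrom(x, order$chrom, window)
  x <- x - apply(x, 1, median)

  structure(list(signal = x, residuals = res, genes = order,
                 window = window, reference_ids = reference_cells),
            class = "CNAProfileMatrix")
}

smooth_by_chrom <- function(x, chroms, window) {
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    x[, idx] <- smooth_window(x[, idx, drop = FALSE], window)
  }
  x
}

# centred moving average along columns with a symmetric window that shrinks
# near the edges: position i averages i-h..i+h, h = min(half, i-1, m-i)
smooth_window <- function(x, window) {
  m <- ncol(x)
  half <- (window - 1) / 2
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  h <- pmin(half, seq_len(m) - 1, m - seq_len(m))
  lo <- seq_len(m) - h
  hi <- seq_len(m) + h
  (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(2 * h + 1, each = nrow(x))
}

#' @export
print.CNAProfileMatrix <- function(x, ...) {
  cat(sprintf("CNAProfileMatrix: %d cells x %d genes, window %d, %d reference cells\n",
              nrow(x$signal), ncol(x$signal), x$window, length(x$reference_ids)))
  invisible(x)
}

#' Call tumor subclones by dendrogram cutting
#'
#' Partitions non-reference cells into genomically distinct subclones in
#' three stages. (1) Cells are hierarchically clustered (Euclidean, Ward
#' linkage by default) on CNA profiles built from the even-indexed genes
#' along the genome, and the dendrogram is cut into fine clusters (about
#' one per `min_cells` cells). (2) Clusters are merged back together while
#' no chromosome arm distinguishes them. Because a CNA spans a whole arm,
#' the held-out odd-indexed genes carry the same dosage signal but
#' independent noise, so testing arm differences on them is free of the
#' selection bias that otherwise makes noise-driven clusters look
#' distinct: a pair of clusters stays separate only if some arm's
#' mean-signal difference on held-out genes exceeds `delta_min` (an effect
#' floor of about half a single-copy dosage shift) and lies `z_crit`
#' standard errors from zero, with per-cell arm-signal SDs taken from the
#' reference cells. (3) Clusters still smaller than `min_cells` are
#' absorbed into their nearest cluster by mean-profile distance — planted
#' minor clones below the floor end up inside their closest relative — and
#' a final centroid reassignment pass cleans up the boundaries (in
#' centroid comparisons the noise dimensions shared by all clusters
#' cancel, so cells classify along the arms that actually differ).
#' Genomically homogeneous cohorts collapse back to a single subclone.
#'
#' @param cna a `CNAProfileMatrix`.
#' @param linkage `hclust` method; "ward" maps to "ward.D2".
#' @param min_cells minimum cells per subclone.
#' @param delta_min minimum arm-level mean-signal difference for two
#'   clusters to count as different subclones.
#' @param z_crit minimum z-score (difference over its standard error) for
#'   that arm difference.
#' @return a `SubcloneSet`: per-cell `labels` (factor "S1".. in decreasing
#'   size), `profiles` (subclone x gene mean signal), `n_cells`, `hclust`
#'   (the linkage record), `states` (filled by [call_region_state()]).
#' @export
call_subclones <- function(cna, linkage = "ward", min_cells = 40,
                           delta_min = 0.15, z_crit = 5) {
  if (linkage == "ward") linkage <- "ward.D2"
  cells <- setdiff(rownames(cna$signal), cna$reference_ids)
  x <- cna$signal[cells, , drop = FALSE]
  if (length(cells) < min_cells)
    warning("fewer cells than min_cells; returning a single subclone")
  hc <- NULL
  raw <- if (length(cells) < 2 * min_cells)
    rep(1L, length(cells))
  else {
    g <- nrow(cna$genes)
    even <- seq(1, g, by = 2)
    odd <- seq(2, g, by = 2)
    w_half <- max(3L, (cna$window %/% 2) %/% 2 * 2 + 1L)
    half_sig <- smooth_by_chrom(cna$residuals[, even, drop = FALSE],
                                cna$genes$chrom[even], w_half)
    half_sig <- half_sig - apply(half_sig, 1, median)
    hc <- hclust(dist(half_sig[cells, , drop = FALSE]), method = linkage)
    arm_feat <- arm_features(cna$residuals[, odd, drop = FALSE],
                             cna$genes$arm[odd], cna$genes$chrom[odd],
                             min_genes = 10)
    ref_sd <- apply(arm_feat[cna$reference_ids, , drop = FALSE], 2, sd)
    # fine initial cut at about half the reporting floor per cluster, so
    # clones barely above min_cells still land in (mergeable) pieces
    k0 <- max(2L, min(length(cells) %/% (min_cells %/% 2), 60L))
    cl <- cutree(hc, k = k0)
    cl <- refine_assignments(cl, half_sig[cells, , drop = FALSE])
    # alternate gating, size-floor absorption and refinement to a fixed
    # point: refinement can move cells between clusters, after which a
    # pair may no longer be distinguishable and must merge (later rounds
    # only ever merge, so the selection-free guarantee of the first
    # held-out test is preserved)
    for (round in 1:4) {
      cl_new <- arm_gated_merge(cl, arm_feat[cells, , drop = FALSE],
                                ref_sd, delta_min, z_crit)
      cl_new <- dissolve_mixtures(cl_new, arm_feat[cells, , drop = FALSE],
                                  arm_feat[cna$reference_ids, , drop = FALSE],
                                  ref_sd, delta_min, z_crit)
      cl_new <- merge_small_clusters(cl_new, x, min_cells)
      cl_new <- refine_assignments(cl_new, x)
      if (identical(cl_new, cl)) break
      cl <- cl_new
    }
    cl
  }
  # relabel by decreasing size, ties by first appearance
  sizes <- table(raw)
  new_ids <- sprintf("S%d", seq_along(sizes))
  rank_map <- new_ids[rank(-as.numeric(sizes), ties.method = "first")]
  labels <- factor(rank_map[match(raw, as.integer(names(sizes)))],
                   levels = new_ids)
  names(labels) <- cells
  profiles <- do.call(rbind, lapply(levels(labels), function(l)
    colMeans(x[labels == l, , drop = FALSE])))
  rownames(profiles) <- levels(labels)
  structure(list(labels = labels, profiles = profiles,
                 n_cells = as.integer(table(labels)),
                 genes = cna$genes, min_cells = min_cells,
                 reference_ids = cna$reference_ids,
                 cna = cna, hclust = hc, states = NULL),
            class = "SubcloneSet")
}

# per-cell mean signal per chromosome arm (falls back to whole chromosomes
# where no arm annotation exists); arms with fewer than min_genes columns
# are dropped — their means are too artifact-prone to distinguish clones
arm_features <- function(x, arm, chrom, min_genes = 1) {
  arm[is.na(arm)] <- chrom[is.na(arm)]
  arms <- names(which(table(arm) >= min_genes))
  out <- vapply(arms, function(a)
    rowMeans(x[, arm == a, drop = FALSE]), numeric(nrow(x)))
  rownames(out) <- rownames(x)
  out
}

# Separation of two clusters' arm-mean profiles. The per-cell amplitude of
# the log-scale dosage signal varies with library depth, so one clone's
# depth strata show the same CNA pattern at different intensity; magnitude
# differences on a shared aberrant arm therefore never separate clusters.
# What separates them is a state contrast with hysteresis: some arm must be
# clearly aberrant in one cluster (|mean| > delta_min), clearly neutral in
# the other (|mean| < delta_min / 2) or aberrant in the opposite direction,
# and the difference must exceed z_crit standard errors.
pair_separation <- function(ci, cj, ni, nj, ref_sd, delta_min) {
  se <- ref_sd * sqrt(1 / ni + 1 / nj)
  z <- abs(ci - cj) / se
  active_i <- abs(ci) > delta_min
  active_j <- abs(cj) > delta_min
  contrast <- (active_i & abs(cj) < delta_min / 2) |
              (active_j & abs(ci) < delta_min / 2) |
              (active_i & active_j & sign(ci) * sign(cj) < 0)
  if (!any(contrast)) 0 else max(z[contrast])
}

# merge clusters until every remaining pair is separated by at least one
# chromosome arm; deterministic: always merges the least-separated pair
arm_gated_merge <- function(cl, arm_feat, ref_sd, delta_min, z_crit) {
  ref_sd[ref_sd == 0] <- mean(ref_sd[ref_sd > 0])
  repeat {
    ids <- sort(unique(cl))
    if (length(ids) <= 1) break
    cent <- do.call(rbind, lapply(ids, function(l)
      colMeans(arm_feat[cl == l, , drop = FALSE])))
    n <- as.numeric(table(factor(cl, levels = ids)))
    best <- Inf; pair <- NULL
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1):length(ids)) {
      sep <- pair_separation(cent[i, ], cent[j, ], n[i], n[j],
                             ref_sd, delta_min)
      if (sep < best) { best <- sep; pair <- c(i, j) }
    }
    if (best >= z_crit) break
    cl[cl == ids[pair[2]]] <- ids[pair[1]]
  }
  cl
}

# centroid-reassignment refinement of a cluster assignment (k-means step
# seeded by the dendrogram cut): differences of centroid distances cancel
# the noise dimensions shared by all clusters, so cells are classified
# along the directions that actually separate the clones
refine_assignments <- function(cl, x, max_iter = 20) {
  for (it in seq_len(max_iter)) {
    ids <- sort(unique(cl))
    if (length(ids) <= 1) break
    cent <- do.call(rbind, lapply(ids, function(l)
      colMeans(x[cl == l, , drop = FALSE])))
    d2 <- -2 * x %*% t(cent) +
      rep(rowSums(cent^2), each = nrow(x))
    new_cl <- ids[max.col(-d2, ties.method = "first")]
    if (all(new_cl == cl)) break
    cl <- new_cl
  }
  cl
}

# Dissolve chimeric clusters: refinement can stabilise a cluster that is
# really a mixture of two clones (its centroid shows both clones' events
# at partial amplitude, making it "distinct" from each parent). A cluster
# is dissolved when (a) no arm distinguishes its centroid from the best
# convex combination of two other centroids and (b) its cells are spread
# along the parents' separation axis far beyond reference noise (a
# genuine ancestral clone with an intermediate pattern is unimodal and
# survives (b)). Dissolved cells go to the nearest other centroid.
dissolve_mixtures <- function(cl, arm_feat, ref_feat, ref_sd, delta_min,
                              z_crit) {
  repeat {
    ids <- sort(unique(cl))
    if (length(ids) < 3) break
    cent <- do.call(rbind, lapply(ids, function(l)
      colMeans(arm_feat[cl == l, , drop = FALSE])))
    rownames(cent) <- ids
    n <- as.numeric(table(factor(cl, levels = ids)))
    changed <- FALSE
    for (i in order(n)) {
      if (n[i] < 5) next  # too few cells to assess; size floor handles it
      others <- setdiff(seq_along(ids), i)
      for (j in others) for (k in others) {
        if (changed || j >= k) next
        d <- cent[j, ] - cent[k, ]
        if (sum(d^2) < 1e-12) next
        alpha <- min(1, max(0, sum((cent[i, ] - cent[k, ]) * d) / sum(d^2)))
        r <- abs(cent[i, ] - (alpha * cent[j, ] + (1 - alpha) * cent[k, ]))
        se <- ref_sd * sqrt(1 / n[i])
        if (any(r > delta_min & r / se > z_crit)) next
        u <- d / sqrt(sum(d^2))
        spread <- var(as.numeric(arm_feat[cl == ids[i], , drop = FALSE] %*% u))
        ref_spread <- var(as.numeric(ref_feat %*% u))
        if (spread > 2 * ref_spread) {
          members <- which(cl == ids[i])
          d2 <- -2 * arm_feat[members, , drop = FALSE] %*%
            t(cent[others, , drop = FALSE]) +
            rep(rowSums(cent[others, , drop = FALSE]^2), each = length(members))
          cl[members] <- as.integer(ids[others[max.col(-d2, "first")]])
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  cl
}

# merge clusters below the size floor into their nearest cluster by mean
# CNA profile (Euclidean), smallest cluster first
merge_small_clusters <- function(cl, x, min_cells) {
  repeat {
    sizes <- table(cl)
    if (length(sizes) <= 1 || min(sizes) >= min_cells) break
    small <- names(sizes)[order(as.numeric(sizes),
                                as.integer(names(sizes)))][1]
    cent <- do.call(rbind, lapply(names(sizes), function(l)
      colMeans(x[cl == l, , drop = FALSE])))
    rownames(cent) <- names(sizes)
    others <- setdiff(names(sizes), small)
    d <- sqrt(rowSums(sweep(cent[others, , drop = FALSE], 2,
                            cent[small, ])^2))
    cl[cl == as.integer(small)] <- as.integer(others[which.min(d)])
  }
  cl
}

#' @export
print.SubcloneSet <- function(x, ...) {
  cat(sprintf("SubcloneSet: %d subclones over %d cells (min %d cells/clone)\n",
              nlevels(x$labels), length(x$labels), x$min_cells))
  print(table(x$labels))
  invisible(x)
}

#' Call per-subclone gain/neutral/loss state of a chromosome arm
#'
#' A subclone is called gained (lost) on an arm when its mean smoothed
#' signal over the arm's genes exceeds `gain_thresh` (falls below
#' `loss_thresh`). Default thresholds are +/- 3 SDs of the reference cells'
#' arm means — the reference defines what "neutral" fluctuation looks like.
#'
#' @param sub a `SubcloneSet`.
#' @param arm arm label as in the gene order (e.g. "1q").
#' @param gain_thresh,loss_thresh explicit thresholds; NULL = +/-3 reference SD.
#' @param sd_mult multiplier for the reference-SD default thresholds.
#' @return the `SubcloneSet` with `$states[[arm]]` set: a named character
#'   vector over subclones with values in gain/neutral/loss, plus attributes
#'   `gain_thresh`/`loss_thresh`.
#' @export
call_region_state <- function(sub, arm = "1q", gain_thresh = NULL,
                              loss_thresh = NULL, sd_mult = 3) {
  idx <- which(!is.na(sub$genes$arm) & sub$genes$arm == arm)
  if (!length(idx)) stop(sprintf("arm %s not present in the gene order", arm))
  if (length(idx) < 10)
    stop(sprintf("arm %s has only %d retained genes (need >= 10)", arm, length(idx)))
  ref_means <- rowMeans(sub$cna$signal[sub$reference_ids, idx, drop = FALSE])
  s <- sd(ref_means)
  if (is.null(gain_thresh)) gain_thresh <- sd_mult * s
  if (is.null(loss_thresh)) loss_thresh <- -sd_mult * s
  arm_mean <- rowMeans(sub$profiles[, idx, drop = FALSE])
  state <- ifelse(arm_mean > gain_thresh, "gain",
                  ifelse(arm_mean < loss_thresh, "loss", "neutral"))
  names(state) <- rownames(sub$profiles)
  attr(state, "gain_thresh") <- gain_thresh
  attr(state, "loss_thresh") <- loss_thresh
  attr(state, "arm_mean") <- arm_mean
  sub$states[[arm]] <- state
  sub
}

#' Fraction of tumor cells in arm-gained subclones
#'
#' @param sub a `SubcloneSet` with states called for `arm`.
#' @param arm arm label.
#' @return cells in gain-state subclones / all non-reference tumor cells.
#' @export
fraction_aberrant_cells <- function(sub, arm = "1q") {
  state <- sub$states[[arm]]
  if (is.null(state)) stop("call_region_state() has not been run for this arm")
  gained <- names(state)[state == "gain"]
  sum(sub$labels %in% gained) / length(sub$labels)
}

#' Classify a sample's +1q group from its aberrant-cell fraction
#'
#' Groups follow the clinical convention: not-detected/rare below 10
#' percent, dominant above 80 percent, subclonal in between (boundaries 0.1
#' and 0.8 belong to the subclonal band).
#'
#' @param fraction fraction of +1q cells in `[0,1]` (vectorised).
#' @return factor with levels `ND_rare`, `subclonal`, `dominant`.
#' @export
classify_1q_group <- function(fraction) {
  if (any(is.na(fraction) | fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]")
  out <- ifelse(fraction < 0.10, "ND_rare",
                ifelse(fraction > 0.80, "dominant", "subclonal"))
  factor(out, levels = c("ND_rare", "subclonal", "dominant"))
}

#' Find the closest relative of a subclone without gain on an arm
#'
#' Among subclones not called "gain" on `exclude_arm`, returns the one whose
#' mean CNA profile (computed over genes outside the arm) is nearest in
#' Euclidean distance to the target — the matched comparator for
#' clone-versus-clone differential expression. Ties break to the
#' alphabetically lower label.
#'
#' @param sub a `SubcloneSet` with states called for `exclude_arm`.
#' @param target subclone id whose relative is sought.
#' @param exclude_arm arm excluded from the distance and used for the
#'   gain filter.
#' @return a subclone id.
#' @export
match_closest_clone <- function(sub, target, exclude_arm = "1q") {
  state <- sub$states[[exclude_arm]]
  if (is.null(state)) stop("call_region_state() has not been run for this arm")
  stopifnot(target %in% rownames(sub$profiles))
  candidates <- setdiff(names(state)[state != "gain"], target)
  if (!length(candidates))
    stop(sprintf("no %s-neutral comparator clone exists", exclude_arm))
  keep <- is.na(sub$genes$arm) | sub$genes$arm != exclude_arm
  p <- sub$profiles[, keep, drop = FALSE]
  d <- sqrt(colSums((t(p[candidates, , drop = FALSE]) - p[target, ])^2))
  candidates[order(d, candidates)][1]
}

#' Clone-stability score of pre/post clonal composition
#'
#' For every subclone in the union of the two timepoints, the ratio of its
#' minor to its major fraction is computed (a clone absent at one timepoint
#' contributes 0); the score is the mean ratio over those N clones. 1 means
#' an unchanged clonal composition, 0 complete turnover.
#'
#' @param pre,post named numeric vectors of clone fractions (each summing
#'   to 1 over its clones).
#' @return score in `[0, 1]`.
#' @export
clone_stability_score <- function(pre, post) {
  clones <- union(names(pre), names(post))
  if (!length(clones)) stop("no clones given")
  f_pre <- ifelse(clones %in% names(pre), pre[clones], 0)
  f_post <- ifelse(clones %in% names(post), post[clones], 0)
  keep <- pmax(f_pre, f_post) > 0
  if (!any(keep)) stop("all clone fractions are zero")
  ratios <- pmin(f_pre[keep], f_post[keep]) / pmax(f_pre[keep], f_post[keep])
  mean(ratios)
}

#' Per-sample clone-fraction table from subclone labels
#'
#' @param sub a `SubcloneSet`.
#' @param sample_ids per-cell sample id aligned with `names(sub$labels)`
#'   (e.g. patient x timepoint).
#' @return data.frame (sample_id, subclone, n, fraction); fractions sum to 1
#'   within each sample.
#' @export
clone_fractions <- function(sub, sample_ids) {
  stopifnot(length(sample_ids) == length(sub$labels))
  tab <- table(sample_id = sample_ids, subclone = sub$labels)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  colnames(df)[3] <- "n"
  totals <- tapply(df$n, df$sample_id, sum)
  df$fraction <- df$n / as.numeric(totals[df$sample_id])
  df[order(df$sample_id, df$subclone), , drop = FALSE]
}
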