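#' @importFrom stats pnorm wilcox.test p.adjust cor.test
NULL

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Genes expressed in at least `min_pct` of either group are tested with a
#' two-sided Wilcoxon rank-sum test (exact enumeration when the two groups
#' together hold at most 20 cells and no ties occur; otherwise the normal
#' approximation with tie correction and continuity correction). P-values
#' are Bonferroni-adjusted over the tested genes. The log fold change uses
#' the common single-cell convention on log-normalized values `v`:
#' `logFC = ln[(mean(exp(v_a)-1)+1) / (mean(exp(v_b)-1)+1)]`.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param cells_a,cells_b cell ids of the two groups (>= 3 cells each).
#' @param alpha significance level on the adjusted p-value.
#' @param min_logfc absolute logFC required for significance.
#' @param min_pct minimum expressing fraction in either group for a gene to
#'   be tested.
#' @return a `DETable` data.frame: gene, pct_a, pct_b, logfc, p, p_adj,
#'   direction ("up" = higher in group A), significant.
#' @export
differential_expression <- function(norm, cells_a, cells_b, alpha = 0.05,
                                    min_logfc = 0.1, min_pct = 0.1) {
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop("both groups need >= 3 cells")
  a <- as.matrix(norm[cells_a, , drop = FALSE])
  b <- as.matrix(norm[cells_b, , drop = FALSE])
  pct_a <- colMeans(a > 0)
  pct_b <- colMeans(b > 0)
  test <- pct_a >= min_pct | pct_b >= min_pct
  a <- a[, test, drop = FALSE]
  b <- b[, test, drop = FALSE]

  logfc <- log((colMeans(expm1(a)) + 1) / (colMeans(expm1(b)) + 1))
  n_a <- nrow(a); n_b <- nrow(b); n <- n_a + n_b
  if (n <= 20) {
    p <- vapply(seq_len(ncol(a)), function(j)
      suppressWarnings(wilcox.test(a[, j], b[, j], exact = TRUE)$p.value),
      numeric(1))
  } else {
    p <- rank_sum_p(rbind(a, b), seq_len(n_a))
  }
  p_adj <- pmin(1, p * ncol(a))
  out <- data.frame(gene = colnames(a),
                    pct_a = pct_a[test], pct_b = pct_b[test],
                    logfc = logfc, p = p, p_adj = p_adj,
                    direction = ifelse(logfc >= 0, "up", "down"),
                    significant = p_adj < alpha & abs(logfc) > min_logfc,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$gene
  class(out) <- c("DETable", "data.frame")
  out
}

# vectorised two-sided rank-sum p over matrix columns; normal approximation
# with tie and continuity correction (the large-sample path of wilcox.test)
rank_sum_p <- function(x, idx_a) {
  n <- nrow(x); n_a <- length(idx_a); n_b <- n - n_a
  vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])
    w <- sum(r[idx_a]) - n_a * (n_a + 1) / 2
    ties <- table(x[, j])
    sigma2 <- (n_a * n_b / 12) *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- w - n_a * n_b / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-abs(z)))
  }, numeric(1))
}

#' Derive a recurrence-filtered, arm-restricted upregulation signature
#'
#' From per-patient matched-clone DE tables (each comparing an arm-gained
#' clone to its closest relative without the gain), keeps genes
#' significantly upregulated in at least `min_recurrence` patients that lie
#' on the restriction arm and are not mitochondrially encoded.
#'
#' @param per_patient_results named list of `DETable`s, one per contributing
#'   patient.
#' @param min_recurrence minimum number of patients with significant
#'   upregulation.
#' @param order a `GeneOrder` with arm annotation.
#' @param arm restriction arm (membership required).
#' @param mito_prefix gene prefix marking mitochondrially encoded genes.
#' @return a `SignatureGeneSet` data.frame (gene, recurrence), ordered by
#'   decreasing recurrence then gene id, with attributes `arm` and
#'   `n_patients`.
#' @export
derive_signature <- function(per_patient_results, min_recurrence = 5,
                             order, arm = "1q", mito_prefix = "MT-") {
  if (length(per_patient_results) < min_recurrence) {
    warning(sprintf("only %d contributing patients (< min_recurrence = %d); empty signature",
                    length(per_patient_results), min_recurrence))
  }
  up <- lapply(per_patient_results, function(de)
    de$gene[de$significant & de$logfc > 0])
  counts <- table(unlist(up))
  keep <- as.character(names(counts)[counts >= min_recurrence])
  on_arm <- rownames(order)[!is.na(order$arm) & order$arm == arm]
  keep <- keep[keep %in% on_arm & !startsWith(keep, mito_prefix)]
  rec <- as.integer(counts[keep])
  ord <- base::order(-rec, keep)
  out <- data.frame(gene = keep[ord], recurrence = rec[ord],
                    stringsAsFactors = FALSE)
  attr(out, "arm") <- arm
  attr(out, "n_patients") <- length(per_patient_results)
  class(out) <- c("SignatureGeneSet", "data.frame")
  out
}

#' Per-cell module score with expression-bin-matched controls
#'
#' Seurat-style module scoring: genes are binned into `n_bins` by their
#' average expression across cells; for each signature gene, `n_ctrl`
#' control genes are drawn (with replacement) from its bin excluding
#' signature genes, and the score is the mean signature expression minus
#' the mean over the pooled control draws. A random gene set therefore
#' scores ~0 regardless of its expression level. When a bin holds no
#' non-signature gene, all its genes serve as controls unsampled (so a
#' signature scored against only itself is exactly 0).
#'
#' @param norm cells x genes log-normalized matrix.
#' @param genes a `SignatureGeneSet` or character vector of gene ids.
#' @param n_bins expression bins.
#' @param n_ctrl control genes drawn per signature gene.
#' @param seed RNG seed fixing the control draw.
#' @return numeric per-cell score vector (named), with attributes `n_bins`,
#'   `n_ctrl`, `seed`, `genes_used`.
#' @export
score_signature <- function(norm, genes, n_bins = 24, n_ctrl = 100,
                            seed = 1L) {
  if (inherits(genes, "SignatureGeneSet")) genes <- genes$gene
  genes <- intersect(genes, colnames(norm))
  if (!length(genes)) stop("no signature gene present in the matrix")
  avg <- Matrix::colMeans(norm)
  n_genes <- length(avg)
  bins <- ceiling(rank(avg, ties.method = "first") * n_bins / n_genes)
  names(bins) <- colnames(norm)

  ctrl_weights <- withr::with_seed(seed, {
    w <- numeric(n_genes); names(w) <- colnames(norm)
    for (g in genes) {
      pool <- names(bins)[bins == bins[g]]
      eligible <- setdiff(pool, genes)
      if (length(eligible)) {
        draw <- sample(eligible, n_ctrl, replace = TRUE)
        tab <- table(draw)
        w[names(tab)] <- w[names(tab)] + as.numeric(tab)
      } else {
        w[pool] <- w[pool] + n_ctrl / length(pool)
      }
    }
    w
  })
  sig_score <- Matrix::rowMeans(norm[, genes, drop = FALSE])
  used <- ctrl_weights > 0
  ctrl_score <- as.numeric(norm[, used, drop = FALSE] %*% ctrl_weights[used]) /
    sum(ctrl_weights)
  out <- sig_score - ctrl_score
  names(out) <- rownames(norm)
  attr(out, "n_bins") <- n_bins
  attr(out, "n_ctrl") <- n_ctrl
  attr(out, "seed") <- seed
  attr(out, "genes_used") <- genes
  out
}

#' Positive predictive value of score-thresholded calls
#'
#' Cells with `score >= threshold` are called positive; PPV = TP/(TP+FP)
#' against a per-cell truth (e.g. membership in a CNA-called +1q clone).
#'
#' @param scores per-cell numeric scores.
#' @param truth per-cell logical truth, aligned with `scores`.
#' @param threshold score cutoff (inclusive).
#' @return list(ppv, tp, fp, n_positive); ppv is NaN when nothing is called.
#' @export
evaluate_ppv <- function(scores, truth, threshold) {
  stopifnot(length(scores) == length(truth), !any(is.na(truth)))
  pos <- scores >= threshold
  tp <- sum(pos & truth)
  fp <- sum(pos & !truth)
  list(ppv = if (tp + fp == 0) NaN else tp / (tp + fp),
       tp = tp, fp = fp, n_positive = tp + fp)
}

#' Pearson correlation of per-sample mean score against aberrant fraction
#'
#' @param sample_scores per-sample mean signature score.
#' @param sample_fractions per-sample aberrant-cell fraction, same order.
#' @return Pearson r (numeric scalar) with attribute `p` from [cor.test()].
#' @export
score_fraction_correlation <- function(sample_scores, sample_fractions) {
  stopifnot(length(sample_scores) == length(sample_fractions))
  if (length(sample_scores) < 3) stop("need >= 3 samples")
  if (sd(sample_scores) == 0 || sd(sample_fractions) == 0)
    stop("zero variance in scores or fractions")
  ct <- cor.test(sample_scores, sample_fractions, method = "pearson")
  r <- unname(ct$estimate)
  attr(r, "p") <- ct$p.value
  r
}
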