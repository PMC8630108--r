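#' Per-sample cell-type fraction table
#'
#' Within each sample, cell types with fewer than `min_cells` cells are
#' dropped (lowly abundant populations are unstable denominators) and
#' fractions are renormalized over the retained types.
#'
#' @param labels per-cell type labels.
#' @param sample_ids per-cell sample ids, same length.
#' @param min_cells abundance floor per sample.
#' @param renormalize divide by the retained-cell total (TRUE) or the full
#'   sample total (FALSE).
#' @return a `FractionTable` data.frame (sample_id, cell_type, n, fraction).
#'   Samples with no retained cells are dropped with a warning.
#' @export
compute_fractions <- function(labels, sample_ids, min_cells = 5,
                              renormalize = TRUE) {
  stopifnot(length(labels) == length(sample_ids))
  tab <- as.data.frame(table(sample_id = as.character(sample_ids),
                             cell_type = as.character(labels)),
                       stringsAsFactors = FALSE)
  colnames(tab)[3] <- "n"
  full_totals <- tapply(tab$n, tab$sample_id, sum)
  tab <- tab[tab$n >= min_cells, , drop = FALSE]
  lost <- setdiff(names(full_totals), tab$sample_id)
  if (length(lost))
    warning("samples with no retained cells dropped: ",
            paste(lost, collapse = ", "))
  denom <- if (renormalize) tapply(tab$n, tab$sample_id, sum) else full_totals
  tab$fraction <- tab$n / as.numeric(denom[tab$sample_id])
  tab <- tab[base::order(tab$sample_id, tab$cell_type), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("FractionTable", "data.frame")
  tab
}

#' Compare cell-type fractions between two sample groups
#'
#' Per cell type, a two-sided Wilcoxon rank-sum test on per-sample fractions
#' (samples lacking the type contribute fraction 0), Bonferroni-adjusted
#' over the number of types tested. Types observed in only one group are
#' reported with NaN p-values and flagged.
#'
#' @param table a `FractionTable`.
#' @param groups named vector mapping sample_id to group label.
#' @param group_a,group_b the two group labels to compare (>= 3 samples
#'   each).
#' @return data.frame per cell type: mean_a, mean_b, direction ("up" =
#'   higher in group A), p_raw, p_bonferroni, one_group_only.
#' @export
compare_fractions <- function(table, groups, group_a, group_b) {
  samples_a <- names(groups)[groups == group_a]
  samples_b <- names(groups)[groups == group_b]
  samples_a <- intersect(samples_a, unique(table$sample_id))
  samples_b <- intersect(samples_b, unique(table$sample_id))
  if (length(samples_a) < 3 || length(samples_b) < 3)
    stop("need >= 3 samples per group")
  types <- sort(unique(table$cell_type))
  frac_of <- function(samples, ty) {
    v <- setNames(rep(0, length(samples)), samples)
    sub <- table[table$cell_type == ty & table$sample_id %in% samples, ]
    v[sub$sample_id] <- sub$fraction
    v
  }
  rows <- lapply(types, function(ty) {
    fa <- frac_of(samples_a, ty)
    fb <- frac_of(samples_b, ty)
    one_group <- all(fa == 0) || all(fb == 0)
    p <- if (one_group) NaN
    else if (length(unique(c(fa, fb))) == 1) 1  # fully tied: no evidence
    else suppressWarnings(wilcox.test(fa, fb)$p.value)
    data.frame(cell_type = ty, mean_a = mean(fa), mean_b = mean(fb),
               direction = ifelse(mean(fa) >= mean(fb), "up", "down"),
               p_raw = p, one_group_only = one_group,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_tested <- sum(!is.nan(out$p_raw))
  out$p_bonferroni <- pmin(1, out$p_raw * n_tested)
  rownames(out) <- NULL
  out
}
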