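#' Read a ligand-receptor pair table
#'
#' CSV with columns `pair_id, ligand_genes, receptor_genes, direction`;
#' multi-subunit complexes join genes with `+` (e.g. `IL18R1+IL18RAP`).
#'
#' @param path CSV path.
#' @return an `LRPairSet` data.frame with list-columns `ligand` and
#'   `receptor` holding the subunit gene vectors.
#' @export
read_lr_pairs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pair_id", "ligand_genes", "receptor_genes") %in% colnames(df)))
  if (anyDuplicated(df$pair_id)) stop("duplicate pair ids")
  df$ligand <- strsplit(df$ligand_genes, "+", fixed = TRUE)
  df$receptor <- strsplit(df$receptor_genes, "+", fixed = TRUE)
  class(df) <- c("LRPairSet", "data.frame")
  df
}

#' Permutation test of ligand-receptor interactions between cell types
#'
#' For every ligand-receptor pair and every ordered (sender, receiver) pair
#' of eligible cell types (those with more than `min_cells` cells), the
#' interaction statistic is half the sum of the mean ligand-complex
#' expression in the sender and the mean receptor-complex expression in the
#' receiver; complex expression per cell is the minimum over subunits. A
#' pair is tested only where both complexes are expressed (value > 0) in
#' more than `min_frac` of their cells. The null distribution permutes cell
#' type labels over the eligible cells; `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param norm cells x genes log-normalized matrix.
#' @param labels per-cell type labels aligned with `rownames(norm)`.
#' @param pairs an `LRPairSet`.
#' @param n_perm label permutations.
#' @param alpha significance level.
#' @param min_cells cell types with more than this many cells are eligible.
#' @param min_frac minimum expressing fraction of each complex.
#' @param seed RNG seed for the permutations.
#' @return an `InteractionResult` data.frame per (pair_id, sender, receiver):
#'   stat, p, significant, frac_ligand, frac_receptor, tested; attributes
#'   `eligible_types`, `skipped_pairs`, `n_perm`.
#' @export
test_interactions <- function(norm, labels, pairs, n_perm = 1000,
                              alpha = 0.05, min_cells = 20, min_frac = 0.1,
                              seed = 1L) {
  stopifnot(length(labels) == nrow(norm))
  labels <- as.character(labels)
  sizes <- table(labels)
  eligible <- sort(names(sizes)[sizes > min_cells])
  if (length(eligible) < 2)
    stop(sprintf("need >= 2 cell types with > %d cells; have %d",
                 min_cells, length(eligible)))
  keep <- labels %in% eligible
  x <- norm[keep, , drop = FALSE]
  lab <- labels[keep]

  resolvable <- vapply(seq_len(nrow(pairs)), function(i)
    all(pairs$ligand[[i]] %in% colnames(x)) &&
    all(pairs$receptor[[i]] %in% colnames(x)), logical(1))
  skipped <- pairs$pair_id[!resolvable]
  if (length(skipped))
    message("skipping pairs with unresolvable genes: ",
            paste(skipped, collapse = ", "))
  pairs <- pairs[resolvable, , drop = FALSE]
  if (!nrow(pairs)) stop("no resolvable ligand-receptor pairs")

  complex_values <- function(complexes) {
    vapply(complexes, function(gs) {
      v <- as.matrix(x[, gs, drop = FALSE])
      if (length(gs) > 1) apply(v, 1, min) else v[, 1]
    }, numeric(nrow(x)))
  }
  L <- complex_values(pairs$ligand)    # cells x pairs
  R <- complex_values(pairs$receptor)
  colnames(L) <- colnames(R) <- pairs$pair_id

  type_means <- function(lab_vec) {
    counts <- as.numeric(table(factor(lab_vec, levels = eligible)))
    ml <- rowsum(L, factor(lab_vec, levels = eligible)) / counts
    mr <- rowsum(R, factor(lab_vec, levels = eligible)) / counts
    list(l = ml, r = mr)
  }
  obs <- type_means(lab)
  frac_l <- rowsum((L > 0) + 0, factor(lab, levels = eligible)) /
    as.numeric(table(factor(lab, levels = eligible)))
  frac_r <- rowsum((R > 0) + 0, factor(lab, levels = eligible)) /
    as.numeric(table(factor(lab, levels = eligible)))

  combos <- expand.grid(sender = eligible, receiver = eligible,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$sender != combos$receiver, , drop = FALSE]
  P <- nrow(pairs)
  stat <- matrix(NA_real_, nrow(combos), P)
  tested <- matrix(FALSE, nrow(combos), P)
  for (i in seq_len(nrow(combos))) {
    s <- combos$sender[i]; r <- combos$receiver[i]
    stat[i, ] <- 0.5 * (obs$l[s, ] + obs$r[r, ])
    tested[i, ] <- frac_l[s, ] > min_frac & frac_r[r, ] > min_frac
  }

  ge_counts <- matrix(0L, nrow(combos), P)
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- type_means(sample(lab))
      for (i in seq_len(nrow(combos))) {
        ps <- 0.5 * (perm$l[combos$sender[i], ] + perm$r[combos$receiver[i], ])
        ge_counts[i, ] <- ge_counts[i, ] + (ps >= stat[i, ])
      }
    }
  })
  pval <- (1 + ge_counts) / (n_perm + 1)

  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    data.frame(pair_id = pairs$pair_id,
               sender = combos$sender[i], receiver = combos$receiver[i],
               stat = stat[i, ], p = ifelse(tested[i, ], pval[i, ], NA_real_),
               tested = tested[i, ],
               significant = tested[i, ] & pval[i, ] < alpha,
               frac_ligand = frac_l[combos$sender[i], ],
               frac_receptor = frac_r[combos$receiver[i], ],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "eligible_types") <- eligible
  attr(out, "skipped_pairs") <- skipped
  attr(out, "n_perm") <- n_perm
  class(out) <- c("InteractionResult", "data.frame")
  out
}

#' Mean number of significant interactions per cell-type pair across patients
#'
#' Significant interactions between two cell types are counted per patient
#' and averaged over the patients in which both types were eligible.
#'
#' @param results list of `InteractionResult`s, one per patient/sample.
#' @return data.frame (sender, receiver, mean_count, n_patients).
#' @export
count_interactions <- function(results) {
  stopifnot(length(results) >= 1)
  agg <- interaction_accumulate(results, function(df) sum(df$significant))
  agg$mean_count <- agg$total / agg$n_patients
  agg[, c("sender", "receiver", "mean_count", "n_patients")]
}

#' Summed interaction strength per cell-type pair across patients
#'
#' Sums the observed statistics of significant pairs, accumulated over
#' patients.
#'
#' @param results list of `InteractionResult`s, one per patient/sample.
#' @return data.frame (sender, receiver, strength, n_patients).
#' @export
interaction_strength <- function(results) {
  stopifnot(length(results) >= 1)
  agg <- interaction_accumulate(results, function(df)
    sum(df$stat[df$significant]))
  agg$strength <- agg$total
  agg[, c("sender", "receiver", "strength", "n_patients")]
}

interaction_accumulate <- function(results, f) {
  all_types <- sort(unique(unlist(lapply(results, attr, "eligible_types"))))
  combos <- expand.grid(sender = all_types, receiver = all_types,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$sender != combos$receiver, , drop = FALSE]
  combos$total <- 0
  combos$n_patients <- 0L
  for (res in results) {
    elig <- attr(res, "eligible_types")
    for (i in seq_len(nrow(combos))) {
      s <- combos$sender[i]; r <- combos$receiver[i]
      if (s %in% elig && r %in% elig) {
        combos$n_patients[i] <- combos$n_patients[i] + 1L
        combos$total[i] <- combos$total[i] +
          f(res[res$sender == s & res$receiver == r, , drop = FALSE])
      }
    }
  }
  combos <- combos[combos$n_patients > 0, , drop = FALSE]
  rownames(combos) <- NULL
  combos
}

#' Top-k interaction network of cell types
#'
#' Each cell type selects its `k` strongest partners by symmetrized strength
#' (`strength(A,B) + strength(B,A)`), ties broken lexicographically; the
#' network is the union of the selections, with node degree computed on the
#' union.
#'
#' @param strengths data.frame from [interaction_strength()].
#' @param k partners selected per node.
#' @return an `InteractionNetwork` list: `edges` (a, b, weight, ordered
#'   a < b), `nodes` (type, degree, strength = summed incident weight), and
#'   `graph` (an undirected weighted igraph object).
#' @export
build_network <- function(strengths, k = 4) {
  if (k < 1) stop("k must be >= 1")
  types <- sort(unique(c(strengths$sender, strengths$receiver)))
  if (length(types) < 2) stop("need >= 2 cell types")
  S <- matrix(0, length(types), length(types),
              dimnames = list(types, types))
  for (i in seq_len(nrow(strengths)))
    S[strengths$sender[i], strengths$receiver[i]] <- strengths$strength[i]
  sym <- S + t(S)

  edges <- character(0)
  for (ty in types) {
    partners <- setdiff(types, ty)
    ord <- partners[base::order(-sym[ty, partners], partners)]
    sel <- ord[seq_len(min(k, length(ord)))]
    edges <- c(edges, vapply(sel, function(p)
      paste(sort(c(ty, p)), collapse = "\r"), character(1)))
  }
  edges <- sort(unique(edges))
  ab <- do.call(rbind, strsplit(edges, "\r", fixed = TRUE))
  edf <- data.frame(a = ab[, 1], b = ab[, 2],
                    weight = sym[cbind(ab[, 1], ab[, 2])],
                    stringsAsFactors = FALSE)
  deg <- table(factor(c(edf$a, edf$b), levels = types))
  node_strength <- vapply(types, function(ty)
    sum(edf$weight[edf$a == ty | edf$b == ty]), numeric(1))
  nodes <- data.frame(type = types, degree = as.integer(deg),
                      strength = node_strength, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                     vertices = nodes)
  structure(list(edges = edf, nodes = nodes, graph = g, k = k),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d cell types, %d edges (top-%d selection)\n",
              nrow(x$nodes), nrow(x$edges), x$k))
  invisible(x)
}
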