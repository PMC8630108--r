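# brute-force oracle for the shrinking-window moving average
naive_smooth <- function(x, window) {
  half <- (window - 1) / 2
  out <- x
  m <- ncol(x)
  for (i in seq_len(m)) {
    h <- min(half, i - 1, m - i)
    out[, i] <- rowMeans(x[, (i - h):(i + h), drop = FALSE])
  }
  out
}

test_that("genome smoothing matches the brute-force moving average", {
  withr::with_seed(5, x <- matrix(rnorm(60), 4, 15))
  expect_equal(cnasig:::smooth_window(x, 5), naive_smooth(x, 5))
  expect_equal(cnasig:::smooth_window(x, 15), naive_smooth(x, 15))
  # window wider than the chromosome still shrinks symmetrically
  expect_equal(cnasig:::smooth_window(x[, 1:3], 101),
               naive_smooth(x[, 1:3], 101))
  # constants are fixed points; interior of a linear trend is preserved
  const <- matrix(2, 3, 9)
  expect_equal(cnasig:::smooth_window(const, 5), const)
  trend <- matrix(rep(1:11, each = 2), 2, 11, byrow = FALSE)
  sm <- cnasig:::smooth_window(trend, 5)
  expect_equal(sm[, 3:9], trend[, 3:9])
  # chromosome boundaries are respected
  chroms <- rep(c("1", "2"), c(8, 7))
  by_chrom <- cnasig:::smooth_by_chrom(x, chroms, 5)
  expect_equal(by_chrom[, 1:8], naive_smooth(x[, 1:8], 5))
  expect_equal(by_chrom[, 9:15], naive_smooth(x[, 9:15], 5))
  # smoothing approximately conserves the per-chromosome cell means
  expect_equal(rowMeans(by_chrom[, 1:8]), rowMeans(x[, 1:8]),
               tolerance = 0.2)
})

test_that("profile inference validates its inputs", {
  norm <- normalize_log(expression_matrix(toy_counts(40, 500, seed = 2) + 1L))
  go <- gene_order(data.frame(gene = colnames(norm), chrom = "1",
                              start = seq_len(500) * 10, end = seq_len(500) * 10 + 5))
  expect_error(infer_cna_profiles(norm, go, rownames(norm)[1:10]),
               ">= 30 reference cells")
  expect_error(infer_cna_profiles(norm, go, rownames(norm)[1:30],
                                  mean_cutoff = 1e6), "mean_cutoff")
})

test_that("clone stability score matches hand-evaluated cases", {
  expect_equal(clone_stability_score(c(A = 0.5, B = 0.5),
                                     c(A = 0.5, B = 0.5)), 1.0)
  expect_equal(clone_stability_score(c(A = 0.8, B = 0.2),
                                     c(A = 0.2, B = 0.8)), 0.25)
  expect_equal(clone_stability_score(c(A = 1.0), c(B = 1.0)), 0.0)
  # clone absent post counts as ratio 0 but stays in N
  expect_equal(clone_stability_score(c(A = 0.6, B = 0.4), c(A = 1.0)),
               mean(c(0.6 / 1.0, 0)))
  expect_error(clone_stability_score(c(A = 0), c(A = 0)), "zero")

  # symmetry and identity properties on random fraction pairs
  withr::with_seed(41, for (i in 1:100) {
    k <- sample(2:5, 1)
    pre <- runif(k); pre <- pre / sum(pre)
    post <- runif(k); post <- post / sum(post)
    names(pre) <- names(post) <- LETTERS[1:k]
    s <- clone_stability_score(pre, post)
    expect_equal(s, clone_stability_score(post, pre))
    expect_true(s >= 0 && s <= 1)
    expect_equal(clone_stability_score(pre, pre), 1)
  })
})

test_that("+1q group classification uses the stated boundaries", {
  expect_identical(as.character(classify_1q_group(c(0.05, 0.5, 0.9))),
                   c("ND_rare", "subclonal", "dominant"))
  # boundary convention: [0, 0.1), [0.1, 0.8], (0.8, 1]
  expect_identical(as.character(classify_1q_group(c(0, 0.0999, 0.1, 0.8,
                                                    0.8001, 1))),
                   c("ND_rare", "ND_rare", "subclonal", "subclonal",
                     "dominant", "dominant"))
  expect_error(classify_1q_group(1.2), "0, 1")
  expect_error(classify_1q_group(-0.1), "0, 1")
})

# a hand-built SubcloneSet with controlled profiles and states
fake_subclones <- function(labels, profiles, states_1q, genes) {
  labels <- factor(labels)
  states <- states_1q
  names(states) <- rownames(profiles)
  structure(list(labels = setNames(labels, paste0("cell", seq_along(labels))),
                 profiles = profiles,
                 n_cells = as.integer(table(labels)),
                 genes = genes, min_cells = 40,
                 states = list("1q" = states)),
            class = "SubcloneSet")
}

fake_genes <- gene_order(
  data.frame(gene = paste0("g", 1:6),
             chrom = c("1", "1", "1", "2", "2", "2"),
             start = c(10, 200, 300, 10, 20, 30),
             end = c(15, 205, 305, 15, 25, 35)),
  data.frame(chrom = c("1", "1", "2", "2"), arm = c("p", "q", "p", "q"),
             boundary = c(100, 1e9, 5, 1e9)))

test_that("aberrant-cell fraction is a direct ratio, label-invariant", {
  prof <- matrix(0, 3, 6, dimnames = list(c("S1", "S2", "S3"),
                                          paste0("g", 1:6)))
  labels <- rep(c("S1", "S2", "S3"), c(40, 100, 60))
  sub <- fake_subclones(labels, prof, c("gain", "neutral", "neutral"),
                        fake_genes)
  expect_equal(fraction_aberrant_cells(sub), 0.2)
  sub_all <- fake_subclones(labels, prof, c("gain", "gain", "gain"),
                            fake_genes)
  expect_equal(fraction_aberrant_cells(sub_all), 1.0)
  sub_none <- fake_subclones(labels, prof,
                             c("neutral", "neutral", "loss"), fake_genes)
  expect_equal(fraction_aberrant_cells(sub_none), 0.0)
  # relabeling the subclones leaves the fraction unchanged
  relabel <- c(S1 = "S3", S2 = "S1", S3 = "S2")
  sub_rl <- fake_subclones(unname(relabel[labels]),
                           prof[c("S2", "S3", "S1"), ][c("S1","S2","S3"), ],
                           c(S1 = "neutral", S2 = "neutral", S3 = "gain")[
                             c("S1", "S2", "S3")], fake_genes)
  sub_rl$states[["1q"]] <- setNames(c("neutral", "neutral", "gain"),
                                    c("S1", "S2", "S3"))
  expect_equal(fraction_aberrant_cells(sub_rl), 0.2)
})

test_that("closest-relative matching minimizes off-arm distance", {
  # profiles over genes g1..g6; 1q = g2, g3 (excluded from the distance)
  prof <- rbind(
    S1 = c(0, 0.5, 0.5, 0.30, 0.00, 0),   # the +1q clone, shares g4 with S2
    S2 = c(0, 0.0, 0.0, 0.28, 0.00, 0),
    S3 = c(0, 0.0, 0.0, 0.00, 0.45, 0))
  colnames(prof) <- paste0("g", 1:6)
  sub <- fake_subclones(rep(c("S1", "S2", "S3"), each = 50), prof,
                        c("gain", "neutral", "neutral"), fake_genes)
  expect_identical(match_closest_clone(sub, "S1"), "S2")
  # brute-force oracle over off-1q coordinates
  keep <- c(1, 4, 5, 6)
  d <- apply(prof[c("S2", "S3"), keep], 1,
             function(p) sqrt(sum((p - prof["S1", keep])^2)))
  expect_identical(match_closest_clone(sub, "S1"),
                   names(which.min(d)))
  # single eligible comparator is returned directly
  sub2 <- fake_subclones(rep(c("S1", "S2", "S3"), each = 50), prof,
                         c("gain", "neutral", "gain"), fake_genes)
  expect_identical(match_closest_clone(sub2, "S1"), "S2")
  # equidistant candidates break ties to the lower label (exactly
  # representable values so the tie is exact in floating point)
  prof3 <- prof
  prof3["S1", ] <- c(0, 0.5, 0.5, 0.5, 0, 0)
  prof3["S3", ] <- c(0, 0, 0, 0.25, 0, 0)
  prof3["S2", ] <- c(0, 0, 0, 0.75, 0, 0)  # both at distance 0.25 from S1
  sub3 <- fake_subclones(rep(c("S1", "S2", "S3"), each = 50), prof3,
                         c("gain", "neutral", "neutral"), fake_genes)
  expect_identical(match_closest_clone(sub3, "S1"), "S2")
  # no eligible comparator
  sub4 <- fake_subclones(rep(c("S1", "S2", "S3"), each = 50), prof,
                         c("gain", "gain", "gain"), fake_genes)
  expect_error(match_closest_clone(sub4, "S1"), "neutral comparator")
})

test_that("clone fraction tables sum to one per sample", {
  labels <- factor(rep(c("S1", "S2"), c(60, 40)))
  names(labels) <- paste0("c", 1:100)
  sub <- list(labels = labels)
  samples <- rep(c("pre", "post"), 50)
  cf <- clone_fractions(sub, samples)
  sums <- tapply(cf$fraction, cf$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("two planted clones are recovered exactly and homogeneity gives one", {
  pat <- sim_patient("P1", list(
    sim_subclone("a", c(pre = 0.5),
                 events = list(list(arm = "1q", copy = 3))),
    sim_subclone("b", c(pre = 0.5),
                 events = list(list(arm = "13q", copy = 1)))),
    n_tumor = c(pre = 500), n_reference = 120)
  cfg <- sim_config(seed = 8, patients = list(pat))
  sim <- simulate_cohort(cfg)
  norm <- normalize_log(sim$em)
  ref <- rownames(sim$em$cell_meta)[sim$em$cell_meta$compartment == "reference"]
  cna <- infer_cna_profiles(norm, sim$gene_order, ref)
  sub <- call_subclones(cna)
  truth <- sim$truth$cells$subclone[match(names(sub$labels),
                                          sim$truth$cells$cell_id)]
  expect_equal(nlevels(sub$labels), 2)
  expect_gte(adj_rand_index(truth, sub$labels), 0.9)
  # planted gain/loss arm states
  sub <- call_region_state(sub, "1q")
  st <- sub$states[["1q"]]
  gained <- names(st)[st == "gain"]
  expect_equal(length(gained), 1)

  # genomically identical cells: a single subclone
  pat0 <- sim_patient("P1", list(sim_subclone("only", c(pre = 1))),
                      n_tumor = c(pre = 400), n_reference = 120)
  cfg0 <- sim_config(seed = 9, patients = list(pat0), n_genes = 1200,
                     oneq_genes = 80, oneq_responsive = 60)
  sim0 <- simulate_cohort(cfg0)
  norm0 <- normalize_log(sim0$em)
  ref0 <- rownames(sim0$em$cell_meta)[sim0$em$cell_meta$compartment == "reference"]
  sub0 <- call_subclones(infer_cna_profiles(norm0, sim0$gene_order, ref0))
  expect_equal(nlevels(sub0$labels), 1)
})
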