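# independent oracle: exact two-sided rank-sum p by exhaustive enumeration
# of all assignments of the pooled values to group A
exact_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  idx <- combn(length(pooled), length(a))
  stats <- apply(idx, 2, function(i) sum(r[i]))
  obs <- sum(r[seq_along(a)])
  mu <- length(a) * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

norm_from_counts <- function(counts) normalize_log(expression_matrix(counts))

test_that("Wilcoxon DE reproduces the exact 4-vs-4 enumeration", {
  # equal per-cell totals so normalization preserves the count ordering
  counts <- matrix(0L, 8, 2, dimnames = list(paste0("c", 1:8),
                                             c("gA", "g2")))
  counts[, "gA"] <- c(5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L)
  counts[, "g2"] <- 12L - counts[, "gA"]
  norm <- norm_from_counts(counts)
  de <- differential_expression(norm, paste0("c", 1:4), paste0("c", 5:8))
  expect_equal(de["gA", "p"], 2 / 70, tolerance = 1e-9)
  expect_equal(de["gA", "p"],
               exact_wilcox_p(norm[1:4, "gA"], norm[5:8, "gA"]),
               tolerance = 1e-9)
  expect_gt(de["gA", "logfc"], 0)
  expect_identical(de["gA", "direction"], "up")
})

test_that("identical groups yield no significant genes", {
  counts <- toy_counts(12, 50, seed = 9, mu = 3)
  counts <- counts + 1L  # ensure totals > 0 and genes expressed
  norm <- norm_from_counts(counts)
  cells <- rownames(counts)
  de <- differential_expression(norm, cells[1:6], cells[1:6])
  expect_equal(sum(de$significant), 0)
  expect_true(all(abs(de$logfc) < 1e-12))
})

test_that("DE is antisymmetric under group swap and matches wilcox.test", {
  counts <- toy_counts(60, 40, seed = 4, mu = 3) + 1L
  norm <- norm_from_counts(counts)
  cells <- rownames(counts)
  a <- cells[1:30]; b <- cells[31:60]
  de_ab <- differential_expression(norm, a, b)
  de_ba <- differential_expression(norm, b, a)
  expect_equal(de_ab$logfc, -de_ba$logfc)
  expect_equal(de_ab$p, de_ba$p)
  # large-sample path agrees with stats::wilcox.test
  for (g in colnames(counts)[c(1, 7, 20)]) {
    ref <- suppressWarnings(wilcox.test(norm[a, g], norm[b, g]))$p.value
    expect_equal(de_ab[g, "p"], ref, tolerance = 1e-6)
  }
})

test_that("planted two-fold upregulation is recovered", {
  withr::with_seed(31, {
    n <- 200; g <- 300
    mu <- matrix(4, 2 * n, g)
    mu[1:n, 1:10] <- 8  # planted genes doubled in group A
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), 2 * n, g,
                     dimnames = list(sprintf("c%03d", 1:(2 * n)),
                                     sprintf("g%03d", 1:g)))
  })
  norm <- norm_from_counts(counts)
  cells <- rownames(counts)
  de <- differential_expression(norm, cells[1:200], cells[201:400])
  planted <- sprintf("g%03d", 1:10)
  expect_true(all(de[planted, "significant"]))
  expect_true(all(de[planted, "logfc"] > 0))
  expect_lt(sum(de$significant[!de$gene %in% planted]), 3)
})

fake_de <- function(up_genes, all_genes = c("sigA", "sigB", "off2q",
                                            "MT-sig", "weak")) {
  data.frame(gene = all_genes,
             logfc = ifelse(all_genes %in% up_genes, 0.5, 0),
             p = 0.5, p_adj = ifelse(all_genes %in% up_genes, 1e-6, 1),
             direction = "up",
             significant = all_genes %in% up_genes,
             row.names = all_genes, stringsAsFactors = FALSE)
}

sig_order <- gene_order(
  data.frame(gene = c("sigA", "sigB", "MT-sig", "off2q", "weak"),
             chrom = c("1", "1", "1", "2", "1"),
             start = c(400, 500, 600, 100, 700),
             end = c(450, 550, 650, 150, 750)),
  data.frame(chrom = c("1", "1", "2", "2"), arm = c("p", "q", "p", "q"),
             boundary = c(100, 1e9, 10, 1e9)))

test_that("signature derivation enforces recurrence, location and mito rules", {
  des <- c(replicate(5, fake_de(c("sigA", "off2q", "MT-sig")),
                     simplify = FALSE),
           replicate(5, fake_de(c("sigA", "sigB", "off2q", "MT-sig")),
                     simplify = FALSE))
  sig <- derive_signature(des, min_recurrence = 5, order = sig_order)
  expect_identical(sig$gene, c("sigA", "sigB"))
  expect_identical(sig$recurrence, c(10L, 5L))
  # off2q recurrent in 10/10 but not on 1q; MT-sig excluded as mitochondrial
  expect_false("off2q" %in% sig$gene)
  expect_false("MT-sig" %in% sig$gene)
  # invariant to patient ordering
  sig_rev <- derive_signature(rev(des), min_recurrence = 5,
                              order = sig_order)
  expect_identical(sig_rev, sig)
  # sigB below recurrence floor at 6
  expect_identical(derive_signature(des, 6, sig_order)$gene, "sigA")
  # empty DE tables give an empty signature
  empty <- derive_signature(replicate(5, fake_de(character(0)),
                                      simplify = FALSE),
                            min_recurrence = 5, order = sig_order)
  expect_equal(nrow(empty), 0)
  expect_warning(derive_signature(des[1:3], 5, sig_order), "contributing")
})

test_that("module scoring is seeded, centred, and exactly zero against itself", {
  counts <- toy_counts(150, 400, seed = 6, mu = 2)
  norm <- norm_from_counts(counts + 1L)
  genes <- colnames(norm)[21:45]
  s1 <- score_signature(norm, genes, seed = 7)
  s2 <- score_signature(norm, genes, seed = 7)
  expect_identical(s1, s2)
  s3 <- score_signature(norm, genes, seed = 8)
  expect_false(identical(as.numeric(s1), as.numeric(s3)))

  # degenerate case: matrix holding only the signature genes, one bin
  self <- score_signature(norm[, genes], genes, n_bins = 1, seed = 1)
  expect_equal(max(abs(self)), 0)

  # random gene sets score ~0 on average (light calibration)
  biases <- withr::with_seed(99, vapply(1:20, function(i) {
    mean(score_signature(norm, sample(colnames(norm), 25), seed = i))
  }, numeric(1)))
  expect_lt(mean(abs(biases)), 0.05)
})

test_that("cells with planted dosage on signature genes score higher", {
  withr::with_seed(13, {
    g <- 300; n <- 120
    sig <- sprintf("g%03d", 1:30)
    mu <- matrix(2, 2 * n, g)
    mu[1:n, 1:30] <- 3  # 1.5x dosage on signature genes in first group
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), 2 * n, g,
                     dimnames = list(sprintf("c%03d", 1:(2 * n)),
                                     sprintf("g%03d", 1:g)))
  })
  norm <- norm_from_counts(counts + 1L)
  sc <- score_signature(norm, sig, seed = 2)
  gained <- sc[1:120]; neutral <- sc[121:240]
  expect_gt(mean(gained), mean(neutral))
  expect_lt(wilcox.test(gained, neutral, alternative = "greater")$p.value,
            0.01)
})

test_that("evaluate_ppv equals brute-force confusion matrices", {
  expect_equal(evaluate_ppv(c(1, 2, 3), c(TRUE, TRUE, FALSE), 0)$ppv, 2 / 3)
  res <- evaluate_ppv(c(rep(0.9, 3), rep(0.8, 7), rep(-1, 5)),
                      c(rep(TRUE, 3), rep(FALSE, 7), rep(TRUE, 5)), 0.5)
  expect_equal(res$ppv, 0.3)
  expect_equal(res[c("tp", "fp", "n_positive")], list(tp = 3, fp = 7,
                                                      n_positive = 10))
  above <- evaluate_ppv(c(0.1, 0.2), c(TRUE, FALSE), 0.5)
  expect_true(is.nan(above$ppv))
  expect_equal(above$n_positive, 0)

  withr::with_seed(17, for (i in 1:100) {
    sc <- rnorm(50); tr <- runif(50) > 0.5; th <- rnorm(1)
    got <- evaluate_ppv(sc, tr, th)
    pos <- which(sc >= th)
    expect_equal(got$ppv,
                 if (!length(pos)) NaN else sum(tr[pos]) / length(pos))
  })
})

test_that("score-fraction correlation handles exact and degenerate cases", {
  expect_equal(as.numeric(score_fraction_correlation(c(0.1, 0.4, 0.8),
                                                     c(0.1, 0.4, 0.8))), 1)
  expect_equal(as.numeric(score_fraction_correlation(c(0, 0.5, 1),
                                                     c(1, 0.5, 0))), -1)
  expect_error(score_fraction_correlation(c(1, 2), c(1, 2)), ">= 3")
  expect_error(score_fraction_correlation(c(1, 1, 1), c(1, 2, 3)),
               "variance")
})
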