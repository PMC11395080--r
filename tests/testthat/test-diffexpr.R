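test_that("size factors follow the median-of-ratios construction", {
  # identical columns -> all factors 1
  m <- matrix(rep(c(3L, 10L, 50L), 4), ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(estimate_size_factors(m)), rep(1, 4))

  # doubling a column: factor ratio is exactly 2
  m2 <- cbind(s1 = c(2L, 10L, 40L), s2 = c(4L, 20L, 80L))
  rownames(m2) <- paste0("g", 1:3)
  sf <- estimate_size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  # hand-enumerated 3x2 toy: geomeans (sqrt(8), 8, 8), per-sample ratio
  # medians sqrt(1/2) and sqrt(2)
  m3 <- cbind(A = c(2L, 4L, 8L), B = c(4L, 16L, 8L))
  rownames(m3) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m3)), c(sqrt(0.5), sqrt(2)))
})

test_that("size-factor fallback engages when no gene is all-positive", {
  m <- cbind(s1 = c(5L, 0L, 7L, 2L), s2 = c(6L, 3L, 0L, 2L),
             s3 = c(4L, 2L, 8L, 0L), s4 = c(5L, 4L, 9L, 3L))
  rownames(m) <- paste0("g", 1:4)
  sf <- estimate_size_factors(m)
  expect_true(all(sf > 0))
  expect_error(estimate_size_factors(matrix(0L, 2, 4,
                 dimnames = list(c("a", "b"), paste0("s", 1:4)))),
               "size factors")
})

test_that("dispersion estimates floor at 1e-8 and recover the truth", {
  # constant gene -> floor
  m <- matrix(5L, nrow = 2, ncol = 8,
              dimnames = list(c("g1", "g2"), paste0("s", 1:8)))
  m[2, ] <- c(3L, 9L, 2L, 8L, 4L, 7L, 5L, 6L)
  cm <- toy_count_matrix(m, 4)
  disp <- estimate_dispersions(cm, stats::setNames(rep(1, 8), colnames(m)))
  expect_equal(unname(disp["g1"]), 1e-8)

  # Poisson genes: estimate stays near the floor
  set.seed(5)
  hits <- 0
  for (s in 1:20) {
    y <- matrix(rpois(200 * 20, 100), nrow = 20)
    dimnames(y) <- list(paste0("g", 1:20), paste0("s", 1:200))
    cm <- toy_count_matrix(y, 100)
    d <- estimate_dispersions(cm, stats::setNames(rep(1, 200), colnames(y)))
    hits <- hits + sum(d < 0.05)
  }
  expect_gte(hits / (20 * 20), 0.9)

  # NB genes with alpha = 0.5 at n = 500: mean estimate within +/- 0.15
  set.seed(6)
  y <- matrix(rnbinom(200 * 500, mu = 100, size = 2), nrow = 200)
  dimnames(y) <- list(paste0("g", 1:200), paste0("s", 1:500))
  cm <- toy_count_matrix(y, 250)
  d <- estimate_dispersions(cm, stats::setNames(rep(1, 500), colnames(y)))
  expect_lt(abs(mean(d) - 0.5), 0.15)
})

test_that("Wald fit recovers planted effects and handles degenerate genes", {
  cfg <- sim_config(n_genes = 2000, frac_de = 0.1, lfc_magnitude = 1,
                    mean_log_expression = log(100), sd_log_expression = 0,
                    group_sizes = c(6, 6), seed = 13)
  sim <- simulate_counts(cfg)
  res <- run_de(sim$counts)
  expect_equal(res$gene, sim$truth$gene)
  de <- sim$truth$is_de & sim$truth$true_log2fc > 0
  expect_lt(abs(mean(res$log2FoldChange[de]) - 1), 0.15)
  # wald_stat = log2fc / se wherever se > 0
  ok <- !is.na(res$lfcSE) & res$lfcSE > 0
  expect_equal(res$stat[ok], res$log2FoldChange[ok] / res$lfcSE[ok])
  expect_true(all(res$padj >= res$pvalue - 1e-15))

  # all-zero gene: defined degenerate output, record retained
  m <- rbind(g1 = c(10L, 12L, 9L, 11L), g2 = c(0L, 0L, 0L, 0L),
             g3 = c(20L, 18L, 25L, 21L))
  colnames(m) <- paste0("s", 1:4)
  cm <- toy_count_matrix(m, 2)
  res0 <- wald_test(cm)
  expect_equal(nrow(res0), 3)
  expect_equal(res0$log2FoldChange[res0$gene == "g2"], 0)
  expect_equal(res0$pvalue[res0$gene == "g2"], 1)
})

test_that("swapping group labels negates log2FC and preserves p-values", {
  cfg <- sim_config(n_genes = 300, frac_de = 0.1, seed = 17)
  sim <- simulate_counts(cfg)
  cm <- sim$counts
  flipped <- count_matrix(cm$counts,
                          ifelse(cm$group == "case", "control", "case"))
  r1 <- run_de(cm)
  r2 <- run_de(flipped)
  expect_equal(r2$log2FoldChange, -r1$log2FoldChange, tolerance = 1e-6)
  expect_equal(r2$pvalue, r1$pvalue, tolerance = 1e-6)
})

test_that("rescaling a sample moves its size factor, not the estimates", {
  # multiplicative toy (counts = gene level x library scale) where the
  # normalization is exactly identifiable
  g <- c(3L, 5L, 7L, 11L); lib <- c(1L, 2L, 3L, 1L, 2L, 4L)
  m <- outer(g, lib)
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:6))
  cm <- toy_count_matrix(m, 3)
  m2 <- m; m2[, 1] <- m2[, 1] * 5L
  cm2 <- toy_count_matrix(m2, 3)
  sf1 <- estimate_size_factors(cm)
  sf2 <- estimate_size_factors(cm2)
  # relative factor of the scaled sample grows by exactly the constant
  expect_equal(unname((sf2[1] / sf2[2]) / (sf1[1] / sf1[2])), 5,
               tolerance = 1e-12)
  r1 <- wald_test(cm)
  r2 <- wald_test(cm2)
  expect_equal(r2$log2FoldChange, r1$log2FoldChange, tolerance = 1e-6)
  expect_true(all(r1$converged))
})

test_that("BH adjustment matches the hand-computed step-up and is monotone", {
  rec <- data.frame(gene = paste0("g", 1:4), baseMean = 1,
                    log2FoldChange = 0, lfcSE = 1, stat = 0,
                    pvalue = c(0.01, 0.02, 0.03, 0.04), padj = NA_real_)
  adj <- adjust_pvalues(rec)
  expect_equal(adj$padj, rep(0.04, 4))

  one <- adjust_pvalues(rec[1, ])
  expect_equal(one$padj, one$pvalue)

  rec$pvalue <- rep(1, 4)
  expect_equal(adjust_pvalues(rec)$padj, rep(1, 4))

  set.seed(8)
  rec <- data.frame(gene = paste0("g", 1:50), pvalue = runif(50))
  adj <- adjust_pvalues(rec)
  o <- order(adj$pvalue)
  expect_true(all(diff(adj$padj[o]) >= -1e-15))
  expect_true(all(adj$padj <= 1))
  # BH rejections contain Bonferroni rejections at the same level
  q <- 0.2
  bonf <- adj$pvalue <= q / nrow(adj)
  expect_true(all(adj$padj[bonf] <= q))
})

test_that("DEG filter honors its boundary rules", {
  rec <- data.frame(gene = c("a", "b", "c", "d"),
                    log2FoldChange = c(0.5, 0.49, -0.5, 2),
                    pvalue = c(0.049, 1e-10, 0.049, 0.05),
                    padj = c(0.1, 0.1, 0.1, 0.1))
  degs <- filter_degs(rec)
  expect_true("a" %in% degs$up)        # |lfc| = 0.5 inclusive
  expect_false("b" %in% c(degs$up, degs$down))  # fails FC bound
  expect_true("c" %in% degs$down)
  expect_false("d" %in% degs$up)       # p = 0.05 exclusive
  expect_length(intersect(degs$up, degs$down), 0)
})
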