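test_that("count simulation plants exactly the configured DEGs and is deterministic", {
  cfg <- sim_config(n_genes = 1000, frac_de = 0.1, seed = 3)
  sim <- simulate_counts(cfg)
  expect_equal(sum(sim$truth$is_de), 100)
  expect_true(all(abs(sim$truth$true_log2fc[sim$truth$is_de]) == cfg$lfc_magnitude))
  expect_true(all(sim$truth$true_log2fc[!sim$truth$is_de] == 0))
  expect_true(all(sim$counts$counts >= 0))
  expect_true(all(sim$counts$counts == round(sim$counts$counts)))

  sim2 <- simulate_counts(cfg)
  expect_identical(sim$counts$counts, sim2$counts$counts)

  none <- simulate_counts(sim_config(n_genes = 200, frac_de = 0, seed = 4))
  expect_false(any(none$truth$is_de))
})

test_that("simulator validates its configuration fields by name", {
  expect_error(sim_config(n_genes = -5, seed = 1), "n_genes")
  expect_error(sim_config(dispersion = 0, seed = 1), "dispersion")
  expect_error(sim_config(frac_de = 1.5, seed = 1), "frac_de")
  expect_error(sim_config(group_sizes = c(1, 5), seed = 1), "group_sizes")
  expect_error(sim_config(n_genes = 100), "seed")
})

test_that("simulated counts obey the NB mean-variance relation", {
  cfg <- sim_config(n_genes = 8000, frac_de = 0, dispersion = 0.1,
                    sd_log_expression = 0, size_factor_range = c(1, 1),
                    mean_log_expression = log(200), seed = 9)
  sim <- simulate_counts(cfg)
  m <- rowMeans(sim$counts$counts)
  v <- apply(sim$counts$counts, 1, var)
  alpha_hat <- mean((v - m) / m^2)
  expect_lt(abs(alpha_hat - 0.1), 0.02)
})

test_that("dataset trio shares exactly the requested DEG core with fixed signs", {
  cfg <- sim_config(n_genes = 2000, frac_de = 0.05, seed = 21)
  trio <- simulate_dataset_trio(cfg, shared_core = 57, core_up = 35)
  truths <- lapply(trio, function(d) d$truth)
  de_sets <- lapply(truths, function(t) t$gene[t$is_de])
  core <- Reduce(intersect, de_sets)
  expect_length(core, 57)
  expect_setequal(core, attr(trio, "core_genes"))
  core_lfc <- sapply(truths, function(t) t$true_log2fc[match(core, t$gene)])
  expect_true(all(core_lfc[, 1] == core_lfc[, 2] & core_lfc[, 2] == core_lfc[, 3]))
  expect_equal(sum(core_lfc[, 1] > 0), 35)
  expect_equal(sum(core_lfc[, 1] < 0), 22)
  expect_equal(unname(sapply(trio, function(d) ncol(d$counts$counts))),
               c(10, 18, 12))

  expect_error(simulate_dataset_trio(cfg, shared_core = 1e5), "shared_core")

  none <- simulate_dataset_trio(cfg, shared_core = 0)
  expect_length(Reduce(intersect, lapply(none, function(d) d$truth$gene[d$truth$is_de])), 0)
})

test_that("gene-set simulation spikes one set and honors size bounds", {
  universe <- sprintf("G%04d", 1:500)
  spike <- universe[1:10]
  coll <- simulate_gene_sets(universe, n_sets = 30, set_size_range = c(5, 5),
                             spiked_set = spike, seed = 2)
  expect_length(coll$sets, 30)
  expect_setequal(coll$sets$SPIKED, spike)
  expect_true(all(lengths(coll$sets[-1]) == 5))
  # the spiked set must rank first when queried with its own genes
  rec <- ora_test(spike, coll)
  expect_equal(rec$set_id[1], "SPIKED")

  only <- simulate_gene_sets(universe, 1, c(5, 5), spike, seed = 2)
  expect_length(only$sets, 1)
  expect_error(simulate_gene_sets(universe, 5, c(5, 5), c("NOPE"), seed = 2),
               "spiked_set")
})

test_that("planted PPI hubs attain top degree in nearly all seeds", {
  wins <- 0
  for (s in 1:100) {
    g <- simulate_ppi(50, attachment_edges = 2, hub_labels = "IL2RA", seed = s)
    deg <- igraph::degree(g)
    if (names(which.max(deg)) == "IL2RA") wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("PPI graphs are simple and round-trip through STRING TSV", {
  g <- simulate_ppi(40, 2, hub_labels = c("A", "B"), seed = 7)
  expect_true(igraph::is_simple(g))
  expect_false(igraph::is_directed(g))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_string_tsv(g, tmp)
  g2 <- read_string_tsv(tmp, min_score = 0)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_true(igraph::isomorphic(g, g2))
  expect_error(simulate_ppi(10, attachment_edges = 10, hub_labels = "A", seed = 1),
               "attachment_edges")
})

test_that("copula panel realizes requested rank correlations", {
  pc <- panel_config(cancer_types = "BRCA", n_samples = 5000,
                     target_rank_corr = c(PDCD1 = 0.5, CD274 = -0.4, CTLA4 = 0.758),
                     seed = 31)
  panel <- simulate_pan_cancer_panel(pc)
  rho <- sapply(c(PDCD1 = "PDCD1", CD274 = "CD274", CTLA4 = "CTLA4"), function(g)
    spearman_cor(panel$CCR8, panel[[g]])$rho)
  expect_lt(max(abs(rho - c(0.5, -0.4, 0.758))), 0.03)
  # TMB is integer-valued (Poisson marginal), MSI bounded in (0, 1)
  expect_true(all(panel$TMB == round(panel$TMB)))
  expect_true(all(panel$MSI > 0 & panel$MSI < 1))
})

test_that("independent panel variables stay uncorrelated under the null", {
  hits <- 0
  for (s in 1:20) {
    pc <- panel_config(cancer_types = "X", n_samples = 1000,
                       target_rank_corr = c(PDCD1 = 0, CD274 = 0, CTLA4 = 0),
                       seed = s)
    panel <- simulate_pan_cancer_panel(pc)
    if (abs(spearman_cor(panel$CCR8, panel$PDCD1)$rho) < 0.1) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # minimal size must still return a well-formed panel
  tiny <- simulate_pan_cancer_panel(panel_config(cancer_types = "X", n_samples = 3, seed = 1))
  expect_equal(nrow(tiny), 3)
  expect_true(all(c("sample", "cancer_type", "TMB", "MSI", "CCR8") %in% colnames(tiny)))
})

test_that("infeasible correlation structures are rejected with guidance", {
  expect_error(panel_config(cancer_types = "X", n_samples = 10,
                            target_rank_corr = c(PDCD1 = 1.2), seed = 1),
               "\\(-1, 1\\)")
  pc <- panel_config(cancer_types = "X", n_samples = 10,
                     target_rank_corr = c(PDCD1 = 0.9, CD274 = 0.9, CTLA4 = 0.9),
                     tmb_corr = c(PDCD1 = 0.9, CD274 = -0.9), seed = 1)
  expect_error(simulate_pan_cancer_panel(pc), "positive definite")
})
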