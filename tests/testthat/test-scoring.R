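test_that("p-value binning honors the rubric boundaries", {
  expect_equal(score_pvalue(9.67e-102), 3L)
  expect_equal(score_pvalue(1e-50), 2L)     # boundary falls in the weaker bin
  expect_equal(score_pvalue(1e-30), 1L)
  expect_equal(score_pvalue(1e-10), 0L)
  expect_equal(score_pvalue(0.5), 0L)
  expect_equal(score_pvalue(0), 3L)
  expect_error(score_pvalue(1.5), "\\[0, 1\\]")
  expect_error(score_pvalue(-1e-3), "\\[0, 1\\]")
})

test_that("correlation binning honors the rubric boundaries", {
  expect_equal(score_correlation(0.31), 3L)
  expect_equal(score_correlation(0.3), 2L)
  expect_equal(score_correlation(0.2), 1L)
  expect_equal(score_correlation(0.1), 0L)
  expect_equal(score_correlation(-0.5), 0L)
  expect_error(score_correlation(1.2), "\\[-1, 1\\]")
})

test_that("biomarker score sums per-gene bins over the panel", {
  expect_equal(score_biomarker(c(CCR8 = 0.35, CD274 = 0.32, PDCD1 = 0.4)), 9L)
  expect_equal(score_biomarker(c(CCR8 = 0.05, CD274 = 0.05, PDCD1 = 0.05)), 0L)
  expect_equal(score_biomarker(c(CCR8 = 0.25, CD274 = 0.25, PDCD1 = 0.15)), 5L)
  expect_warning(z <- score_biomarker(numeric()), "empty")
  expect_equal(z, 0L)
})

test_that("scorecard aggregation sums components plus the standard-of-care bonus", {
  brca <- aggregate_scorecard("BRCA", list(
    checkpoint_p = c(PDCD1 = 9.67e-102, CD274 = 4.12e-63, CTLA4 = 2.64e-206),
    treg_score = 3, tmb_score = 9, msi_score = 6), soc = TRUE)
  expect_equal(unname(brca$checkpoint_scores), c(3L, 3L, 3L))
  expect_equal(brca$final, 30L)

  zero <- aggregate_scorecard("X", list(
    checkpoint_scores = c(PDCD1 = 0, CD274 = 0, CTLA4 = 0),
    treg_score = 0, tmb_score = 0, msi_score = 0), soc = FALSE)
  expect_equal(zero$final, 0L)

  read <- aggregate_scorecard("READ", list(
    checkpoint_scores = c(PDCD1 = 0, CD274 = 0, CTLA4 = 1),
    treg_score = 1, tmb_score = 6, msi_score = 5), soc = FALSE)
  expect_equal(read$final, 13L)

  expect_error(aggregate_scorecard("X", list(checkpoint_p = c(0.5, 0.5, 0.5)),
                                   soc = FALSE), "missing component")
})

test_that("raw values take precedence over pre-binned scores", {
  card <- aggregate_scorecard("X", list(
    checkpoint_p = c(PDCD1 = 1e-60, CD274 = 1e-60, CTLA4 = 1e-60),
    checkpoint_scores = c(PDCD1 = 0, CD274 = 0, CTLA4 = 0),
    treg_rho = 0.35, treg_score = 0,
    tmb_rho = c(CCR8 = 0.35), msi_score = 0), soc = FALSE)
  expect_equal(unname(card$checkpoint_scores), c(3L, 3L, 3L))
  expect_equal(card$treg_infiltration_score, 3L)
  expect_equal(card$tmb_score, 3L)
})

test_that("indication ranking is descending with alphabetical tie-break", {
  mk <- function(ct, final) structure(list(cancer_type = ct, final = final),
                                      class = "scorecard")
  cards <- list(mk("STAD", 23), mk("BRCA", 30), mk("COAD", 23), mk("THCA", 14))
  ranked <- rank_indications(cards)
  expect_equal(vapply(ranked, `[[`, "", "cancer_type"),
               c("BRCA", "COAD", "STAD", "THCA"))
  expect_equal(rank_indications(list(mk("X", 5)))[[1]]$cancer_type, "X")
  tied <- rank_indications(list(mk("B", 7), mk("A", 7), mk("C", 7)))
  expect_equal(vapply(tied, `[[`, "", "cancer_type"), c("A", "B", "C"))
})

test_that("final score is monotone in every component", {
  set.seed(27)
  rubric <- scoring_rubric()
  base_p <- runif(3)
  comp <- function(p, treg, tmb) list(
    checkpoint_p = stats::setNames(p, c("PDCD1", "CD274", "CTLA4")),
    treg_rho = treg, tmb_rho = c(CCR8 = tmb), msi_score = 2)
  for (i in 1:200) {
    p <- 10^(-runif(3, 0, 120))
    treg <- runif(1, -1, 1); tmb <- runif(1, -1, 1)
    f0 <- aggregate_scorecard("X", comp(p, treg, tmb), soc = FALSE, rubric)$final
    # decrease one p-value, increase one rho
    j <- sample(3, 1)
    p2 <- p; p2[j] <- p2[j] * 10^(-runif(1, 0, 50))
    f1 <- aggregate_scorecard("X", comp(p2, treg, tmb), soc = FALSE, rubric)$final
    expect_gte(f1, f0)
    f2 <- aggregate_scorecard("X", comp(p, min(1, treg + runif(1, 0, 0.5)), tmb),
                              soc = FALSE, rubric)$final
    expect_gte(f2, f0)
  }
})

test_that("the bundled six-cancer example reproduces its published totals", {
  path <- system.file("extdata", "ici_components.yaml", package = "treghub")
  cards <- score_components(path)
  tab <- scorecard_table(cards)
  expect_equal(tab$cancer_type, c("BRCA", "HNSC", "COAD", "STAD", "THCA", "READ"))
  expect_equal(tab$final, c(30L, 24L, 23L, 23L, 14L, 13L))
  # every row's final equals the sum of its printed components
  expect_equal(tab$final, tab$PDCD1 + tab$CD274 + tab$CTLA4 +
                 tab$treg_infiltration + tab$TMB + tab$MSI + tab$clinical)
})

test_that("scoring wires directly from correlation-stage outputs", {
  pc <- panel_config(cancer_types = c("BRCA", "THCA"), n_samples = 400,
                     tmb_corr = c(CCR8 = 0.4, CD274 = 0.35, PDCD1 = 0.35),
                     msi_corr = c(CCR8 = 0.25, CD274 = 0.25, PDCD1 = 0.25),
                     seed = 41)
  panel <- simulate_pan_cancer_panel(pc)
  cp <- checkpoint_correlations(panel, "CCR8", c("PDCD1", "CD274", "CTLA4"))
  tmb <- biomarker_correlations(panel, c("CCR8", "CD274", "PDCD1"), "TMB")
  msi <- biomarker_correlations(panel, c("CCR8", "CD274", "PDCD1"), "MSI")
  cards <- score_from_correlations(cp, tmb, msi,
                                   treg_rho = c(BRCA = 0.4, THCA = 0.15),
                                   soc = c(BRCA = TRUE, THCA = FALSE))
  tab <- scorecard_table(cards)
  expect_equal(sort(tab$cancer_type), c("BRCA", "THCA"))
  brca <- tab[tab$cancer_type == "BRCA", ]
  expect_equal(brca$final, brca$PDCD1 + brca$CD274 + brca$CTLA4 +
                 brca$treg_infiltration + brca$TMB + brca$MSI + brca$clinical)
  expect_error(score_from_correlations(cp, tmb, msi, treg_rho = c(BRCA = 0.4),
                                       soc = c(BRCA = TRUE)), "treg_rho")
})
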