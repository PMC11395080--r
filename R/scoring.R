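#' Scoring rubric for the integrated indication score
#'
#' Two bin tables translate correlation statistics into points:
#'
#' * p-value bins (checkpoint correlations): `p < 1e-50` scores 3,
#'   `1e-50 <= p < 1e-30` scores 2, `1e-30 <= p < 1e-10` scores 1, else 0.
#' * correlation bins (Treg infiltration, TMB, MSI): `rho > 0.3` scores 3,
#'   `0.2 < rho <= 0.3` scores 2, `0.1 < rho <= 0.2` scores 1, else 0
#'   (negative correlations score 0).
#'
#' A fixed bonus (`soc_bonus`, default 3) is added for cancers where
#' checkpoint inhibitors are the current standard of care.
#'
#' @param pvalue_bins Strictly decreasing thresholds for the p-value bins.
#' @param corr_bins Strictly decreasing thresholds for the correlation bins.
#' @param soc_bonus Points for standard-of-care ICI status.
#' @export
scoring_rubric <- function(pvalue_bins = c(1e-50, 1e-30, 1e-10),
                           corr_bins = c(0.3, 0.2, 0.1), soc_bonus = 3) {
  if (any(diff(pvalue_bins) <= 0))
    stop_field("pvalue_bins", "must be strictly increasing (most significant first)")
  if (any(diff(corr_bins) >= 0)) stop_field("corr_bins", "must be strictly decreasing")
  structure(list(pvalue_bins = pvalue_bins, corr_bins = corr_bins,
                 soc_bonus = soc_bonus), class = "scoring_rubric")
}

#' Bin a correlation p-value into rubric points
#'
#' Boundaries are half-open downward: a p equal to a threshold falls in the
#' weaker bin (e.g. `p = 1e-50` scores 2, not 3).
#'
#' @param p p-value in `[0, 1]` (vectorized).
#' @param rubric A [scoring_rubric()].
#' @return Integer score(s) in 0..3.
#' @export
score_pvalue <- function(p, rubric = scoring_rubric()) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_field("p", "must lie in [0, 1]")
  b <- rubric$pvalue_bins
  ifelse(p < b[1], 3L, ifelse(p < b[2], 2L, ifelse(p < b[3], 1L, 0L)))
}

#' Bin a correlation coefficient into rubric points
#'
#' Boundaries are half-open upward: `rho = 0.3` scores 2 (`rho > 0.3` is
#' required for 3). Negative and near-zero correlations score 0.
#'
#' @param rho Correlation in `[-1, 1]` (vectorized).
#' @inheritParams score_pvalue
#' @return Integer score(s) in 0..3.
#' @export
score_correlation <- function(rho, rubric = scoring_rubric()) {
  if (any(is.na(rho)) || any(abs(rho) > 1))
    stop_field("rho", "must lie in [-1, 1]")
  b <- rubric$corr_bins
  ifelse(rho > b[1], 3L, ifelse(rho > b[2], 2L, ifelse(rho > b[3], 1L, 0L)))
}

#' Summed biomarker score over a gene panel
#'
#' The TMB and MSI columns of the scorecard sum the per-gene correlation
#' bin scores over the scored gene panel (CCR8, CD274, PDCD1 in the
#' motivating analysis), so each column ranges 0..3 x (number of genes).
#'
#' @param per_gene_rho Named numeric: biomarker correlation per gene.
#' @inheritParams score_pvalue
#' @return Integer sum of per-gene bin scores.
#' @export
score_biomarker <- function(per_gene_rho, rubric = scoring_rubric()) {
  if (length(per_gene_rho) == 0) {
    warning("empty biomarker correlation map; scoring 0")
    return(0L)
  }
  sum(score_correlation(per_gene_rho, rubric))
}

resolve_component <- function(comp, raw_key, score_key, bin_fun, rubric, sum_it = FALSE) {
  if (!is.null(comp[[raw_key]])) {
    v <- unlist(comp[[raw_key]])
    s <- bin_fun(v, rubric)
    if (sum_it) sum(s) else s
  } else if (!is.null(comp[[score_key]])) {
    s <- unlist(comp[[score_key]])
    if (sum_it) sum(s) else as.integer(s)
  } else {
    stop(sprintf("missing component: neither '%s' nor '%s' supplied",
                 raw_key, score_key), call. = FALSE)
  }
}

#' Aggregate component inputs into a per-cancer scorecard
#'
#' Each component may be supplied raw (a p-value or correlation, which is
#' binned with the rubric) or pre-binned (a score); raw takes precedence.
#' The final score is the plain sum of the three checkpoint scores, the
#' Treg-infiltration score, the TMB and MSI sums, and the
#' standard-of-care bonus.
#'
#' @param cancer_type Label.
#' @param components List with entries (raw / pre-binned alternatives):
#'   `checkpoint_p` or `checkpoint_scores` (named over the checkpoint
#'   genes); `treg_rho` or `treg_score`; `tmb_rho` (named per gene) or
#'   `tmb_score` (the summed column value); `msi_rho` or `msi_score`.
#' @param soc Logical: are ICIs standard of care for this cancer?
#' @param rubric A [scoring_rubric()].
#' @return A `scorecard` list with the component scores and `final`.
#' @export
aggregate_scorecard <- function(cancer_type, components, soc,
                                rubric = scoring_rubric()) {
  cp <- resolve_component(components, "checkpoint_p", "checkpoint_scores",
                          score_pvalue, rubric)
  if (is.null(names(cp)) && length(cp) == 3)
    names(cp) <- c("PDCD1", "CD274", "CTLA4")
  treg <- resolve_component(components, "treg_rho", "treg_score",
                            score_correlation, rubric)
  tmb <- resolve_component(components, "tmb_rho", "tmb_score",
                           score_correlation, rubric, sum_it = TRUE)
  msi <- resolve_component(components, "msi_rho", "msi_score",
                           score_correlation, rubric, sum_it = TRUE)
  clinical <- if (isTRUE(soc)) rubric$soc_bonus else 0L
  final <- sum(cp) + treg + tmb + msi + clinical
  structure(list(cancer_type = cancer_type,
                 checkpoint_scores = cp,
                 treg_infiltration_score = as.integer(treg),
                 tmb_score = as.integer(tmb), msi_score = as.integer(msi),
                 clinical_points = as.integer(clinical),
                 final = as.integer(final)),
            class = "scorecard")
}

#' @export
print.scorecard <- function(x, ...) {
  cat(sprintf("%s: checkpoints %s | treg %d | TMB %d | MSI %d | clinical %d => final %d\n",
              x$cancer_type, paste(x$checkpoint_scores, collapse = "/"),
              x$treg_infiltration_score, x$tmb_score, x$msi_score,
              x$clinical_points, x$final))
  invisible(x)
}

#' Rank scorecards into an indication ordering
#'
#' Descending by final score; ties broken by cancer-type label ascending.
#'
#' @param cards List of `scorecard`s.
#' @return The list reordered.
#' @export
rank_indications <- function(cards) {
  if (length(cards) < 1) stop("need at least one scorecard", call. = FALSE)
  finals <- vapply(cards, function(c) as.numeric(c[["final"]]), 0)
  labels <- vapply(cards, `[[`, "", "cancer_type")
  cards[order(-finals, labels)]
}

#' Turn scorecards into a table in the published scorecard schema
#'
#' @param cards List of `scorecard`s.
#' @return Data frame with one row per cancer: the three checkpoint scores,
#'   Treg infiltration, TMB, MSI, clinical points, final.
#' @export
scorecard_table <- function(cards) {
  do.call(rbind, lapply(cards, function(c) {
    cp <- c$checkpoint_scores
    data.frame(cancer_type = c$cancer_type,
               PDCD1 = unname(cp[1]), CD274 = unname(cp[2]), CTLA4 = unname(cp[3]),
               treg_infiltration = c$treg_infiltration_score,
               TMB = c$tmb_score, MSI = c$msi_score,
               clinical = c$clinical_points, final = c$final,
               stringsAsFactors = FALSE)
  }))
}

#' Score all cancers from a components file
#'
#' The YAML lists one block per cancer type, each holding the component
#' entries understood by [aggregate_scorecard()] plus `soc: true/false`.
#' A bundled example (`system.file("extdata", "ici_components.yaml",
#' package = "treghub")`) carries the six-cancer worked example.
#'
#' @param path YAML file path, or a pre-parsed named list.
#' @param rubric A [scoring_rubric()].
#' @return Ranked list of `scorecard`s.
#' @export
score_components <- function(path, rubric = scoring_rubric()) {
  spec <- if (is.character(path)) yaml::read_yaml(path) else path
  cards <- lapply(names(spec), function(ct) {
    comp <- spec[[ct]]
    aggregate_scorecard(ct, comp, soc = isTRUE(comp$soc), rubric = rubric)
  })
  rank_indications(cards)
}

#' Build scorecards directly from correlation-stage outputs
#'
#' Wires the correlation module into the scoring module: checkpoint p-values
#' come from [checkpoint_correlations()] records, per-gene TMB/MSI
#' correlations from [biomarker_correlations()] records. Treg-infiltration
#' correlations (an external estimate, e.g. from an immune-deconvolution
#' platform) and the standard-of-care flags are supplied per cancer.
#'
#' @param checkpoint_records Output of [checkpoint_correlations()].
#' @param tmb_records,msi_records Outputs of [biomarker_correlations()].
#' @param treg_rho Named numeric: Treg-infiltration correlation per cancer.
#' @param soc Named logical: standard-of-care ICI status per cancer.
#' @param rubric A [scoring_rubric()].
#' @return Ranked list of `scorecard`s.
#' @export
score_from_correlations <- function(checkpoint_records, tmb_records, msi_records,
                                    treg_rho, soc, rubric = scoring_rubric()) {
  cts <- unique(checkpoint_records$cancer_type)
  cards <- lapply(cts, function(ct) {
    cp <- checkpoint_records[checkpoint_records$cancer_type == ct, ]
    tmb <- tmb_records[tmb_records$cancer_type == ct, ]
    msi <- msi_records[msi_records$cancer_type == ct, ]
    if (!ct %in% names(treg_rho))
      stop(sprintf("missing component: treg_rho for %s", ct), call. = FALSE)
    comp <- list(
      checkpoint_p = stats::setNames(cp$p_value, cp$y_name),
      treg_rho = treg_rho[[ct]],
      tmb_rho = stats::setNames(tmb$rho, tmb$x_name),
      msi_rho = stats::setNames(msi$rho, msi$x_name))
    aggregate_scorecard(ct, comp, soc = isTRUE(soc[[ct]]), rubric = rubric)
  })
  rank_indications(cards)
}

#' @rdname scorecard_table
#' @param path Output path (TSV for the table, JSON for the cards).
#' @export
write_scorecards <- function(cards, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(lapply(cards, unclass), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(scorecard_table(cards), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
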