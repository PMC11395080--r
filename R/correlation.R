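#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the two-sided p-value comes from `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on n - 2 degrees of freedom, the large-sample approximation the
#' pan-cancer web platforms report. `rho = +/-1` yields p = 0. Zero-variance
#' input is an error (the correlation is undefined, not zero).
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop_field("x/y", "must have equal length")
  n <- length(x)
  if (n < 3) stop_field("x/y", "need at least 3 observations")
  if (any(is.na(x)) || any(is.na(y))) stop_field("x/y", "must not contain NA")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for zero-variance input", call. = FALSE)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
    rho <- sign(rho)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

star_label <- function(p) ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))

panel_gene_cols <- function(panel) {
  setdiff(colnames(panel), c("sample", "cancer_type", "TMB", "MSI"))
}

#' Per-cancer correlation of a target gene with partner genes
#'
#' One record per (cancer type, partner): Spearman rho and p of the target
#' gene's expression against the partner's, over the samples of that cancer.
#'
#' @param panel Panel data frame (columns `sample`, `cancer_type`, `TMB`,
#'   `MSI`, plus gene columns), as from [simulate_pan_cancer_panel()] or
#'   [read_panel_tsv()].
#' @param target Target gene column name.
#' @param partners Character vector of partner gene columns.
#' @return Data frame `cancer_type`, `x_name`, `y_name`, `rho`, `p_value`,
#'   `n`.
#' @export
checkpoint_correlations <- function(panel, target, partners) {
  genes <- panel_gene_cols(panel)
  missing <- setdiff(c(target, partners), genes)
  if (length(missing))
    stop(sprintf("gene(s) not in panel: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  out <- list()
  for (ct in unique(panel$cancer_type)) {
    sub <- panel[panel$cancer_type == ct, , drop = FALSE]
    for (g in partners) {
      r <- spearman_cor(sub[[target]], sub[[g]])
      out[[length(out) + 1]] <- data.frame(
        cancer_type = ct, x_name = target, y_name = g,
        rho = r$rho, p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-cancer correlation of genes with TMB or MSI
#'
#' One record per (cancer type, gene), with significance stars in the
#' radar-chart convention: `"*"` for p < 0.05, `"**"` for p < 0.01.
#'
#' @inheritParams checkpoint_correlations
#' @param genes Gene columns to correlate with the biomarker.
#' @param biomarker `"TMB"` or `"MSI"`.
#' @return Data frame `cancer_type`, `x_name`, `y_name` (= biomarker),
#'   `rho`, `p_value`, `n`, `stars`.
#' @export
biomarker_correlations <- function(panel, genes, biomarker = c("TMB", "MSI")) {
  biomarker <- match.arg(biomarker)
  missing <- setdiff(genes, panel_gene_cols(panel))
  if (length(missing))
    stop(sprintf("gene(s) not in panel: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  out <- list()
  for (ct in unique(panel$cancer_type)) {
    sub <- panel[panel$cancer_type == ct, , drop = FALSE]
    for (g in genes) {
      r <- spearman_cor(sub[[g]], sub[[biomarker]])
      out[[length(out) + 1]] <- data.frame(
        cancer_type = ct, x_name = g, y_name = biomarker,
        rho = r$rho, p_value = r$p_value, n = r$n,
        stars = star_label(r$p_value), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @rdname checkpoint_correlations
#' @param records Correlation table.
#' @param path Output TSV path.
#' @export
write_correlations_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Radar-chart data: biomarker correlations keyed by cancer type
#'
#' @param records Output of [biomarker_correlations()].
#' @param path Output JSON path.
#' @export
write_radar_json <- function(records, path) {
  by_ct <- split(records[, c("x_name", "y_name", "rho", "p_value", "stars")],
                 records$cancer_type)
  jsonlite::write_json(by_ct, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
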