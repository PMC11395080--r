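#' Median-of-ratios size factors
#'
#' For each sample j, the size factor is the median over reference genes of
#' `count[i, j] / geomean_i`, where `geomean_i` is the geometric mean of gene
#' i across samples. Reference genes are those with strictly positive counts
#' in every sample; if none exist, genes positive in at least half the
#' samples are used instead (geometric means then taken over their positive
#' entries). Factors are reported as-is, with no further rescaling.
#'
#' @param cm A [count_matrix()] or a counts matrix.
#' @return Named positive numeric vector, one entry per sample.
#' @export
estimate_size_factors <- function(cm) {
  counts <- if (inherits(cm, "count_matrix")) cm$counts else cm
  n <- ncol(counts)
  allpos <- rowSums(counts > 0) == n
  if (any(allpos)) {
    sub <- counts[allpos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    ratios <- sub / geo
  } else {
    mostpos <- rowSums(counts > 0) >= n / 2
    if (!any(mostpos))
      stop("no gene is expressed in at least half the samples; ",
           "size factors cannot be estimated", call. = FALSE)
    sub <- counts[mostpos, , drop = FALSE]
    logs <- log(sub)
    logs[!is.finite(logs)] <- NA
    geo <- exp(rowMeans(logs, na.rm = TRUE))
    ratios <- sub / geo
    ratios[sub == 0] <- NA
  }
  sf <- apply(ratios, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor estimate; check for empty samples", call. = FALSE)
  stats::setNames(sf, colnames(counts))
}

#' Per-gene method-of-moments NB dispersion
#'
#' Estimates the dispersion alpha of Var = mu + alpha * mu^2 on normalized
#' counts. Within each group the moment estimate
#' `(var_g - mean_g) / mean_g^2` is formed around the group's own mean, and
#' the larger of the two group estimates is kept — a conservative envelope
#' that keeps the downstream Wald test close to nominal size at small n —
#' floored at `alpha_floor` so under-dispersed (e.g. constant) genes remain
#' valid NB fits.
#'
#' @param cm A [count_matrix()].
#' @param size_factors As from [estimate_size_factors()].
#' @param alpha_floor Lower bound for the estimate.
#' @return Named positive numeric vector, one entry per gene.
#' @export
estimate_dispersions <- function(cm, size_factors = estimate_size_factors(cm),
                                 alpha_floor = 1e-8) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(size_factors <= 0)) stop_field("size_factors", "must be positive")
  z <- sweep(cm$counts, 2, size_factors[colnames(cm$counts)], "/")
  per_group <- sapply(c("case", "control"), function(g) {
    zg <- z[, cm$group == g, drop = FALSE]
    m <- rowMeans(zg)
    v <- apply(zg, 1, stats::var)
    ifelse(m > 0, (v - m) / m^2, 0)
  })
  alpha <- pmax(alpha_floor, apply(per_group, 1, max))
  stats::setNames(alpha, rownames(cm$counts))
}

# Vectorized IRLS for the per-gene NB GLM with log link, design
# [intercept, case indicator] and offsets log(s_j). All genes are iterated
# simultaneously; the 2x2 weighted normal equations are solved in closed
# form. Returns coefficients on the natural-log scale plus SEs from the
# expected Fisher information (weights mu / (1 + alpha * mu)).
nb_irls <- function(counts, x, offset, alpha, max_iter = 100, tol = 1e-8,
                    beta_cap = 30) {
  ng <- nrow(counts)
  mean_norm <- rowMeans(sweep(counts, 2, exp(offset[1, ]), "/"))
  b0 <- log(pmax(mean_norm, 1e-8))
  b1 <- numeric(ng)
  converged <- rep(FALSE, ng)
  dev_old <- rep(Inf, ng)
  deviance <- function(mu) {
    term1 <- counts * log(ifelse(counts > 0, counts / mu, 1))
    term2 <- (counts + 1 / alpha) * log((1 + alpha * counts) / (1 + alpha * mu))
    2 * rowSums(term1 - term2)
  }
  for (it in seq_len(max_iter)) {
    eta <- offset + b0 + outer(b1, x)
    mu <- pmax(exp(eta), 1e-10)
    W <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (counts - mu) / mu
    sw <- rowSums(W)
    swx <- as.vector(W %*% x)                 # x is 0/1 so sum(W x^2) = sum(W x)
    swz <- rowSums(W * z)
    swxz <- as.vector((W * z) %*% x)
    det <- sw * swx - swx^2
    ok <- det > 1e-12
    nb0 <- ifelse(ok, (swx * swz - swx * swxz) / det, b0)
    nb1 <- ifelse(ok, (sw * swxz - swx * swz) / det, b1)
    nb1 <- pmin(pmax(nb1, -beta_cap), beta_cap)
    b0 <- nb0; b1 <- nb1
    eta <- offset + b0 + outer(b1, x)
    mu <- pmax(exp(eta), 1e-10)
    dev <- deviance(mu)
    converged <- converged | abs(dev - dev_old) < tol * (abs(dev_old) + 1)
    dev_old <- dev
    if (all(converged)) break
  }
  W <- mu / (1 + alpha * mu)
  sw <- rowSums(W)
  swx <- as.vector(W %*% x)
  det <- sw * swx - swx^2
  se1 <- ifelse(det > 1e-12, sqrt(sw / det), NA_real_)
  list(beta0 = b0, beta1 = b1, se1 = se1, converged = converged)
}

#' Negative-binomial Wald test for differential expression
#'
#' Fits, per gene, an NB GLM with log link, offsets `log(size_factors)` and
#' design intercept + case indicator, with the dispersion fixed at its
#' per-gene estimate. The group coefficient is reported in log2 units; its
#' standard error comes from the expected Fisher information, and the
#' two-sided p-value from the standard normal reference for
#' `stat = log2FoldChange / lfcSE`. Genes with all-zero counts receive
#' `log2FoldChange = 0`, `pvalue = 1`. Genes whose fit does not converge
#' within the iteration cap are flagged (`converged = FALSE`) and assigned
#' the conservative `pvalue = 1`.
#'
#' @param cm A [count_matrix()].
#' @param size_factors,dispersions Precomputed estimates; defaults recompute
#'   them from `cm`.
#' @return Data frame with columns `gene`, `baseMean`, `log2FoldChange`,
#'   `lfcSE`, `stat`, `pvalue`, `padj` (NA until [adjust_pvalues()]),
#'   `converged`.
#' @export
wald_test <- function(cm, size_factors = estimate_size_factors(cm),
                      dispersions = estimate_dispersions(cm, size_factors)) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  genes <- rownames(counts)
  if (!all(genes %in% names(dispersions)) && length(dispersions) != nrow(counts))
    stop("dispersions must cover every gene", call. = FALSE)
  sf <- size_factors[colnames(counts)]
  alpha <- if (!is.null(names(dispersions))) dispersions[genes] else dispersions
  x <- as.numeric(cm$group == "case")
  offset <- matrix(log(sf), nrow(counts), ncol(counts), byrow = TRUE)
  nonzero <- rowSums(counts) > 0

  res <- data.frame(gene = genes, baseMean = rowMeans(sweep(counts, 2, sf, "/")),
                    log2FoldChange = 0, lfcSE = NA_real_, stat = NA_real_,
                    pvalue = 1, padj = NA_real_, converged = TRUE,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (any(nonzero)) {
    fit <- nb_irls(counts[nonzero, , drop = FALSE], x,
                   offset[nonzero, , drop = FALSE], alpha[nonzero])
    l2fc <- fit$beta1 / log(2)
    se <- fit$se1 / log(2)
    stat <- ifelse(is.finite(se) & se > 0, l2fc / se, NA_real_)
    p <- ifelse(is.na(stat), 1, 2 * stats::pnorm(-abs(stat)))
    p[!fit$converged] <- 1
    if (any(!fit$converged))
      warning(sprintf("%d gene fits did not converge; their p-values were set to 1",
                      sum(!fit$converged)))
    res$log2FoldChange[nonzero] <- l2fc
    res$lfcSE[nonzero] <- se
    res$stat[nonzero] <- stat
    res$pvalue[nonzero] <- p
    res$converged[nonzero] <- fit$converged
  }
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Fills the `padj` column with the BH step-up adjustment (monotone,
#' capped at 1; ties share a value).
#'
#' @param records DE table from [wald_test()].
#' @return The table with `padj` populated.
#' @export
adjust_pvalues <- function(records) {
  if (any(records$pvalue < 0 | records$pvalue > 1, na.rm = TRUE))
    stop_field("pvalue", "must lie in [0, 1]")
  records$padj <- stats::p.adjust(records$pvalue, method = "BH")
  records
}

#' Threshold DE records into up/down DEG sets
#'
#' A gene is upregulated when `log2FoldChange >= lfc_min` and its (raw by
#' default) p-value is `< p_max`; downregulated when
#' `log2FoldChange <= -lfc_min` under the same p rule. The fold-change
#' boundary is inclusive, the p boundary exclusive.
#'
#' @param records DE table.
#' @param lfc_min Minimum absolute log2 fold change (default 0.5).
#' @param p_max Significance threshold (default 0.05).
#' @param use_adjusted Filter on `padj` instead of `pvalue`.
#' @return A `deg_set`: list with character vectors `up`, `down` and the
#'   thresholds used.
#' @export
filter_degs <- function(records, lfc_min = 0.5, p_max = 0.05,
                        use_adjusted = FALSE) {
  p <- if (use_adjusted) records$padj else records$pvalue
  if (use_adjusted && all(is.na(p)))
    stop("padj is empty; run adjust_pvalues() first", call. = FALSE)
  sig <- !is.na(p) & p < p_max
  structure(list(
    up = records$gene[sig & records$log2FoldChange >= lfc_min],
    down = records$gene[sig & records$log2FoldChange <= -lfc_min],
    thresholds = list(lfc_min = lfc_min, p_max = p_max,
                      use_adjusted = use_adjusted)),
    class = "deg_set")
}

#' Run the full DE stage on one dataset
#'
#' Size factors, dispersions, Wald test and BH adjustment in one call.
#'
#' @inheritParams wald_test
#' @return DE table with `padj` populated.
#' @export
run_de <- function(cm) {
  sf <- estimate_size_factors(cm)
  disp <- estimate_dispersions(cm, sf)
  adjust_pvalues(wald_test(cm, sf, disp))
}

#' @rdname run_de
#' @param records DE table.
#' @param path Output TSV path.
#' @export
write_de_tsv <- function(records, path) {
  utils::write.table(records[, c("gene", "baseMean", "log2FoldChange",
                                 "lfcSE", "stat", "pvalue", "padj")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname run_de
#' @export
read_de_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "log2FoldChange", "pvalue")
  if (!all(need %in% colnames(df)))
    stop("DE TSV must have columns gene, log2FoldChange, pvalue", call. = FALSE)
  df
}
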