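#' Configuration for the negative-binomial count simulator
#'
#' Defines the generative model the differential-expression stage assumes:
#' counts are drawn NB(mean = s_j * mu_i * 2^(x_j * beta_i), dispersion alpha)
#' with Var = mu + alpha * mu^2, where s_j is a per-sample size factor drawn
#' log-uniformly from `size_factor_range`, x_j the case indicator and beta_i
#' the planted log2 fold change (`lfc_magnitude` in absolute value for planted
#' DEGs, 0 otherwise).
#'
#' @param n_genes Number of genes simulated.
#' @param group_sizes Integer pair `(case, control)`; each must be >= 2.
#' @param mean_log_expression Natural-log mean of the baseline gene means
#'   mu_i, which are drawn log-normally.
#' @param sd_log_expression Natural-log spread of the baseline means
#'   (0 makes all genes share `exp(mean_log_expression)`).
#' @param dispersion NB dispersion alpha (Var = mu + alpha * mu^2). The
#'   default 0.05 is a typical bulk RNA-seq value.
#' @param frac_de Fraction of genes planted as differentially expressed;
#'   `round(frac_de * n_genes)` genes are flagged.
#' @param lfc_magnitude Absolute log2 fold change of planted DEGs.
#' @param size_factor_range Positive pair; size factors are sampled
#'   log-uniformly within it.
#' @param frac_up Fraction of planted DEGs that are upregulated.
#' @param seed Required integer seed; generation is deterministic given the
#'   full configuration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000, group_sizes = c(5, 5),
                       mean_log_expression = log(100), sd_log_expression = 1,
                       dispersion = 0.05, frac_de = 0.02, lfc_magnitude = 2,
                       size_factor_range = c(0.7, 1.4), frac_up = 0.5,
                       seed) {
  if (missing(seed)) stop_field("seed", "is required")
  if (length(sd_log_expression) != 1L || !is.numeric(sd_log_expression) ||
      is.na(sd_log_expression) || sd_log_expression < 0)
    stop_field("sd_log_expression", "must be a single nonnegative number")
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    group_sizes = c(assert_count(group_sizes[1], "group_sizes"),
                    assert_count(group_sizes[2], "group_sizes")),
    mean_log_expression = as.numeric(mean_log_expression),
    sd_log_expression = as.numeric(sd_log_expression),
    dispersion = assert_positive(dispersion, "dispersion"),
    frac_de = assert_fraction(frac_de, "frac_de"),
    lfc_magnitude = assert_positive(lfc_magnitude, "lfc_magnitude"),
    size_factor_range = assert_range(size_factor_range, "size_factor_range"),
    frac_up = assert_fraction(frac_up, "frac_up"),
    seed = assert_count(seed, "seed", min = 0L))
  if (any(cfg$group_sizes < 2)) stop_field("group_sizes", "each group needs >= 2 samples")
  class(cfg) <- "sim_config"
  cfg
}

gene_labels <- function(n, prefix = "G") sprintf("%s%05d", prefix, seq_len(n))

# Internal core shared by simulate_counts and simulate_dataset_trio: given a
# per-gene true log2FC vector, draws the count matrix. Assumes RNG is seeded.
draw_counts <- function(cfg, true_l2fc, sample_prefix = "S") {
  n1 <- cfg$group_sizes[1]; n2 <- cfg$group_sizes[2]
  n <- n1 + n2
  grp <- c(rep("case", n1), rep("control", n2))
  x <- as.numeric(grp == "case")
  sf <- exp(stats::runif(n, log(cfg$size_factor_range[1]),
                         log(cfg$size_factor_range[2])))
  mu_base <- exp(stats::rnorm(cfg$n_genes, cfg$mean_log_expression,
                              cfg$sd_log_expression))
  mu <- outer(mu_base, sf) * 2^outer(true_l2fc, x)
  counts <- matrix(stats::rnbinom(cfg$n_genes * n, mu = mu,
                                  size = 1 / cfg$dispersion),
                   nrow = cfg$n_genes)
  rownames(counts) <- gene_labels(cfg$n_genes)
  colnames(counts) <- sprintf("%s%02d_%s", sample_prefix, seq_len(n),
                              ifelse(grp == "case", "case", "ctrl"))
  count_matrix(counts, stats::setNames(grp, colnames(counts)))
}

truth_table <- function(genes, l2fc) {
  data.frame(gene = genes, is_de = l2fc != 0, true_log2fc = l2fc,
             stringsAsFactors = FALSE)
}

#' Simulate a count matrix with planted differential expression
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`
#'   (data frame `gene`, `is_de`, `true_log2fc`). Exactly
#'   `round(frac_de * n_genes)` genes carry `true_log2fc` of
#'   `+/- lfc_magnitude`; all others are 0.
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n_de <- round(cfg$frac_de * cfg$n_genes)
    genes <- gene_labels(cfg$n_genes)
    l2fc <- numeric(cfg$n_genes)
    if (n_de > 0) {
      de_idx <- sample.int(cfg$n_genes, n_de)
      n_up <- round(cfg$frac_up * n_de)
      signs <- c(rep(1, n_up), rep(-1, n_de - n_up))
      l2fc[de_idx] <- signs * cfg$lfc_magnitude
    }
    cm <- draw_counts(cfg, l2fc)
    list(counts = cm, truth = truth_table(genes, l2fc))
  })
}

#' Simulate three count datasets sharing a planted DEG core
#'
#' Emulates the three-cohort design of the motivating study (case/control
#' splits 5/5, 12/6 and 6/6 by default): each dataset has its own planted
#' DEGs, but exactly `shared_core` of them (with identical signs,
#' `core_up` upregulated) are common to all three. The remaining planted
#' DEGs are dataset-private and drawn from disjoint gene pools so that the
#' truth-table intersection is exactly the shared core.
#'
#' @param cfg A [sim_config()]; `group_sizes` supplies the first dataset's
#'   shape unless `group_sizes_list` is given.
#' @param shared_core Number of DEGs common to all three datasets; must not
#'   exceed the per-dataset planted count `round(frac_de * n_genes)`.
#' @param core_up Number of upregulated genes in the shared core
#'   (default 35 of 57, mirroring the up/down split the pipeline is
#'   expected to recover).
#' @param group_sizes_list List of three `(case, control)` pairs.
#' @return List of three elements, each as returned by [simulate_counts()],
#'   named `dataset1..dataset3`.
#' @export
simulate_dataset_trio <- function(cfg, shared_core = 57,
                                  core_up = NULL,
                                  group_sizes_list = list(c(5, 5), c(12, 6), c(6, 6))) {
  stopifnot(inherits(cfg, "sim_config"))
  shared_core <- assert_count(shared_core, "shared_core", min = 0L)
  n_de <- round(cfg$frac_de * cfg$n_genes)
  if (shared_core > n_de)
    stop_field("shared_core", sprintf(
      "exceeds the planted DEG count %d (= round(frac_de * n_genes))", n_de))
  core_up <- if (is.null(core_up)) min(35L, shared_core) else
    assert_count(core_up, "core_up", min = 0L)
  if (core_up > shared_core) stop_field("core_up", "exceeds shared_core")
  if (length(group_sizes_list) != 3)
    stop_field("group_sizes_list", "must list three (case, control) pairs")

  with_seed(cfg$seed, {
    genes <- gene_labels(cfg$n_genes)
    n_private <- n_de - shared_core
    need <- shared_core + 3 * n_private
    if (need > cfg$n_genes)
      stop_field("frac_de", "too many planted DEGs for disjoint private pools")
    picked <- sample.int(cfg$n_genes, need)
    core_idx <- picked[seq_len(shared_core)]
    core_sign <- c(rep(1, core_up), rep(-1, shared_core - core_up))
    priv <- if (n_private > 0)
      split(picked[(shared_core + 1):need], rep(1:3, each = n_private))
    else list()
    seeds <- sample.int(.Machine$integer.max - 1L, 3)
    out <- lapply(1:3, function(d) {
      cfg_d <- cfg
      cfg_d$group_sizes <- c(assert_count(group_sizes_list[[d]][1], "group_sizes_list"),
                             assert_count(group_sizes_list[[d]][2], "group_sizes_list"))
      l2fc <- numeric(cfg$n_genes)
      l2fc[core_idx] <- core_sign * cfg$lfc_magnitude
      if (n_private > 0) {
        pidx <- priv[[as.character(d)]]
        l2fc[pidx] <- sample(c(-1, 1), n_private, replace = TRUE) * cfg$lfc_magnitude
      }
      cm <- with_seed(seeds[d], draw_counts(cfg_d, l2fc, sample_prefix = sprintf("D%d_S", d)))
      list(counts = cm, truth = truth_table(genes, l2fc))
    })
    names(out) <- paste0("dataset", 1:3)
    attr(out, "core_genes") <- genes[core_idx]
    attr(out, "core_sign") <- core_sign
    out
  })
}

#' Simulate a gene-set collection with one spiked set
#'
#' Builds a collection in which one set is exactly `spiked_set` and the
#' remaining sets are uniform draws from `universe` — the fixture used to
#' verify that over-representation analysis ranks a truly enriched set first.
#'
#' @param universe Character vector of gene labels.
#' @param n_sets Total number of sets (including the spiked one).
#' @param set_size_range Integer pair; random set sizes are drawn uniformly
#'   within it.
#' @param spiked_set Character vector, a subset of `universe`.
#' @param seed Integer seed.
#' @return A [gene_set_collection()] whose first set (`"SPIKED"`) equals
#'   `spiked_set`.
#' @export
simulate_gene_sets <- function(universe, n_sets, set_size_range, spiked_set, seed) {
  n_sets <- assert_count(n_sets, "n_sets")
  if (!all(spiked_set %in% universe))
    stop_field("spiked_set", "contains genes outside the universe")
  sr <- c(assert_count(set_size_range[1], "set_size_range"),
          assert_count(set_size_range[2], "set_size_range"))
  if (sr[1] > sr[2]) stop_field("set_size_range", "must be nondecreasing")
  with_seed(seed, {
    sets <- list(SPIKED = unique(spiked_set))
    if (n_sets > 1) {
      for (i in seq_len(n_sets - 1)) {
        sz <- if (sr[1] == sr[2]) sr[1] else sample(seq(sr[1], sr[2]), 1)
        sets[[sprintf("RAND%03d", i)]] <- sample(universe, min(sz, length(universe)))
      }
    }
    gene_set_collection(sets, universe = universe)
  })
}

#' Simulate a protein-interaction graph with planted hubs
#'
#' Grows a simple undirected graph by preferential attachment and labels the
#' earliest-added (hence highest-expected-degree) vertices with `hub_labels`,
#' so downstream centrality ranking has a known truth. Edge confidence
#' scores are drawn uniformly in 400..999 on the STRING 0-1000 scale.
#'
#' @param n_nodes Total vertices; must exceed `length(hub_labels)` (>= 1 hub).
#' @param attachment_edges Edges added per new vertex; must be < `n_nodes`.
#' @param hub_labels Character vector of planted hub gene labels.
#' @param seed Integer seed.
#' @return An [igraph::igraph] with vertex attribute `name` and edge
#'   attribute `combined_score`.
#' @export
simulate_ppi <- function(n_nodes, attachment_edges = 2, hub_labels, seed) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 2L)
  attachment_edges <- assert_count(attachment_edges, "attachment_edges")
  if (attachment_edges >= n_nodes)
    stop_field("attachment_edges", "must be smaller than n_nodes")
  if (length(hub_labels) < 1 || length(hub_labels) >= n_nodes)
    stop_field("hub_labels", "need 1 <= length(hub_labels) < n_nodes")
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attachment_edges, directed = FALSE,
                           algorithm = "psumtree")
    g <- igraph::simplify(g)
    # hub labels go on the most connected vertices
    labels <- character(n_nodes)
    ord <- order(igraph::degree(g), decreasing = TRUE)
    labels[ord[seq_along(hub_labels)]] <- hub_labels
    labels[labels == ""] <- gene_labels(n_nodes - length(hub_labels),
                                        prefix = "N")
    igraph::V(g)$name <- labels
    igraph::E(g)$combined_score <- sample(400:999, igraph::ecount(g), replace = TRUE)
    g
  })
}

#' Configuration for the pan-cancer correlation panel simulator
#'
#' @param cancer_types Character labels (TCGA-style, e.g. `"BRCA"`).
#' @param n_samples Samples per cancer type.
#' @param target_gene Label of the target gene (default `"CCR8"`).
#' @param partner_genes Labels of partner (checkpoint) genes.
#' @param target_rank_corr Named numeric in (-1, 1): requested Spearman
#'   correlation of each partner with the target.
#' @param tmb_corr,msi_corr Named numeric in (-1, 1): requested Spearman
#'   correlation of genes with TMB / MSI. Genes not named default to 0.
#' @param tmb_rate Mean mutation count for the Poisson TMB marginal.
#' @param seed Integer seed.
#' @export
panel_config <- function(cancer_types, n_samples, target_gene = "CCR8",
                         partner_genes = c("PDCD1", "CD274", "CTLA4"),
                         target_rank_corr = c(PDCD1 = 0.584, CD274 = 0.606, CTLA4 = 0.758),
                         tmb_corr = numeric(), msi_corr = numeric(),
                         tmb_rate = 100, seed) {
  if (missing(seed)) stop_field("seed", "is required")
  for (v in list(target_rank_corr, tmb_corr, msi_corr))
    if (length(v) && any(abs(v) >= 1))
      stop_field("rank_corr", "requested correlations must lie in (-1, 1)")
  if (!all(names(target_rank_corr) %in% partner_genes))
    stop_field("target_rank_corr", "names must be partner genes")
  structure(list(cancer_types = as.character(cancer_types),
                 n_samples = assert_count(n_samples, "n_samples"),
                 target_gene = target_gene,
                 partner_genes = as.character(partner_genes),
                 target_rank_corr = target_rank_corr,
                 tmb_corr = tmb_corr, msi_corr = msi_corr,
                 tmb_rate = assert_positive(tmb_rate, "tmb_rate"),
                 seed = assert_count(seed, "seed", min = 0L)),
            class = "panel_config")
}

# Spearman -> Pearson correlation of the Gaussian copula's latent normals.
# For bivariate normals, rho_S = (6/pi) asin(r/2); inverting gives exact
# rank-correlation control for continuous marginals.
spearman_to_latent <- function(rho_s) 2 * sin(pi * rho_s / 6)

build_latent_sigma <- function(cfg) {
  vars <- c(cfg$target_gene, cfg$partner_genes, "TMB", "MSI")
  p <- length(vars)
  S <- diag(p); dimnames(S) <- list(vars, vars)
  set_pair <- function(a, b, rho_s) {
    S[a, b] <<- spearman_to_latent(rho_s); S[b, a] <<- S[a, b]
  }
  for (g in names(cfg$target_rank_corr)) set_pair(cfg$target_gene, g, cfg$target_rank_corr[[g]])
  # unspecified gene-gene pairs follow a one-factor completion through the
  # target, which keeps the requested entries and is PD for moderate values
  for (i in seq_along(cfg$partner_genes)) for (j in seq_along(cfg$partner_genes)) {
    if (i < j) {
      a <- cfg$partner_genes[i]; b <- cfg$partner_genes[j]
      S[a, b] <- S[b, a] <- S[cfg$target_gene, a] * S[cfg$target_gene, b]
    }
  }
  for (g in names(cfg$tmb_corr)) set_pair(g, "TMB", cfg$tmb_corr[[g]])
  for (g in names(cfg$msi_corr)) set_pair(g, "MSI", cfg$msi_corr[[g]])
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10)
    stop("requested correlation structure is not positive definite; ",
         "reduce the magnitudes or use Matrix::nearPD(S, corr = TRUE) on the ",
         "implied latent matrix to find the nearest feasible structure",
         call. = FALSE)
  S
}

#' Simulate a pan-cancer expression/TMB/MSI panel with controlled rank correlations
#'
#' Per cancer type, draws samples from a Gaussian copula whose latent
#' correlations are chosen so realized Spearman correlations converge to the
#' requested setpoints, then applies marginal transforms: expression is
#' log-normal (reported on the natural-log scale), TMB is Poisson with a
#' copula-driven rate, MSI is a logit-normal score in (0, 1).
#'
#' @param cfg A [panel_config()].
#' @return A data frame with columns `sample`, `cancer_type`, `TMB`, `MSI`
#'   and one column per gene.
#' @export
simulate_pan_cancer_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_config"))
  S <- build_latent_sigma(cfg)
  L <- chol(S)
  vars <- colnames(S)
  with_seed(cfg$seed, {
    out <- lapply(cfg$cancer_types, function(ct) {
      Z <- matrix(stats::rnorm(cfg$n_samples * length(vars)), ncol = length(vars)) %*% L
      colnames(Z) <- vars
      U <- stats::pnorm(Z)
      expr <- Z[, c(cfg$target_gene, cfg$partner_genes), drop = FALSE] + 3  # log expression
      tmb <- stats::qpois(U[, "TMB"], lambda = cfg$tmb_rate)
      msi <- stats::plogis(Z[, "MSI"])
      df <- data.frame(sample = sprintf("%s_%04d", ct, seq_len(cfg$n_samples)),
                       cancer_type = ct, TMB = tmb, MSI = msi,
                       stringsAsFactors = FALSE)
      cbind(df, as.data.frame(expr))
    })
    do.call(rbind, out)
  })
}

#' @rdname simulate_pan_cancer_panel
#' @param panel Panel data frame.
#' @param path Output TSV path.
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname simulate_pan_cancer_panel
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "cancer_type", "TMB", "MSI")
  if (!all(need %in% colnames(df)))
    stop("panel TSV must have columns sample, cancer_type, TMB, MSI", call. = FALSE)
  df
}
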