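#' Default end-to-end pipeline configuration
#'
#' Stage order: simulate (or load) three count cohorts, per-cohort NB Wald
#' differential expression, direction-consistent intersection,
#' over-representation analysis of the common DEGs, PPI centrality and hub
#' selection, pan-cancer correlation, and integrated indication scoring.
#' Every stage reads and writes plain files under `out_dir`, so any stage
#' can be re-run standalone from the previous stage's outputs.
#'
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return Nested configuration list; override entries before passing to
#'   [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("treghub_run_")) {
  list(
    out_dir = out_dir,
    seed = assert_count(seed, "seed", min = 0L),
    stages = c("simulate", "de", "overlap", "enrich", "network",
               "correlate", "score"),
    simulate = list(n_genes = 5000, frac_de = 0.02, lfc_magnitude = 2,
                    dispersion = 0.05, mean_log_expression = log(100),
                    shared_core = 57, core_up = 35,
                    group_sizes_list = list(c(5, 5), c(12, 6), c(6, 6)),
                    n_gene_sets = 50, set_size_range = c(10, 40),
                    ppi_nodes = 57, ppi_hubs = c("IL2RA", "TNFRSF4", "CCR8"),
                    panel_cancers = c("BRCA", "HNSC", "COAD", "STAD", "THCA", "READ"),
                    panel_n = 500),
    de = list(lfc_min = 0.5, p_max = 0.05, use_adjusted = FALSE),
    enrich = list(alpha = 0.05, on_adjusted = FALSE),
    network = list(min_score = 400, top = 10),
    correlate = list(target = "CCR8",
                     partners = c("PDCD1", "CD274", "CTLA4"),
                     biomarker_genes = c("CCR8", "CD274", "PDCD1")),
    score = list(treg_rho = NULL, soc = NULL))
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order, hands results between stages as
#' TSV/GMT/JSON files under `config$out_dir`, and writes a `manifest.json`
#' echoing every parameter and the per-stage record counts. Re-running with
#' an identical configuration reproduces identical outputs.
#'
#' @param config As from [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("treghub")),
                   seed = config$seed, parameters = config[setdiff(names(config), "out_dir")],
                   stages = list())
  note <- function(stage, ...) manifest$stages[[stage]] <<- list(...)
  on_fail <- function(stage, e) {
    writeLines(sprintf("FAILED at stage %s: %s", stage, conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  path <- function(...) file.path(config$out_dir, ...)
  enabled <- function(s) s %in% config$stages
  seeds <- (config$seed %% 1000000L) * 1000L + seq_len(10)  # keep < 2^31

  trio <- NULL
  if (enabled("simulate")) tryCatch({
    sc <- config$simulate
    cfg <- sim_config(n_genes = sc$n_genes, frac_de = sc$frac_de,
                      lfc_magnitude = sc$lfc_magnitude,
                      dispersion = sc$dispersion,
                      mean_log_expression = sc$mean_log_expression,
                      seed = seeds[1])
    trio <- simulate_dataset_trio(cfg, shared_core = sc$shared_core,
                                  core_up = sc$core_up,
                                  group_sizes_list = sc$group_sizes_list)
    for (nm in names(trio)) {
      write_counts_tsv(trio[[nm]]$counts, path(paste0(nm, "_counts.tsv")),
                       path(paste0(nm, "_meta.tsv")))
    }
    ppi <- simulate_ppi(sc$ppi_nodes, attachment_edges = 2,
                        hub_labels = sc$ppi_hubs, seed = seeds[2])
    write_string_tsv(ppi, path("ppi_edges.tsv"))
    panel_cfg <- panel_config(cancer_types = sc$panel_cancers,
                              n_samples = sc$panel_n,
                              tmb_corr = c(CCR8 = 0.35, CD274 = 0.3, PDCD1 = 0.3),
                              msi_corr = c(CCR8 = 0.25, CD274 = 0.25, PDCD1 = 0.2),
                              seed = seeds[3])
    write_panel_tsv(simulate_pan_cancer_panel(panel_cfg), path("panel.tsv"))
    note("simulate", datasets = length(trio),
         planted_core = length(attr(trio, "core_genes")))
  }, error = function(e) on_fail("simulate", e))

  de_tables <- NULL
  if (enabled("de")) tryCatch({
    files <- sort(list.files(config$out_dir, "_counts\\.tsv$", full.names = TRUE))
    if (!length(files)) stop("no *_counts.tsv inputs found in out_dir")
    de_tables <- lapply(files, function(f) {
      cm <- read_counts_tsv(f, sub("_counts", "_meta", f))
      run_de(cm)
    })
    names(de_tables) <- sub("_counts\\.tsv$", "", basename(files))
    for (nm in names(de_tables))
      write_de_tsv(de_tables[[nm]], path(paste0(nm, "_de.tsv")))
    note("de", datasets = length(de_tables),
         genes = vapply(de_tables, nrow, 0L))
  }, error = function(e) on_fail("de", e))

  common <- NULL
  if (enabled("overlap")) tryCatch({
    if (is.null(de_tables)) {
      files <- sort(list.files(config$out_dir, "_de\\.tsv$", full.names = TRUE))
      de_tables <- lapply(files, read_de_tsv)
      names(de_tables) <- sub("_de\\.tsv$", "", basename(files))
    }
    harmonized <- harmonize_gene_ids(de_tables)
    common <- intersect_degs(harmonized, lfc_min = config$de$lfc_min,
                             p_max = config$de$p_max,
                             use_adjusted = config$de$use_adjusted)
    write_common_degs_tsv(common, path("common_degs.tsv"))
    degs <- lapply(harmonized, filter_degs, lfc_min = config$de$lfc_min,
                   p_max = config$de$p_max,
                   use_adjusted = config$de$use_adjusted)
    venn <- list(up = venn_counts(lapply(degs, `[[`, "up")),
                 down = venn_counts(lapply(degs, `[[`, "down")))
    jsonlite::write_json(venn, path("venn_regions.json"), auto_unbox = FALSE)
    note("overlap", up = length(common$up), down = length(common$down))
  }, error = function(e) on_fail("overlap", e))

  if (enabled("enrich")) tryCatch({
    query <- c(common$up, common$down)
    universe <- unique(unlist(lapply(de_tables, `[[`, "gene")))
    coll <- simulate_gene_sets(universe, n_sets = config$simulate$n_gene_sets,
                               set_size_range = config$simulate$set_size_range,
                               spiked_set = if (length(query)) query else universe[1:5],
                               seed = seeds[4])
    write_gmt(coll, path("gene_sets.gmt"))
    records <- ora_test(query, coll)
    write_enrichment_tsv(records, path("enrichment.tsv"))
    sig <- significant_records(records, alpha = config$enrich$alpha,
                               on_adjusted = config$enrich$on_adjusted)
    note("enrich", sets_tested = nrow(records), significant = nrow(sig))
  }, error = function(e) on_fail("enrich", e))

  hubs <- NULL
  if (enabled("network")) tryCatch({
    g <- read_string_tsv(path("ppi_edges.tsv"),
                         min_score = config$network$min_score)
    cent <- centralities(g)
    write_centralities_tsv(cent, path("centralities.tsv"))
    hubs <- select_hubs(cent, k = min(config$network$top, nrow(cent)))
    writeLines(hubs, path("hubs.txt"))
    note("network", nodes = nrow(cent), edges = igraph::ecount(g),
         hubs = length(hubs))
  }, error = function(e) on_fail("network", e))

  cp <- tmb <- msi <- NULL
  if (enabled("correlate")) tryCatch({
    panel <- read_panel_tsv(path("panel.tsv"))
    cc <- config$correlate
    cp <- checkpoint_correlations(panel, cc$target, cc$partners)
    tmb <- biomarker_correlations(panel, cc$biomarker_genes, "TMB")
    msi <- biomarker_correlations(panel, cc$biomarker_genes, "MSI")
    write_correlations_tsv(cp, path("checkpoint_correlations.tsv"))
    write_correlations_tsv(rbind(tmb, msi), path("biomarker_correlations.tsv"))
    write_radar_json(rbind(tmb, msi), path("radar.json"))
    note("correlate", checkpoint_records = nrow(cp),
         biomarker_records = nrow(tmb) + nrow(msi))
  }, error = function(e) on_fail("correlate", e))

  if (enabled("score")) tryCatch({
    cts <- unique(cp$cancer_type)
    treg_rho <- config$score$treg_rho %||%
      stats::setNames(rep(0.35, length(cts)), cts)
    soc <- config$score$soc %||%
      stats::setNames(cts %in% c("BRCA", "HNSC", "COAD", "STAD"), cts)
    cards <- score_from_correlations(cp, tmb, msi, treg_rho = treg_rho,
                                     soc = soc)
    write_scorecards(cards, path("scorecards.tsv"))
    write_scorecards(cards, path("scorecards.json"))
    note("score", cancers = length(cards),
         top = cards[[1]]$cancer_type, top_score = cards[[1]]$final)
  }, error = function(e) on_fail("score", e))

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(manifest)
}
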