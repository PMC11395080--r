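#' Harmonize gene identifiers across DE tables
#'
#' Cross-cohort intersection needs one symbol space even when cohorts come
#' from different species. An optional two-column ortholog map
#' (`from`, `to`) is applied first, then symbols are case-folded to
#' uppercase. When two records collapse onto one symbol the record with the
#' smallest p-value is kept.
#'
#' @param de_tables Named list of DE tables (columns `gene`,
#'   `log2FoldChange`, `pvalue`, optionally `padj`).
#' @param ortholog_map Optional data frame or TSV path with two columns
#'   mapping source symbols to target symbols.
#' @return The list with harmonized, deduplicated `gene` columns.
#' @export
harmonize_gene_ids <- function(de_tables, ortholog_map = NULL) {
  map <- NULL
  if (!is.null(ortholog_map)) {
    if (is.character(ortholog_map)) {
      lines <- readLines(ortholog_map)
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      bad <- which(lengths(parts) != 2)
      if (length(bad))
        stop(sprintf("malformed ortholog map at line %d: expected 2 tab-separated fields",
                     bad[1]), call. = FALSE)
      map <- stats::setNames(vapply(parts, `[`, "", 2), vapply(parts, `[`, "", 1))
    } else {
      if (ncol(ortholog_map) < 2) stop_field("ortholog_map", "needs two columns")
      map <- stats::setNames(as.character(ortholog_map[[2]]),
                             as.character(ortholog_map[[1]]))
    }
  }
  lapply(de_tables, function(df) {
    g <- df$gene
    if (!is.null(map)) {
      hit <- g %in% names(map)
      g[hit] <- unname(map[g[hit]])
    }
    df$gene <- toupper(g)
    if (anyDuplicated(df$gene)) {
      df <- df[order(df$pvalue), , drop = FALSE]
      df <- df[!duplicated(df$gene), , drop = FALSE]
      df <- df[order(df$gene), , drop = FALSE]
      rownames(df) <- NULL
    }
    df
  })
}

#' Direction-consistent intersection of per-dataset DEG sets
#'
#' A gene is a common upregulated DEG only if it passes the up filter
#' (`log2FoldChange >= lfc_min`, p < `p_max`) in *every* dataset, and
#' likewise for down; genes with conflicting directions are excluded from
#' both lists. Also returns the log2FC matrix of the common genes across
#' datasets (the data behind a common-DEG heatmap).
#'
#' @param de_tables Named list (>= 2) of harmonized DE tables.
#' @inheritParams filter_degs
#' @return List with `up`, `down` (sorted character vectors) and
#'   `lfc_matrix` (data frame `gene`, `direction`, one log2FC column per
#'   dataset).
#' @export
intersect_degs <- function(de_tables, lfc_min = 0.5, p_max = 0.05,
                           use_adjusted = FALSE) {
  if (length(de_tables) < 2) stop("need at least two DE tables", call. = FALSE)
  if (is.null(names(de_tables)) || any(!nzchar(names(de_tables))))
    names(de_tables) <- paste0("dataset", seq_along(de_tables))
  degs <- lapply(de_tables, filter_degs, lfc_min = lfc_min, p_max = p_max,
                 use_adjusted = use_adjusted)
  up <- sort(Reduce(intersect, lapply(degs, `[[`, "up")))
  down <- sort(Reduce(intersect, lapply(degs, `[[`, "down")))
  common <- c(up, down)
  lfc <- sapply(de_tables, function(df)
    df$log2FoldChange[match(common, df$gene)])
  lfc_matrix <- data.frame(gene = common,
                           direction = rep(c("up", "down"), c(length(up), length(down))),
                           stringsAsFactors = FALSE)
  if (length(common)) lfc_matrix <- cbind(lfc_matrix, as.data.frame(lfc))
  structure(list(up = up, down = down, lfc_matrix = lfc_matrix),
            class = "common_degs")
}

#' @export
print.common_degs <- function(x, ...) {
  cat(sprintf("common DEGs: %d total (%d up, %d down)\n",
              length(x$up) + length(x$down), length(x$up), length(x$down)))
  invisible(x)
}

#' Venn region counts for a list of gene sets
#'
#' Counts every region of the Venn partition: for each non-empty subset of
#' datasets, the genes present in exactly those sets. Region names join the
#' member dataset names with `&`. Counts sum to the union size.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return Named integer vector over all `2^k - 1` regions.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets", call. = FALSE)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  k <- length(sets)
  regions <- integer(0)
  for (size in seq_len(k)) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      inside <- rowSums(member[, idx, drop = FALSE]) == size
      outside <- rowSums(member[, -idx, drop = FALSE]) == 0
      regions[paste(names(sets)[idx], collapse = "&")] <-
        if (length(genes)) sum(inside & outside) else 0L
    }
  }
  regions
}

#' @rdname intersect_degs
#' @param common A `common_degs` object.
#' @param path Output TSV path.
#' @export
write_common_degs_tsv <- function(common, path) {
  utils::write.table(common$lfc_matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
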