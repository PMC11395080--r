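#' Gene-set collection
#'
#' Named gene sets over a gene universe, the input of over-representation
#' analysis. The universe defaults to the union of all set members. Sets are
#' deduplicated, restricted to the universe, and must be non-empty.
#'
#' @param sets Named list of character vectors (set members), or a named
#'   list of `list(description =, genes =)` entries.
#' @param universe Optional character vector of background genes.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_field("sets", "must have unique names")
  genes_of <- lapply(sets, function(s) unique(as.character(if (is.list(s)) s$genes else s)))
  if (is.null(universe)) universe <- sort(unique(unlist(genes_of)))
  genes_of <- lapply(genes_of, intersect, y = universe)
  if (any(lengths(genes_of) == 0))
    stop_field("sets", "every set must retain at least one universe gene")
  desc <- descriptions %||% stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = genes_of, descriptions = desc, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets over %d universe genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path File path.
#' @param universe Optional explicit background; defaults to the union of
#'   set members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT at line %d: expected at least 3 tab-separated fields",
                 bad[1]), call. = FALSE)
  nm <- vapply(parts, `[`, "", 1)
  desc <- stats::setNames(vapply(parts, `[`, "", 2), nm)
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), nm)
  gene_set_collection(sets, universe = universe, descriptions = desc)
}

#' @rdname read_gmt
#' @param coll A [gene_set_collection()].
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gene_set_collection"))
  lines <- vapply(names(coll$sets), function(nm) {
    paste(c(nm, coll$descriptions[[nm]] %||% "", coll$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Over-representation analysis (hypergeometric upper tail)
#'
#' For each set, with universe size N, set size K, query size n and overlap
#' k, the p-value is the upper hypergeometric tail P(X >= k) — identical to
#' the one-sided Fisher exact test on the 2x2 overlap table. Query genes
#' outside the universe are dropped (with a message). BH adjustment is
#' applied across all sets in the collection.
#'
#' @param query Character vector of query genes (e.g. the common DEGs).
#' @param coll A [gene_set_collection()].
#' @return Data frame with columns `set_id`, `description`, `k`, `K`, `n`,
#'   `N`, `p_value`, `p_adjusted`, `overlap_genes` (comma-separated), sorted
#'   by `p_value` then `set_id`.
#' @export
ora_test <- function(query, coll) {
  stopifnot(inherits(coll, "gene_set_collection"))
  query <- unique(as.character(query))
  dropped <- sum(!query %in% coll$universe)
  if (dropped > 0)
    message(sprintf("ora_test: dropped %d query gene(s) outside the universe", dropped))
  query <- intersect(query, coll$universe)
  N <- length(coll$universe)
  n <- length(query)
  if (n == 0) {
    warning("empty query after universe restriction; returning no records")
    return(data.frame(set_id = character(), description = character(),
                      k = integer(), K = integer(), n = integer(), N = integer(),
                      p_value = numeric(), p_adjusted = numeric(),
                      overlap_genes = character(), stringsAsFactors = FALSE))
  }
  rec <- lapply(names(coll$sets), function(nm) {
    set <- coll$sets[[nm]]
    ov <- intersect(query, set)
    k <- length(ov); K <- length(set)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = nm, description = coll$descriptions[[nm]] %||% "",
               k = k, K = K, n = n, N = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set_id", "description", "k", "K", "n", "N",
          "p_value", "p_adjusted", "overlap_genes")]
}

#' Filter enrichment records at a significance level
#'
#' Keeps records with p strictly below `alpha` (raw p by default, matching
#' the upstream pipeline's stated rule; set `on_adjusted` to filter on BH
#' adjusted p), ordered by ascending p.
#'
#' @param records Output of [ora_test()].
#' @param alpha Significance level (default 0.05).
#' @param on_adjusted Filter on `p_adjusted` instead of `p_value`.
#' @export
significant_records <- function(records, alpha = 0.05, on_adjusted = FALSE) {
  p <- if (on_adjusted) records$p_adjusted else records$p_value
  out <- records[!is.na(p) & p < alpha, , drop = FALSE]
  out <- out[order(if (on_adjusted) out$p_adjusted else out$p_value, out$set_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname ora_test
#' @param records Enrichment table.
#' @param path Output TSV path.
#' @export
write_enrichment_tsv <- function(records, path) {
  out <- records
  colnames(out)[colnames(out) == "set_id"] <- "Pathway.ID"
  colnames(out)[colnames(out) == "description"] <- "Description"
  colnames(out)[colnames(out) == "p_value"] <- "p.Value"
  colnames(out)[colnames(out) == "k"] <- "Count"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
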