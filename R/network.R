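#' Read a STRING-format interaction edge list
#'
#' Expects tab-separated rows `node1 <TAB> node2 <TAB> combined_score` with
#' scores on the STRING 0-1000 scale (a header row is detected and
#' skipped). Edges below `min_score` are discarded; duplicate undirected
#' pairs are collapsed keeping the maximum score; self-loops are dropped
#' with a message.
#'
#' @param path File path.
#' @param min_score Minimum combined score to keep an edge (default 400,
#'   STRING's "medium confidence").
#' @return A simple undirected [igraph::igraph] with edge attribute
#'   `combined_score`. Isolated nodes are not represented (the file format
#'   carries no node list).
#' @export
read_string_tsv <- function(path, min_score = 400) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(parts) && suppressWarnings(is.na(as.numeric(parts[[1]][3]))))
    start <- 2L  # header row
  rows <- parts[seq(start, length.out = max(0, length(parts) - start + 1))]
  bad <- which(lengths(rows) < 3 |
                 vapply(rows, function(p) suppressWarnings(is.na(as.numeric(p[3]))), TRUE))
  if (length(bad))
    stop(sprintf("malformed STRING TSV at line %d: expected node1, node2, numeric score",
                 bad[1] + start - 1L), call. = FALSE)
  df <- data.frame(a = vapply(rows, `[`, "", 1), b = vapply(rows, `[`, "", 2),
                   score = vapply(rows, function(p) as.numeric(p[3]), 0),
                   stringsAsFactors = FALSE)
  loops <- df$a == df$b
  if (any(loops)) {
    message(sprintf("read_string_tsv: dropped %d self-loop(s)", sum(loops)))
    df <- df[!loops, , drop = FALSE]
  }
  df <- df[df$score >= min_score, , drop = FALSE]
  if (nrow(df) == 0) return(igraph::make_empty_graph(directed = FALSE))
  key <- ifelse(df$a < df$b, paste(df$a, df$b, sep = "\r"),
                paste(df$b, df$a, sep = "\r"))
  score <- tapply(df$score, key, max)
  pairs <- do.call(rbind, strsplit(names(score), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1], to = pairs[, 2],
               combined_score = as.numeric(score)), directed = FALSE)
  g
}

#' @rdname read_string_tsv
#' @param g An [igraph::igraph] with a `combined_score` edge attribute
#'   (1000 is written when absent).
#' @export
write_string_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g)
  score <- igraph::E(g)$combined_score %||% rep(1000, igraph::ecount(g))
  utils::write.table(data.frame(node1 = el[, 1], node2 = el[, 2],
                                combined_score = score),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Node centralities in the NetworkAnalyzer convention
#'
#' For every node of a simple undirected graph: degree (incident edge
#' count); betweenness (Brandes, unweighted shortest paths) normalized by
#' `(n - 1)(n - 2) / 2` with n the node count of the node's connected
#' component; closeness as the reciprocal of the mean shortest-path
#' distance to the other nodes of its component (0 for isolated nodes);
#' and the local clustering coefficient `2 e_i / (k_i (k_i - 1))`, 0 when
#' degree <= 1. Edge scores are not used as weights.
#'
#' @param g An [igraph::igraph].
#' @return Data frame `gene`, `degree`, `betweenness`, `closeness`,
#'   `clustering`, in vertex order.
#' @export
centralities <- function(g) {
  nv <- igraph::vcount(g)
  if (nv == 0)
    return(data.frame(gene = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric(),
                      clustering = numeric(), stringsAsFactors = FALSE))
  nm <- igraph::V(g)$name %||% as.character(seq_len(nv))
  deg <- as.integer(igraph::degree(g))
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  btw_raw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  denom <- (csize - 1) * (csize - 2) / 2
  btw <- ifelse(denom > 0, btw_raw / denom, 0)
  d <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(nv), function(i) {
    if (csize[i] <= 1) return(0)
    others <- setdiff(which(comp$membership == comp$membership[i]), i)
    1 / mean(d[i, others])
  }, 0)
  clus <- igraph::transitivity(g, type = "local", isolates = "zero")
  clus[deg <= 1] <- 0
  data.frame(gene = nm, degree = deg, betweenness = btw, closeness = clo,
             clustering = clus, stringsAsFactors = FALSE)
}

#' Rank nodes and select hub genes
#'
#' Sort key: degree (desc), betweenness (desc), closeness (desc), then gene
#' label (asc) to break remaining ties deterministically.
#'
#' @param records Output of [centralities()].
#' @param k Number of hubs to return (default 10).
#' @return Character vector of the top-k gene labels, in rank order.
#' @export
select_hubs <- function(records, k = 10) {
  k <- assert_count(k, "k")
  if (k > nrow(records)) stop_field("k", "exceeds the number of records")
  ord <- order(-records$degree, -records$betweenness, -records$closeness,
               records$gene)
  records$gene[ord][seq_len(k)]
}

#' Restrict a hub list to an annotation gene set
#'
#' Keeps, in their original rank order, the hubs present in
#' `annotation_set` (e.g. a chemokine-signaling gene list used to isolate
#' migration-related hubs).
#'
#' @param hubs Ordered character vector.
#' @param annotation_set Character vector.
#' @export
annotate_filter <- function(hubs, annotation_set) {
  hubs[hubs %in% annotation_set]
}

#' @rdname centralities
#' @param records Centrality table.
#' @param path Output TSV path.
#' @export
write_centralities_tsv <- function(records, path) {
  out <- records
  colnames(out) <- c("Gene", "Degree.Centrality", "Betweenness.Centrality",
                     "Closeness.Centrality", "Clustering.Coefficient")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
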