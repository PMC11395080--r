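# Independent brute-force oracles used to verify the implementation.
# These deliberately avoid the code paths (and libraries) they check.

# Exhaustive-path centrality oracle for small graphs (n <= 8).
# adj: symmetric 0/1 matrix with zero diagonal, rownames = gene labels.
oracle_centralities <- function(adj) {
  n <- nrow(adj)
  labels <- rownames(adj)
  deg <- rowSums(adj)

  # all simple paths s -> t by DFS; keep shortest, count pass-throughs
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(cur, visited) {
      if (cur == t) { paths[[length(paths) + 1]] <<- visited; return() }
      for (nxt in which(adj[cur, ] == 1)) if (!(nxt %in% visited))
        walk(nxt, c(visited, nxt))
    }
    walk(s, s)
    paths
  }

  # connected components by label propagation
  comp <- seq_len(n)
  repeat {
    new <- comp
    for (i in seq_len(n)) for (j in which(adj[i, ] == 1))
      new[i] <- min(new[i], comp[j])
    if (identical(new, comp)) break
    comp <- new
  }
  csize <- as.vector(table(comp)[as.character(comp)])

  dist <- matrix(Inf, n, n); diag(dist) <- 0
  btw_raw <- numeric(n)
  if (n >= 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (comp[s] != comp[t]) next
      paths <- all_paths(s, t)
      lens <- vapply(paths, length, 0L) - 1L
      d <- min(lens)
      dist[s, t] <- dist[t, s] <- d
      shortest <- paths[lens == d]
      sigma <- length(shortest)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(shortest, function(p) v %in% p, TRUE))
        btw_raw[v] <- btw_raw[v] + through / sigma
      }
    }
  }
  denom <- (csize - 1) * (csize - 2) / 2
  btw <- ifelse(denom > 0, btw_raw / denom, 0)

  clo <- vapply(seq_len(n), function(i) {
    others <- setdiff(which(comp == comp[i]), i)
    if (!length(others)) return(0)
    1 / mean(dist[i, others])
  }, 0)

  clus <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k <= 1) return(0)
    e <- sum(adj[nb, nb]) / 2
    2 * e / (k * (k - 1))
  }, 0)

  data.frame(gene = labels, degree = deg, betweenness = btw,
             closeness = clo, clustering = clus,
             row.names = NULL, stringsAsFactors = FALSE)
}

random_adj <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  upper <- which(upper.tri(adj))
  adj[upper] <- stats::rbinom(length(upper), 1, p)
  adj <- adj + t(adj)
  rownames(adj) <- colnames(adj) <- sprintf("V%02d", seq_len(n))
  adj
}

adj_to_graph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- rownames(adj)
  g
}

# Explicit mid-rank computation (ties get the average of the positions
# they occupy), independent of base::rank.
oracle_midranks <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, 0)
}

oracle_spearman_rho <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Permutation p-value for Spearman rho (two-sided)
oracle_spearman_perm_p <- function(x, y, n_perm = 20000) {
  obs <- abs(oracle_spearman_rho(x, y))
  hits <- 0
  for (b in seq_len(n_perm)) {
    r <- abs(oracle_spearman_rho(x, sample(y)))
    if (r >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# tiny all-positive count matrix for size-factor / GLM toys
toy_count_matrix <- function(counts, n_case) {
  grp <- c(rep("case", n_case), rep("control", ncol(counts) - n_case))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  count_matrix(counts, stats::setNames(grp, colnames(counts)))
}
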