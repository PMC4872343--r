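# Independent brute-force oracles and small fixtures used across tests.
# These deliberately avoid the package's own code paths (and igraph) so that
# agreement is a genuine dual-route check.

# adjacency matrix of a named undirected graph given an edge data frame
adj_matrix <- function(edges, ids = sort(unique(c(edges$from, edges$to)))) {
  m <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(edges))) {
    m[edges$from[i], edges$to[i]] <- TRUE
    m[edges$to[i], edges$from[i]] <- TRUE
  }
  diag(m) <- FALSE
  m
}

# connected components of the subgraph induced on `keep` (flood fill)
oracle_components <- function(m, keep) {
  if (length(keep) == 0) return(list())
  remaining <- keep
  comps <- list()
  while (length(remaining)) {
    frontier <- remaining[1]
    comp <- frontier
    remaining <- remaining[-1]
    while (length(frontier)) {
      nxt <- remaining[vapply(remaining, function(v) any(m[v, frontier]), logical(1))]
      comp <- c(comp, nxt)
      remaining <- setdiff(remaining, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

oracle_mnc <- function(m, v) {
  nb <- colnames(m)[m[v, ]]
  if (length(nb) == 0) return(0)
  max(lengths(oracle_components(m, nb)))
}

oracle_dmnc <- function(m, v, epsilon = 1.7) {
  nb <- colnames(m)[m[v, ]]
  if (length(nb) == 0) return(0)
  comps <- oracle_components(m, nb)
  sizes <- lengths(comps)
  best <- comps[sizes == max(sizes)]
  n_edges <- vapply(best, function(cp) sum(m[cp, cp, drop = FALSE]) / 2, numeric(1))
  if (max(sizes) <= 1) return(0)
  max(n_edges) / max(sizes)^epsilon
}

# BFS shortest-path tree with sorted-neighbor ordering; counts, per root, the
# non-root nodes whose subtree exceeds a quarter of the tree
oracle_bottleneck <- function(m) {
  ids <- colnames(m)
  n <- length(ids)
  score <- stats::setNames(numeric(n), ids)
  for (root in ids) {
    parent <- stats::setNames(rep(NA_character_, n), ids)
    visited <- stats::setNames(logical(n), ids)
    visited[root] <- TRUE
    queue <- root
    order_visited <- root
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- ids[m[u, ]]
      nb <- sort(nb[!visited[nb]])
      visited[nb] <- TRUE
      parent[nb] <- u
      queue <- c(queue, nb)
      order_visited <- c(order_visited, nb)
    }
    n_tree <- sum(visited)
    if (n_tree <= 1) next
    # subtree size of v = 1 + sizes of all nodes whose parent chain passes v
    subtree <- stats::setNames(rep(1, n), ids)
    for (v in rev(order_visited)) {
      if (!is.na(parent[v])) subtree[parent[v]] <- subtree[parent[v]] + subtree[v]
    }
    hit <- names(which(visited & subtree > n_tree / 4))
    hit <- setdiff(hit, root)
    score[hit] <- score[hit] + 1
  }
  score
}

random_edge_df <- function(n, p = 0.4) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2], stringsAsFactors = FALSE)
}

graph_from_edges <- function(edges, ids = sort(unique(c(edges$from, edges$to)))) {
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = ids)
}

# exact hypergeometric upper tail by direct summation of the density
oracle_hyper_tail <- function(k, K, n, N) {
  j <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# minimal labelled DEG table for stages that don't need real expression data
fake_degs <- function(gene_id, pathway) {
  structure(
    tibble::tibble(
      gene_id = gene_id, pathway = pathway,
      ratio_step1 = 1, p_step1 = 1,
      call_step1 = ifelse(pathway == "none", "ns", "up"),
      ratio_step2 = 1, p_step2 = 1, call_step2 = "ns"
    ),
    class = c("deg_table", class(tibble::tibble()))
  )
}

# tiny expression fixture: known per-stage means, controllable noise
make_expr_fixture <- function(n_genes = 50, means, noise = 0.05, reps = 2, seed = 1) {
  withr::with_seed(seed, {
    design <- tidyr::expand_grid(
      stage = factor(c("s1", "s2", "s3"), levels = c("s1", "s2", "s3")),
      replicate = seq_len(reps)
    )
    design$sample <- paste0(design$stage, "_r", design$replicate)
    design <- design[, c("sample", "stage", "replicate")]
    expr <- tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes)))
    for (i in seq_len(nrow(design))) {
      s <- match(design$stage[i], c("s1", "s2", "s3"))
      expr[[design$sample[i]]] <- 2^(means[, s] + stats::rnorm(n_genes, 0, noise))
    }
    list(expression = expr, design = design)
  })
}
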