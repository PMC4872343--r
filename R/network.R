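#' Select high-confidence oncogene ChIP targets
#'
#' Keeps peaks with `-log10(p) >= min_neglog10p` (default 300) and assigns
#' each to the genes whose TSS lies within `window` bp of the peak summit; the
#' resulting gene set is deduplicated.
#'
#' @param peaks Peak tibble with `chrom`, `summit`, `neg_log10_p` columns.
#' @param tss TSS annotation.
#' @param min_neglog10p Confidence threshold on -log10(p).
#' @param window Promoter half-width in bp for summit-to-TSS assignment.
#' @return Character vector of target gene ids.
#' @export
filter_oncogene_targets <- function(peaks, tss, min_neglog10p = 300, window = 1000) {
  if (!"neg_log10_p" %in% names(peaks)) abort("peak file lacks a -log10(p) column")
  keep <- peaks %>% filter(.data$neg_log10_p >= min_neglog10p)
  if (nrow(keep) == 0) return(character())
  summits <- GenomicRanges::GRanges(keep$chrom, IRanges::IRanges(keep$summit + 1, keep$summit + 1))
  promoters <- GenomicRanges::GRanges(
    tss$chrom, IRanges::IRanges(pmax(tss$tss - window, 0) + 1, tss$tss + window + 1)
  )
  hits <- GenomicRanges::findOverlaps(summits, promoters)
  gi <- S4Vectors::subjectHits(hits)
  pi <- S4Vectors::queryHits(hits)
  ok <- abs(keep$summit[pi] - tss$tss[gi]) <= window
  unique(tss$gene_id[gi[ok]])
}

#' Assemble the multi-provenance gene regulatory network
#'
#' Three evidence layers over the DEG set:
#' * `interaction`: undirected edges kept only when both endpoints are DEGs;
#' * `regulon`: directed TF-to-target edges kept when the TF passed
#'   [select_tfs()] and the target is a DEG;
#' * `oncogene_chip`: directed edges from the oncogene node to each
#'   high-confidence ChIP target that is a DEG or selected TF.
#'
#' Duplicates within one provenance are collapsed; the same pair may carry
#' edges of several provenances. Self-loops are dropped.
#'
#' @param degs Labelled `deg_table`.
#' @param interactions Tibble `from`, `type`, `to` (see [read_sif()]).
#' @param regulons Long tibble `tf`, `target`.
#' @param tfs Selected TF ids (from [select_tfs()]).
#' @param oncogene_targets Gene ids bound by the oncogene (from
#'   [filter_oncogene_targets()]); `NULL` to skip the layer.
#' @param oncogene_id Node id of the oncogene.
#' @param crm_catalog Optional CRM catalog used to tag node roles.
#' @return A `grn` object with `nodes` and `edges` tibbles and the undirected
#'   topology as an igraph graph.
#' @export
assemble_grn <- function(degs, interactions, regulons, tfs = character(),
                         oncogene_targets = NULL, oncogene_id = NULL,
                         crm_catalog = NULL) {
  deg_ids <- degs$gene_id[degs$pathway != "none"]
  if (length(deg_ids) == 0) {
    warn("empty DEG set: returning an empty network")
  }

  inter <- interactions %>%
    filter(.data$from %in% deg_ids, .data$to %in% deg_ids, .data$from != .data$to) %>%
    mutate(
      a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to),
      provenance = "interaction", directed = FALSE
    ) %>%
    distinct(.data$a, .data$b, .keep_all = TRUE) %>%
    select(from = "a", to = "b", "provenance", "directed")

  reg <- regulon_list(regulons)
  reg_edges <- purrr::map_dfr(intersect(names(reg), tfs), function(tf) {
    tibble(from = tf, to = intersect(reg[[tf]], deg_ids))
  })
  if (nrow(reg_edges)) {
    reg_edges <- reg_edges %>%
      filter(.data$from != .data$to) %>%
      distinct() %>%
      mutate(provenance = "regulon", directed = TRUE)
  } else {
    reg_edges <- tibble(
      from = character(), to = character(),
      provenance = character(), directed = logical()
    )
  }

  onco_edges <- reg_edges[0, ]
  if (!is.null(oncogene_targets) && !is.null(oncogene_id) && length(oncogene_targets)) {
    onco_to <- setdiff(intersect(oncogene_targets, c(deg_ids, tfs)), oncogene_id)
    if (length(onco_to)) {
      onco_edges <- tibble(
        from = oncogene_id, to = onco_to,
        provenance = "oncogene_chip", directed = TRUE
      )
    }
  }

  edges <- bind_rows(inter, reg_edges, onco_edges)
  crm_ids <- if (is.null(crm_catalog)) character() else crm_catalog$gene_id
  node_ids <- sort(unique(c(edges$from, edges$to)))
  nodes <- tibble(id = node_ids) %>%
    left_join(
      as_tibble(degs) %>% select("gene_id", "pathway", "ratio_step1", "ratio_step2"),
      by = c(id = "gene_id")
    ) %>%
    mutate(role = case_when(
      .data$id %in% c(tfs, oncogene_id %||% character()) ~ "TF",
      .data$id %in% crm_ids ~ "CRM",
      TRUE ~ "gene"
    ))
  new_grn(nodes, edges)
}

new_grn <- function(nodes, edges) {
  skeleton <- edges %>%
    mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) %>%
    distinct(.data$a, .data$b)
  g <- igraph::graph_from_data_frame(
    skeleton,
    directed = FALSE,
    vertices = nodes$id
  )
  structure(list(nodes = nodes, edges = edges, graph = g), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(
    "<grn> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
    paste(
      sprintf("%s: %d", names(table(x$edges$provenance)), as.integer(table(x$edges$provenance))),
      collapse = ", "
    ), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.grn <- function(x, ...) x$edges

#' @export
glance.grn <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    n_interaction = sum(x$edges$provenance == "interaction"),
    n_regulon = sum(x$edges$provenance == "regulon"),
    n_oncogene = sum(x$edges$provenance == "oncogene_chip"),
    n_components = igraph::count_components(x$graph)
  )
}

# sorted integer adjacency list of the undirected skeleton
adjacency_ints <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph, mode = "all")
  lapply(adj, function(v) sort(unique(as.integer(v))))
}

#' Maximum Neighborhood Component (MNC)
#'
#' Size of the largest connected component of the subgraph induced by a node's
#' neighbors (the node itself excluded). Isolated nodes score 0. Computed on
#' the undirected skeleton, ignoring edge direction and provenance.
#'
#' @param grn A `grn` object or an igraph graph.
#' @param nodes Node ids (default: all).
#' @return Named numeric vector of MNC scores.
#' @export
mnc <- function(grn, nodes = NULL) {
  g <- if (inherits(grn, "grn")) grn$graph else grn
  ids <- igraph::V(g)$name
  nodes <- nodes %||% ids
  out <- vapply(nodes, function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) == 0) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    max(igraph::components(sub)$csize)
  }, numeric(1))
  setNames(out, nodes)
}

# largest neighborhood component as an igraph subgraph (ties: most edges)
max_neighborhood_component <- function(g, v) {
  nb <- igraph::neighbors(g, v)
  if (length(nb) == 0) return(NULL)
  sub <- igraph::induced_subgraph(g, nb)
  comp <- igraph::components(sub)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  if (length(cand) > 1) {
    ecounts <- vapply(cand, function(k) {
      igraph::ecount(igraph::induced_subgraph(sub, which(comp$membership == k)))
    }, numeric(1))
    cand <- cand[[which.max(ecounts)]]
  }
  igraph::induced_subgraph(sub, which(comp$membership == cand))
}

#' Density of the Maximum Neighborhood Component (DMNC)
#'
#' `|E| / |V|^epsilon` of the node's maximum neighborhood component, 0 when
#' the MNC has at most one node. The exponent follows the Hubba convention
#' (default 1.7); `epsilon = 1` reduces the score to the component's plain
#' edge-to-node ratio.
#'
#' @inheritParams mnc
#' @param epsilon Density exponent.
#' @return Named numeric vector of DMNC scores.
#' @export
dmnc <- function(grn, nodes = NULL, epsilon = 1.7) {
  g <- if (inherits(grn, "grn")) grn$graph else grn
  nodes <- nodes %||% igraph::V(g)$name
  out <- vapply(nodes, function(v) {
    comp <- max_neighborhood_component(g, v)
    if (is.null(comp) || igraph::vcount(comp) <= 1) return(0)
    igraph::ecount(comp) / igraph::vcount(comp)^epsilon
  }, numeric(1))
  setNames(out, nodes)
}

#' BottleNeck score
#'
#' For every root node a breadth-first shortest-path tree is grown with
#' deterministic sorted-neighbor ordering (each newly discovered node hangs
#' under its smallest-id discovered neighbor). A node `v != root` is a
#' bottleneck in that tree when its subtree contains more than a quarter of
#' the tree's nodes; the score counts the trees in which the node is a
#' bottleneck. Disconnected graphs are handled per component.
#'
#' @inheritParams mnc
#' @return Named numeric vector of BottleNeck scores.
#' @export
bottleneck_score <- function(grn, nodes = NULL) {
  g <- if (inherits(grn, "grn")) grn$graph else grn
  ids <- igraph::V(g)$name
  n <- length(ids)
  nodes <- nodes %||% ids
  if (n == 0) return(setNames(numeric(0), character(0)))
  # order vertices by id so "sorted neighbor" is well defined
  ord <- order(ids)
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)
  adj <- adjacency_ints(g)
  adj <- lapply(adj, function(v) v[order(rank_of[v])])

  score <- numeric(n)
  parent <- integer(n)
  bfs_order <- integer(n)
  for (root in seq_len(n)) {
    visited <- logical(n)
    visited[root] <- TRUE
    parent[] <- 0L
    bfs_order[1] <- root
    head_i <- 1L
    tail_i <- 1L
    while (head_i <= tail_i) {
      u <- bfs_order[head_i]
      head_i <- head_i + 1L
      for (w in adj[[u]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- u
          tail_i <- tail_i + 1L
          bfs_order[tail_i] <- w
        }
      }
    }
    n_tree <- tail_i
    if (n_tree <= 1) next
    subtree <- rep(1L, n)
    for (k in seq(n_tree, 2)) {
      v <- bfs_order[k]
      subtree[parent[v]] <- subtree[parent[v]] + subtree[v]
    }
    thresh <- n_tree / 4
    in_tree <- bfs_order[seq_len(n_tree)]
    hits <- in_tree[subtree[in_tree] > thresh & in_tree != root]
    score[hits] <- score[hits] + 1
  }
  setNames(score, ids)[nodes]
}

#' All topological node metrics of a GRN
#'
#' @param grn A `grn` object.
#' @param epsilon DMNC exponent.
#' @return Tibble `id`, `degree`, `mnc`, `dmnc`, `bottleneck`.
#' @export
node_metrics <- function(grn, epsilon = 1.7) {
  g <- grn$graph
  tibble(
    id = igraph::V(g)$name,
    degree = as.numeric(igraph::degree(g)),
    mnc = as.numeric(mnc(g)),
    dmnc = as.numeric(dmnc(g, epsilon = epsilon)),
    bottleneck = as.numeric(bottleneck_score(g))
  )
}

#' Reduce a GRN by hub/bottleneck double screening
#'
#' Keeps the union of the top `k_hubs` nodes by MNC, the top `k_hubs` by DMNC,
#' and the top `k_bottlenecks` by BottleNeck score (ties broken by degree,
#' then lexicographic id), and returns the induced subgraph with edge
#' provenance preserved: no edge between retained nodes is lost.
#'
#' @param grn A `grn` object.
#' @param k_hubs Nodes kept from each hub ranking (MNC and DMNC).
#' @param k_bottlenecks Nodes kept from the BottleNeck ranking.
#' @param metrics Optional precomputed [node_metrics()] table.
#' @param epsilon DMNC exponent (used if metrics are computed here).
#' @return The reduced `grn`, with the metrics table attached as attribute
#'   `metrics` and the kept ids as attribute `kept`.
#' @export
reduce_grn <- function(grn, k_hubs = 32, k_bottlenecks = 10,
                       metrics = NULL, epsilon = 1.7) {
  metrics <- metrics %||% node_metrics(grn, epsilon = epsilon)
  n <- nrow(metrics)
  if (k_hubs >= n || k_bottlenecks >= n) {
    warn("k exceeds node count: returning the full network")
    out <- grn
    attr(out, "metrics") <- metrics
    attr(out, "kept") <- metrics$id
    return(out)
  }
  top_by <- function(col, k) {
    metrics %>%
      arrange(desc(.data[[col]]), desc(.data$degree), .data$id) %>%
      head(k) %>%
      pull(.data$id)
  }
  kept <- union(
    union(top_by("mnc", k_hubs), top_by("dmnc", k_hubs)),
    top_by("bottleneck", k_bottlenecks)
  )
  nodes <- grn$nodes %>% filter(.data$id %in% kept)
  edges <- grn$edges %>% filter(.data$from %in% kept, .data$to %in% kept)
  out <- new_grn(nodes, edges)
  attr(out, "metrics") <- metrics
  attr(out, "kept") <- kept
  out
}

#' Export a GRN as SIF plus node attributes
#'
#' Writes the edge multiset as a SIF file (provenance as the interaction type)
#' and a node-attribute TSV carrying the pathway segment, per-step expression
#' ratios, and node role, loadable by standard graph-visualization tools.
#'
#' @param grn A `grn` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
export_grn <- function(grn, dir, prefix = "grn") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sif <- file.path(dir, paste0(prefix, "_edges.sif"))
  attrs <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  write_sif(
    grn$edges %>% select("from", type = "provenance", "to"),
    sif
  )
  readr::write_tsv(grn$nodes, attrs)
  invisible(c(edges = sif, nodes = attrs))
}
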