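#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least the given overlap between a regulon and a
#' pathway when the regulon's targets are drawn without replacement from the
#' gene universe: `P(X >= overlap)` with
#' `X ~ Hypergeometric(N = |universe|, K = |regulon|, n = |pathway|)`.
#' Over-representation only; the p-value is monotone decreasing in the overlap
#' at fixed margins.
#'
#' @param regulon,pathway Character vectors of gene ids (subsets of
#'   `universe`), or single counts if `universe` is a count.
#' @param universe The gene universe (character vector) or its size.
#' @param overlap Overlap count; required when counts are given, ignored when
#'   sets are given.
#' @return The upper-tail p-value.
#' @examples
#' hypergeom_enrichment(5, 5, 10, overlap = 5) # 1/252
#' @export
hypergeom_enrichment <- function(regulon, pathway, universe, overlap = NULL) {
  if (is.character(universe)) {
    if (length(universe) == 0) abort("empty universe")
    regulon <- intersect(regulon, universe)
    pathway <- intersect(pathway, universe)
    overlap <- length(intersect(regulon, pathway))
    k_reg <- length(regulon)
    n_path <- length(pathway)
    n_all <- length(unique(universe))
  } else {
    if (universe <= 0) abort("empty universe")
    if (is.null(overlap)) abort("`overlap` required with count inputs")
    k_reg <- regulon
    n_path <- pathway
    n_all <- universe
  }
  phyper(overlap - 1, k_reg, n_all - k_reg, n_path, lower.tail = FALSE)
}

regulon_list <- function(regulons) {
  if (is_tibble(regulons) || is.data.frame(regulons)) {
    split(regulons$target, regulons$tf)
  } else {
    regulons
  }
}

pathway_sets <- function(degs) {
  deg <- degs %>% filter(.data$pathway != "none")
  split(deg$gene_id, deg$pathway)
}

#' Select candidate transcription factors
#'
#' A TF is kept iff (a) its regulon covers strictly more than `min_cover` of
#' the DEGs of at least one co-expression pathway, and (b) RNA polymerase II
#' is present at the TF's own promoter in at least one stage (or in every
#' stage with `polII_stages = "all"`). TFs absent from the promoter-mark
#' matrix are excluded with a warning rather than an error.
#'
#' @param regulons Long tibble `tf`, `target` (see [read_gmt()]).
#' @param degs Labelled `deg_table`.
#' @param marks `promoter_marks` tibble covering the TF genes.
#' @param min_cover Strict lower bound on pathway coverage (default 0.10).
#' @param polII_stages `"any"` (default) or `"all"`.
#' @param polII_target Track name of RNA polymerase II.
#' @return Character vector of selected TF ids.
#' @export
select_tfs <- function(regulons, degs, marks, min_cover = 0.10,
                       polII_stages = c("any", "all"), polII_target = "RNAPII") {
  polII_stages <- match.arg(polII_stages)
  regs <- regulon_list(regulons)
  paths <- pathway_sets(degs)
  if (length(paths) == 0) return(character())

  covered <- vapply(regs, function(targets) {
    any(vapply(paths, function(p) {
      length(intersect(targets, p)) / length(p) > min_cover
    }, logical(1)))
  }, logical(1))

  pol <- marks %>%
    filter(.data$target == polII_target) %>%
    group_by(.data$gene_id) %>%
    summarise(ok = if (polII_stages == "any") any(.data$present) else all(.data$present))
  tfs <- names(regs)[covered]
  unknown <- setdiff(tfs, pol$gene_id)
  if (length(unknown)) {
    warn(paste(
      "TF(s) without promoter annotation excluded:",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  tfs <- intersect(tfs, pol$gene_id[pol$ok])
  tfs
}

#' Associate TF regulons with co-expression pathways
#'
#' Hypergeometric over-representation of each TF's regulon in each pathway's
#' DEG set, against the expression universe, with -log10(p) capped so that
#' downstream clustering distances stay finite.
#'
#' @param regulons Long tibble `tf`, `target`; normally pre-filtered with
#'   [select_tfs()].
#' @param degs Labelled `deg_table`.
#' @param universe Gene universe; defaults to all genes in `degs`.
#' @param cap Cap on -log10(p) (default 300).
#' @return A `tf_association` object: long table with `tf`, `pathway`,
#'   `overlap`, `coverage`, `p_value`, `neg_log10_p`, plus the -log10 matrix.
#' @export
tf_pathway_association <- function(regulons, degs, universe = degs$gene_id, cap = 300) {
  regs <- regulon_list(regulons)
  paths <- pathway_sets(degs)
  if (length(regs) == 0 || length(paths) == 0) abort("need at least one regulon and one pathway")
  universe <- unique(universe)

  tab <- tidyr::expand_grid(tf = names(regs), pathway = names(paths)) %>%
    mutate(
      overlap = purrr::map2_int(.data$tf, .data$pathway, function(tf, pw) {
        length(intersect(intersect(regs[[tf]], universe), paths[[pw]]))
      }),
      regulon_size = lengths(lapply(regs[.data$tf], intersect, universe)),
      pathway_size = lengths(paths[.data$pathway]),
      p_value = phyper(
        .data$overlap - 1, .data$regulon_size,
        length(universe) - .data$regulon_size, .data$pathway_size,
        lower.tail = FALSE
      ),
      coverage = .data$overlap / .data$pathway_size,
      neg_log10_p = pmin(-log10(.data$p_value), cap)
    )
  mat <- tab %>%
    select("tf", "pathway", "neg_log10_p") %>%
    tidyr::pivot_wider(names_from = "pathway", values_from = "neg_log10_p")
  m <- as.matrix(mat[, -1])
  rownames(m) <- mat$tf
  structure(
    list(table = tab, matrix = m, row_order = rownames(m), col_order = colnames(m)),
    class = "tf_association"
  )
}

#' Hierarchically cluster a TF-pathway association matrix
#'
#' Agglomerative clustering (average linkage, Euclidean distance) of the
#' -log10(p) rows and columns; the stored row/column orders are the
#' dendrogram leaf orders. Deterministic given the input. A single row or
#' column yields the trivial order.
#'
#' @param assoc A `tf_association` object.
#' @param method Linkage method for [stats::hclust()].
#' @return The object with `row_order`, `col_order` and the `hclust` trees
#'   filled in.
#' @export
cluster_associations <- function(assoc, method = "average") {
  stopifnot(inherits(assoc, "tf_association"))
  m <- assoc$matrix
  if (nrow(m) > 1) {
    hr <- hclust(dist(m), method = method)
    assoc$row_order <- rownames(m)[hr$order]
    assoc$row_tree <- hr
  }
  if (ncol(m) > 1) {
    hc <- hclust(dist(t(m)), method = method)
    assoc$col_order <- colnames(m)[hc$order]
    assoc$col_tree <- hc
  }
  assoc
}

#' @export
print.tf_association <- function(x, ...) {
  cat(
    "<tf_association> ", nrow(x$matrix), " TFs x ", ncol(x$matrix),
    " pathways; min p = ", format(min(x$table$p_value), digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.tf_association <- function(x, ...) x$table

#' @export
glance.tf_association <- function(x, ...) {
  tibble(
    n_tfs = nrow(x$matrix), n_pathways = ncol(x$matrix),
    min_p = min(x$table$p_value),
    n_significant = sum(x$table$p_value < 0.05)
  )
}

#' Integrate chromatin-state clusters with co-expression pathways
#'
#' Contingency table of transition cluster by pathway over the genes shared by
#' both inputs, with expected counts `E = row total x column total / N` and
#' Pearson residuals `(O - E)/sqrt(E)`. The residual sum of squares equals the
#' chi-square statistic of the table. Cells with residual above
#' `enrich_cutoff` are flagged enriched. A degenerate table (a single row or
#' column) yields all-zero residuals and is flagged.
#'
#' @param trajectories A `state_trajectories` object.
#' @param degs Labelled `deg_table`.
#' @param enrich_cutoff Residual above which a cell is flagged (default 2).
#' @return An `integration_table` object with `observed`, `expected`,
#'   `residuals` matrices and the chi-square statistic.
#' @export
integrate_states_pathways <- function(trajectories, degs, enrich_cutoff = 2) {
  joined <- as_tibble(trajectories) %>%
    inner_join(
      degs %>% filter(.data$pathway != "none") %>% select("gene_id", "pathway"),
      by = "gene_id"
    )
  if (nrow(joined) == 0) abort("no genes shared between trajectories and DEGs")
  obs <- table(cluster = joined$cluster, pathway = joined$pathway)
  obs <- unclass(obs)
  degenerate <- nrow(obs) < 2 || ncol(obs) < 2
  if (degenerate) {
    warn("degenerate contingency table (single row or column); residuals set to 0")
    expected <- obs
    residuals <- obs * 0
  } else {
    expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    residuals <- (obs - expected) / sqrt(expected)
  }
  structure(
    list(
      observed = obs, expected = expected, residuals = residuals,
      chisq = sum(residuals^2), n = sum(obs),
      enriched = residuals > enrich_cutoff, degenerate = degenerate
    ),
    class = "integration_table"
  )
}

#' @export
print.integration_table <- function(x, ...) {
  cat(
    "<integration_table> ", nrow(x$observed), " state clusters x ",
    ncol(x$observed), " pathways, n = ", x$n,
    ", chi-square = ", format(x$chisq, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.integration_table <- function(x, ...) {
  as_tibble(as.data.frame.table(x$observed, responseName = "observed")) %>%
    mutate(
      expected = as.vector(x$expected),
      residual = as.vector(x$residuals),
      enriched = as.vector(x$enriched),
      cluster = as.character(.data$cluster),
      pathway = as.character(.data$pathway)
    )
}

#' @export
glance.integration_table <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$observed), n_pathways = ncol(x$observed),
    n_genes = x$n, chisq = x$chisq,
    df = (nrow(x$observed) - 1) * (ncol(x$observed) - 1),
    n_enriched = sum(x$enriched), degenerate = x$degenerate
  )
}

#' Annotate differentially expressed chromatin remodelers/modifiers
#'
#' Intersects the DEG set with a CRM catalog (gene id -> class among writer,
#' eraser, reader, other) and reports when each CRM changed expression.
#'
#' @param degs Labelled `deg_table`.
#' @param catalog Tibble with columns `gene_id`, `class`.
#' @return Tibble of DEG CRMs with `class` and `step_of_change` in
#'   `{step1_only, step2_only, both}`.
#' @export
annotate_crms <- function(degs, catalog) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    warn("empty CRM catalog")
    return(tibble(
      gene_id = character(), class = character(), pathway = character(),
      step_of_change = character()
    ))
  }
  degs %>%
    filter(.data$call_step1 != "ns" | .data$call_step2 != "ns") %>%
    inner_join(catalog, by = "gene_id") %>%
    mutate(step_of_change = case_when(
      .data$call_step1 != "ns" & .data$call_step2 != "ns" ~ "both",
      .data$call_step1 != "ns" ~ "step1_only",
      TRUE ~ "step2_only"
    )) %>%
    select("gene_id", "class", "pathway", "call_step1", "call_step2", "step_of_change")
}
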