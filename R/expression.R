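#' Welch's unequal-variance two-sample t-test
#'
#' The per-gene test used by the differential-expression caller: two-sample t
#' for independent normal populations with unequal variances, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. Accepts
#' plain numeric vectors (one gene) or matrices with one gene per row, in
#' which case the test is vectorized across rows.
#'
#' Degenerate inputs follow fixed conventions: if both samples have zero
#' variance and equal means the statistic is 0 and p = 1; zero pooled variance
#' with unequal means gives an infinite statistic and p = 0 (degrees of
#' freedom then fall back to n1 + n2 - 2).
#'
#' @param x,y Numeric vectors, or matrices with genes in rows. Each sample
#'   needs at least two values.
#' @return A tibble with columns `statistic` (t for `x` minus `y`), `df`, and
#'   `p_value`, one row per gene.
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
#' @export
welch_t <- function(x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have the same number of rows")
  n1 <- ncol(x)
  n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) abort("each sample needs at least 2 values")

  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))

  stat <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(-abs(stat), df)

  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    stat[eq] <- 0
    p[eq] <- 1
    ne <- zero & (m1 != m2)
    stat[ne] <- sign(m1[ne] - m2[ne]) * Inf
    p[ne] <- 0
    df[zero] <- n1 + n2 - 2
  }
  tibble(statistic = stat, df = df, p_value = p)
}

#' Call differentially expressed genes across two transformation steps
#'
#' Compares the second and third stage of a three-stage design against the
#' first (baseline) stage. Fold ratios are computed from replicate means on
#' the linear scale; significance comes from [welch_t()] on log2-transformed
#' values. A gene is called `up` at a step iff its ratio exceeds `fc_up` and
#' p < `alpha`; `down` iff the ratio is below `fc_down` and p < `alpha`;
#' otherwise `ns`. A gene is a DEG iff at least one step call is non-`ns`.
#'
#' @param expr Expression tibble: `gene_id` plus one positive numeric column
#'   per sample (see [read_expression_matrix()]).
#' @param design Tibble mapping `sample` to `stage` and `replicate`; exactly
#'   three stages, each with at least two replicates. The first stage level is
#'   the baseline.
#' @param fc_up,fc_down Fold-change gates (defaults 2 and 1/2).
#' @param alpha Significance gate on the (optionally adjusted) p-value.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()];
#'   `"none"` by default, matching a plain per-gene threshold.
#' @return A `deg_table` tibble with per-gene ratios, p-values, and
#'   `call_step1` / `call_step2` in `{up, down, ns}`.
#' @export
call_degs <- function(expr, design, fc_up = 2, fc_down = 1 / fc_up,
                      alpha = 0.05, adjust = "none") {
  stages <- stage_levels(design)
  stages <- stages[stages %in% as.character(design$stage)]
  if (length(stages) != 3) abort("design must contain exactly three stages")
  missing_samples <- setdiff(design$sample, names(expr))
  if (length(missing_samples)) {
    abort(paste("samples missing from expression matrix:", paste(missing_samples, collapse = ", ")))
  }
  reps <- table(design$stage)
  if (any(reps < 2)) abort("every stage needs at least two replicates")
  if (fc_up <= 1 || fc_down >= 1) abort("need fc_up > 1 and fc_down < 1")

  mats <- lapply(stages, function(s) {
    m <- as.matrix(expr[, design$sample[design$stage == s], drop = FALSE])
    if (any(m <= 0)) abort("expression values must be positive (linear scale)")
    m
  })
  names(mats) <- stages

  step_stats <- function(m_alt, m_base) {
    ratio <- rowMeans(m_alt) / rowMeans(m_base)
    p <- welch_t(log2(m_alt), log2(m_base))$p_value
    p <- stats::p.adjust(p, method = adjust)
    call <- rep("ns", length(ratio))
    call[ratio > fc_up & p < alpha] <- "up"
    call[ratio < fc_down & p < alpha] <- "down"
    list(ratio = ratio, p = p, call = call)
  }

  s1 <- step_stats(mats[[2]], mats[[1]])
  s2 <- step_stats(mats[[3]], mats[[1]])

  out <- tibble(
    gene_id = expr$gene_id,
    ratio_step1 = s1$ratio, p_step1 = s1$p, call_step1 = s1$call,
    ratio_step2 = s2$ratio, p_step2 = s2$p, call_step2 = s2$call
  )
  structure(
    out,
    class = c("deg_table", class(out)),
    params = list(
      fc_up = fc_up, fc_down = fc_down, alpha = alpha, adjust = adjust,
      stages = stages
    )
  )
}

#' Default pattern-to-pathway mapping
#'
#' The eight non-(ns, ns) call patterns over the two transformation steps are
#' mapped onto seven co-expression pathway labels, merging the two discordant
#' reversal patterns (up-then-down, down-then-up) into a single label:
#'
#' * i: up at step 1 only
#' * ii: reversal (up, down) or (down, up)
#' * iii: down at step 1 only
#' * iv: up at both steps
#' * v: down at both steps
#' * vi: up at step 2 only
#' * vii: down at step 2 only
#'
#' The mapping is data, not code: pass an edited copy to [assign_pathways()]
#' to use a different labelling.
#'
#' @return Tibble with columns `call_step1`, `call_step2`, `pathway`.
#' @export
default_pathway_mapping <- function() {
  tibble(
    call_step1 = c("up", "up", "down", "down", "up", "down", "ns", "ns"),
    call_step2 = c("ns", "down", "up", "ns", "up", "down", "up", "down"),
    pathway = c("i", "ii", "ii", "iii", "iv", "v", "vi", "vii")
  )
}

#' Assign co-expression pathway labels to DEG calls
#'
#' @param degs A `deg_table` from [call_degs()].
#' @param mapping Pattern-to-label table covering all eight non-(ns, ns)
#'   patterns; see [default_pathway_mapping()]. Genes with (ns, ns) calls get
#'   the label `"none"`.
#' @return The input with a `pathway` column added.
#' @export
assign_pathways <- function(degs, mapping = default_pathway_mapping()) {
  patterns <- expand.grid(
    call_step1 = c("up", "down", "ns"), call_step2 = c("up", "down", "ns"),
    stringsAsFactors = FALSE
  )
  patterns <- patterns[!(patterns$call_step1 == "ns" & patterns$call_step2 == "ns"), ]
  covered <- paste(mapping$call_step1, mapping$call_step2)
  missing <- setdiff(paste(patterns$call_step1, patterns$call_step2), covered)
  if (length(missing)) {
    abort(paste("mapping does not cover pattern(s):", paste(missing, collapse = "; ")))
  }

  attrs <- attr(degs, "params")
  out <- degs %>%
    left_join(mapping, by = c("call_step1", "call_step2")) %>%
    mutate(pathway = dplyr::if_else(
      .data$call_step1 == "ns" & .data$call_step2 == "ns", "none", .data$pathway
    ))
  structure(out, class = c("deg_table", class(tibble())), params = attrs)
}

#' Summarise when DEGs change expression
#'
#' Fractions of DEGs altered at the pre-transformation step, after full
#' transformation, and at both, over the DEG set. The inclusion-exclusion
#' identity `frac_step1 + frac_step2 - frac_both = 1` holds by construction.
#'
#' @param degs A labelled `deg_table`.
#' @return One-row tibble with `n_degs`, `frac_step1`, `frac_step2`,
#'   `frac_both`. If there are no DEGs the fractions are `NA` and a warning is
#'   raised.
#' @export
pathway_summary <- function(degs) {
  deg <- degs %>% filter(.data$call_step1 != "ns" | .data$call_step2 != "ns")
  if (nrow(deg) == 0) {
    warn("no DEGs: step fractions undefined")
    return(tibble(n_degs = 0L, frac_step1 = NA_real_, frac_step2 = NA_real_, frac_both = NA_real_))
  }
  c1 <- deg$call_step1 != "ns"
  c2 <- deg$call_step2 != "ns"
  tibble(
    n_degs = nrow(deg),
    frac_step1 = mean(c1),
    frac_step2 = mean(c2),
    frac_both = mean(c1 & c2)
  )
}

#' @export
glance.deg_table <- function(x, ...) {
  s <- pathway_summary(x)
  p <- attr(x, "params")
  tibble(
    n_genes = nrow(x), n_degs = s$n_degs,
    frac_step1 = s$frac_step1, frac_step2 = s$frac_step2, frac_both = s$frac_both,
    fc_up = p$fc_up %||% NA_real_, alpha = p$alpha %||% NA_real_
  )
}

#' Write / read a DEG table
#' @param degs A `deg_table`.
#' @param path Output TSV path.
#' @export
write_deg_table <- function(degs, path) {
  readr::write_tsv(as_tibble(degs), path)
  invisible(path)
}

#' @rdname write_deg_table
#' @export
read_deg_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(x, class = c("deg_table", class(x)))
}
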