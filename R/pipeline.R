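#' Pipeline configuration
#'
#' Aggregates every stage parameter with defaults reproducing the reference
#' thresholds: fold gate 2.0 (and its reciprocal), alpha 0.05, promoter window
#' 500 bp, z > 1.65, dispersion < 0.15, pathway coverage > 0.10, oncogene
#' -log10(p) >= 300, DMNC exponent 1.7. Serializable to and from a YAML file.
#'
#' @param fc_up,fc_down Fold-change gates for DEG calling.
#' @param alpha Significance gate.
#' @param adjust Multiple-testing adjustment method (default none).
#' @param window Promoter half-width (bp) for mark presence.
#' @param zmin Minimum peak z-score.
#' @param max_dispersion Maximum subsampling dispersion.
#' @param disp_fractions,disp_reps Subsampling scheme for the dispersion check.
#' @param bivalent_closure Chromatin classifier closure switch.
#' @param flank Half-width (bp) of median display profiles.
#' @param min_cover Strict pathway-coverage threshold for TF selection.
#' @param polII_stages `"any"` or `"all"` stages for the Pol II filter.
#' @param neg_log10_cap Cap on -log10(p) in the association matrix.
#' @param enrich_cutoff Pearson-residual enrichment flag threshold.
#' @param minlogp Oncogene peak confidence threshold (-log10 p).
#' @param oncogene_window Promoter half-width (bp) for oncogene targets.
#' @param oncogene_id Node id of the oncogene (ignored for simulated runs,
#'   which use the planted oncogene).
#' @param epsilon DMNC exponent.
#' @param k_hubs,k_bottlenecks Double-screen reduction sizes.
#' @param mapping Pattern-to-pathway mapping table.
#' @param seed Seed for the pipeline's own randomness (dispersion subsampling
#'   and, for simulated runs, the generator).
#' @param simulate Generate inputs with [simulate_study()]?
#' @param sim A `simulation_config` (used when `simulate = TRUE`).
#' @param input_dir Directory of on-disk inputs in [write_study()] layout
#'   (used when `simulate = FALSE`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fc_up = 2, fc_down = 1 / fc_up, alpha = 0.05,
                            adjust = "none",
                            window = 500, zmin = 1.65, max_dispersion = 0.15,
                            disp_fractions = c(0.9, 0.7, 0.5), disp_reps = 3,
                            bivalent_closure = TRUE, flank = 1500,
                            min_cover = 0.10, polII_stages = "any",
                            neg_log10_cap = 300, enrich_cutoff = 2,
                            minlogp = 300, oncogene_window = 1000,
                            oncogene_id = "MYC",
                            epsilon = 1.7, k_hubs = 32, k_bottlenecks = 10,
                            mapping = default_pathway_mapping(),
                            seed = 1, simulate = TRUE,
                            sim = NULL, input_dir = NULL) {
  sim <- sim %||% simulation_config(seed = seed)
  structure(
    list(
      fc_up = fc_up, fc_down = fc_down, alpha = alpha, adjust = adjust,
      window = window, zmin = zmin, max_dispersion = max_dispersion,
      disp_fractions = disp_fractions, disp_reps = disp_reps,
      bivalent_closure = bivalent_closure, flank = flank,
      min_cover = min_cover, polII_stages = polII_stages,
      neg_log10_cap = neg_log10_cap, enrich_cutoff = enrich_cutoff,
      minlogp = minlogp, oncogene_window = oncogene_window,
      oncogene_id = oncogene_id,
      epsilon = epsilon, k_hubs = k_hubs, k_bottlenecks = k_bottlenecks,
      mapping = as_tibble(mapping),
      seed = as.integer(seed), simulate = isTRUE(simulate),
      sim = sim, input_dir = input_dir
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$mapping <- as.data.frame(x$mapping)
  x$sim <- unclass(x$sim)
  x$sim$pathway_proportions <- as.list(x$sim$pathway_proportions)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(simulation_config, modifyList(
    x$sim,
    list(pathway_proportions = unlist(x$sim$pathway_proportions))
  ))
  x$sim <- NULL
  mapping <- as_tibble(as.data.frame(lapply(x$mapping, unlist)))
  x$mapping <- NULL
  do.call(pipeline_config, c(x, list(sim = sim, mapping = mapping)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> DEG calling -> chromatin normalization,
#' presence and state trajectories -> TF/pathway association and
#' epigenome-transcriptome integration -> GRN assembly and hub/bottleneck
#' reduction, and returns the full result bundle with a reproducibility
#' manifest. Identical configuration and seed give identical outputs.
#'
#' @param config A `pipeline_config`.
#' @param study Optional pre-built `synthetic_study` (overrides
#'   `config$simulate` / `config$input_dir`).
#' @return A `pipeline_result` list.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  if (is.null(study)) {
    if (config$simulate) {
      study <- simulate_study(config$sim)
    } else {
      if (is.null(config$input_dir)) abort("configuration error: no input_dir and simulate = FALSE")
      for (f in c("expression.tsv", "design.tsv", "tss.bed", "regulons.gmt", "interactions.sif")) {
        if (!file.exists(file.path(config$input_dir, f))) {
          abort(paste("configuration error: missing input file", f))
        }
      }
      study <- read_study(config$input_dir)
    }
  }
  oncogene_id <- study$gold$oncogene_id %||% config$oncogene_id

  # --- expression -----------------------------------------------------------
  degs <- call_degs(study$expression, study$design,
    fc_up = config$fc_up, fc_down = config$fc_down,
    alpha = config$alpha, adjust = config$adjust
  ) %>%
    assign_pathways(config$mapping)
  deg_summary <- pathway_summary(degs)

  # --- chromatin ------------------------------------------------------------
  tracks <- study$tracks %>%
    quantile_normalize() %>%
    zscore_scale()
  marks <- call_presence(
    study$peaks, tracks, study$tss,
    window = config$window, zmin = config$zmin,
    max_dispersion = config$max_dispersion,
    fractions = config$disp_fractions, reps = config$disp_reps,
    seed = config$seed + 3L
  )
  states <- state_calls(marks, bivalent_closure = config$bivalent_closure)
  stages <- stage_levels(study$design)
  deg_ids <- degs$gene_id[degs$pathway != "none"]
  trajectories <- state_trajectories(
    states %>% filter(.data$gene_id %in% deg_ids), stages
  )

  # --- association ----------------------------------------------------------
  tfs <- select_tfs(study$regulons, degs, marks,
    min_cover = config$min_cover, polII_stages = config$polII_stages
  )
  assoc <- NULL
  if (length(tfs) > 0 && any(degs$pathway != "none")) {
    assoc <- tf_pathway_association(
      study$regulons %>% filter(.data$tf %in% tfs), degs,
      universe = degs$gene_id, cap = config$neg_log10_cap
    ) %>%
      cluster_associations()
  } else {
    warn("no TFs selected: association stage skipped")
  }
  integration <- integrate_states_pathways(trajectories, degs,
    enrich_cutoff = config$enrich_cutoff
  )
  crms <- annotate_crms(degs, study$crm_catalog)

  # --- network --------------------------------------------------------------
  onco_targets <- filter_oncogene_targets(
    study$oncogene_peaks, study$tss,
    min_neglog10p = config$minlogp, window = config$oncogene_window
  )
  grn <- assemble_grn(degs, study$interactions, study$regulons,
    tfs = tfs, oncogene_targets = onco_targets, oncogene_id = oncogene_id,
    crm_catalog = study$crm_catalog
  )
  metrics <- node_metrics(grn, epsilon = config$epsilon)
  reduced <- reduce_grn(grn,
    k_hubs = config$k_hubs, k_bottlenecks = config$k_bottlenecks,
    metrics = metrics
  )

  manifest <- list(
    package = "stepomics",
    version = as.character(utils::packageVersion("stepomics")),
    seed = config$seed,
    simulate = config$simulate,
    parameters = config[c(
      "fc_up", "fc_down", "alpha", "adjust", "window", "zmin", "max_dispersion",
      "min_cover", "polII_stages", "minlogp", "oncogene_window",
      "epsilon", "k_hubs", "k_bottlenecks", "enrich_cutoff", "bivalent_closure"
    )],
    n_genes = nrow(degs),
    n_degs = deg_summary$n_degs,
    stages = as.character(stages)
  )

  structure(
    list(
      config = config, study = study,
      degs = degs, deg_summary = deg_summary,
      tracks = tracks, marks = marks, states = states,
      trajectories = trajectories, census = cluster_census(trajectories),
      tfs = tfs, association = assoc, integration = integration, crms = crms,
      oncogene_targets = onco_targets,
      grn = grn, metrics = metrics, reduced = reduced,
      manifest = manifest
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  DEGs:", x$deg_summary$n_degs, "of", nrow(x$degs), "genes\n")
  cat("  transition clusters:", nrow(x$census), "\n")
  cat("  selected TFs:", length(x$tfs), "\n")
  cat(
    "  GRN:", nrow(x$grn$nodes), "nodes /", nrow(x$grn$edges), "edges;",
    "reduced:", nrow(x$reduced$nodes), "/", nrow(x$reduced$edges), "\n"
  )
  invisible(x)
}

#' Write a pipeline result bundle to disk
#'
#' Tab-separated tables for every stage output, SIF + attribute exports of the
#' full and reduced networks, and a JSON manifest. Deterministic: identical
#' configuration and seed give byte-identical bundles.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(as_tibble(result$degs), file.path(dir, "degs.tsv"))
  readr::write_tsv(result$deg_summary, file.path(dir, "deg_summary.tsv"))
  readr::write_tsv(as_tibble(result$marks), file.path(dir, "promoter_marks.tsv"))
  readr::write_tsv(result$states, file.path(dir, "states.tsv"))
  readr::write_tsv(as_tibble(result$trajectories), file.path(dir, "trajectories.tsv"))
  readr::write_tsv(result$census, file.path(dir, "transition_clusters.tsv"))
  if (!is.null(result$association)) {
    readr::write_tsv(tidy(result$association), file.path(dir, "tf_associations.tsv"))
  }
  readr::write_tsv(tidy(result$integration), file.path(dir, "integration.tsv"))
  readr::write_tsv(result$crms, file.path(dir, "crms.tsv"))
  readr::write_tsv(tibble(gene_id = result$oncogene_targets), file.path(dir, "oncogene_targets.tsv"))
  readr::write_tsv(result$metrics, file.path(dir, "node_metrics.tsv"))
  export_grn(result$grn, dir, prefix = "grn_full")
  export_grn(result$reduced, dir, prefix = "grn_reduced")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}

#' DEG table implied by a study's planted truth
#'
#' Builds the `deg_table` a perfect expression stage would produce from the
#' generator's gold standard (ratios are the planted fold changes, calls their
#' signs). Used to assess the downstream stages' own recovery independently of
#' the power of the expression stage.
#'
#' @param study A `synthetic_study`.
#' @return A labelled `deg_table`.
#' @export
gold_deg_table <- function(study) {
  g <- study$gold$genes
  call_of <- function(d) dplyr::case_when(d > 0 ~ "up", d < 0 ~ "down", TRUE ~ "ns")
  out <- tibble(
    gene_id = g$gene_id,
    ratio_step1 = 2^g$delta_step1, p_step1 = dplyr::if_else(g$delta_step1 != 0, 0, 1),
    call_step1 = call_of(g$delta_step1),
    ratio_step2 = 2^g$delta_step2, p_step2 = dplyr::if_else(g$delta_step2 != 0, 0, 1),
    call_step2 = call_of(g$delta_step2),
    pathway = g$pathway
  )
  structure(out, class = c("deg_table", class(tibble())))
}

#' Recovery of the planted structure by a pipeline run
#'
#' Compares a result bundle against its study's gold standard:
#' `deg_recovery` (planted DEGs called as DEGs), `pathway_recovery` (planted
#' DEGs with the exact planted label recovered), `state_recovery` (promoter-
#' stage state calls matching the planted states, over all genes), and
#' `oncogene_target_recovery`.
#'
#' @param result A `pipeline_result` from a simulated run.
#' @return One-row tibble of recovery fractions.
#' @export
recovery_metrics <- function(result) {
  gold <- result$study$gold
  if (is.null(gold)) abort("recovery metrics need a simulated study with a gold standard")
  g <- gold$genes
  planted <- g %>% filter(.data$pathway != "none")
  called <- as_tibble(result$degs) %>% select("gene_id", called = "pathway")
  cmp <- planted %>% left_join(called, by = "gene_id")

  st <- result$states %>%
    left_join(
      g %>%
        select("gene_id", "state_stage1", "state_stage2", "state_stage3") %>%
        tidyr::pivot_longer(-"gene_id", names_to = "stage_i", values_to = "true_state") %>%
        mutate(stage = as.character(stage_levels(result$study$design))[
          as.integer(sub("state_stage", "", .data$stage_i))
        ]),
      by = c("gene_id", "stage")
    )

  tibble(
    deg_recovery = mean(cmp$called != "none"),
    pathway_recovery = mean(cmp$called == cmp$pathway),
    state_recovery = mean(st$state == st$true_state),
    oncogene_target_recovery =
      length(intersect(result$oncogene_targets, gold$oncogene_targets)) /
        length(gold$oncogene_targets)
  )
}
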