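#' Configuration for the synthetic study generator
#'
#' Defines the planted structure of a synthetic three-stage transformation
#' study: co-expression pathways, promoter chromatin-state trajectories
#' correlated with them, TF regulons driving pathways, and a modular
#' interaction network with engineered hub cliques and bottleneck connectors.
#' One seed fixes every output bit-identically.
#'
#' @param n_genes Number of genes.
#' @param n_tfs Number of transcription factors (drivers plus decoys); TFs are
#'   themselves genes of the universe.
#' @param stages Stage labels in biological order (first = baseline).
#' @param n_replicates Replicates per stage.
#' @param pathway_proportions Named fractions of genes planted into each
#'   co-expression pathway (names i..vii); must sum to at most 1, the
#'   remainder being non-DEGs. The default plants 35% DEGs split so that the
#'   expected step fractions mirror a mostly-late-changing design
#'   (~47%/65%/12% of DEGs at step 1/step 2/both).
#' @param effect_size Mean |log2 ratio| of planted changes.
#' @param noise_sd Log2-scale replicate noise sd.
#' @param base_mean,base_sd Log2-scale baseline abundance distribution.
#' @param state_emission Probability that a planted state emits its defining
#'   marks at a promoter-stage (applied jointly to the full mark set).
#' @param regulon_size Mean regulon size (targets per TF).
#' @param drivers_per_pathway Planted driver TFs per pathway.
#' @param ppi_attachment Preferential-attachment power for the spoke trees.
#' @param n_communities Interaction-network communities.
#' @param hubs_per_community Engineered clique hubs per community.
#' @param n_bottleneck_connectors Connector nodes inserted as sole links
#'   between consecutive communities (at most `n_communities - 1`).
#' @param tss_spacing Distance between consecutive TSSs (bp); promoter windows
#'   never overlap at the default 10 kb.
#' @param bin_size Coverage bin width (bp).
#' @param peak_mean_count Mean per-bin read count of a planted peak.
#' @param background_mu,background_size Negative-binomial background coverage.
#' @param background_decoy_rate Decoy peaks away from TSSs, as a fraction of
#'   `n_genes` per track (genuine signal in the wrong place).
#' @param promoter_decoy_rate Weak decoy peaks at promoters lacking the mark,
#'   as a fraction of `n_genes` per track (fail the z / dispersion gates).
#' @param n_oncogene_targets Genes designated as oncogene ChIP targets.
#' @param n_crms Genes designated chromatin remodelers/modifiers.
#' @param seed Random seed (fixes all outputs).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              n_tfs = 25,
                              stages = c("baseline", "immortalized", "transformed"),
                              n_replicates = 2,
                              pathway_proportions = c(
                                i = 0.061, ii = 0.014, iii = 0.061, iv = 0.014,
                                v = 0.014, vi = 0.093, vii = 0.093
                              ),
                              effect_size = 1.5,
                              noise_sd = 0.25,
                              base_mean = 8,
                              base_sd = 1.5,
                              state_emission = 0.95,
                              regulon_size = 40,
                              drivers_per_pathway = 2,
                              ppi_attachment = 1,
                              n_communities = 4,
                              hubs_per_community = 8,
                              n_bottleneck_connectors = 3,
                              tss_spacing = 10000,
                              bin_size = 100,
                              peak_mean_count = 200,
                              background_mu = 8,
                              background_size = 4,
                              background_decoy_rate = 0.1,
                              promoter_decoy_rate = 0.05,
                              n_oncogene_targets = 50,
                              n_crms = 30,
                              seed = 1) {
  assert_count(n_genes, "n_genes")
  assert_count(n_replicates, "n_replicates", min = 2L)
  assert_count(n_communities, "n_communities")
  assert_count(bin_size, "bin_size")
  assert_count(tss_spacing, "tss_spacing")
  if (length(stages) != 3) abort("exactly three stages are supported")
  if (is.null(names(pathway_proportions)) ||
    !all(names(pathway_proportions) %in% roman_pathways())) {
    abort("pathway_proportions must be named with labels among i..vii")
  }
  assert_fraction(pathway_proportions, "pathway_proportions")
  if (sum(pathway_proportions) > 1 + 1e-12) {
    abort("pathway_proportions sum to more than 1")
  }
  assert_fraction(state_emission, "state_emission")
  if (noise_sd < 0 || effect_size < 0) abort("effect_size and noise_sd must be non-negative")
  if (n_bottleneck_connectors > n_communities - 1) {
    abort("need n_bottleneck_connectors <= n_communities - 1")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs), stages = stages,
      n_replicates = as.integer(n_replicates),
      pathway_proportions = pathway_proportions,
      effect_size = effect_size, noise_sd = noise_sd,
      base_mean = base_mean, base_sd = base_sd,
      state_emission = state_emission,
      regulon_size = regulon_size, drivers_per_pathway = drivers_per_pathway,
      ppi_attachment = ppi_attachment, n_communities = as.integer(n_communities),
      hubs_per_community = as.integer(hubs_per_community),
      n_bottleneck_connectors = as.integer(n_bottleneck_connectors),
      tss_spacing = as.integer(tss_spacing), bin_size = as.integer(bin_size),
      peak_mean_count = peak_mean_count,
      background_mu = background_mu, background_size = background_size,
      background_decoy_rate = background_decoy_rate,
      promoter_decoy_rate = promoter_decoy_rate,
      n_oncogene_targets = as.integer(n_oncogene_targets),
      n_crms = as.integer(n_crms), seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# pathway label -> step direction pair; "ii" is resolved per gene to one of
# the two reversal patterns
pathway_directions <- function(label) {
  switch(label,
    i = c(1, 0), iii = c(-1, 0), iv = c(1, 1), v = c(-1, -1),
    vi = c(0, 1), vii = c(0, -1),
    abort(paste("unknown pathway", label))
  )
}

# planted chromatin-state trajectory per pathway; non-DEG genes get constant
# states drawn from `none_state_weights`
pathway_trajectories <- function() {
  list(
    i = c("bivalent", "active", "active"),
    ii = c("bivalent", "active", "repressed"),
    iii = c("active", "empty", "empty"),
    iv = c("ambiguous", "weakly_active", "active"),
    v = c("active", "weakly_active", "empty"),
    vi = c("bivalent", "bivalent", "active"),
    vii = c("active", "active", "empty")
  )
}

none_state_weights <- c(empty = 0.4, repressed = 0.2, active = 0.2, transcription_prone = 0.2)

# defining marks emitted by each chromatin state (representative combination;
# classify_state() maps each back to its own state)
state_marks <- function(state) {
  switch(state,
    active = c("H3K4me3", "H3K9ac", "RNAPII"),
    weakly_active = c("H3K4me3", "RNAPII"),
    transcription_prone = c("H3K4me3", "H3K9ac"),
    bivalent = c("H3K4me3", "H3K27me3"),
    ambiguous = "H3K4me3",
    empty = character(),
    repressed = "H3K27me3",
    abort(paste("unknown state label:", state))
  )
}

chip_targets <- function() c("H3K4me3", "H3K9ac", "H3K27ac", "RNAPII", "H3K27me3")

#' TSS annotation of the toy genome
#'
#' One linear chromosome with TSSs `tss_spacing` bp apart (promoter windows
#' never overlap) and random strands.
#'
#' @param config A `simulation_config`.
#' @return Tibble `gene_id`, `chrom`, `tss`, `strand`.
#' @export
make_tss <- function(config) {
  with_seed(config$seed + 7L, tibble(
    gene_id = sprintf("G%05d", seq_len(config$n_genes)),
    chrom = "chr1",
    tss = as.integer(seq_len(config$n_genes) - 1L) * config$tss_spacing + 5000L,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
  ))
}

#' Simulate the expression matrix with planted co-expression pathways
#'
#' Genes are assigned pathway labels per `pathway_proportions`; each planted
#' step change draws a log2 ratio of magnitude centred on `effect_size`
#' (sd 15% of it), non-DEGs have mean-zero ratios, and replicate noise is
#' Normal(0, `noise_sd`) on the log2 scale. Planted chromatin-state
#' trajectories correlated with the pathways are recorded in the gold
#' standard.
#'
#' @param config A `simulation_config`.
#' @return List with `expression` (wide tibble), `design`, and `gold` (tibble
#'   of per-gene truths: pathway, per-step log2 deltas, per-stage states).
#' @export
simulate_expression <- function(config) {
  with_seed(config$seed, {
    n <- config$n_genes
    gene_id <- sprintf("G%05d", seq_len(n))

    props <- config$pathway_proportions
    counts <- round(props * n)
    if (sum(counts) > n) abort("pathway proportions sum to more than 1")
    pathway <- rep("none", n)
    idx <- sample(n, sum(counts))
    pathway[idx] <- rep(names(counts), counts)

    d1 <- numeric(n)
    d2 <- numeric(n)
    for (lab in names(counts)) {
      rows <- which(pathway == lab)
      if (!length(rows)) next
      mag1 <- abs(rnorm(length(rows), config$effect_size, 0.15 * config$effect_size))
      mag2 <- abs(rnorm(length(rows), config$effect_size, 0.15 * config$effect_size))
      if (lab == "ii") {
        flip <- sample(c(1, -1), length(rows), replace = TRUE)
        d1[rows] <- flip * mag1
        d2[rows] <- -flip * mag2
      } else {
        dirs <- pathway_directions(lab)
        d1[rows] <- dirs[[1]] * mag1
        d2[rows] <- dirs[[2]] * mag2
      }
    }

    traj <- pathway_trajectories()
    states <- matrix("", n, 3)
    is_deg <- pathway != "none"
    for (lab in names(traj)) {
      rows <- which(pathway == lab)
      if (length(rows)) states[rows, ] <- matrix(traj[[lab]], length(rows), 3, byrow = TRUE)
    }
    none_rows <- which(!is_deg)
    const <- sample(names(none_state_weights), length(none_rows),
      replace = TRUE, prob = none_state_weights
    )
    states[none_rows, ] <- matrix(const, length(none_rows), 3)

    base <- rnorm(n, config$base_mean, config$base_sd)
    design <- tidyr::expand_grid(
      stage = factor(config$stages, levels = config$stages),
      replicate = seq_len(config$n_replicates)
    ) %>%
      mutate(sample = paste0(.data$stage, "_r", .data$replicate)) %>%
      select("sample", "stage", "replicate")

    deltas <- cbind(0, d1, d2)
    expr <- tibble(gene_id = gene_id)
    for (i in seq_len(nrow(design))) {
      stage_i <- match(design$stage[[i]], config$stages)
      expr[[design$sample[[i]]]] <-
        2^(base + deltas[, stage_i] + rnorm(n, 0, config$noise_sd))
    }

    gold <- tibble(
      gene_id = gene_id, pathway = pathway,
      delta_step1 = d1, delta_step2 = d2,
      state_stage1 = states[, 1], state_stage2 = states[, 2], state_stage3 = states[, 3]
    )
    list(expression = expr, design = design, gold = gold)
  })
}

#' Simulate ChIP-seq peaks and binned coverage from planted states
#'
#' For each promoter-stage, the defining marks of the gene's planted state
#' emit (jointly, with probability `state_emission`) a peak whose summit lies
#' within 400 bp of the TSS and whose per-bin counts sit far in the upper tail
#' of the track's count distribution, so the z > 1.65 gate separates them from
#' the negative-binomial background by construction. Decoy peaks are added
#' away from TSSs (high counts, wrong place) and at promoters lacking the mark
#' (low counts, failing the z and dispersion gates).
#'
#' @param config A `simulation_config`.
#' @param gold Per-gene truth tibble from [simulate_expression()].
#' @param tss TSS annotation (defaults to [make_tss()]).
#' @param always_emit Gene ids whose planted states emit deterministically
#'   (the study generator passes the driver TFs here: they anchor the planted
#'   regulatory layer, and the Pol II filter is exercised by decoys instead).
#' @return List with `peaks` (tibble over all targets/stages) and `tracks`
#'   (raw `chip_tracks`).
#' @export
simulate_chromatin <- function(config, gold, tss = make_tss(config),
                               always_emit = character()) {
  state_cols <- paste0("state_stage", 1:3)
  all_states <- unlist(gold[state_cols], use.names = FALSE)
  unknown <- setdiff(unique(all_states), chromatin_states())
  if (length(unknown)) abort(paste("unknown state label:", paste(unknown, collapse = ", ")))

  with_seed(config$seed + 1L, {
    n <- config$n_genes
    genome_len <- n * config$tss_spacing
    n_bins <- genome_len %/% config$bin_size
    bins <- tibble(
      chrom = "chr1",
      start = (seq_len(n_bins) - 1L) * config$bin_size,
      end = seq_len(n_bins) * config$bin_size
    )
    targets <- chip_targets()
    meta <- tidyr::expand_grid(target = targets, stage = config$stages) %>%
      mutate(track_id = paste(.data$target, .data$stage, sep = ":")) %>%
      select("track_id", "target", "stage")

    scores <- matrix(0, n_bins, nrow(meta))
    peak_list <- vector("list", nrow(meta))
    mark_sets <- lapply(chromatin_states(), state_marks)
    names(mark_sets) <- chromatin_states()

    for (s in seq_along(config$stages)) {
      emit <- runif(n) < config$state_emission
      emit[tss$gene_id %in% always_emit] <- TRUE
      gene_states <- gold[[state_cols[[s]]]]
      # one summit per emitting promoter-stage, shared by its defining marks
      summit <- tss$tss + round(runif(n, -400, 400))
      for (tg in targets) {
        k <- which(meta$target == tg & meta$stage == config$stages[[s]])
        col <- rnbinom(n_bins, mu = config$background_mu, size = config$background_size)

        has_mark <- vapply(gene_states, function(st) tg %in% mark_sets[[st]], logical(1))
        planted <- which(has_mark & emit)
        rows <- list()
        if (length(planted)) {
          s_bin <- summit[planted] %/% config$bin_size + 1L
          for (off in -2:2) {
            b <- s_bin + off
            ok <- b >= 1 & b <= n_bins
            col[b[ok]] <- col[b[ok]] + rpois(sum(ok), config$peak_mean_count)
          }
          rows$planted <- tibble(
            chrom = "chr1",
            start = pmax(summit[planted] - 250L, 0L),
            end = summit[planted] + 250L,
            name = paste0(tg, "_", config$stages[[s]], "_", tss$gene_id[planted]),
            score = 1000L, strand = ".",
            signal = 5 * config$peak_mean_count,
            neg_log10_p = round(runif(length(planted), 20, 100), 3),
            neg_log10_q = round(runif(length(planted), 10, 50), 3),
            summit_offset = summit[planted] - pmax(summit[planted] - 250L, 0L)
          )
        }
        # decoys away from TSSs: real signal, wrong place
        n_far <- round(config$background_decoy_rate * n)
        far_gene <- sample(n, n_far, replace = TRUE)
        far_pos <- tss$tss[far_gene] +
          sample(c(-1L, 1L), n_far, replace = TRUE) * round(runif(n_far, 2500, 7500))
        far_pos <- pmin(pmax(far_pos, 300L), genome_len - 300L)
        fb <- far_pos %/% config$bin_size + 1L
        for (off in -1:1) {
          b <- fb + off
          ok <- b >= 1 & b <= n_bins
          col[b[ok]] <- col[b[ok]] + rpois(sum(ok), config$peak_mean_count / 2)
        }
        rows$far <- tibble(
          chrom = "chr1", start = far_pos - 150L, end = far_pos + 150L,
          name = paste0(tg, "_", config$stages[[s]], "_bg", seq_len(n_far)),
          score = 300L, strand = ".",
          signal = 1.5 * config$peak_mean_count,
          neg_log10_p = round(runif(n_far, 5, 40), 3),
          neg_log10_q = round(runif(n_far, 2, 20), 3),
          summit_offset = 150L
        )
        # weak promoter decoys at genes lacking the mark: fail the z gate
        weak_cand <- which(!has_mark)
        n_weak <- min(length(weak_cand), round(config$promoter_decoy_rate * n))
        if (n_weak > 0) {
          wk <- sample(weak_cand, n_weak)
          w_pos <- tss$tss[wk] + round(runif(n_weak, -400, 400))
          wb <- w_pos %/% config$bin_size + 1L
          for (off in -2:2) {
            b <- wb + off
            ok <- b >= 1 & b <= n_bins
            col[b[ok]] <- col[b[ok]] + rpois(sum(ok), 3)
          }
          rows$weak <- tibble(
            chrom = "chr1", start = pmax(w_pos - 250L, 0L), end = w_pos + 250L,
            name = paste0(tg, "_", config$stages[[s]], "_wk", seq_len(n_weak)),
            score = 50L, strand = ".",
            signal = 15,
            neg_log10_p = round(runif(n_weak, 2, 10), 3),
            neg_log10_q = round(runif(n_weak, 1, 5), 3),
            summit_offset = w_pos - pmax(w_pos - 250L, 0L)
          )
        }
        scores[, k] <- col
        pk <- bind_rows(rows)
        pk$target <- tg
        pk$stage <- config$stages[[s]]
        pk$summit <- pk$start + pk$summit_offset
        peak_list[[k]] <- pk
      }
    }
    list(
      peaks = bind_rows(peak_list),
      tracks = chip_tracks(bins, scores, meta)
    )
  })
}

#' Simulate regulons, the interaction network, and oncogene ChIP peaks
#'
#' Driver TFs (genes of their own pathway) receive regulons concentrated
#' (~75%, never below 50%) in that pathway; decoy TFs get uniform regulons,
#' half of them at promoters without RNA Pol II so the Pol II filter has work
#' to do. The interaction network over planted DEGs is modular: per community
#' a clique of engineered hubs, a preferential-attachment spoke tree, and one
#' hub attachment per spoke; consecutive communities are joined only through
#' designated bottleneck connector nodes. Oncogene ChIP peaks with
#' -log10(p) >= 300 are planted at the promoters of a designated target set.
#'
#' @param config A `simulation_config`.
#' @param gold Per-gene truth tibble from [simulate_expression()].
#' @param tss TSS annotation (defaults to [make_tss()]).
#' @return List with `regulons`, `interactions`, `oncogene_peaks`,
#'   `crm_catalog`, and `gold_network` (drivers, hubs, bottlenecks, oncogene
#'   id and target set).
#' @export
simulate_regulons_and_network <- function(config, gold, tss = make_tss(config)) {
  n_drivers <- length(roman_pathways()) * config$drivers_per_pathway
  if (config$n_tfs == 0 && n_drivers > 0) {
    abort("n_tfs = 0 but driver regulons are requested")
  }
  if (config$n_tfs < n_drivers) {
    abort("n_tfs smaller than drivers_per_pathway x 7")
  }

  with_seed(config$seed + 2L, {
    paths <- split(gold$gene_id, gold$pathway)
    paths <- paths[intersect(roman_pathways(), names(paths))]
    none_genes <- gold %>% filter(.data$pathway == "none")
    deg_ids <- gold$gene_id[gold$pathway != "none"]

    # communities are aligned with the co-expression pathways (co-expressed
    # genes interact preferentially), assigning pathways greedily to the
    # lightest community and placing the two largest groups at the chain ends
    # so every connector separates more than a quarter of the network
    sizes <- lengths(paths)
    comm_of_path <- integer(length(paths))
    names(comm_of_path) <- names(paths)
    load <- numeric(config$n_communities)
    for (lab in names(sort(sizes, decreasing = TRUE))) {
      k <- which.min(load)
      comm_of_path[[lab]] <- k
      load[[k]] <- load[[k]] + sizes[[lab]]
    }
    ends_first <- order(load, decreasing = TRUE)
    chain_pos <- integer(config$n_communities)
    chain_pos[c(1, config$n_communities)] <- ends_first[1:2]
    if (config$n_communities > 2) {
      chain_pos[2:(config$n_communities - 1)] <- ends_first[-(1:2)]
    }
    comm_of_path[] <- match(comm_of_path, chain_pos)

    # driver TFs: genes of the pathway they drive (their promoters carry
    # Pol II at some stage by construction of the planted trajectories)
    drivers <- purrr::map_dfr(names(paths), function(lab) {
      k <- min(config$drivers_per_pathway, length(paths[[lab]]))
      tibble(
        tf = sample(paths[[lab]], k),
        driver = TRUE, pathway = lab
      )
    })
    n_decoys <- config$n_tfs - nrow(drivers)
    n_pol <- ceiling(n_decoys / 2)
    pol_pool <- none_genes$gene_id[none_genes$state_stage1 == "active"]
    nopol_pool <- setdiff(
      none_genes$gene_id[none_genes$state_stage1 %in% c("empty", "repressed")],
      pol_pool
    )
    decoys <- tibble(
      tf = c(
        sample(pol_pool, min(n_pol, length(pol_pool))),
        sample(nopol_pool, min(n_decoys - n_pol, length(nopol_pool)))
      ),
      driver = FALSE, pathway = NA_character_
    )
    tfs <- bind_rows(drivers, decoys)

    # --- interaction network over planted DEGs -------------------------------
    # Engineered geometry: per community a clique of hub genes plus a
    # preferential-attachment spoke tree; spokes attach to exactly one hub and
    # the spokes attached to one hub are pairwise at tree distance >= 3
    # (distance-2 independent), so each hub's maximum neighborhood component
    # is exactly the clique of its peers. All planted regulatory target sets
    # below are sampled tree-independent for the same reason: the regulatory
    # layers stay orthogonal to the engineered topological roles.
    connectors <- sample(setdiff(deg_ids, tfs$tf), config$n_bottleneck_connectors)
    pool <- setdiff(deg_ids, connectors)
    community <- comm_of_path[gold$pathway[match(pool, gold$gene_id)]]
    hubs <- character()
    edge_rows <- list()
    hub_by_comm <- vector("list", config$n_communities)
    tree_adj <- list() # gene id -> tree-neighbor gene ids, across communities
    for (cmt in seq_len(config$n_communities)) {
      members <- pool[community == cmt]
      hub_pool <- setdiff(members, tfs$tf)
      h <- sample(hub_pool, min(config$hubs_per_community, length(hub_pool)))
      hub_by_comm[[cmt]] <- h
      hubs <- c(hubs, h)
      spokes <- setdiff(members, h)
      if (length(h) > 1) {
        cc <- utils::combn(sort(h), 2)
        edge_rows[[length(edge_rows) + 1]] <- tibble(from = cc[1, ], to = cc[2, ])
      }
      if (length(spokes) > 1) {
        tree <- igraph::sample_pa(length(spokes),
          power = config$ppi_attachment, m = 1, directed = FALSE
        )
        el <- igraph::as_edgelist(tree)
        perm <- sample(spokes)
        from <- perm[as.integer(el[, 1])]
        to <- perm[as.integer(el[, 2])]
        edge_rows[[length(edge_rows) + 1]] <- tibble(from = from, to = to)
        adj_new <- split(c(to, from), c(from, to))
        tree_adj[names(adj_new)] <- adj_new
      }
      if (length(spokes) > 0 && length(h) > 0) {
        cap <- ceiling(length(spokes) / length(h))
        unattached <- spokes
        for (hb in h) {
          att <- greedy_tree_sample(unattached, tree_adj, cap, d2 = TRUE)
          unattached <- setdiff(unattached, att)
          if (length(att)) {
            edge_rows[[length(edge_rows) + 1]] <- tibble(from = att, to = hb)
          }
        }
      }
    }
    for (j in seq_len(config$n_bottleneck_connectors)) {
      edge_rows[[length(edge_rows) + 1]] <- tibble(
        from = connectors[[j]],
        to = c(sample(hub_by_comm[[j]], 1), sample(hub_by_comm[[j + 1]], 1))
      )
    }
    # decoy edges touching non-DEGs: must be dropped by DEG-only assembly
    n_decoy_edges <- min(100L, nrow(none_genes))
    decoy_from <- sample(none_genes$gene_id, n_decoy_edges)
    decoy_to <- sample(gold$gene_id, n_decoy_edges)
    keep <- decoy_from != decoy_to
    edge_rows[[length(edge_rows) + 1]] <- tibble(from = decoy_from[keep], to = decoy_to[keep])

    interactions <- bind_rows(edge_rows) %>%
      mutate(type = "pp") %>%
      select("from", "type", "to")

    # --- regulons -------------------------------------------------------------
    # Targets are drawn from the spoke periphery of the TF's own community
    # (excluding TF genes, hubs and connectors) as tree-independent sets, and
    # co-drivers of one pathway receive disjoint in-pathway targets.
    reserved <- c(tfs$tf, hubs, connectors)
    regulon_rows <- list()
    for (lab in names(paths)) {
      drv <- drivers$tf[drivers$pathway == lab]
      in_pool <- setdiff(paths[[lab]], reserved)
      per_in <- floor(length(in_pool) / length(drv))
      for (j in seq_along(drv)) {
        size <- max(5L, round(rnorm(1, config$regulon_size, 0.15 * config$regulon_size)))
        in_n <- max(1L, min(ceiling(0.75 * size), per_in))
        size <- min(size, floor(in_n / 0.5)) # keep >=50% of targets in-pathway
        mine <- greedy_tree_sample(in_pool, tree_adj, in_n)
        in_pool <- setdiff(in_pool, mine)
        # the remainder of the regulon falls outside the DEG set entirely, so
        # driver regulons never compete across pathways; its size is capped so
        # in-pathway targets stay at least half the regulon
        size <- min(size, max(1L, floor(length(mine) / 0.5)))
        extra_pool <- setdiff(none_genes$gene_id, drv)
        extra <- sample(extra_pool, min(max(0L, size - length(mine)), length(extra_pool)))
        regulon_rows[[length(regulon_rows) + 1]] <- tibble(
          tf = drv[[j]], target = c(mine, extra)
        )
      }
    }
    for (tf in decoys$tf) {
      size <- max(5L, round(rnorm(1, config$regulon_size, 0.15 * config$regulon_size)))
      n_deg <- round(0.2 * size)
      cmt <- sample(config$n_communities, 1)
      deg_pool <- setdiff(pool[community == cmt], reserved)
      none_pool <- setdiff(none_genes$gene_id, tf)
      targets <- c(
        sample(none_pool, min(size - n_deg, length(none_pool))),
        greedy_tree_sample(deg_pool, tree_adj, min(n_deg, length(deg_pool)))
      )
      regulon_rows[[length(regulon_rows) + 1]] <- tibble(tf = tf, target = targets)
    }
    regulons <- bind_rows(regulon_rows)

    # --- oncogene ChIP layer -------------------------------------------------
    # the oncogene's cistrome is confined to its own co-expression module and
    # sampled tree-independent jointly with the oncogene's own regulon
    onco_tf <- drivers$tf[drivers$pathway == "vi"][1]
    if (is.na(onco_tf)) onco_tf <- drivers$tf[[1]]
    onco_comm <- comm_of_path[[drivers$pathway[drivers$tf == onco_tf][[1]]]]
    onco_pool <- setdiff(pool[community == onco_comm], reserved)
    onco_regulon <- regulons$target[regulons$tf == onco_tf]
    onco_targets <- greedy_tree_sample(
      onco_pool, tree_adj, min(config$n_oncogene_targets, length(onco_pool)),
      blocked = onco_regulon
    )
    onco_targets <- sort(onco_targets)
    t_tss <- tss[match(onco_targets, tss$gene_id), ]
    t_pos <- t_tss$tss + round(runif(length(onco_targets), -300, 300))
    others_pool <- setdiff(tss$gene_id, onco_targets)
    others <- sample(others_pool, min(50L, length(others_pool)))
    o_tss <- tss[match(others, tss$gene_id), ]
    o_pos <- o_tss$tss + round(runif(length(others), -300, 300))
    n_far_onco <- min(20L, length(tss$tss))
    far_pos <- sample(tss$tss, n_far_onco) + 5000L
    onco_peaks <- bind_rows(
      tibble(
        chrom = "chr1", start = t_pos - 100L, end = t_pos + 100L,
        name = paste0("onco_", onco_targets), score = 1000L, strand = ".",
        signal = 100, neg_log10_p = round(runif(length(t_pos), 300, 600), 2),
        neg_log10_q = 250, summit_offset = 100L
      ),
      tibble(
        chrom = "chr1", start = o_pos - 100L, end = o_pos + 100L,
        name = paste0("onco_lo_", others), score = 200L, strand = ".",
        signal = 20, neg_log10_p = round(runif(length(others), 10, 299), 2),
        neg_log10_q = 8, summit_offset = 100L
      ),
      tibble(
        chrom = "chr1", start = far_pos - 100L, end = far_pos + 100L,
        name = paste0("onco_far_", seq_len(n_far_onco)), score = 900L, strand = ".",
        signal = 90, neg_log10_p = round(runif(n_far_onco, 300, 600), 2),
        neg_log10_q = 240, summit_offset = 100L
      )
    ) %>%
      mutate(summit = .data$start + .data$summit_offset)

    crm_deg <- sample(deg_ids, min(round(2 / 3 * config$n_crms), length(deg_ids)))
    crm_none <- sample(
      none_genes$gene_id,
      min(config$n_crms - length(crm_deg), nrow(none_genes))
    )
    crm_catalog <- tibble(
      gene_id = c(crm_deg, crm_none),
      class = sample(c("writer", "eraser", "reader", "other"),
        length(crm_deg) + length(crm_none),
        replace = TRUE
      )
    )

    list(
      regulons = regulons,
      interactions = interactions,
      oncogene_peaks = onco_peaks,
      crm_catalog = crm_catalog,
      gold_network = list(
        tfs = tfs, hubs = sort(hubs), bottlenecks = sort(connectors),
        oncogene_id = onco_tf, oncogene_targets = sort(onco_targets)
      )
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Runs the expression, chromatin, and regulon/network generators under one
#' seed and bundles all pipeline inputs together with the gold standard.
#'
#' @param config A `simulation_config`.
#' @return A `synthetic_study` list: `expression`, `design`, `tss`, `peaks`,
#'   `tracks`, `regulons`, `interactions`, `oncogene_peaks`, `crm_catalog`,
#'   `gold` (genes, tfs, hubs, bottlenecks, oncogene id/targets), `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  ex <- simulate_expression(config)
  tss <- make_tss(config)
  nw <- simulate_regulons_and_network(config, ex$gold, tss)
  ch <- simulate_chromatin(config, ex$gold, tss,
    always_emit = nw$gold_network$tfs$tf[nw$gold_network$tfs$driver]
  )
  structure(
    list(
      config = config,
      expression = ex$expression, design = ex$design, tss = tss,
      peaks = ch$peaks, tracks = ch$tracks,
      regulons = nw$regulons, interactions = nw$interactions,
      oncogene_peaks = nw$oncogene_peaks, crm_catalog = nw$crm_catalog,
      gold = c(list(genes = ex$gold), nw$gold_network)
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(
    "<synthetic_study> ", x$config$n_genes, " genes, ",
    sum(x$gold$genes$pathway != "none"), " planted DEGs, ",
    nrow(x$gold$tfs), " TFs, seed ", x$config$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic study to disk in standard formats
#'
#' Expression TSV + design TSV, BED6 TSSs, per-track narrowPeak and bedGraph
#' files, GMT regulons, SIF interactions, oncogene narrowPeak, CRM catalog
#' TSV, and the gold-standard tables.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  readr::write_tsv(study$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(study$design, file.path(dir, "design.tsv"))
  write_tss_bed(study$tss, file.path(dir, "tss.bed"))
  meta <- study$tracks$meta
  for (k in seq_len(nrow(meta))) {
    stem <- paste0(meta$target[[k]], "_", meta$stage[[k]])
    write_narrowpeak(
      study$peaks %>% filter(.data$target == meta$target[[k]], .data$stage == meta$stage[[k]]),
      file.path(dir, "peaks", paste0(stem, ".narrowPeak"))
    )
    write_bedgraph(
      study$tracks$bins, study$tracks$raw[, k],
      file.path(dir, "coverage", paste0(stem, ".bedgraph"))
    )
  }
  write_gmt(study$regulons, file.path(dir, "regulons.gmt"))
  write_sif(study$interactions, file.path(dir, "interactions.sif"))
  write_narrowpeak(study$oncogene_peaks, file.path(dir, "oncogene_peaks.narrowPeak"))
  readr::write_tsv(study$crm_catalog, file.path(dir, "crm_catalog.tsv"))
  readr::write_tsv(study$gold$genes, file.path(dir, "gold_genes.tsv"))
  readr::write_tsv(study$gold$tfs, file.path(dir, "gold_tfs.tsv"))
  readr::write_tsv(
    tibble(
      id = c(study$gold$hubs, study$gold$bottlenecks),
      role = rep(c("hub", "bottleneck"), c(length(study$gold$hubs), length(study$gold$bottlenecks)))
    ),
    file.path(dir, "gold_network.tsv")
  )
  onco_t <- study$gold$oncogene_targets
  readr::write_tsv(
    tibble(
      oncogene = study$gold$oncogene_id,
      target = if (length(onco_t)) onco_t else NA_character_
    ),
    file.path(dir, "gold_oncogene_targets.tsv")
  )
  invisible(dir)
}

#' Read a synthetic study back from disk
#'
#' Inverse of [write_study()]; every file round-trips through the package's
#' standard-format readers.
#'
#' @param dir Directory written by [write_study()].
#' @return A `synthetic_study`-shaped list (without the config).
#' @export
read_study <- function(dir) {
  peak_files <- sort(list.files(file.path(dir, "peaks"), full.names = TRUE))
  peaks <- purrr::map_dfr(peak_files, function(f) {
    stem <- sub("\\.narrowPeak$", "", basename(f))
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    read_narrowpeak(f, target = parts[[1]], stage = paste(parts[-1], collapse = "_"))
  })
  cov_files <- sort(list.files(file.path(dir, "coverage"), full.names = TRUE))
  covs <- lapply(cov_files, read_bedgraph)
  stems <- sub("\\.bedgraph$", "", basename(cov_files))
  parts <- strsplit(stems, "_", fixed = TRUE)
  meta <- tibble(
    target = vapply(parts, `[[`, character(1), 1),
    stage = vapply(parts, function(p) paste(p[-1], collapse = "_"), character(1))
  ) %>% mutate(track_id = paste(.data$target, .data$stage, sep = ":"))
  tracks <- chip_tracks(
    covs[[1]][, c("chrom", "start", "end")],
    do.call(cbind, lapply(covs, function(x) x$score)),
    meta[, c("track_id", "target", "stage")]
  )
  gold_net <- readr::read_tsv(file.path(dir, "gold_network.tsv"), show_col_types = FALSE, progress = FALSE)
  gold_onco <- readr::read_tsv(file.path(dir, "gold_oncogene_targets.tsv"), show_col_types = FALSE, progress = FALSE)
  list(
    expression = read_expression_matrix(file.path(dir, "expression.tsv")),
    design = read_design(file.path(dir, "design.tsv")),
    tss = read_tss_bed(file.path(dir, "tss.bed")),
    peaks = peaks,
    tracks = tracks,
    regulons = read_gmt(file.path(dir, "regulons.gmt")),
    interactions = read_sif(file.path(dir, "interactions.sif")),
    oncogene_peaks = read_narrowpeak(file.path(dir, "oncogene_peaks.narrowPeak")),
    crm_catalog = readr::read_tsv(file.path(dir, "crm_catalog.tsv"), show_col_types = FALSE, progress = FALSE),
    gold = list(
      genes = readr::read_tsv(file.path(dir, "gold_genes.tsv"), show_col_types = FALSE, progress = FALSE),
      tfs = readr::read_tsv(file.path(dir, "gold_tfs.tsv"), show_col_types = FALSE, progress = FALSE),
      hubs = gold_net$id[gold_net$role == "hub"],
      bottlenecks = gold_net$id[gold_net$role == "bottleneck"],
      oncogene_id = gold_onco$oncogene[1],
      oncogene_targets = as.character(gold_onco$target[!is.na(gold_onco$target)])
    )
  )
}
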