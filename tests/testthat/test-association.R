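fake_marks <- function(gene_id, polII_present) {
  n <- length(gene_id)
  tibble::tibble(
    gene_id = rep(gene_id, each = 3),
    target = "RNAPII",
    stage = rep(c("s1", "s2", "s3"), n),
    present = rep(polII_present, each = 3),
    offset = 0, z = 2, dispersion = 0.05
  )
}

test_that("hypergeometric enrichment matches exact combinatorics", {
  expect_equal(hypergeom_enrichment(5, 5, 10, overlap = 5), 1 / 252)
  expect_equal(hypergeom_enrichment(5, 5, 10, overlap = 0), 1)

  # full enumeration over all C(10,5) pathway draws for N = 10
  universe <- letters[1:10]
  regulon <- letters[1:5]
  draws <- utils::combn(universe, 5)
  for (k in 0:5) {
    p_enum <- mean(apply(draws, 2, function(s) length(intersect(s, regulon)) >= k))
    expect_equal(hypergeom_enrichment(5, 5, 10, overlap = k), p_enum, tolerance = 1e-12)
  }

  # set interface, and the tail-sum oracle at larger margins
  expect_equal(
    hypergeom_enrichment(letters[1:6], letters[4:11], letters[1:20]),
    oracle_hyper_tail(3, 6, 8, 20)
  )
  # monotone decreasing in overlap at fixed margins
  ps <- vapply(0:6, function(k) hypergeom_enrichment(6, 8, 20, overlap = k), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(hypergeom_enrichment(1, 1, 0, overlap = 0), "empty universe")
})

test_that("TF selection applies the strict coverage and Pol II filters", {
  pathway_genes <- sprintf("p%02d", 1:20)
  degs <- fake_degs(
    c(pathway_genes, "tfA", "tfB", "tfC", "x1"),
    c(rep("i", 20), rep("none", 4))
  )
  regulons <- dplyr::bind_rows(
    tibble::tibble(tf = "tfA", target = c(pathway_genes[1:3], "x1")), # 15% coverage
    tibble::tibble(tf = "tfB", target = c(pathway_genes[1:2], "x1")), # exactly 10%
    tibble::tibble(tf = "tfC", target = pathway_genes[1:10]) # 50% but no Pol II
  )
  marks <- fake_marks(c("tfA", "tfB", "tfC"), c(TRUE, TRUE, FALSE))

  kept <- select_tfs(regulons, degs, marks)
  expect_equal(kept, "tfA")

  # strictness at the boundary: >10% is required, 10% exactly is excluded
  expect_false("tfB" %in% kept)
  # monotone non-increasing in min_cover
  for (mc in c(0.05, 0.10, 0.20, 0.5)) {
    expect_true(all(select_tfs(regulons, degs, marks, min_cover = mc) %in%
      select_tfs(regulons, degs, marks, min_cover = 0.01)))
  }
  # unannotated TF excluded with a warning, not an error
  expect_warning(
    kept2 <- select_tfs(regulons, degs, fake_marks("tfC", FALSE)),
    "without promoter annotation"
  )
  expect_equal(kept2, character(0))
})

test_that("association matrices rank planted regulons and cluster reproducibly", {
  withr::with_seed(14, {
    genes <- sprintf("g%03d", 1:200)
    pw <- rep("none", 200)
    pw[1:30] <- "i"
    pw[31:60] <- "ii"
    degs <- fake_degs(genes, pw)
    regulons <- dplyr::bind_rows(
      tibble::tibble(tf = "driver_i", target = c(genes[1:20], genes[100:110])),
      tibble::tibble(tf = "driver_i2", target = c(genes[5:25], genes[120:130])),
      tibble::tibble(tf = "driver_ii", target = c(genes[31:50], genes[140:150])),
      tibble::tibble(tf = "driver_ii2", target = c(genes[40:60], genes[160:170])),
      tibble::tibble(tf = "random", target = sample(genes, 25))
    )
    assoc <- tf_pathway_association(regulons, degs)
    tab <- assoc$table
    expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
    expect_true(all(tab$coverage >= 0 & tab$coverage <= 1))
    # planted drivers dominate their own pathway column
    best_i <- tab$tf[tab$pathway == "i"][order(tab$p_value[tab$pathway == "i"])][1:2]
    expect_setequal(best_i, c("driver_i", "driver_i2"))

    cl <- cluster_associations(assoc)
    # two identical rows merge at height zero first
    dup <- assoc
    dup$matrix <- rbind(dup$matrix, dup$matrix["driver_i", , drop = FALSE])
    rownames(dup$matrix)[nrow(dup$matrix)] <- "clone"
    dup_cl <- cluster_associations(dup)
    h <- dup_cl$row_tree
    first <- sort(h$labels[-h$merge[1, ]])
    expect_equal(h$height[1], 0)
    expect_setequal(first, c("driver_i", "clone"))

    # block structure splits at the top; invariant to row permutation
    part <- stats::cutree(cl$row_tree, k = 2)
    expect_equal(part[["driver_i"]], part[["driver_i2"]])
    expect_equal(part[["driver_ii"]], part[["driver_ii2"]])
    expect_false(part[["driver_i"]] == part[["driver_ii"]])

    perm <- assoc
    perm$matrix <- perm$matrix[sample(nrow(perm$matrix)), ]
    part2 <- stats::cutree(cluster_associations(perm)$row_tree, k = 2)
    expect_equal(
      part2[["driver_i"]] == part2[["driver_ii"]],
      part[["driver_i"]] == part[["driver_ii"]]
    )
  })
})

test_that("state-pathway integration produces exact Pearson residuals", {
  mk_inputs <- function(counts) {
    # counts: matrix cluster x pathway
    rows <- list()
    g <- 0
    for (i in seq_len(nrow(counts))) {
      for (j in seq_len(ncol(counts))) {
        n <- counts[i, j]
        if (n == 0) next
        ids <- sprintf("g%04d", g + seq_len(n))
        g <- g + n
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene_id = ids, cluster = rownames(counts)[i], pathway = colnames(counts)[j]
        )
      }
    }
    df <- dplyr::bind_rows(rows)
    traj <- structure(
      tibble::tibble(
        gene_id = df$gene_id, state_stage1 = "x", state_stage2 = "x",
        state_stage3 = "x", cluster = df$cluster
      ),
      class = c("state_trajectories", class(tibble::tibble()))
    )
    degs <- fake_degs(df$gene_id, df$pathway)
    list(traj = traj, degs = degs)
  }

  u <- mk_inputs(matrix(10, 2, 2, dimnames = list(c("c1", "c2"), c("i", "ii"))))
  res_u <- integrate_states_pathways(u$traj, u$degs)
  expect_equal(unname(res_u$residuals), matrix(0, 2, 2))
  expect_equal(res_u$chisq, 0)

  m <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE,
    dimnames = list(c("c1", "c2"), c("i", "ii"))
  )
  res <- integrate_states_pathways(mk_inputs(m)$traj, mk_inputs(m)$degs)
  expect_equal(abs(unname(res$residuals)), matrix(5 / sqrt(15), 2, 2), tolerance = 1e-12)
  expect_equal(res$chisq, 20 / 3, tolerance = 1e-12)

  # random tables: residual identities and chi-square agreement (dual route)
  withr::with_seed(2, {
    for (rep in 1:5) {
      counts <- matrix(rpois(12, 8) + 1, 3, 4,
        dimnames = list(paste0("c", 1:3), c("i", "ii", "iii", "iv"))
      )
      inp <- mk_inputs(counts)
      res_r <- integrate_states_pathways(inp$traj, inp$degs)
      o <- res_r$observed
      e <- res_r$expected
      expect_equal(unname(rowSums(o - e)), rep(0, 3), tolerance = 1e-9)
      expect_equal(unname(colSums(o - e)), rep(0, 4), tolerance = 1e-9)
      ref <- suppressWarnings(chisq.test(o, correct = FALSE))
      expect_equal(res_r$chisq, unname(ref$statistic), tolerance = 1e-9)
      expect_equal(res_r$residuals, unclass(ref$residuals), tolerance = 1e-9)
    }
  })

  # degenerate single-column table
  one <- mk_inputs(matrix(c(5, 5), 2, 1, dimnames = list(c("c1", "c2"), "i")))
  expect_warning(res1 <- integrate_states_pathways(one$traj, one$degs), "degenerate")
  expect_true(all(res1$residuals == 0))
  expect_true(res1$degenerate)
})

test_that("a planted state cluster lights up its pathway's residual cell", {
  cfg <- simulation_config(
    n_genes = 400, state_emission = 1, seed = 17,
    background_decoy_rate = 0, promoter_decoy_rate = 0
  )
  st <- simulate_study(cfg)
  tracks <- zscore_scale(quantile_normalize(st$tracks))
  marks <- call_presence(st$peaks, tracks, st$tss, seed = 20)
  states <- state_calls(marks)
  gd <- gold_deg_table(st)
  deg_ids <- gd$gene_id[gd$pathway != "none"]
  traj <- state_trajectories(states %>% dplyr::filter(gene_id %in% deg_ids), cfg$stages)
  res <- integrate_states_pathways(traj, gd)
  # the trajectory planted for pathway i peaks in the i column
  expect_equal(
    unname(which.max(res$residuals[, "i"])),
    unname(which(rownames(res$residuals) == "bivalent>active>active"))
  )
})

test_that("CRM annotation intersects DEGs with the catalog and reports the step", {
  degs <- structure(
    tibble::tibble(
      gene_id = c("w1", "e1", "r1", "o1", "x1"),
      pathway = c("i", "vi", "iv", "none", "ii"),
      ratio_step1 = 1, p_step1 = 1,
      call_step1 = c("up", "ns", "up", "ns", "down"),
      ratio_step2 = 1, p_step2 = 1,
      call_step2 = c("ns", "up", "up", "ns", "up")
    ),
    class = c("deg_table", class(tibble::tibble()))
  )
  catalog <- tibble::tibble(
    gene_id = c("w1", "e1", "r1", "o1", "zz"),
    class = c("writer", "eraser", "reader", "other", "writer")
  )
  crms <- annotate_crms(degs, catalog)
  expect_setequal(crms$gene_id, c("w1", "e1", "r1")) # o1 is not a DEG
  expect_equal(crms$step_of_change[crms$gene_id == "w1"], "step1_only")
  expect_equal(crms$step_of_change[crms$gene_id == "e1"], "step2_only")
  expect_equal(crms$step_of_change[crms$gene_id == "r1"], "both")
  # classes partition the CRM DEGs
  expect_equal(sum(table(crms$class)), nrow(crms))

  expect_warning(empty <- annotate_crms(degs, catalog[0, ]), "empty CRM catalog")
  expect_equal(nrow(empty), 0)
})
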