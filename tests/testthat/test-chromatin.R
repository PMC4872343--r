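# small two-track fixture on a 10 kb toy chromosome
make_tracks <- function(scores, targets, stages) {
  n <- nrow(scores)
  bins <- tibble::tibble(
    chrom = "chr1", start = (seq_len(n) - 1) * 100L, end = seq_len(n) * 100L
  )
  meta <- tibble::tibble(
    track_id = paste(targets, stages, sep = ":"), target = targets, stage = stages
  )
  chip_tracks(bins, scores, meta)
}

test_that("quantile normalization performs rank-mean substitution", {
  tr <- make_tracks(cbind(c(1, 2, 3), c(4, 5, 6)), c("X", "X"), c("a", "b"))
  qn <- quantile_normalize(tr)
  expect_equal(unname(qn$scores[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$scores[, 2]), c(2.5, 3.5, 4.5))

  # already-identical samples are a fixed point
  tr2 <- make_tracks(cbind(c(2, 9, 4), c(2, 9, 4)), c("X", "X"), c("a", "b"))
  expect_equal(quantile_normalize(tr2)$scores, tr2$scores, ignore_attr = TRUE)

  withr::with_seed(4, {
    sc <- cbind(rgamma(200, 2), rgamma(200, 5), rgamma(200, 1))
    tr3 <- make_tracks(sc, rep("X", 3), c("a", "b", "c"))
    qn3 <- quantile_normalize(tr3)
    # sorted multisets identical, hence equal column means
    expect_equal(sort(qn3$scores[, 1]), sort(qn3$scores[, 2]))
    expect_equal(sort(qn3$scores[, 1]), sort(qn3$scores[, 3]))
    expect_equal(mean(qn3$scores[, 1]), mean(qn3$scores[, 2]))
    # idempotent
    expect_equal(quantile_normalize(qn3)$scores, qn3$scores, tolerance = 1e-12)
    # permutation-equivariant across samples
    tr4 <- make_tracks(sc[, c(2, 1, 3)], rep("X", 3), c("a", "b", "c"))
    qn4 <- quantile_normalize(tr4)
    expect_equal(qn4$scores[, 1], qn3$scores[, 2], ignore_attr = TRUE)
  })

  # normalization is per target: other targets untouched by X's pool
  mixed <- make_tracks(cbind(c(1, 2, 3), c(400, 500, 600)), c("X", "Y"), c("a", "a"))
  expect_equal(unname(quantile_normalize(mixed)$scores[, 1]), c(1, 2, 3))
})

test_that("z-score scaling standardizes each track", {
  withr::with_seed(9, {
    sc <- cbind(rnorm(500, 10, 3), rnorm(500, 50, 8))
    tr <- make_tracks(sc, c("X", "X"), c("a", "b"))
    z <- zscore_scale(tr)
    expect_equal(colMeans(z$scores), c(0, 0), tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(apply(z$scores, 2, sd), c(1, 1), tolerance = 1e-10, ignore_attr = TRUE)

    # location-scale invariance: a shifted/scaled copy maps to the same z track
    tr_shift <- make_tracks(cbind(sc[, 1], 5 + 2 * sc[, 1]), c("X", "X"), c("a", "b"))
    zz <- zscore_scale(tr_shift)
    expect_equal(zz$scores[, 1], zz$scores[, 2], ignore_attr = TRUE)

    # z > 1.65 captures ~5% of a normal-like track
    big <- make_tracks(matrix(rnorm(40000), ncol = 1), "X", "a")
    expect_lt(abs(mean(zscore_scale(big)$scores[, 1] > 1.65) - 0.05), 0.01)
  })
  flat <- make_tracks(matrix(rep(3, 10), ncol = 1), "X", "a")
  expect_error(zscore_scale(flat), "zero-variance")
})

test_that("subsampling dispersion behaves as a count-noise measure", {
  # deep rectangular peak: essentially no dispersion
  expect_lt(subsample_dispersion(rep(5000, 5), seed = 1), 0.01)
  # dispersion shrinks as counts grow
  d_small <- subsample_dispersion(rep(10, 5), seed = 1, reps = 20)
  d_big <- subsample_dispersion(rep(1000, 5), seed = 1, reps = 20)
  expect_gt(d_small, d_big)
  # deterministic under seed
  expect_identical(
    subsample_dispersion(rep(25, 5), seed = 7),
    subsample_dispersion(rep(25, 5), seed = 7)
  )
  expect_error(subsample_dispersion(numeric(0)), "empty")
  expect_identical(subsample_dispersion(c(0, 0, 0), seed = 1), Inf)

  # Poisson-count peak vs a read-level resampling oracle
  withr::with_seed(31, {
    counts <- rpois(5, 10)
    f <- 0.7
    oracle <- replicate(4000, {
      kept <- vapply(counts, function(k) sum(runif(k) < f), numeric(1))
      sum(kept) / f
    })
    oracle_cv <- sd(oracle) / mean(oracle)
    got <- subsample_dispersion(counts, fractions = f, reps = 500, seed = 2)
    expect_lt(abs(got - oracle_cv), 0.25 * oracle_cv)
  })
})

test_that("promoter presence requires summit, z, and dispersion criteria jointly", {
  # one RNAPII track; background zeros with three planted peaks
  n_bins <- 200
  sc <- matrix(rpois(n_bins, 5) + 0, ncol = 1)
  # deep peak at bin 55 (pos 5400-5500), weak peak at bin 151
  sc[54:56, 1] <- 800
  sc[150:152, 1] <- 9
  tr <- make_tracks(sc, "RNAPII", "s1")
  tr <- zscore_scale(tr)

  tss <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = "chr1", tss = c(5000L, 4800L, 15000L, 18000L),
    strand = c("+", "-", "+", "+")
  )
  peaks <- tibble::tibble(
    target = "RNAPII", stage = "s1", chrom = "chr1",
    summit = c(5400L, 5400L, 15050L, 18400L),
    name = c("p1", "p1", "p2", "p3")
  )
  marks <- call_presence(peaks, tr, tss, seed = 3)
  got <- marks[match(c("gA", "gB", "gC", "gD"), marks$gene_id), ]
  expect_true(got$present[got$gene_id == "gA"]) # summit at TSS+400, deep
  expect_false(got$present[got$gene_id == "gB"]) # summit 600 bp away
  expect_false(got$present[got$gene_id == "gC"]) # z below 1.65
  expect_false(got$present[got$gene_id == "gD"]) # no peak near TSS at all
  # offsets are reported 5'->3'
  expect_equal(got$offset[got$gene_id == "gA"], 400)

  # monotone: raising zmin or shrinking the window never adds presences
  strict_z <- call_presence(peaks, tr, tss, zmin = 3, seed = 3)
  strict_w <- call_presence(peaks, tr, tss, window = 100, seed = 3)
  expect_true(all(strict_z$present <= marks$present))
  expect_true(all(strict_w$present <= marks$present))

  expect_error(call_presence(peaks, tr, tss, genes = "gZ", seed = 3), "without TSS")
  raw <- make_tracks(sc, "RNAPII", "s1")
  expect_error(call_presence(peaks, raw, tss), "z-scaled")
})

test_that("the state classifier is a total 7-label partition of 32 combinations", {
  expect_equal(classify_state(TRUE, TRUE, FALSE, TRUE, FALSE), "active")
  expect_equal(classify_state(FALSE, FALSE, FALSE, FALSE, TRUE), "repressed")
  expect_equal(classify_state(TRUE, TRUE, FALSE, TRUE, TRUE), "bivalent")
  expect_equal(classify_state(FALSE, FALSE, FALSE, FALSE, FALSE), "empty")
  expect_equal(classify_state(TRUE, FALSE, FALSE, TRUE, FALSE), "weakly_active")
  expect_equal(classify_state(FALSE, TRUE, TRUE, FALSE, FALSE), "transcription_prone")
  expect_equal(classify_state(FALSE, FALSE, TRUE, FALSE, FALSE), "ambiguous")
  expect_equal(classify_state(FALSE, FALSE, FALSE, TRUE, FALSE), "ambiguous")

  combos <- expand.grid(k4 = 0:1, k9 = 0:1, k27ac = 0:1, pol = 0:1, k27me3 = 0:1)
  lab <- classify_state(combos$k4, combos$k9, combos$k27ac, combos$pol, combos$k27me3)
  expect_equal(length(lab), 32)
  expect_false(anyNA(lab))
  expect_setequal(unique(lab), chromatin_states())
  expect_equal(length(unique(lab)), 7)

  # closure switch: single active evidence plus H3K27me3 demotes to ambiguous
  expect_equal(
    classify_state(TRUE, FALSE, FALSE, FALSE, TRUE, bivalent_closure = FALSE),
    "ambiguous"
  )
  expect_equal(
    classify_state(TRUE, FALSE, FALSE, FALSE, TRUE, bivalent_closure = TRUE),
    "bivalent"
  )
  # definition-(d) combinations are bivalent under both conventions
  expect_equal(
    classify_state(TRUE, TRUE, FALSE, TRUE, TRUE, bivalent_closure = FALSE),
    "bivalent"
  )
})

test_that("trajectories cluster genes by their ordered state triple", {
  states <- tidyr::expand_grid(gene_id = c("g1", "g2", "g3"), stage = c("s1", "s2", "s3")) %>%
    dplyr::mutate(state = "active", combination = "11010")
  tr <- state_trajectories(states, stages = c("s1", "s2", "s3"))
  expect_equal(nrow(cluster_census(tr)), 1)
  expect_equal(cluster_census(tr)$n_genes, 3)
  expect_equal(unique(tr$cluster), "active>active>active")

  expect_error(
    state_trajectories(states[states$stage != "s2", ], stages = c("s1", "s2", "s3")),
    "three stages"
  )
})

test_that("a noiseless simulation recovers exactly the planted transition clusters", {
  cfg <- simulation_config(
    n_genes = 250, state_emission = 1, seed = 6,
    background_decoy_rate = 0, promoter_decoy_rate = 0
  )
  st <- simulate_study(cfg)
  tracks <- zscore_scale(quantile_normalize(st$tracks))
  marks <- call_presence(st$peaks, tracks, st$tss, seed = 10)
  states <- state_calls(marks)
  tr <- state_trajectories(states, stages = cfg$stages)

  gold <- st$gold$genes
  planted <- unique(paste(gold$state_stage1, gold$state_stage2, gold$state_stage3, sep = ">"))
  expect_setequal(cluster_census(tr)$cluster, planted)

  # planted early-activation genes follow the bivalent -> active -> active path
  gi <- gold$gene_id[gold$pathway == "i"]
  expect_true(all(tr$cluster[tr$gene_id %in% gi] == "bivalent>active>active"))

  # per promoter-stage state calls equal the planted truth everywhere
  truth <- tidyr::pivot_longer(
    gold[, c("gene_id", "state_stage1", "state_stage2", "state_stage3")],
    -gene_id,
    names_to = "k", values_to = "true_state"
  )
  truth$stage <- cfg$stages[as.integer(sub("state_stage", "", truth$k))]
  cmp <- dplyr::inner_join(states, truth[, c("gene_id", "stage", "true_state")],
    by = c("gene_id", "stage")
  )
  expect_equal(mean(cmp$state == cmp$true_state), 1)
})

test_that("median profiles equal the brute-force per-bin median", {
  withr::with_seed(12, {
    n_bins <- 400
    sc <- matrix(rnorm(2 * n_bins), ncol = 2)
    tr <- make_tracks(sc, c("X", "X"), c("a", "b"))
    tr$meta$status <- "z"
    tss <- tibble::tibble(
      gene_id = sprintf("g%02d", 1:10), chrom = "chr1",
      tss = seq(5000L, 32000L, by = 3000L),
      strand = rep(c("+", "-"), 5)
    )
    prof <- median_profile(tr, tss, tss$gene_id, flank = 1500)
    expect_equal(nrow(prof), 2 * 31)

    # brute force for one track and one relative bin
    rel <- -15:15
    for (rb in c(-15, 0, 7)) {
      vals <- vapply(seq_len(10), function(i) {
        i0 <- tss$tss[i] %/% 100 + 1
        idx <- if (tss$strand[i] == "-") i0 - rb else i0 + rb
        sc[idx, 1]
      }, numeric(1))
      got <- prof$median_z[prof$stage == "a" & prof$rel_pos == rb * 100]
      expect_equal(got, median(vals))
    }

    # single-gene cluster: the profile is that gene's own signal
    p1 <- median_profile(tr, tss, "g01", flank = 500)
    i0 <- tss$tss[1] %/% 100 + 1
    expect_equal(p1$median_z[p1$stage == "a"], sc[(i0 - 5):(i0 + 5), 1])

    # the median is unchanged by adding an extreme opposite-sign outlier pair
    base <- median_profile(tr, tss, c("g01", "g03", "g05"), flank = 500)
    tr_out <- tr
    i2 <- tss$tss[2] %/% 100 + 1
    i4 <- tss$tss[4] %/% 100 + 1
    tr_out$scores[(i2 - 6):(i2 + 6), ] <- 1000
    tr_out$scores[(i4 - 6):(i4 + 6), ] <- -1000
    more <- median_profile(tr_out, tss, c("g01", "g03", "g05", "g02", "g04"), flank = 500)
    expect_equal(more$median_z, base$median_z)
  })
  tr <- make_tracks(matrix(1:10, ncol = 1), "X", "a")
  expect_error(median_profile(tr, tibble::tibble(), character(0)), "empty cluster")
})
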