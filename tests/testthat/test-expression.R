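test_that("welch_t reproduces the closed-form unequal-variance test", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.021312, tolerance = 1e-4)

  # dual route against stats::t.test on random inputs, including unequal n
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- rnorm(sample(2:6, 1), sd = runif(1, 0.5, 2))
      y <- rnorm(sample(2:6, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
      ref <- t.test(x, y)
      got <- welch_t(x, y)
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("welch_t symmetries and degenerate conventions hold", {
  x <- c(1.2, 3.1, 0.4)
  y <- c(2.2, 0.9, 4.4, 1.1)
  a <- welch_t(x, y)
  b <- welch_t(y, x)
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p_value, b$p_value)

  sc <- welch_t(3.7 * x, 3.7 * y)
  expect_equal(sc$statistic, a$statistic, tolerance = 1e-12)
  expect_equal(sc$df, a$df, tolerance = 1e-12)

  same <- welch_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  flat <- welch_t(c(2, 2), c(2, 2))
  expect_equal(flat$p_value, 1)
  expect_equal(flat$statistic, 0)
  sep <- welch_t(c(2, 2), c(5, 5))
  expect_equal(sep$p_value, 0)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("welch_t agrees with a permutation test within Monte-Carlo error", {
  withr::with_seed(5, {
    for (i in 1:3) {
      x <- rnorm(4)
      y <- rnorm(4, mean = 1)
      obs <- abs(welch_t(x, y)$statistic)
      pool <- c(x, y)
      perm <- replicate(4000, {
        idx <- sample(8, 4)
        abs(welch_t(pool[idx], pool[-idx])$statistic)
      })
      p_perm <- mean(perm >= obs - 1e-12)
      p_welch <- welch_t(x, y)$p_value
      expect_lt(abs(p_perm - p_welch), 0.08)
    }
  })
})

test_that("call_degs applies the fold and significance gates jointly", {
  # three crafted genes: fold gate + significant; fold gate failed; p gate failed
  expr <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    s1_r1 = c(100, 100, 100), s1_r2 = c(100.8, 100.8, 30),
    s2_r1 = c(250, 150, 25.2), s2_r2 = c(251, 150.9, 24.8),
    s3_r1 = c(100, 100, 100), s3_r2 = c(100.4, 100.6, 31)
  )
  design <- tibble::tibble(
    sample = c("s1_r1", "s1_r2", "s2_r1", "s2_r2", "s3_r1", "s3_r2"),
    stage = factor(rep(c("s1", "s2", "s3"), each = 2), levels = c("s1", "s2", "s3")),
    replicate = rep(1:2, 3)
  )
  degs <- call_degs(expr, design)
  expect_equal(degs$call_step1, c("up", "ns", "ns"))
  expect_gt(degs$ratio_step1[1], 2)
  expect_lt(degs$p_step1[1], 0.05)
  expect_lt(degs$ratio_step1[2], 2) # 1.5-fold: significant but below the gate
  expect_lt(degs$p_step1[2], 0.05)
  expect_lt(degs$ratio_step1[3], 0.5) # strong fold but not significant
  expect_gt(degs$p_step1[3], 0.05)

  # the call column is exactly the conjunction of the two gates
  p <- attr(degs, "params")
  up <- degs$ratio_step1 > p$fc_up & degs$p_step1 < p$alpha
  dn <- degs$ratio_step1 < p$fc_down & degs$p_step1 < p$alpha
  expect_equal(degs$call_step1, ifelse(up, "up", ifelse(dn, "down", "ns")))

  expect_error(call_degs(expr, design[design$stage != "s3", ]), "three stages")
  bad <- expr
  bad$s1_r1[1] <- 0
  expect_error(call_degs(bad, design), "positive")
})

test_that("the default pattern mapping collapses eight patterns to seven labels", {
  mapping <- default_pathway_mapping()
  expect_equal(nrow(mapping), 8)
  expect_equal(sort(unique(mapping$pathway)), c("i", "ii", "iii", "iv", "v", "vi", "vii"))
  # the two discordant reversals share one label
  rev1 <- mapping$pathway[mapping$call_step1 == "up" & mapping$call_step2 == "down"]
  rev2 <- mapping$pathway[mapping$call_step1 == "down" & mapping$call_step2 == "up"]
  expect_equal(rev1, "ii")
  expect_equal(rev2, "ii")

  calls <- expand.grid(
    call_step1 = c("up", "down", "ns"), call_step2 = c("up", "down", "ns"),
    stringsAsFactors = FALSE
  )
  fake <- tibble::tibble(
    gene_id = sprintf("g%d", 1:9),
    ratio_step1 = 1, p_step1 = 1, call_step1 = calls$call_step1,
    ratio_step2 = 1, p_step2 = 1, call_step2 = calls$call_step2
  )
  fake <- structure(fake, class = c("deg_table", class(tibble::tibble())))
  lab <- assign_pathways(fake)
  expect_equal(lab$pathway[lab$call_step1 == "ns" & lab$call_step2 == "ns"], "none")
  expect_equal(sort(unique(lab$pathway[lab$pathway != "none"])), sort(unique(mapping$pathway)))

  expect_error(assign_pathways(fake, mapping[-1, ]), "does not cover")
})

test_that("pathway_summary satisfies inclusion-exclusion and flags empty DEG sets", {
  withr::with_seed(3, {
    for (i in 1:5) {
      calls <- sample(c("up", "down", "ns"), 40, replace = TRUE)
      calls2 <- sample(c("up", "down", "ns"), 40, replace = TRUE)
      fake <- structure(
        tibble::tibble(
          gene_id = sprintf("g%d", 1:40),
          call_step1 = calls, call_step2 = calls2
        ),
        class = c("deg_table", class(tibble::tibble()))
      )
      s <- pathway_summary(fake)
      if (s$n_degs > 0) {
        expect_equal(s$frac_step1 + s$frac_step2 - s$frac_both, 1)
      }
    }
  })
  only1 <- structure(
    tibble::tibble(gene_id = "g", call_step1 = "up", call_step2 = "ns"),
    class = c("deg_table", class(tibble::tibble()))
  )
  expect_equal(pathway_summary(only1)$frac_step1, 1)
  expect_equal(pathway_summary(only1)$frac_both, 0)

  none <- structure(
    tibble::tibble(gene_id = "g", call_step1 = "ns", call_step2 = "ns"),
    class = c("deg_table", class(tibble::tibble()))
  )
  expect_warning(s0 <- pathway_summary(none), "no DEGs")
  expect_true(is.na(s0$frac_step1))
})

test_that("planted step fractions are recovered under a well-powered design", {
  cfg <- simulation_config(
    n_genes = 1500, n_replicates = 4, noise_sd = 0.1, effect_size = 2,
    pathway_proportions = c(
      i = 0.10, iii = 0.10, vi = 0.08, vii = 0.08, iv = 0.02, v = 0.01, ii = 0.01
    ),
    seed = 21
  )
  sim <- simulate_expression(cfg)
  degs <- call_degs(sim$expression, sim$design) %>% assign_pathways()
  s <- pathway_summary(degs)
  # planted: 60% of DEGs change at step 1, 50% at step 2, 10% at both
  expect_lt(abs(s$frac_step1 - 0.6), 0.06)
  expect_lt(abs(s$frac_step2 - 0.5), 0.06)
  expect_lt(abs(s$frac_both - 0.1), 0.05)
})

test_that("null simulations respect the nominal error rates", {
  cfg <- simulation_config(n_genes = 1500, effect_size = 0, seed = 8)
  sim <- simulate_expression(cfg)
  degs <- call_degs(sim$expression, sim$design)

  # significance gate alone: type-I error within 3 SE of alpha
  se <- sqrt(0.05 * 0.95 / 1500)
  expect_lt(mean(degs$p_step1 < 0.05), 0.05 + 3 * se)
  # with the fold gate the empirical false-call rate collapses to ~0
  expect_lt(mean(degs$call_step1 != "ns"), 0.005)
  expect_lt(mean(degs$call_step2 != "ns"), 0.005)

  # non-DEG marginal log2 ratio is centred on zero
  lr <- log2(degs$ratio_step1)
  expect_lt(abs(mean(lr)), 3 * sd(lr) / sqrt(length(lr)))
})
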