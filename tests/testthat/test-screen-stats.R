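test_that("guide log fold change matches hand arithmetic", {
  m <- cbind(t1 = c(20, 0, 10), ctrl_a = c(10, 10, 10),
             ctrl_b = c(10, 10, 10))
  rownames(m) <- paste0("g", 1:3)
  lfc <- guide_log_fold_change(m, "t1", c("ctrl_a", "ctrl_b"))
  expect_equal(unname(lfc),
               c(log2(21 / 11), log2(1 / 11), 0), tolerance = 1e-12)
  expect_equal(unname(lfc[1]), 0.9328858, tolerance = 1e-6)
  expect_equal(unname(lfc[2]), -3.4594316, tolerance = 1e-6)

  expect_error(guide_log_fold_change(m, "t1", "t1"), "overlap")
  expect_error(guide_log_fold_change(m, "t1", character(0)), "empty")
  expect_error(guide_log_fold_change(m, "t1", "nope"), "not in matrix")
})

test_that("z-scoring uses the population SD and is affine-invariant", {
  z <- zscore_guides(c(a = -1, b = 0, c = 1))
  expect_equal(unname(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(z[3]), 1.224745, tolerance = 1e-6)

  set.seed(5)
  lfc <- rnorm(20)
  expect_equal(zscore_guides(lfc + 3.7), zscore_guides(lfc))
  expect_equal(zscore_guides(lfc * 5), zscore_guides(lfc))
  expect_error(zscore_guides(rep(2, 10)), "zero SD")
  expect_error(zscore_guides(c(1)), ">= 2")
})

test_that("gene viability score is the median over guides, then replicates", {
  lib <- guide_library(
    paste0("g", 1:3), drebic:::.unique_dna(3, 20), rep("X", 3), rep(FALSE, 3)
  )
  z1 <- matrix(c(-1.2, -0.5, -2.0), 3, 1, dimnames = list(paste0("g", 1:3), "r1"))
  expect_equal(gene_viability_score(z1, lib)$score, -1.2)

  # median across replicate comparisons of the per-replicate gene medians
  z3 <- matrix(c(-1, -1, -1, -2, -2, -2, -3, -3, -3), 3, 3,
               dimnames = list(paste0("g", 1:3), paste0("r", 1:3)))
  expect_equal(gene_viability_score(z3, lib)$score, -2)

  # constant z propagates unchanged
  zc <- matrix(0.7, 3, 2, dimnames = list(paste0("g", 1:3), c("r1", "r2")))
  expect_equal(gene_viability_score(zc, lib)$score, 0.7)

  expect_error(gene_viability_score(z1, lib, genes = "NOPE"),
               "absent from library")
})

test_that("viability scores are invariant to per-sample count rescaling", {
  scr <- simulate_screen(n_genes = 30, guides_per_gene = 4,
                         n_control_guides = 10, depth = 200,
                         arm = "in_vitro", seed = 9)
  tab1 <- score_screen(normalize_counts(scr$counts)$counts,
                       scr$library, scr$design, arm = "in_vitro")
  scaled <- scr$counts
  scaled[, "treatment_2"] <- scaled[, "treatment_2"] * 5
  tab2 <- score_screen(normalize_counts(scaled)$counts,
                       scr$library, scr$design, arm = "in_vitro")
  # size factors absorb the rescaling up to a global scalar; the LFC
  # pseudocount leaves a small residual, so equality is approximate
  expect_equal(tab2$score, tab1$score, tolerance = 0.02)
  expect_gt(cor(tab1$score, tab2$score, method = "spearman"), 0.999)
})

test_that("KS test matches closed forms and the enumeration oracle", {
  id <- gene_ks_test(c(0, 1), c(0, 1))
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)

  sep <- gene_ks_test(c(1, 2), c(3, 4))
  expect_equal(sep$statistic, 1)
  expect_equal(sep$p_value, 1 / 3, tolerance = 1e-12)

  # exact enumeration oracle over tie-free random instances with n + m <= 8
  set.seed(11)
  for (i in 1:20) {
    n <- sample(2:4, 1); m <- sample(2:4, 1)
    x <- round(rnorm(n), 6); y <- round(rnorm(m, 0.5), 6)
    got <- gene_ks_test(x, y)
    expect_equal(got$statistic, ks_stat_oracle(x, y), tolerance = 1e-12)
    expect_equal(got$p_value, ks_exact_p_oracle(x, y), tolerance = 1e-10)
  }

  # asymptotic p stays near the exact enumeration value at n = m = 10
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10, 0.3)
  p_asym <- suppressWarnings(
    stats::ks.test(x, y, exact = FALSE)$p.value
  )
  p_exact <- stats::ks.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(p_asym - p_exact), 0.05)

  # "less" flags depletion: gene z far below controls
  dep <- gene_ks_test(c(-3, -2.5, -2), c(0, 0.5, 1, 1.5),
                      alternative = "less")
  enr <- gene_ks_test(c(-3, -2.5, -2), c(0, 0.5, 1, 1.5),
                      alternative = "greater")
  expect_lt(dep$p_value, 0.1)
  expect_gt(enr$p_value, 0.5)

  expect_error(gene_ks_test(c(1, 2), numeric(0)), "control")
})

test_that("guides classify against the control interquartile range", {
  ctrl <- c(-0.4, -0.2, 0.2, 0.4)  # Q1 = -0.25, Q3 = 0.25 (type 7)
  expect_equal(
    unname(classify_guides_vs_controls(c(-0.5, 0, 0.3), ctrl)),
    c("depleted", "unchanged", "enriched")
  )
  # boundary values are 'unchanged' (strict inequalities)
  q <- quantile(ctrl, c(.25, .75), names = FALSE)
  expect_equal(unname(classify_guides_vs_controls(q, ctrl)),
               c("unchanged", "unchanged"))
  expect_error(classify_guides_vs_controls(0, c(1, 2, 3)), ">= 4 control")
})

test_that("consistent hits require agreement in every replicate and rank by evidence", {
  lib <- guide_library(
    paste0("g", 1:6), drebic:::.unique_dna(6, 20),
    rep(c("A", "B"), each = 3), rep(FALSE, 6)
  )
  gid <- paste0("g", 1:6)
  classes <- matrix("unchanged", 6, 3, dimnames = list(gid, NULL))
  classes[c("g1", "g2", "g3"), ] <- "depleted"          # A: 3 true guides
  classes[c("g4", "g5"), ] <- "depleted"                # B: 2 true guides
  classes["g6", ] <- c("depleted", "depleted", "unchanged")  # not true
  lfc <- matrix(-1, 6, 3, dimnames = list(gid, NULL))
  lfc[c("g1", "g2", "g3"), ] <- -2

  hits <- consistent_hit_genes(classes, lfc, lib)
  expect_equal(hits$gene, c("A", "B"))
  expect_equal(hits$hit_class, c("depleted", "depleted"))
  expect_equal(hits$n_true_guides, c(3L, 2L))
  expect_equal(hits$median_hit_lfc, c(-2, -1))

  # 2/3 replicates is not consistent
  expect_false("g6" %in% rownames(classes)[classes[, 3] == "depleted"])

  # equal true-guide counts: |median LFC| breaks the tie
  classes2 <- classes
  classes2[c("g4", "g5", "g6"), ] <- "depleted"
  lfc2 <- lfc; lfc2[c("g4", "g5", "g6"), ] <- -5
  hits2 <- consistent_hit_genes(classes2, lfc2, lib)
  expect_equal(hits2$gene, c("B", "A"))
})

test_that("median gene score resists a single corrupted guide", {
  lib <- guide_library(paste0("g", 1:5), drebic:::.unique_dna(5, 20),
                       rep("X", 5), rep(FALSE, 5))
  z <- matrix(c(-1.0, -1.1, -0.9, -1.2, -0.8), 5, 1,
              dimnames = list(paste0("g", 1:5), "r1"))
  clean <- gene_viability_score(z, lib)$score
  z["g3", 1] <- 50  # wildly corrupted guide
  corrupt <- gene_viability_score(z, lib)$score
  # median moves only to a neighboring order statistic
  expect_lt(abs(corrupt - clean), 0.25)
})
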