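test_that("responder stratification labels the IC50 quartiles", {
  set.seed(41)
  x <- setNames(sample(rnorm(500)), paste0("s", 1:500))
  lab <- stratify_responders(x)
  expect_equal(sum(lab == "responder"), 125)
  expect_equal(sum(lab == "non_responder"), 125)
  expect_equal(sum(lab == "ambiguous"), 250)
  # responders hold the lowest IC50s
  expect_lt(max(x[lab == "responder"]), min(x[lab == "ambiguous"]))

  lab4 <- stratify_responders(setNames(1:4, letters[1:4]))
  expect_equal(unname(lab4), c("responder", "ambiguous", "ambiguous",
                               "non_responder"))
  expect_error(stratify_responders(rep(1, 10)), "degenerate")
  expect_error(stratify_responders(c(1, 2, 3)), ">= 4")
})

test_that("roc_auc equals the pair-counting oracle, pROC, and its symmetries", {
  lab <- c(r1 = "responder", r2 = "responder",
           n1 = "non_responder", n2 = "non_responder")
  expect_equal(roc_auc(c(r1 = .9, r2 = .8, n1 = .7, n2 = .6), lab)$auc, 1)
  expect_equal(roc_auc(c(r1 = .9, r2 = .7, n1 = .8, n2 = .6), lab)$auc, 0.75)

  set.seed(42)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    sc <- setNames(sample(round(rnorm(n), 1)), paste0("s", 1:n))  # with ties
    labs <- setNames(sample(c("responder", "non_responder"), n,
                            replace = TRUE), names(sc))
    if (length(unique(labs)) < 2) next
    r <- roc_auc(sc, labs)
    expect_equal(r$auc, auc_pair_oracle(sc, labs == "responder"),
                 tolerance = 1e-12)
    # flipping labels mirrors the AUC
    flipped <- setNames(ifelse(labs == "responder", "non_responder",
                               "responder"), names(labs))
    expect_equal(roc_auc(sc, flipped)$auc, 1 - r$auc, tolerance = 1e-12)
    # curve is a staircase from (0,0) to (1,1)
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    # independent implementation agrees
    pr <- suppressMessages(pROC::auc(pROC::roc(
      response = labs == "responder", predictor = sc, quiet = TRUE,
      direction = "<")))
    expect_equal(r$auc, as.numeric(pr), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(a = 1), c(a = "responder")), "non-responder")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(43)
  sc <- setNames(rnorm(40), paste0("s", 1:40))
  labs <- setNames(rep(c("responder", "non_responder"), 20), names(sc))
  a0 <- roc_auc(sc, labs)$auc
  expect_equal(roc_auc(rescale_scores(sc), labs)$auc, a0)
  expect_equal(roc_auc(exp(sc), labs)$auc, a0)
  expect_equal(roc_auc(sc * 100 - 7, labs)$auc, a0)
})

test_that("model-size optimization reports the full grid and finds a planted size", {
  scr <- simulate_screen(n_genes = 300, guides_per_gene = 5,
                         n_control_guides = 30, arm = "in_vitro", seed = 51)
  tab <- score_screen(normalize_counts(scr$counts)$counts,
                      scr$library, scr$design, arm = "in_vitro")
  cohort <- simulate_expression_response(tab, n_samples = 400,
                                         n_causal_depleted = 50,
                                         n_causal_enriched = 0,
                                         noise_sd = 0.25, seed = 52)
  cen <- center_log_expression(cohort$expression, epsilon = 0)
  lab <- stratify_responders(setNames(cohort$response$log_ic50,
                                      cohort$response$sample_id))
  grid <- c(10, 30, 50, 70, 100, 150)
  opt <- optimize_model_size(tab, cen, lab, grid = grid)
  expect_equal(opt$curve_depleted$size, grid)
  expect_equal(opt$curve_enriched$size, grid)
  expect_false(anyNA(opt$curve_depleted$auc))
  # depleted-part optimum within one grid step of the planted causal size
  expect_true(opt$n_depleted %in% c(30, 50, 70))

  # single-point grid returns that size for both parts
  one <- optimize_model_size(tab, cen, lab, grid = 25)
  expect_equal(c(one$n_depleted, one$n_enriched), c(25, 25))
})

test_that("permutation null is seed-deterministic with a fractional p-value", {
  set.seed(61)
  genes <- sprintf("g%03d", 1:200)
  sc <- data.frame(gene = genes, score = rnorm(200))
  G <- matrix(rnorm(200 * 60), 200, 60,
              dimnames = list(genes, paste0("s", 1:60)))
  lab <- setNames(rep(c("responder", "non_responder"), 30), colnames(G))

  p1 <- permutation_null(sc, G, lab, n_depleted = 20, n_enriched = 30,
                         reps = 100, seed = 7)
  p2 <- permutation_null(sc, G, lab, n_depleted = 20, n_enriched = 30,
                         reps = 100, seed = 7)
  expect_identical(p1$auc_samples, p2$auc_samples)
  p3 <- permutation_null(sc, G, lab, n_depleted = 20, n_enriched = 30,
                         reps = 100, seed = 8)
  expect_false(identical(p1$auc_samples, p3$auc_samples))

  # p is the fraction of permutation AUCs at least as large as observed
  obs <- sort(p1$auc_samples, decreasing = TRUE)[3]
  pv <- permutation_null(sc, G, lab, n_depleted = 20, n_enriched = 30,
                         reps = 100, seed = 7, observed_auc = obs)$p_value
  expect_equal(pv, 0.03)

  # labels independent of expression: mean AUC near 1/2. The replicate
  # AUCs share one cohort, so the mean converges to the cohort-conditional
  # chance level, which itself varies O(1/sqrt(n_samples)) around 1/2.
  G2 <- matrix(rnorm(200 * 400), 200, 400,
               dimnames = list(genes, paste0("s", 1:400)))
  lab2 <- setNames(rep(c("responder", "non_responder"), 200), colnames(G2))
  pn <- permutation_null(sc, G2, lab2, n_depleted = 20, n_enriched = 30,
                         reps = 200, seed = 9)
  expect_lt(abs(pn$mean_auc - 0.5), 0.02 + 3 * pn$sd_auc / sqrt(pn$n_reps))
  expect_error(permutation_null(sc, G, lab, reps = 0, seed = 1), "reps")
  expect_error(permutation_null(sc, G, lab, n_depleted = 150,
                                n_enriched = 100, seed = 1, reps = 2),
               "smaller than")
})

test_that("ROC averaging takes per-x maxima with population SD", {
  lab <- setNames(rep(c("responder", "non_responder"), 5), paste0("s", 1:10))
  set.seed(62)
  c1 <- roc_auc(setNames(rnorm(10), names(lab)), lab)
  # a single curve averages to itself with zero SD
  av1 <- average_roc(list(c1))
  expect_equal(max(av1$sd_tpr), 0)
  y_at <- function(cv, x) max(cv$tpr[cv$fpr <= x])
  expect_equal(av1$mean_tpr, vapply(av1$fpr, function(x) y_at(c1, x),
                                    numeric(1)))

  # hand-sized example: upper values 0.6 and 0.8 at x = 0.5
  cva <- structure(list(fpr = c(0, 0.5, 1), tpr = c(0, 0.6, 1),
                        thresholds = c(Inf, 1, 0), auc = NA),
                   class = "roc_result")
  cvb <- structure(list(fpr = c(0, 0.5, 1), tpr = c(0, 0.8, 1),
                        thresholds = c(Inf, 1, 0), auc = NA),
                   class = "roc_result")
  av <- average_roc(list(cva, cvb))
  i <- which(av$fpr == 0.5)
  expect_equal(av$mean_tpr[i], 0.7)
  expect_equal(av$sd_tpr[i], 0.1)

  # identical tie-free curves keep their AUC
  sc <- setNames(sample(seq(0.01, 1, length = 10)), names(lab))
  cv <- roc_auc(sc, lab)
  expect_equal(average_roc(list(cv, cv, cv))$auc, cv$auc, tolerance = 1e-12)
  expect_error(average_roc(list()), "empty")
})

test_that("tissues rank by ascending median score", {
  scores <- setNames(c(0.2, 0.2, -0.4, -0.4, 0.1), paste0("s", 1:5))
  resp <- data.frame(sample_id = paste0("s", 1:5), drug = "d",
                     log_ic50 = c(1, 2, 3, 4, 5),
                     tissue = c("skin", "skin", "heme", "heme", "skin"))
  tr <- tissue_rank(scores, resp)
  expect_equal(tr$tissue, c("heme", "skin"))
  expect_equal(tr$median_score, c(-0.4, 0.2))
  expect_equal(tr$n, c(2L, 3L))
  # a constant shift moves medians, not the order
  tr2 <- tissue_rank(scores + 10, resp)
  expect_equal(tr2$tissue, tr$tissue)
  expect_equal(tr2$median_score, tr$median_score + 10)
})

test_that("score-IC50 correlation matches the covariance formula", {
  s <- setNames(c(1, 2, 3), letters[1:3])
  expect_equal(score_ic50_correlation(s, setNames(c(2, 4, 6), letters[1:3]))$r, 1)
  expect_equal(score_ic50_correlation(s, -s)$r, -1)
  set.seed(63)
  x <- setNames(rnorm(5), letters[1:5]); y <- setNames(rnorm(5), letters[1:5])
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(score_ic50_correlation(x, y)$r, r_direct, tolerance = 1e-12)
  expect_error(score_ic50_correlation(s, setNames(rep(1, 3), letters[1:3])),
               "zero variance")
})
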