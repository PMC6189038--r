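#' Stratify samples into responders and non-responders by IC50 quartiles
#'
#' For one drug, samples in the lowest quartile of log IC50 (most growth
#' inhibition at low dose) are labeled `responder`, the highest quartile
#' `non_responder`, and the middle half `ambiguous`. Quartiles use linear
#' interpolation (R type 7); values tied exactly with a quartile boundary
#' are included on the labeled side. With ~500 distinct-valued cell lines
#' this yields ~125 samples per labeled class.
#'
#' @param log_ic50 named numeric vector of log IC50 values (>= 4 finite).
#' @return named character vector in
#'   `{"responder", "ambiguous", "non_responder"}`.
#' @export
stratify_responders <- function(log_ic50) {
  x <- log_ic50[is.finite(log_ic50)]
  if (length(x) < 4L) stop("need >= 4 finite log IC50 values", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  if (q[1] >= q[2]) {
    stop("degenerate IC50 distribution: quartiles coincide", call. = FALSE)
  }
  lab <- rep("ambiguous", length(x))
  lab[x <= q[1]] <- "responder"
  lab[x >= q[2]] <- "non_responder"
  names(lab) <- names(x)
  lab
}

#' ROC curve and AUC of scores against responder labels
#'
#' Responders are the positive class; ambiguous samples are excluded. The
#' AUC is computed by the Mann-Whitney pairwise-concordance identity (ties
#' count 1/2): the probability that a random responder outscores a random
#' non-responder. The curve is the threshold-sweep staircase from (0,0) to
#' (1,1).
#'
#' @param scores named numeric score vector (higher = predicted more
#'   sensitive).
#' @param labels named label vector from [stratify_responders()] (or any
#'   vector using the same level names).
#' @return object of class `roc_result`: list with `fpr`, `tpr`,
#'   `thresholds` and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  common <- intersect(names(scores), names(labels))
  if (length(common)) {
    scores <- scores[common]
    labels <- labels[common]
  }
  keep <- labels %in% c("responder", "non_responder") & is.finite(scores)
  scores <- scores[keep]
  pos <- labels[keep] == "responder"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("need >= 1 responder and >= 1 non-responder", call. = FALSE)
  }
  r <- rank(scores)  # midranks handle ties with the 1/2 convention
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied thresholds so the curve moves diagonally through ties
  last_of_run <- c(diff(s) != 0, TRUE)
  tp <- cumsum(p)[last_of_run]
  fp <- cumsum(!p)[last_of_run]
  structure(list(fpr = unname(c(0, fp / n0)), tpr = unname(c(0, tp / n1)),
                 thresholds = unname(c(Inf, s[last_of_run])),
                 auc = unname(auc)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC curve (", length(x$fpr), " points), AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

# fast internal AUC used in hot loops (scores numeric, pos logical)
.auc <- function(scores, pos) {
  n1 <- sum(pos); n0 <- length(pos) - n1
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimize DREBIC model size by grid search
#'
#' The depleted and enriched parts of the model are optimized separately:
#' stage 1 evaluates depleted-only models of every size in `grid` and picks
#' the AUC argmax; stage 2 does the same for enriched-only models. Ties go
#' to the smaller size. The screen this package emulates used a grid
#' spanning 5 to 600 genes and found 175 depleted / 225 enriched optimal.
#'
#' @param scores gene viability score data.frame (`gene`, `score`).
#' @param centered centered expression matrix covering the cohort.
#' @param labels responder labels from [stratify_responders()].
#' @param grid integer vector of candidate set sizes.
#' @param convention passed to [score_samples()].
#' @return list with `n_depleted`, `n_enriched`, and data.frames
#'   `curve_depleted`, `curve_enriched` (columns `size`, `auc`, one row per
#'   grid point).
#' @export
optimize_model_size <- function(scores, centered, labels,
                                grid = c(5, 10, 25, 50, 100, 175, 225,
                                         300, 450, 600),
                                convention = "signed_sum") {
  grid <- sort(unique(as.integer(grid)))
  if (any(grid < 1) || max(grid) > nrow(scores)) {
    stop("grid sizes must be in [1, number of scored genes]", call. = FALSE)
  }
  stage <- function(side) {
    auc <- vapply(grid, function(k) {
      m <- if (side == "depleted") {
        suppressWarnings(build_drebic_model(scores, n_depleted = k,
                                            n_enriched = 0))
      } else {
        suppressWarnings(build_drebic_model(scores, n_depleted = 0,
                                            n_enriched = k))
      }
      roc_auc(score_samples(m, centered, convention = convention), labels)$auc
    }, numeric(1))
    data.frame(size = grid, auc = auc)
  }
  cd <- stage("depleted")
  ce <- stage("enriched")
  list(n_depleted = cd$size[which.max(cd$auc)],
       n_enriched = ce$size[which.max(ce$auc)],
       curve_depleted = cd, curve_enriched = ce)
}

#' Permutation null distribution of DREBIC AUC
#'
#' Repeatedly draws two disjoint random gene sets of sizes `n_depleted` and
#' `n_enriched` from the scored gene universe (without replacement), builds
#' a DREBIC model carrying those genes' actual viability scores, scores the
#' cohort, and records the AUC against the given labels. The p-value is the
#' fraction of permutation AUCs at least as extreme as `observed_auc`
#' (right-tailed by default; `tail = "two_sided"` uses the absolute
#' deviation from 0.5). When labels are independent of expression, the mean
#' permutation AUC is 0.5.
#'
#' @param scores gene viability score data.frame (`gene`, `score`).
#' @param centered centered expression matrix.
#' @param labels responder labels.
#' @param n_depleted,n_enriched random set sizes (defaults 175 / 225).
#' @param reps number of permutations (default 10000).
#' @param seed mandatory RNG seed for reproducibility.
#' @param observed_auc AUC of the real model, or `NULL` to skip the p-value.
#' @param tail `"right"` (default, higher AUC is more extreme) or
#'   `"two_sided"`.
#' @param convention passed to [score_samples()].
#' @return list with `auc_samples`, `mean_auc`, `sd_auc`, `p_value`
#'   (`NA` without `observed_auc`) and `n_reps`.
#' @export
permutation_null <- function(scores, centered, labels,
                             n_depleted = 175, n_enriched = 225,
                             reps = 10000, seed,
                             observed_auc = NULL,
                             tail = c("right", "two_sided"),
                             convention = c("signed_sum", "printed_eq1")) {
  tail <- match.arg(tail)
  convention <- match.arg(convention)
  .assert_number(reps, "reps", min = 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n_depleted + n_enriched > nrow(scores)) {
    stop("gene universe smaller than n_depleted + n_enriched", call. = FALSE)
  }
  centered <- as.matrix(centered)
  genes <- intersect(scores$gene, rownames(centered))
  if (length(genes) < n_depleted + n_enriched) {
    stop("too few scored genes present in the expression matrix",
         call. = FALSE)
  }
  C <- stats::setNames(scores$score, scores$gene)[genes]
  G <- centered[genes, , drop = FALSE]
  keep <- labels[colnames(G)] %in% c("responder", "non_responder")
  keep[is.na(keep)] <- FALSE
  Gk <- G[, keep, drop = FALSE]
  pos <- labels[colnames(Gk)] == "responder"
  enr_sign <- if (convention == "signed_sum") 1 else -1

  set.seed(seed)
  n_tot <- n_depleted + n_enriched
  auc_samples <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(length(genes), n_tot)
    dep <- idx[seq_len(n_depleted)]
    enr <- idx[seq_len(n_enriched) + n_depleted]
    raw <- as.vector(crossprod(Gk[dep, , drop = FALSE], C[dep])) +
      enr_sign * as.vector(crossprod(Gk[enr, , drop = FALSE], C[enr]))
    .auc(raw, pos)
  }, numeric(1))

  p <- NA_real_
  if (!is.null(observed_auc)) {
    p <- if (tail == "right") {
      mean(auc_samples >= observed_auc)
    } else {
      mean(abs(auc_samples - 0.5) >= abs(observed_auc - 0.5))
    }
  }
  list(auc_samples = auc_samples, mean_auc = mean(auc_samples),
       sd_auc = stats::sd(auc_samples), p_value = p, n_reps = as.integer(reps))
}

#' Average several ROC curves
#'
#' At each x (false-positive rate) on the union of all curves'
#' breakpoints, each curve contributes the maximal y it attains at that x
#' (the upper value of its staircase); the average curve is the mean of
#' those values and the spread is their population (n-denominator) standard
#' deviation.
#'
#' @param curves list of `roc_result` objects.
#' @return list with `fpr`, `mean_tpr`, `sd_tpr`, and `auc` (left-step
#'   integral of the mean curve).
#' @export
average_roc <- function(curves) {
  if (length(curves) == 0L) stop("empty curve list", call. = FALSE)
  xs <- sort(unique(c(0, 1, unlist(lapply(curves, `[[`, "fpr")))))
  ymat <- vapply(curves, function(cv) {
    vapply(xs, function(x) max(cv$tpr[cv$fpr <= x]), numeric(1))
  }, numeric(length(xs)))
  ymat <- matrix(ymat, nrow = length(xs))
  mean_tpr <- rowMeans(ymat)
  sd_tpr <- sqrt(rowMeans((ymat - mean_tpr)^2))
  auc <- sum(mean_tpr[-length(xs)] * diff(xs))
  list(fpr = xs, mean_tpr = mean_tpr, sd_tpr = sd_tpr, auc = auc)
}

#' Rank tissues by their median DREBIC score
#'
#' Summarizes the cohort per tissue of origin: sample count, median and
#' mean DREBIC score, and median log IC50; rows are ordered by ascending
#' median DREBIC score (least to most predicted-sensitive tissue).
#'
#' @param scores named per-sample score vector.
#' @param responses data.frame with columns `sample_id`, `log_ic50`,
#'   `tissue`.
#' @return data.frame with columns `tissue`, `n`, `median_score`,
#'   `mean_score`, `median_log_ic50`.
#' @export
tissue_rank <- function(scores, responses) {
  if (!all(c("sample_id", "log_ic50", "tissue") %in% names(responses))) {
    stop("responses needs sample_id, log_ic50, tissue columns", call. = FALSE)
  }
  resp <- responses[responses$sample_id %in% names(scores), , drop = FALSE]
  if (nrow(resp) == 0L) stop("no samples in common", call. = FALSE)
  sc <- scores[resp$sample_id]
  agg <- lapply(split(seq_len(nrow(resp)), resp$tissue), function(i) {
    data.frame(tissue = resp$tissue[i[1]], n = length(i),
               median_score = stats::median(sc[i]),
               mean_score = mean(sc[i]),
               median_log_ic50 = stats::median(resp$log_ic50[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$median_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between DREBIC scores and log IC50
#'
#' A working model shows an inverse correlation: higher predicted
#' sensitivity, lower IC50.
#'
#' @param scores named per-sample score vector.
#' @param log_ic50 named log IC50 vector.
#' @return list with `r` and `p_value` (two-sided t approximation).
#' @export
score_ic50_correlation <- function(scores, log_ic50) {
  common <- intersect(names(scores), names(log_ic50))
  x <- scores[common]; y <- log_ic50[common]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need >= 3 paired finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in scores or IC50", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Read or write a drug response table
#'
#' Tab-separated with columns `sample_id`, `drug`, `log_ic50` and optional
#' `tissue`; (sample, drug) pairs must be unique.
#'
#' @param path file path.
#' @export
read_drug_response <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("sample_id", "drug", "log_ic50") %in% names(df))) {
    stop("response table needs sample_id, drug, log_ic50", call. = FALSE)
  }
  if (anyDuplicated(df[c("sample_id", "drug")])) {
    stop("duplicate (sample_id, drug) rows", call. = FALSE)
  }
  df
}

#' @rdname read_drug_response
#' @param responses the response data.frame.
#' @export
write_drug_response <- function(responses, path) {
  .write_tsv(responses, path)
}
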