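#' Guide-level log2 fold change between screen conditions
#'
#' LFC of each guide's normalized abundance in the numerator sample(s)
#' relative to the mean of the denominator (control) samples, with a
#' pseudocount guarding against zeros:
#' `lfc = log2((mean_num + pseudocount) / (mean_den + pseudocount))`.
#' For the in vivo screen the denominator is the mean of the control tumor
#' replicates.
#'
#' @param norm normalized guide x sample matrix (see [normalize_counts()]).
#' @param numerator sample name(s) forming the numerator; their mean is used.
#' @param denominator sample name(s) forming the denominator mean.
#' @param pseudocount added to both means (default 1).
#' @return named numeric vector of log2 fold changes, one per guide.
#' @export
guide_log_fold_change <- function(norm, numerator, denominator,
                                  pseudocount = 1) {
  if (is.list(norm) && !is.null(norm$counts)) norm <- norm$counts
  norm <- as.matrix(norm)
  if (length(denominator) == 0L) {
    stop("denominator sample set is empty", call. = FALSE)
  }
  if (length(intersect(numerator, denominator))) {
    stop("numerator and denominator sample sets overlap", call. = FALSE)
  }
  missing_s <- setdiff(c(numerator, denominator), colnames(norm))
  if (length(missing_s)) {
    stop("sample(s) not in matrix: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  .assert_number(pseudocount, "pseudocount", min = 0)
  num <- rowMeans(norm[, numerator, drop = FALSE])
  den <- rowMeans(norm[, denominator, drop = FALSE])
  lfc <- log2((num + pseudocount) / (den + pseudocount))
  names(lfc) <- rownames(norm)
  lfc
}

#' Standardize guide LFCs within a comparison
#'
#' z = (lfc - mean) / SD, with mean and population SD (denominator n) taken
#' over all guides scored in the comparison.
#'
#' @param lfc named numeric vector of guide LFCs for one comparison.
#' @return named numeric vector of z-scores.
#' @examples
#' zscore_guides(c(a = -1, b = 0, c = 1))  # +-1.2247, 0
#' @export
zscore_guides <- function(lfc) {
  lfc <- lfc[is.finite(lfc)]
  n <- length(lfc)
  if (n < 2L) stop("need >= 2 finite LFCs to standardize", call. = FALSE)
  mu <- mean(lfc)
  sdev <- sqrt(sum((lfc - mu)^2) / n)
  if (sdev == 0) stop("zero SD: degenerate comparison", call. = FALSE)
  (lfc - mu) / sdev
}

#' Gene-level CRISPR viability score
#'
#' For each replicate comparison the gene value is the median of the
#' z-scores of its targeting guides; the final score is the median of those
#' per-comparison values across replicates. Negative scores mark genes whose
#' knockout depletes (sensitizes) cells under treatment, positive scores
#' mark resistance-conferring (enriched) knockouts. Control guides never
#' contribute to gene scores.
#'
#' @param z guide x comparison matrix of z-scores (or a single named vector
#'   for one comparison).
#' @param library a [guide_library()] mapping guides to genes.
#' @param genes optional subset of genes to score (default: all targeted
#'   genes in the library with z values).
#' @return data.frame with columns `gene`, `score`, `n_guides`.
#' @export
gene_viability_score <- function(z, library, genes = NULL) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1, dimnames = list(names(z), "c1"))
  targeting <- library[!library$is_control, , drop = FALSE]
  if (is.null(genes)) {
    genes <- unique(targeting$gene[targeting$guide_id %in% rownames(z)])
  } else {
    unknown <- setdiff(genes, targeting$gene)
    if (length(unknown)) {
      stop("gene(s) absent from library: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }
  guide_of <- split(targeting$guide_id, targeting$gene)
  score <- numeric(length(genes))
  n_guides <- integer(length(genes))
  for (i in seq_along(genes)) {
    gids <- intersect(guide_of[[genes[i]]], rownames(z))
    if (length(gids) == 0L) {
      score[i] <- NA_real_
      next
    }
    per_comp <- apply(z[gids, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    score[i] <- stats::median(per_comp, na.rm = TRUE)
    n_guides[i] <- length(gids)
  }
  data.frame(gene = genes, score = score, n_guides = n_guides,
             stringsAsFactors = FALSE)
}

#' Alternative gene score: log2 of the median abundance ratio
#'
#' Aggregation variant in which the per-gene median of raw abundance ratios
#' (numerator mean / denominator mean, with pseudocount) across guides and
#' replicates is taken first and log-transformed afterwards. Provided for
#' comparison with the default z-score-median pipeline; not used downstream.
#'
#' @inheritParams guide_log_fold_change
#' @param numerators list of numerator sample sets (one per replicate
#'   comparison).
#' @param library a [guide_library()].
#' @return data.frame with columns `gene`, `score`.
#' @export
gene_score_log_median_ratio <- function(norm, numerators, denominator,
                                        library, pseudocount = 1) {
  if (is.list(norm) && !is.null(norm$counts)) norm <- norm$counts
  den <- rowMeans(as.matrix(norm)[, denominator, drop = FALSE]) + pseudocount
  ratios <- sapply(numerators, function(nm) {
    (rowMeans(as.matrix(norm)[, nm, drop = FALSE]) + pseudocount) / den
  })
  targeting <- library[!library$is_control, , drop = FALSE]
  keep <- targeting$guide_id %in% rownames(norm)
  targeting <- targeting[keep, , drop = FALSE]
  ratios <- ratios[targeting$guide_id, , drop = FALSE]
  med <- sapply(split(seq_len(nrow(targeting)), targeting$gene),
                function(i) stats::median(as.vector(ratios[i, ])))
  data.frame(gene = names(med), score = log2(as.numeric(med)),
             stringsAsFactors = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test of a gene's guides against controls
#'
#' Compares the z-scores of guides targeting one gene with those of the
#' non-targeting control guides. `alternative = "less"` tests stochastic
#' depletion (the gene's z-scores tend to lie below the controls'),
#' `"greater"` tests enrichment. Exact p-values are used for small samples
#' without ties, the asymptotic formula otherwise.
#'
#' @param gene_z z-scores of the gene's guides (>= 2 values).
#' @param control_z z-scores of control guides (>= 2 values).
#' @param alternative `"two_sided"` (default), `"less"`, or `"greater"`.
#' @return list with `statistic` (D) and `p_value`.
#' @export
gene_ks_test <- function(gene_z, control_z,
                         alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(control_z) < 2L) stop("empty/degenerate control set", call. = FALSE)
  if (length(gene_z) < 2L) stop("need >= 2 gene guide values", call. = FALSE)
  # stats::ks.test's "greater" means the CDF of x lies above that of y,
  # i.e. x stochastically smaller -- which is our "less" (depletion)
  alt <- switch(alternative, two_sided = "two.sided",
                less = "greater", greater = "less")
  res <- suppressWarnings(stats::ks.test(gene_z, control_z, alternative = alt))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Classify a guide's LFC against the control interquartile range
#'
#' A guide is `depleted` if its LFC falls below the controls' first quartile,
#' `enriched` if above their third quartile, `unchanged` otherwise.
#' Quartiles use linear interpolation (R type 7), so calls near the boundary
#' depend on that estimator.
#'
#' @param lfc numeric vector of guide LFCs to classify.
#' @param control_lfc LFCs of >= 4 control guides.
#' @return character vector in `{"depleted", "enriched", "unchanged"}`.
#' @export
classify_guides_vs_controls <- function(lfc, control_lfc) {
  if (length(control_lfc) < 4L) {
    stop("need >= 4 control guides for quartiles", call. = FALSE)
  }
  q <- stats::quantile(control_lfc, c(0.25, 0.75), names = FALSE, type = 7)
  out <- rep("unchanged", length(lfc))
  out[lfc < q[1]] <- "depleted"
  out[lfc > q[2]] <- "enriched"
  names(out) <- names(lfc)
  out
}

#' Replicate-consistent hit genes
#'
#' A guide is "truly" enriched/depleted when it carries the same
#' non-`unchanged` class in every replicate comparison. A gene is called a
#' hit when at least `min_consistent_guides` of its guides are true in the
#' same direction (and more than in the opposite direction); hits are ranked
#' by the number of true guides (descending), then by the absolute median
#' LFC of those guides (descending), then by gene name.
#'
#' @param classes guide x replicate character matrix from
#'   [classify_guides_vs_controls()].
#' @param lfc guide x replicate numeric matrix of LFCs.
#' @param library a [guide_library()].
#' @param min_consistent_guides minimum agreeing true guides for a hit
#'   (default 2).
#' @return data.frame (one row per gene, ranked hits first) with columns
#'   `gene`, `hit_class`, `n_true_guides`, `median_hit_lfc`.
#' @export
consistent_hit_genes <- function(classes, lfc, library,
                                 min_consistent_guides = 2) {
  classes <- as.matrix(classes)
  lfc <- as.matrix(lfc)
  if (ncol(classes) < 2L) {
    stop("need >= 2 replicate comparisons", call. = FALSE)
  }
  stopifnot(identical(dim(classes), dim(lfc)))
  same <- apply(classes, 1, function(r) length(unique(r)) == 1L)
  true_class <- ifelse(same & classes[, 1] != "unchanged", classes[, 1], "none")
  names(true_class) <- rownames(classes)

  targeting <- library[!library$is_control &
                         library$guide_id %in% rownames(classes), , drop = FALSE]
  genes <- unique(targeting$gene)
  res <- data.frame(gene = genes, hit_class = "none",
                    n_true_guides = 0L, median_hit_lfc = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    gids <- targeting$guide_id[targeting$gene == genes[i]]
    tc <- true_class[gids]
    n_dep <- sum(tc == "depleted")
    n_enr <- sum(tc == "enriched")
    dir <- if (n_dep >= min_consistent_guides && n_dep > n_enr) "depleted"
           else if (n_enr >= min_consistent_guides && n_enr > n_dep) "enriched"
           else "none"
    if (dir != "none") {
      hit_guides <- gids[tc == dir]
      res$hit_class[i] <- dir
      res$n_true_guides[i] <- sum(tc == dir)
      res$median_hit_lfc[i] <- stats::median(lfc[hit_guides, ])
    }
  }
  is_hit <- res$hit_class != "none"
  ord <- order(!is_hit, -res$n_true_guides,
               -abs(ifelse(is.na(res$median_hit_lfc), 0, res$median_hit_lfc)),
               res$gene)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Full screen scoring: counts to gene viability table
#'
#' Convenience wrapper chaining [guide_log_fold_change()],
#' [zscore_guides()], [gene_viability_score()] and [gene_ks_test()] over the
#' replicate structure in a [sample_design()]: each treatment replicate is
#' compared against the mean of all control samples in the same arm.
#'
#' @param norm normalized count matrix (or result of [normalize_counts()]).
#' @param library a [guide_library()].
#' @param design a [sample_design()] covering the matrix samples.
#' @param arm which screening arm to score (default `"in_vivo"`).
#' @param pseudocount passed to [guide_log_fold_change()].
#' @param alternative passed to [gene_ks_test()].
#' @return data.frame with columns `gene`, `score`, `p_value`, `n_guides`.
#' @export
score_screen <- function(norm, library, design, arm = "in_vivo",
                         pseudocount = 1,
                         alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.list(norm) && !is.null(norm$counts)) norm <- norm$counts
  des <- design[design$arm == arm & design$sample_id %in% colnames(norm), ]
  controls <- des$sample_id[des$condition == "control"]
  treatments <- des$sample_id[des$condition == "treatment"]
  if (length(controls) == 0L || length(treatments) == 0L) {
    stop("arm '", arm, "' needs >= 1 control and >= 1 treatment sample",
         call. = FALSE)
  }
  zmat <- sapply(treatments, function(s) {
    zscore_guides(guide_log_fold_change(norm, s, controls, pseudocount))
  })
  tab <- gene_viability_score(zmat, library)
  ctrl_guides <- library$guide_id[library$is_control]
  ctrl_z <- as.vector(zmat[intersect(ctrl_guides, rownames(zmat)), ])
  tab$p_value <- NA_real_
  if (length(ctrl_z) >= 2L) {
    targeting <- library[!library$is_control, ]
    for (i in seq_len(nrow(tab))) {
      gids <- intersect(targeting$guide_id[targeting$gene == tab$gene[i]],
                        rownames(zmat))
      gz <- as.vector(zmat[gids, ])
      if (length(gz) >= 2L) {
        tab$p_value[i] <- gene_ks_test(gz, ctrl_z, alternative)$p_value
      }
    }
  }
  tab[c("gene", "score", "p_value", "n_guides")]
}

#' Read or write a per-gene viability score table
#'
#' Tab-separated with at least columns `gene` and `score`.
#'
#' @param path file path.
#' @export
read_gene_scores <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("gene", "score") %in% names(df))) {
    stop("gene score table needs columns gene, score", call. = FALSE)
  }
  df
}

#' @rdname read_gene_scores
#' @param scores data.frame with `gene` and `score` columns.
#' @export
write_gene_scores <- function(scores, path) {
  .write_tsv(scores, path)
}
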