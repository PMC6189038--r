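#' Center expression in log space
#'
#' Transforms a linear-scale expression matrix to per-gene mean-centered
#' log2 values: `G[g, S] = log2(x[g, S] + epsilon) - mean_S(log2(x[g, ] +
#' epsilon))`, i.e. each entry becomes the log2 ratio of the sample's
#' expression to the gene's geometric mean over the centering cohort.
#' Constant genes center to zero. If the input is already on a log scale
#' (e.g. microarray data), set `already_log = TRUE` to skip the log step.
#'
#' @param expr non-negative gene x sample matrix (linear scale unless
#'   `already_log`).
#' @param epsilon pseudo-expression added before the log (default 1).
#' @param already_log if `TRUE`, `expr` is taken as log-scale and only
#'   centered.
#' @param reference optional matrix of the same genes defining a frozen
#'   centering cohort: row means are computed from it instead of from
#'   `expr`, so new samples can be scored against a fixed reference.
#' @return centered gene x sample matrix (attribute `centered = TRUE`).
#' @examples
#' center_log_expression(matrix(c(1, 2, 4), 1,
#'                              dimnames = list("g", NULL)), epsilon = 0)
#' @export
center_log_expression <- function(expr, epsilon = 1, already_log = FALSE,
                                  reference = NULL) {
  expr <- as.matrix(expr)
  if (!already_log && any(expr < 0)) {
    stop("linear-scale expression must be non-negative", call. = FALSE)
  }
  if (all(expr == 0)) warning("all-zero expression matrix", call. = FALSE)
  lg <- if (already_log) expr else log2(expr + epsilon)
  ctr <- if (is.null(reference)) {
    rowMeans(lg)
  } else {
    reference <- as.matrix(reference)
    if (!all(rownames(lg) %in% rownames(reference))) {
      stop("reference matrix missing genes", call. = FALSE)
    }
    ref_lg <- if (already_log) reference else log2(reference + epsilon)
    rowMeans(ref_lg)[rownames(lg)]
  }
  out <- lg - ctr
  attr(out, "centered") <- TRUE
  out
}

#' Build a DREBIC model from gene viability scores
#'
#' Selects the `n_depleted` genes with the most negative CRISPR viability
#' scores and the `n_enriched` genes with the most positive ones. Ties are
#' broken deterministically by gene name. Under the default construction the
#' two sets are disjoint; a warning flags depleted genes with non-negative
#' (or enriched genes with non-positive) scores, which indicates the
#' requested set sizes exceed the genes actually depleted/enriched.
#'
#' The headline model in the screen this package emulates used the 175 most
#' depleted and 225 most enriched genes, hence the defaults.
#'
#' @param scores data.frame with columns `gene` and `score` (the viability
#'   score C; negative = depleted).
#' @param n_depleted number of depleted genes, >= 0 (default 175).
#' @param n_enriched number of enriched genes, >= 0 (default 225).
#' @return object of class `drebic_model`: list with data.frames `depleted`
#'   and `enriched` (columns `gene`, `score`, extreme scores first).
#' @export
build_drebic_model <- function(scores, n_depleted = 175, n_enriched = 225) {
  .assert_number(n_depleted, "n_depleted", min = 0)
  .assert_number(n_enriched, "n_enriched", min = 0)
  if (n_depleted + n_enriched < 1) {
    stop("model needs at least one gene", call. = FALSE)
  }
  scores <- scores[is.finite(scores$score), , drop = FALSE]
  if (n_depleted + n_enriched > nrow(scores)) {
    stop("n_depleted + n_enriched (", n_depleted + n_enriched,
         ") exceeds the ", nrow(scores), "-gene universe", call. = FALSE)
  }
  asc <- scores[order(scores$score, scores$gene), , drop = FALSE]
  desc <- scores[order(-scores$score, scores$gene), , drop = FALSE]
  depleted <- asc[seq_len(n_depleted), c("gene", "score"), drop = FALSE]
  enriched <- desc[seq_len(n_enriched), c("gene", "score"), drop = FALSE]
  rownames(depleted) <- rownames(enriched) <- NULL
  if (n_depleted > 0 && any(depleted$score >= 0)) {
    warning("depleted set contains non-negative scores", call. = FALSE)
  }
  if (n_enriched > 0 && any(enriched$score <= 0)) {
    warning("enriched set contains non-positive scores", call. = FALSE)
  }
  structure(list(depleted = depleted, enriched = enriched),
            class = "drebic_model")
}

#' @export
print.drebic_model <- function(x, ...) {
  cat("DREBIC model:", nrow(x$depleted), "depleted +",
      nrow(x$enriched), "enriched genes\n")
  invisible(x)
}

#' Score samples with a DREBIC model
#'
#' The raw DREBIC score of a sample is the sum over model genes of the
#' gene's CRISPR viability score times the sample's centered log expression.
#' Under the default `signed_sum` convention each score enters with its own
#' sign (depleted genes have C < 0, enriched C > 0), so a sample expressing
#' depleted genes below the cohort mean and enriched genes above it scores
#' high -- i.e. is predicted more drug-sensitive. The `printed_eq1`
#' convention instead subtracts the enriched-gene sum; it reverses the
#' enriched genes' directionality and is retained only for comparison (see
#' the methods vignette for why `signed_sum` is the default).
#'
#' @param model a [build_drebic_model()] result.
#' @param centered centered gene x sample matrix from
#'   [center_log_expression()].
#' @param convention `"signed_sum"` (default) or `"printed_eq1"`.
#' @param missing_genes `"error"` (default) or `"skip"`: what to do when a
#'   model gene is absent from the expression matrix (skipping logs a
#'   warning).
#' @return named numeric vector of raw (unbounded) scores, one per sample;
#'   higher = predicted more sensitive (under `signed_sum`).
#' @export
score_samples <- function(model, centered,
                          convention = c("signed_sum", "printed_eq1"),
                          missing_genes = c("error", "skip")) {
  convention <- match.arg(convention)
  missing_genes <- match.arg(missing_genes)
  centered <- as.matrix(centered)
  miss <- setdiff(c(model$depleted$gene, model$enriched$gene),
                  rownames(centered))
  if (length(miss)) {
    if (missing_genes == "error") {
      stop("model gene(s) absent from expression matrix: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) ", ...", call. = FALSE)
    }
    warning("skipping ", length(miss), " model gene(s) absent from expression",
            call. = FALSE)
  }
  part <- function(set, sign) {
    set <- set[!(set$gene %in% miss), , drop = FALSE]
    if (nrow(set) == 0L) return(rep(0, ncol(centered)))
    sign * as.vector(crossprod(centered[set$gene, , drop = FALSE], set$score))
  }
  enr_sign <- if (convention == "signed_sum") 1 else -1
  raw <- part(model$depleted, 1) + part(model$enriched, enr_sign)
  names(raw) <- colnames(centered)
  raw
}

#' Rescale raw DREBIC scores to \[-1, +1\]
#'
#' Affine map sending the cohort minimum to -1 and maximum to +1; a
#' degenerate cohort (single sample or all raw scores equal) maps to 0.
#' Rescaling preserves the sample ranking exactly, so it never changes
#' ROC/AUC evaluation results.
#'
#' @param raw numeric vector of raw scores over the cohort.
#' @return numeric vector of the same length in \[-1, +1\].
#' @examples
#' rescale_scores(c(-3, 1, 5))  # -1 0 1
#' @export
rescale_scores <- function(raw) {
  if (length(raw) == 0L) stop("empty score vector", call. = FALSE)
  rng <- range(raw)
  if (diff(rng) == 0) {
    return(stats::setNames(rep(0, length(raw)), names(raw)))
  }
  2 * (raw - rng[1]) / diff(rng) - 1
}

#' Read or write a DREBIC model table
#'
#' Tab-separated with columns `gene`, `score`, `set` (`depleted` or
#' `enriched`).
#'
#' @param path file path.
#' @export
read_drebic_model <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("gene", "score", "set") %in% names(df))) {
    stop("model table needs columns gene, score, set", call. = FALSE)
  }
  dep <- df[df$set == "depleted", c("gene", "score")]
  enr <- df[df$set == "enriched", c("gene", "score")]
  dep <- dep[order(dep$score, dep$gene), ]
  enr <- enr[order(-enr$score, enr$gene), ]
  rownames(dep) <- rownames(enr) <- NULL
  structure(list(depleted = dep, enriched = enr), class = "drebic_model")
}

#' @rdname read_drebic_model
#' @param model a `drebic_model`.
#' @export
write_drebic_model <- function(model, path) {
  df <- rbind(
    data.frame(model$depleted, set = "depleted", stringsAsFactors = FALSE),
    data.frame(model$enriched, set = "enriched", stringsAsFactors = FALSE)
  )
  .write_tsv(df, path)
}

#' Read or write an expression matrix
#'
#' Tab-separated: first column `gene`, remaining columns one per sample.
#'
#' @param path file path.
#' @export
read_expression_matrix <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene") {
    stop("expression table must start with a gene column", call. = FALSE)
  }
  m <- as.matrix(df[-1])
  rownames(m) <- df$gene
  m
}

#' @rdname read_expression_matrix
#' @param expr gene x sample matrix.
#' @export
write_expression_matrix <- function(expr, path) {
  .write_tsv(data.frame(gene = rownames(expr), expr, check.names = FALSE,
                        stringsAsFactors = FALSE), path)
}

#' Write per-sample DREBIC scores
#'
#' Tab-separated with columns `sample_id`, `raw`, `rescaled`.
#'
#' @param raw named raw score vector.
#' @param path file path.
#' @export
write_drebic_scores <- function(raw, path) {
  .write_tsv(data.frame(sample_id = names(raw), raw = unname(raw),
                        rescaled = unname(rescale_scores(raw)),
                        stringsAsFactors = FALSE), path)
}
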