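#' Genes recurrently mutated in the analysis cohort
#'
#' Keeps genes mutated in at least `min_lines` of the cohort samples
#' (default 12, the threshold used in the genotype analysis this package
#' emulates).
#'
#' @param mutations gene x sample binary (0/1 or logical) matrix.
#' @param min_lines minimum number of mutant samples (default 12).
#' @param cohort optional sample subset defining the analysis cohort
#'   (default: all matrix columns).
#' @return character vector of gene names.
#' @export
select_recurrently_mutated <- function(mutations, min_lines = 12,
                                       cohort = NULL) {
  mutations <- as.matrix(mutations)
  if (length(mutations) == 0L) stop("empty mutation table", call. = FALSE)
  .assert_number(min_lines, "min_lines", min = 0)
  if (!is.null(cohort)) {
    cohort <- intersect(cohort, colnames(mutations))
    mutations <- mutations[, cohort, drop = FALSE]
  }
  rownames(mutations)[rowSums(mutations != 0) >= min_lines]
}

#' Mutation-stratified shifts in DREBIC score and drug response
#'
#' For one gene, splits the cohort (intersection of the score, response and
#' mutation tables) into mutant and wild-type samples and reports the
#' difference of medians for the DREBIC score (Delta DREBIC) and for log
#' IC50 (Delta log IC50), with two-sample Kolmogorov-Smirnov p-values for
#' each. A positive Delta DREBIC with a negative Delta log IC50 means the
#' mutation associates with increased predicted and measured sensitivity.
#'
#' @param scores named per-sample DREBIC score vector.
#' @param log_ic50 named per-sample log IC50 vector.
#' @param mutations gene x sample binary matrix.
#' @param gene gene to stratify by.
#' @return one-row data.frame: `gene`, `n_mut`, `n_wt`, `delta_drebic`,
#'   `delta_log_ic50`, `p_drebic`, `p_ic50`.
#' @export
mutation_delta_stats <- function(scores, log_ic50, mutations, gene) {
  mutations <- as.matrix(mutations)
  if (!gene %in% rownames(mutations)) {
    stop("gene not in mutation table: ", gene, call. = FALSE)
  }
  common <- Reduce(intersect, list(names(scores), names(log_ic50),
                                   colnames(mutations)))
  if (length(common) < 2L) stop("cohort intersection too small", call. = FALSE)
  mut <- mutations[gene, common] != 0
  if (!any(mut) || all(mut)) {
    stop("empty mutant or wild-type group for ", gene, call. = FALSE)
  }
  sc <- scores[common]; ic <- log_ic50[common]
  ksp <- function(a, b) {
    if (length(a) < 1L || length(b) < 1L) return(NA_real_)
    suppressWarnings(stats::ks.test(a, b)$p.value)
  }
  data.frame(
    gene = gene, n_mut = sum(mut), n_wt = sum(!mut),
    delta_drebic = stats::median(sc[mut]) - stats::median(sc[!mut]),
    delta_log_ic50 = stats::median(ic[mut]) - stats::median(ic[!mut]),
    p_drebic = ksp(sc[mut], sc[!mut]),
    p_ic50 = ksp(ic[mut], ic[!mut]),
    stringsAsFactors = FALSE
  )
}

#' Mutation effect table over all recurrently mutated genes
#'
#' Runs [mutation_delta_stats()] for every gene passing the recurrence
#' filter on the intersected cohort. Raw KS p-values are reported (matching
#' the emulated analysis); Benjamini-Hochberg adjusted columns are appended
#' for convenience.
#'
#' @inheritParams mutation_delta_stats
#' @param min_lines recurrence threshold passed to
#'   [select_recurrently_mutated()].
#' @return data.frame, one row per gene, ordered by `delta_drebic`
#'   (descending), with columns of [mutation_delta_stats()] plus
#'   `padj_drebic`, `padj_ic50`.
#' @export
mutation_effect_table <- function(scores, log_ic50, mutations,
                                  min_lines = 12) {
  common <- Reduce(intersect, list(names(scores), names(log_ic50),
                                   colnames(mutations)))
  dropped <- ncol(as.matrix(mutations)) - length(common)
  if (dropped > 0) {
    message(dropped, " mutation-table sample(s) absent from scores/response; ",
            "analyzing ", length(common), " samples")
  }
  genes <- select_recurrently_mutated(mutations, min_lines, cohort = common)
  genes <- genes[vapply(genes, function(g) {
    m <- as.matrix(mutations)[g, common] != 0
    any(m) && !all(m)
  }, logical(1))]
  if (length(genes) == 0L) {
    stop("no gene passes the recurrence filter", call. = FALSE)
  }
  rows <- lapply(genes, function(g) {
    mutation_delta_stats(scores, log_ic50, mutations, g)
  })
  out <- do.call(rbind, rows)
  out$padj_drebic <- stats::p.adjust(out$p_drebic, method = "BH")
  out$padj_ic50 <- stats::p.adjust(out$p_ic50, method = "BH")
  out <- out[order(-out$delta_drebic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read or write a binary mutation table
#'
#' Tab-separated: first column `gene`, remaining columns one 0/1 entry per
#' sample.
#'
#' @param path file path.
#' @export
read_mutation_table <- function(path) {
  df <- .read_tsv(path)
  if (names(df)[1] != "gene") {
    stop("mutation table must start with a gene column", call. = FALSE)
  }
  m <- as.matrix(df[-1])
  if (!all(m %in% c(0, 1))) stop("mutation entries must be 0/1", call. = FALSE)
  rownames(m) <- df$gene
  m
}

#' @rdname read_mutation_table
#' @param mutations gene x sample binary matrix.
#' @export
write_mutation_table <- function(mutations, path) {
  .write_tsv(data.frame(gene = rownames(mutations), mutations,
                        check.names = FALSE, stringsAsFactors = FALSE), path)
}
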