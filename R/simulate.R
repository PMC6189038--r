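# Synthetic screen / cohort generators with planted ground truth.
# Every generator is seed-deterministic; defaults mirror the statistical
# structure of the emulated screen (a ~3733-gene nuclear library with ~10
# guides/gene plus non-targeting controls; overdispersed counts; ~64% guide
# detectability in untreated in vivo tumors) at a desk-testable scale.

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

.unique_dna <- function(n, len) {
  out <- unique(.random_dna(n, len))
  while (length(out) < n) {
    out <- unique(c(out, .random_dna(n - length(out), len)))
  }
  out[seq_len(n)]
}

#' Simulate a pooled CRISPR knockout screen with planted fitness effects
#'
#' Guide abundances follow a negative binomial around lognormal per-guide
#' baselines. Treatment columns multiply the guide means of planted genes by
#' `2^effect`: depleted genes carry effect `-effect_size`, enriched genes
#' `+effect_size`. In vivo arms additionally pass counts through a random
#' engraftment bottleneck -- guide-level Bernoulli dropout, independent per
#' tumor, calibrated so the expected detectable fraction of an untreated
#' tumor matches `in_vivo_dropout`.
#'
#' @param n_genes number of targeted genes (default 500; the full-scale
#'   preset of the emulated library is 3733).
#' @param guides_per_gene guides per gene (default 10).
#' @param n_control_guides non-targeting controls (default 100).
#' @param depth mean reads per guide (default 400).
#' @param dispersion negative binomial dispersion (NB size = 1/dispersion;
#'   default 0.2).
#' @param frac_depleted,frac_enriched fractions of genes planted as
#'   depleted/enriched (defaults 0.05 each).
#' @param effect_size magnitude of the planted log2 fitness effect
#'   (default 2).
#' @param n_replicates control and treatment replicates (default 3 each).
#' @param arm `"in_vivo"` (default) or `"in_vitro"`; only in vivo samples
#'   undergo the engraftment bottleneck (day 0 cells are pre-injection and
#'   never do).
#' @param in_vivo_dropout target detectable fraction of an untreated in
#'   vivo tumor (default 0.64).
#' @param baseline_sdlog lognormal spread of guide baselines (default 0.5).
#' @param seed mandatory RNG seed.
#' @return list with `library` ([guide_library()]), `counts` (raw integer
#'   matrix), `design` ([sample_design()] with 56-nt barcodes), and `truth`
#'   (data.frame `gene`, `effect`, `direction`).
#' @export
simulate_screen <- function(n_genes = 500, guides_per_gene = 10,
                            n_control_guides = 100, depth = 400,
                            dispersion = 0.2,
                            frac_depleted = 0.05, frac_enriched = 0.05,
                            effect_size = 2, n_replicates = 3,
                            arm = c("in_vivo", "in_vitro"),
                            in_vivo_dropout = 0.64,
                            baseline_sdlog = 0.5, seed) {
  arm <- match.arg(arm)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (frac_depleted < 0 || frac_enriched < 0 ||
      frac_depleted + frac_enriched > 1) {
    stop("planted fractions must be in [0, 1] and sum <= 1", call. = FALSE)
  }
  set.seed(seed)

  genes <- sprintf("GENE%04d", seq_len(n_genes))
  n_guides <- n_genes * guides_per_gene
  lib <- guide_library(
    guide_id = c(sprintf("sg_%s_%02d", rep(genes, each = guides_per_gene),
                         rep(seq_len(guides_per_gene), n_genes)),
                 sprintf("ctrl_%03d", seq_len(n_control_guides))),
    sequence = .unique_dna(n_guides + n_control_guides, 20),
    gene = c(rep(genes, each = guides_per_gene),
             rep("", n_control_guides)),
    is_control = c(rep(FALSE, n_guides), rep(TRUE, n_control_guides))
  )

  n_dep <- round(frac_depleted * n_genes)
  n_enr <- round(frac_enriched * n_genes)
  planted <- sample(genes, n_dep + n_enr)
  effect <- stats::setNames(rep(0, n_genes), genes)
  effect[planted[seq_len(n_dep)]] <- -effect_size
  if (n_enr > 0) effect[planted[n_dep + seq_len(n_enr)]] <- effect_size
  truth <- data.frame(
    gene = genes, effect = unname(effect),
    direction = ifelse(effect < 0, "depleted",
                       ifelse(effect > 0, "enriched", "neutral")),
    stringsAsFactors = FALSE
  )

  size <- 1 / dispersion
  baseline <- stats::rlnorm(nrow(lib),
                            meanlog = log(depth) - baseline_sdlog^2 / 2,
                            sdlog = baseline_sdlog)
  guide_effect <- ifelse(lib$is_control, 0, effect[lib$gene])
  guide_effect[is.na(guide_effect)] <- 0

  samples <- c("day0",
               paste0("control_", seq_len(n_replicates)),
               paste0("treatment_", seq_len(n_replicates)))
  design <- sample_design(
    sample_id = samples,
    condition = c("day0", rep("control", n_replicates),
                  rep("treatment", n_replicates)),
    replicate = c(1L, seq_len(n_replicates), seq_len(n_replicates)),
    arm = arm,
    barcode = .unique_dna(length(samples), 56)
  )

  keep_prob <- 1
  if (arm == "in_vivo") {
    base_detect <- mean(1 - stats::dnbinom(0, mu = baseline, size = size))
    keep_prob <- in_vivo_dropout / base_detect
    if (keep_prob > 1) {
      stop("infeasible dropout target: baseline detectability is only ",
           round(base_detect, 3), call. = FALSE)
    }
  }

  counts <- matrix(0L, nrow = nrow(lib), ncol = length(samples),
                   dimnames = list(lib$guide_id, samples))
  for (s in seq_along(samples)) {
    mu <- if (design$condition[s] == "treatment") {
      baseline * 2^guide_effect
    } else {
      baseline
    }
    col <- stats::rnbinom(nrow(lib), mu = mu, size = size)
    if (arm == "in_vivo" && design$condition[s] != "day0") {
      col <- col * stats::rbinom(nrow(lib), 1L, keep_prob)
    }
    counts[, s] <- col
  }
  list(library = lib, counts = counts, design = design, truth = truth)
}

#' Simulate an expression/response cohort driven by a planted DREBIC model
#'
#' Centered-log expression deviations are standard normal per gene. The
#' latent drug sensitivity of a sample is the viability-score-weighted sum
#' of its causal-gene deviations, standardized to unit variance over the
#' cohort, plus Gaussian noise: `z_S = signal_S / sd(signal) + N(0,
#' noise_sd)` (so `noise_sd` is in units of the signal SD). Measured
#' response is `log_ic50 = -z_S`. The causal set is the
#' `n_causal_depleted` most-negative plus `n_causal_enriched` most-positive
#' scored genes.
#'
#' An optional planted mutation shifts carriers' latent sensitivity by
#' `mutation_shift` (again in signal-SD units). The shift is injected
#' through the carriers' causal-gene expression (along the gradient
#' `C_g / sum(C^2)`), so it is visible both to the measured IC50 and to
#' any expression-based score -- as a real expression-mediated genotype
#' effect would be. Background mutation genes are sprinkled independently
#' of everything.
#'
#' @param scores gene viability score data.frame (`gene`, `score`).
#' @param n_samples cohort size (default 400).
#' @param n_causal_depleted,n_causal_enriched causal set sizes
#'   (defaults 50 / 50).
#' @param noise_sd latent noise SD in signal-SD units (default 0.25).
#' @param mutation_shift latent shift for planted-mutation carriers
#'   (default 0 = no planted mutation).
#' @param mutation_carrier_frac carrier fraction (default 0.15).
#' @param mutation_gene name of the planted mutation gene (default
#'   `"planted_mut"`).
#' @param n_background_mut_genes independent noise mutation genes
#'   (default 20, 5% carrier rate).
#' @param base_log2_mean mean log2 baseline expression (default 6).
#' @param tissues tissue labels sampled uniformly per sample (default 4
#'   generic tissues); `NULL` for none.
#' @param drug drug name in the response table (default `"drugA"`).
#' @param seed mandatory RNG seed.
#' @return list with `expression` (linear-scale gene x sample matrix),
#'   `response` (data.frame `sample_id`, `drug`, `log_ic50`, `tissue`),
#'   `mutations` (gene x sample 0/1 matrix), and `truth` (list with
#'   `latent`, `causal_genes`, `centered`, `carriers`).
#' @export
simulate_expression_response <- function(scores, n_samples = 400,
                                         n_causal_depleted = 50,
                                         n_causal_enriched = 50,
                                         noise_sd = 0.25,
                                         mutation_shift = 0,
                                         mutation_carrier_frac = 0.15,
                                         mutation_gene = "planted_mut",
                                         n_background_mut_genes = 20,
                                         base_log2_mean = 6,
                                         tissues = paste0("tissue", 1:4),
                                         drug = "drugA", seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n_causal <- n_causal_depleted + n_causal_enriched
  if (n_causal > nrow(scores)) {
    stop("n_causal exceeds the scored gene count", call. = FALSE)
  }
  if (n_causal < 1) stop("need >= 1 causal gene", call. = FALSE)
  set.seed(seed)

  genes <- scores$gene
  C <- stats::setNames(scores$score, genes)
  asc <- genes[order(C, genes)]
  desc <- genes[order(-C, genes)]
  causal <- unique(c(asc[seq_len(n_causal_depleted)],
                     desc[seq_len(n_causal_enriched)]))

  samples <- sprintf("s%03d", seq_len(n_samples))
  G <- matrix(stats::rnorm(length(genes) * n_samples), length(genes),
              n_samples, dimnames = list(genes, samples))

  signal <- as.vector(crossprod(G[causal, , drop = FALSE], C[causal]))
  sd_sig <- sqrt(mean((signal - mean(signal))^2))
  if (sd_sig == 0) stop("degenerate causal signal", call. = FALSE)

  carriers <- character(0)
  if (mutation_shift != 0) {
    carriers <- sample(samples, max(1, round(mutation_carrier_frac * n_samples)))
    # gradient step: raises carriers' latent sensitivity by exactly
    # mutation_shift signal-SD units through their causal-gene expression
    step <- mutation_shift * sd_sig * C[causal] / sum(C[causal]^2)
    G[causal, carriers] <- G[causal, carriers] + step
    signal <- as.vector(crossprod(G[causal, , drop = FALSE], C[causal]))
  }

  latent <- signal / sd_sig + stats::rnorm(n_samples, 0, noise_sd)
  names(latent) <- samples

  baseline <- stats::rnorm(length(genes), base_log2_mean, 1)
  expression <- 2^(G + baseline)

  response <- data.frame(
    sample_id = samples, drug = drug, log_ic50 = -latent,
    tissue = if (is.null(tissues)) NA_character_ else
      sample(tissues, n_samples, replace = TRUE),
    stringsAsFactors = FALSE
  )

  mut_genes <- character(0)
  mut_rows <- NULL
  if (n_background_mut_genes > 0) {
    mut_genes <- sprintf("bgmut%02d", seq_len(n_background_mut_genes))
    mut_rows <- matrix(stats::rbinom(n_background_mut_genes * n_samples, 1, 0.05),
                       n_background_mut_genes, n_samples)
  }
  if (mutation_shift != 0) {
    planted_row <- matrix(as.integer(samples %in% carriers), 1, n_samples)
    mut_rows <- rbind(planted_row, mut_rows)
    mut_genes <- c(mutation_gene, mut_genes)
  }
  mutations <- if (is.null(mut_rows)) {
    matrix(0L, 0, n_samples, dimnames = list(NULL, samples))
  } else {
    dimnames(mut_rows) <- list(mut_genes, samples)
    mut_rows
  }

  list(expression = expression, response = response, mutations = mutations,
       truth = list(latent = latent, causal_genes = causal,
                    centered = G, carriers = carriers))
}

#' Write per-sample FASTQ files realizing a count matrix
#'
#' Each guide contributes `count * reads_per_count` reads of the form
#' `barcode (56 nt) + stuffer + spacer (guide sequence)`, so that
#' [count_guides()] recovers the input counts exactly and
#' [assign_sample_barcode()] recovers the sample. Optionally a fraction of
#' extra reads carry a corrupted (non-library) spacer, lowering the match
#' fraction accordingly.
#'
#' @param counts guide x sample count matrix (small -- one read is written
#'   per count unit).
#' @param library a [guide_library()].
#' @param design a [sample_design()] with barcodes for all count-matrix
#'   samples.
#' @param dir output directory (created if needed).
#' @param stuffer fixed sequence between barcode and spacer (default
#'   10 nt); the spacer offset is therefore `56 + nchar(stuffer)`.
#' @param frac_corrupt fraction of additional corrupted-spacer reads
#'   (default 0).
#' @param reads_per_count reads emitted per count unit (default 1).
#' @param seed RNG seed (used for corruption and shuffling; default 1).
#' @return named character vector of FASTQ paths, one per sample.
#' @export
simulate_fastq <- function(counts, library, design, dir,
                           stuffer = "GTTTGAGACG", frac_corrupt = 0,
                           reads_per_count = 1, seed = 1) {
  counts <- as.matrix(counts)
  if (is.null(design$barcode)) {
    stop("design table has no barcodes", call. = FALSE)
  }
  miss <- setdiff(colnames(counts), design$sample_id)
  if (length(miss)) {
    stop("design missing sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seq_of <- stats::setNames(library$sequence, library$guide_id)
  bc_of <- stats::setNames(design$barcode, design$sample_id)
  k <- nchar(library$sequence[1])
  paths <- stats::setNames(file.path(dir, paste0(colnames(counts), ".fastq")),
                           colnames(counts))
  for (s in colnames(counts)) {
    n <- round(counts[, s] * reads_per_count)
    spacers <- rep(seq_of[rownames(counts)], n)
    if (frac_corrupt > 0) {
      n_bad <- round(frac_corrupt / (1 - frac_corrupt) * length(spacers))
      if (n_bad > 0) {
        bad <- .random_dna(n_bad, k)
        while (any(bad %in% library$sequence)) {
          bad[bad %in% library$sequence] <-
            .random_dna(sum(bad %in% library$sequence), k)
        }
        spacers <- c(spacers, bad)
      }
    }
    if (length(spacers) > 1L) spacers <- sample(spacers)
    reads <- paste0(bc_of[s], stuffer, spacers)
    rec <- character(4L * length(reads))
    if (length(reads)) {
      rec[seq(1, length(rec), 4)] <- paste0("@", s, "_r", seq_along(reads))
      rec[seq(2, length(rec), 4)] <- reads
      rec[seq(3, length(rec), 4)] <- "+"
      rec[seq(4, length(rec), 4)] <- strrep("I", nchar(reads))
    }
    writeLines(rec, paths[s])
  }
  paths
}
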