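#' Fit the Chou-Talalay median-effect model
#'
#' Linearizes the median-effect equation
#' `fa/(1-fa) = (D/Dm)^m` to `log(fa/(1-fa)) = m*log(D) - m*log(Dm)` and
#' fits it by least squares. `Dm` is the dose producing 50% effect and `m`
#' the sigmoidicity of the dose-effect curve. Points with `fa` at 0 or 1
#' (undefined under the model) are excluded with a warning.
#'
#' @param doses positive dose vector.
#' @param fa fraction-affected vector in (0, 1), same length.
#' @param drug optional drug label stored in the fit.
#' @return object of class `median_effect_fit`: list with `drug`, `Dm`,
#'   `m`, `r2`, `doses`, `fa`.
#' @examples
#' fit_median_effect(c(0.5, 1, 2), c(0.2, 0.5, 0.8))  # Dm = 1, m = 2
#' @export
fit_median_effect <- function(doses, fa, drug = "drug") {
  if (length(doses) != length(fa)) {
    stop("doses and fa lengths differ", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  usable <- fa > 0 & fa < 1
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with fa at 0 or 1 excluded",
            call. = FALSE)
  }
  d <- doses[usable]; f <- fa[usable]
  if (length(d) < 2L) {
    stop("need >= 2 dose points with 0 < fa < 1", call. = FALSE)
  }
  y <- log10(f / (1 - f))
  x <- log10(d)
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  if (!is.finite(m) || m <= 0) {
    stop("median-effect slope m must be positive; check the dose-effect data",
         call. = FALSE)
  }
  Dm <- 10^(-unname(stats::coef(fit)[1]) / m)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(drug = drug, Dm = Dm, m = m, r2 = r2, doses = d, fa = f),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit [", x$drug, "]: Dm = ", format(x$Dm, digits = 4),
      ", m = ", format(x$m, digits = 4),
      ", r2 = ", format(x$r2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Single-agent dose producing a given effect
#'
#' Inverts the fitted median-effect curve:
#' `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit a [fit_median_effect()] result.
#' @param fa target fraction affected in (0, 1).
#' @return dose (same units as the fitted doses).
#' @export
dose_for_effect <- function(fit, fa) {
  if (any(fa <= 0 | fa >= 1)) {
    stop("fa must lie strictly in (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Chou-Talalay combination index for a constant-ratio combination
#'
#' For each fa level attained by the combination, the combination index is
#' `CI = d1/Dx1(fa) + d2/Dx2(fa)`, where `d1`, `d2` are the component doses
#' in the combination and `Dx1`, `Dx2` the single-agent doses producing the
#' same effect (mutually exclusive form, no cross-term). CI below
#' `1 - tol` is called synergy, above `1 + tol` antagonism, additive in
#' between. Component doses must keep a constant ratio across rows
#' (constant-ratio design).
#'
#' @param fit1,fit2 single-agent [fit_median_effect()] results.
#' @param d1,d2 component dose vectors of the combination (constant ratio).
#' @param fa fraction affected observed for the combination at each dose
#'   pair, in (0, 1).
#' @param tol additivity tolerance for the verdict (default 0.05).
#' @param combo optional combination label.
#' @return object of class `synergy_result`: data.frame with columns
#'   `combo`, `d1`, `d2`, `fa`, `ci`, `verdict`, plus attribute `ratio`.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa, tol = 0.05,
                              combo = paste(fit1$drug, fit2$drug, sep = "+")) {
  if (!(length(d1) == length(d2) && length(d2) == length(fa))) {
    stop("d1, d2, fa lengths differ", call. = FALSE)
  }
  if (any(d1 <= 0 | d2 <= 0)) stop("doses must be positive", call. = FALSE)
  if (any(fa <= 0 | fa >= 1)) stop("fa must lie in (0, 1)", call. = FALSE)
  ratio <- d1 / d2
  if (length(ratio) > 1L &&
      max(abs(ratio - ratio[1])) > 1e-8 * abs(ratio[1])) {
    stop("combination doses do not follow a constant ratio design",
         call. = FALSE)
  }
  ci <- d1 / dose_for_effect(fit1, fa) + d2 / dose_for_effect(fit2, fa)
  verdict <- ifelse(ci < 1 - tol, "synergy",
                    ifelse(ci > 1 + tol, "antagonism", "additive"))
  out <- data.frame(combo = combo, d1 = d1, d2 = d2, fa = fa, ci = ci,
                    verdict = verdict, stringsAsFactors = FALSE)
  attr(out, "ratio") <- ratio[1]
  class(out) <- c("synergy_result", "data.frame")
  out
}

#' Synergy analysis of a dose/fraction-affected table
#'
#' Expects a table with columns `agent` (drug name or combination id),
#' `d1`, `d2` (for single agents `d2 = 0`), and `fa`. Single-agent rows are
#' fitted with [fit_median_effect()]; each combination id of the form
#' `"A+B"` is evaluated with [combination_index()] against the fits of A
#' and B.
#'
#' @param table data.frame or TSV path with the columns above.
#' @param tol additivity tolerance (default 0.05).
#' @return list with `fits` (named list of `median_effect_fit`) and
#'   `synergy` (rbind of `synergy_result` rows).
#' @export
synergy_analysis <- function(table, tol = 0.05) {
  if (is.character(table)) table <- .read_tsv(table)
  need <- c("agent", "d1", "d2", "fa")
  if (!all(need %in% names(table))) {
    stop("synergy table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  singles <- table[table$d2 == 0, , drop = FALSE]
  combos <- table[table$d2 > 0, , drop = FALSE]
  fits <- lapply(split(singles, singles$agent), function(df) {
    fit_median_effect(df$d1, df$fa, drug = df$agent[1])
  })
  res <- lapply(split(combos, combos$agent), function(df) {
    parts <- strsplit(df$agent[1], "+", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% names(fits))) {
      stop("combination '", df$agent[1],
           "' must be named 'A+B' with fitted single agents A and B",
           call. = FALSE)
    }
    combination_index(fits[[parts[1]]], fits[[parts[2]]],
                      df$d1, df$d2, df$fa, tol = tol, combo = df$agent[1])
  })
  list(fits = fits,
       synergy = if (length(res)) do.call(rbind, res) else NULL)
}
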