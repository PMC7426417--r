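#' Two-sample t-test (paired or unpaired)
#'
#' Student's two-sample equal-variance t-test (the default for unpaired
#' comparisons), Welch's variant on request, or the paired t-test. Wraps
#' [stats::t.test()] with one convention added: when both groups have zero
#' variance and equal means (or all paired differences are zero) the test
#' is degenerate and `t = 0, p = 1` is returned; zero variance with
#' unequal means gives `p = 0`.
#'
#' @param a,b Numeric vectors (n >= 2 each; equal length when paired).
#' @param paired Paired test.
#' @param welch Use Welch's unequal-variance test (unpaired only).
#' @return An object of class `ttest_result`: `statistic`, `df`,
#'   `p_value`, `paired`.
#' @export
ttest <- function(a, b, paired = FALSE, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    abort_validation("each group needs at least 2 observations")
  if (paired && length(a) != length(b))
    abort_validation("paired test requires equal group sizes")
  degenerate <- if (paired) stats::var(a - b) == 0 else
    stats::var(a) == 0 && stats::var(b) == 0
  if (degenerate) {
    equal <- if (paired) all(a == b) else isTRUE(all.equal(mean(a), mean(b)))
    return(structure(list(statistic = if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                          df = if (paired) length(a) - 1L else
                            length(a) + length(b) - 2L,
                          p_value = if (equal) 1 else 0,
                          paired = paired),
                     class = "ttest_result"))
  }
  tt <- stats::t.test(a, b, paired = paired,
                      var.equal = !paired && !welch,
                      alternative = "two.sided")
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 paired = paired),
            class = "ttest_result")
}

#' Duration-filter index
#'
#' Quantifies selectivity for sustained over transient stimulation from
#' per-cell fold-changes: the ratio of mean baseline-subtracted responses,
#' `mean(fold_sustained - 1) / mean(fold_transient - 1)`, together with an
#' unpaired two-sided t-test on the folds. A ratio above 1 indicates
#' sustained-selective protein accumulation; a neutral circuit gives a
#' ratio near 1.
#'
#' @param fold_sustained,fold_transient Per-cell fold-changes.
#' @param welch Use Welch's t-test.
#' @return A list with `ratio`, `p_value`, `sustained_selective`
#'   (`ratio > 1`) and `undefined` (`TRUE` when the transient mean fold is
#'   exactly 1, in which case `ratio` is `Inf`).
#' @export
duration_filter_index <- function(fold_sustained, fold_transient,
                                  welch = FALSE) {
  if (!length(fold_sustained) || !length(fold_transient))
    abort_validation("both groups must be nonempty")
  num <- mean(fold_sustained - 1)
  den <- mean(fold_transient - 1)
  undefined <- den == 0
  ratio <- if (undefined) Inf * sign(num) else num / den
  p <- if (length(fold_sustained) >= 2 && length(fold_transient) >= 2)
    ttest(fold_sustained, fold_transient, welch = welch)$p_value
  else NA_real_
  list(ratio = ratio, p_value = p,
       sustained_selective = is.finite(ratio) && ratio > 1,
       undefined = undefined)
}

#' Significance stars
#' @param p A p-value.
#' @return `"***"`, `"**"`, `"*"` or `"ns"` at the 0.001/0.01/0.05 levels.
#' @export
p_stars <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' AND-gate analysis of per-cell AUCs
#'
#' Characterizes combinatorial decoding from per-cell AUC measurements in
#' four conditions: `starve` (no input), `A` (serum), `B` (doxorubicin)
#' and `AB` (both). Computes the synergy
#' `S = mean_AUC(AB) - mean_AUC(A) - mean_AUC(B)`, the unpaired two-sided
#' t-tests reported for such experiments (starve vs each condition, and A
#' and B each vs AB), and a classification:
#'
#' * `AND-like`: `S > 0`, AB significantly exceeds each single input
#'   (`p < alpha`), and each single-input fold-change is below `tau`
#'   (weak single responses; the fold criterion is skipped when folds are
#'   not supplied).
#' * `single-input-driven`: a single input already explains the response
#'   (its fold reaches `tau`, or its mean AUC reaches 90% of AB's).
#' * `additive`: everything else (in particular `AB = A + B`, `S = 0`).
#'
#' The classification is invariant to a global rescaling of all AUCs.
#' This quantitative AND-gate criterion is a definition adopted by this
#' package (reported as such in the output); it deliberately tolerates
#' weak sub-threshold single-input responses.
#'
#' @param auc Numeric vector of per-cell AUCs.
#' @param condition Condition label per cell: `"starve"`, `"A"`, `"B"`,
#'   `"AB"` (all four required, >= 3 cells each).
#' @param fold Optional per-cell fold-changes (same order) used for the
#'   single-input weakness criterion.
#' @param tau Single-input fold threshold (default 1.5).
#' @param alpha Significance level (default 0.05).
#' @param welch Use Welch's t-tests.
#' @return An object of class `gate_report`.
#' @export
gate_analysis <- function(auc, condition, fold = NULL, tau = 1.5,
                          alpha = 0.05, welch = FALSE) {
  need <- c("starve", "A", "B", "AB")
  condition <- as.character(condition)
  missing_cond <- setdiff(need, unique(condition))
  if (length(missing_cond))
    abort_validation("missing condition(s): %s",
                     paste(missing_cond, collapse = ", "))
  if (length(auc) != length(condition))
    abort_validation("`auc` and `condition` lengths differ")
  groups <- split(auc, factor(condition, levels = need))
  small <- names(groups)[vapply(groups, length, integer(1)) < 3L]
  if (length(small))
    abort_validation("need >= 3 cells per condition (too few in: %s)",
                     paste(small, collapse = ", "))

  means <- vapply(groups, mean, numeric(1))
  S <- means[["AB"]] - means[["A"]] - means[["B"]]

  pv <- c(starve_vs_A = ttest(groups$starve, groups$A, welch = welch)$p_value,
          starve_vs_B = ttest(groups$starve, groups$B, welch = welch)$p_value,
          starve_vs_AB = ttest(groups$starve, groups$AB, welch = welch)$p_value,
          A_vs_AB = ttest(groups$A, groups$AB, welch = welch)$p_value,
          B_vs_AB = ttest(groups$B, groups$AB, welch = welch)$p_value)

  single_folds <- if (!is.null(fold)) {
    if (length(fold) != length(condition))
      abort_validation("`fold` must match `condition` in length")
    fg <- split(fold, factor(condition, levels = need))
    c(A = mean(fg$A), B = mean(fg$B))
  } else c(A = NA_real_, B = NA_real_)

  folds_weak <- is.null(fold) ||
    (single_folds[["A"]] < tau && single_folds[["B"]] < tau)
  and_like <- S > 0 && pv[["A_vs_AB"]] < alpha && pv[["B_vs_AB"]] < alpha &&
    folds_weak
  single_driven <- (!is.null(fold) && max(single_folds) >= tau) ||
    means[["A"]] >= 0.9 * means[["AB"]] || means[["B"]] >= 0.9 * means[["AB"]]
  classification <- if (and_like) "AND-like"
    else if (single_driven) "single-input-driven" else "additive"

  structure(list(means = means,
                 n = vapply(groups, length, integer(1)),
                 synergy = unname(S),
                 single_folds = single_folds,
                 p_values = pv,
                 stars = vapply(pv, p_stars, character(1)),
                 tau = tau, alpha = alpha,
                 classification = classification),
            class = "gate_report")
}

#' Write a gate report as JSON
#' @param report A `gate_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gate_report <- function(report, path) {
  jsonlite::write_json(list(
    means = as.list(report$means),
    n = as.list(report$n),
    synergy = report$synergy,
    single_input_folds = as.list(report$single_folds),
    p_values = as.list(report$p_values),
    stars = as.list(report$stars),
    tau = report$tau, alpha = report$alpha,
    classification = report$classification,
    note = paste("AND-like classification rule (synergy > 0, combination",
                 "significantly above each single input, weak single-input",
                 "folds) is this package's operational definition")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("<ttest_result> %s t = %.4g, df = %.4g, p = %.4g\n",
              if (x$paired) "paired" else "unpaired",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
print.gate_report <- function(x, ...) {
  cat("<gate_report>\n  mean AUC: ",
      paste(sprintf("%s=%.4g (n=%d)", names(x$means), x$means, x$n),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  synergy S = %.4g\n", x$synergy))
  if (!anyNA(x$single_folds))
    cat(sprintf("  single-input folds: A=%.3g, B=%.3g (tau=%.2g)\n",
                x$single_folds[["A"]], x$single_folds[["B"]], x$tau))
  for (nm in names(x$p_values))
    cat(sprintf("  %-12s p = %.3g %s\n", nm, x$p_values[[nm]], x$stars[[nm]]))
  cat("  classification:", x$classification, "\n")
  invisible(x)
}
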