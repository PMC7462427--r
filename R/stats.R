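#' One-sample t test against zero, with degenerate-input handling
#'
#' Classical two-sided one-sample t test of the mean against `mu`. A
#' zero-variance sample is flagged as degenerate (statistic and p set to
#' `NA`) rather than reported as an extreme p value.
#'
#' @param x Numeric vector, length >= 2, finite.
#' @param mu Null mean (default 0).
#' @return One-row tibble: `estimate`, `statistic`, `df`, `p_value`,
#'   `degenerate`.
#' @export
one_sample_t <- function(x, mu = 0) {
  if (length(x) < 2 || !all(is.finite(x))) {
    stopf("`x` must contain at least 2 finite values")
  }
  stderr <- stats::sd(x) / sqrt(length(x))
  if (stderr < 10 * .Machine$double.eps * max(1, abs(mean(x)))) {
    return(tibble::tibble(estimate = mean(x), statistic = NA_real_,
                          df = length(x) - 1L, p_value = NA_real_,
                          degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = mu)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 degenerate = FALSE)
}

#' Paired t test as a one-sample test of differences
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return One-row tibble as in [one_sample_t()].
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stopf("`a` and `b` must have equal length")
  one_sample_t(a - b)
}

#' Bonferroni significance flags
#'
#' Significance at familywise level 0.05 over a family of tests:
#' significant iff `p < 0.05 / family_size` (strict inequality; a family
#' of 10 community pairs yields the corrected threshold 0.005).
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @param family_size Number of tests in the family (default
#'   `length(pvals)`).
#' @param alpha Familywise level (default 0.05).
#' @return Tibble: `p_value`, `alpha_corrected`, `significant`.
#' @export
bonferroni <- function(pvals, family_size = length(pvals), alpha = 0.05) {
  stopifnot(family_size >= 1, all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  thr <- alpha / family_size
  tibble::tibble(p_value = pvals, alpha_corrected = thr,
                 significant = !is.na(pvals) & pvals < thr)
}

#' Benjamini-Yekutieli false discovery rate
#'
#' Step-up FDR control valid under arbitrary dependence, i.e. the
#' Benjamini-Hochberg procedure with the harmonic-sum correction factor
#' `c(m) = sum_{i=1}^m 1/i`. Adjusted values are monotone nonincreasing
#' from the largest rank and capped at 1.
#'
#' @param pvals Numeric p values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Tibble: `p_value`, `adjusted`, `significant`
#'   (`adjusted <= q`).
#' @export
fdr_by <- function(pvals, q = 0.05) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(pvals, method = "BY")
  tibble::tibble(p_value = pvals, adjusted = adj,
                 significant = !is.na(adj) & adj <= q)
}
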