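#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test as used for all group
#' comparisons in the pipeline.  For small tie-free samples (combined n of 12
#' or fewer) the p-value comes from the exact null distribution of the
#' Mann-Whitney U statistic, with the two-sided p obtained by doubling the
#' smaller tail and capping at 1.  Larger or tied samples use the
#' tie-corrected normal approximation.  The study's group sizes (3-6 per
#' group) sit squarely in the exact regime.
#'
#' @param a,b Numeric vectors of observations, one per group.
#' @return An object of class `ranksum`: a list with `statistic` (the
#'   Mann-Whitney U for `a`), `p.value` (two-sided), and `method`
#'   (`"exact"` or `"normal-approx"`).
#' @examples
#' wilcoxon_rank_sum(c(7, 8, 9, 10, 11, 12), c(1, 2, 3, 4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1)
    stop("both groups must contain at least one observation")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite observations")
  n <- length(a); m <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && (n + m) <= 12L) {
    lower <- stats::pwilcox(U, n, m)
    upper <- 1 - stats::pwilcox(U - 1, n, m)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * m / 2
    tab <- table(r)
    nt <- n + m
    sigma2 <- n * m / 12 * ((nt + 1) - sum(tab^3 - tab) / (nt * (nt - 1)))
    z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(statistic = U, p.value = p, method = method),
            class = "ranksum")
}

#' @export
print.ranksum <- function(x, ...) {
  cat("Wilcoxon rank-sum test (", x$method, ")\n", sep = "")
  cat("  U = ", x$statistic, ", two-sided p = ",
      format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param family_alpha Family-wise error rate (e.g. 0.05).
#' @param m Number of tests in the family.
#' @return `family_alpha / m`.  For seven frequency bands or seven genes at
#'   alpha 0.05 this gives 0.00714..., the `P < 0.007` bound quoted for the
#'   band-power and qPCR comparisons.
#' @export
bonferroni_alpha <- function(family_alpha, m) {
  stopifnot(family_alpha > 0, family_alpha <= 1, m >= 1)
  family_alpha / m
}
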