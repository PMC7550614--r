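#' 2x2 chi-square test with Yates continuity correction
#'
#' Pearson chi-square on a 2x2 table of counts with continuity correction
#' (statistic `sum(max(|O-E|-0.5, 0)^2 / E)`, df = 1, upper-tail p). This is
#' the test that reproduces the baseline-table p-values computed from printed
#' group counts.
#'
#' @param a,b,c,d cell counts: rows are groups, columns outcome yes/no, i.e.
#'   the table is `rbind(c(a, b), c(c, d))`.
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_yates <- function(a, b, c, d) {
  t <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(t < 0) || sum(t) < 1) stop("cell counts must be non-negative, total >= 1")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("a table margin is zero; use fisher_exact() instead")
  ht <- suppressWarnings(stats::chisq.test(t, correct = TRUE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p as the sum of hypergeometric probabilities of tables (with the
#' observed margins) no more probable than the observed one. Fallback for
#' sparse tables where the chi-square approximation fails.
#'
#' @inheritParams chi2_yates
#' @return list with `p`.
#' @export
fisher_exact <- function(a, b, c, d) {
  t <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  if (any(t < 0)) stop("cell counts must be non-negative")
  list(p = stats::fisher.test(t)$p.value)
}

#' Pooled two-sample t-test from group summaries
#'
#' Student's t with pooled variance from printed means, SDs and group sizes;
#' df = n1 + n2 - 2, two-sided p. Set `welch = TRUE` for the unequal-variance
#' (Welch-Satterthwaite) variant.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @param welch use Welch's t instead of pooled (default FALSE).
#' @return list with `statistic`, `df`, `p`.
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                  welch = FALSE) {
  if (sd1 < 0 || sd2 < 0) stop("sd must be non-negative")
  if (n1 + n2 < 3) stop("n1 + n2 must be >= 3")
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(statistic = 0, df = n1 + n2 - 2, p = 1))
    warning("both SDs are zero with unequal means; p set to 0")
    return(list(statistic = Inf, df = n1 + n2 - 2, p = 0))
  }
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
    t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
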