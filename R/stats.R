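# Two-group comparisons with exact small-sample behaviour: Welch t test and
# the Wilcoxon rank-sum (Mann-Whitney) test with exact enumeration for small
# samples.  Alternatives are relative to group A: "greater" tests whether A
# is shifted above B.

test_result <- function(statistic, p_value, alternative, method, nA, nB,
                        warning_msg = NULL) {
  structure(list(statistic = statistic, p_value = p_value,
                 alternative = alternative, method = method,
                 n = c(nA = nA, nB = nB), warning = warning_msg),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g (%s; n = %d, %d)\n",
              x$method, x$statistic, x$p_value, x$alternative,
              x$n[["nA"]], x$n[["nB"]]))
  if (!is.null(x$warning)) cat("  note:", x$warning, "\n")
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees of
#' freedom.  With zero variance in both groups and equal means the comparison
#' is uninformative and p = 1 is reported.
#'
#' @param groupA,groupB numeric vectors (each n >= 2).
#' @param alternative "two_sided" (default), "greater" (A > B) or "less".
#' @return a `test_result`.
#' @export
t_test <- function(groupA, groupB,
                   alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  nA <- length(groupA); nB <- length(groupB)
  stopifnot(nA >= 2, nB >= 2)
  vA <- stats::var(groupA); vB <- stats::var(groupB)
  delta <- mean(groupA) - mean(groupB)
  if (vA == 0 && vB == 0) {
    if (delta == 0) {
      return(test_result(0, 1, alternative, "Welch t test", nA, nB,
                         "zero variance in both groups"))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  se <- sqrt(vA / nA + vB / nB)
  tstat <- delta / se
  df <- se^4 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- switch(alternative,
              two_sided = 2 * stats::pt(-abs(tstat), df),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  test_result(tstat, p, alternative, "Welch t test", nA, nB)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' The statistic is the Mann-Whitney U for group A.  For combined sample
#' sizes up to `exact_limit` (default 20) the p-value is exact, by full
#' enumeration of all `choose(nA + nB, nA)` assignments of the (mid-)ranks to
#' group A — valid with ties, since enumeration is over the observed rank
#' multiset.  Larger samples use the normal approximation with tie-corrected
#' variance and continuity correction.  When every value is tied across both
#' groups, p = 1 is reported with a tie note.
#'
#' @param groupA,groupB numeric vectors (each n >= 1).
#' @param alternative "two_sided" (default), "greater" (A shifted above B) or
#'   "less".
#' @param exact_limit maximum combined n for exact enumeration.
#' @return a `test_result` with the U statistic for group A.
#' @export
rank_sum_test <- function(groupA, groupB,
                          alternative = c("two_sided", "greater", "less"),
                          exact_limit = 20L) {
  alternative <- match.arg(alternative)
  nA <- length(groupA); nB <- length(groupB)
  stopifnot(nA >= 1, nB >= 1)
  all_v <- c(groupA, groupB)
  r <- rank(all_v) # mid-ranks for ties
  wA <- sum(r[seq_len(nA)])
  uA <- wA - nA * (nA + 1) / 2
  if (length(unique(all_v)) == 1L) {
    return(test_result(uA, 1, alternative, "Wilcoxon rank-sum test", nA, nB,
                       "all values tied across groups"))
  }
  n <- nA + nB
  if (n <= exact_limit) {
    sets <- utils::combn(n, nA)
    ws <- colSums(matrix(r[sets], nrow = nA))
    eps <- 1e-9
    p_ge <- mean(ws >= wA - eps)
    p_le <- mean(ws <= wA + eps)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two_sided = min(1, 2 * min(p_ge, p_le)))
    method <- "Wilcoxon rank-sum test (exact)"
  } else {
    mu <- nA * nB / 2
    ties <- table(r)
    sigma2 <- nA * nB / 12 * (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z_g <- (uA - mu - 0.5) / sigma
    z_l <- (uA - mu + 0.5) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l),
                two_sided = min(1, 2 * min(stats::pnorm(z_g, lower.tail = FALSE),
                                           stats::pnorm(z_l))))
    method <- "Wilcoxon rank-sum test (normal approximation)"
  }
  test_result(uA, p, alternative, method, nA, nB)
}

#' Holm correction across category comparisons
#'
#' Off by default in cohort reporting (per-category p-values are reported
#' uncorrected); provided for sensitivity analyses.
#'
#' @param p numeric vector of p-values.
#' @return Holm-adjusted p-values.
#' @export
holm_adjust <- function(p) stats::p.adjust(p, method = "holm")

#' Tidy several test results into a table
#'
#' @param results named list of `test_result` objects.
#' @return data frame: comparison, method, alternative, statistic, p.
#' @export
test_results_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(comparison = nm, method = x$method,
               alternative = x$alternative,
               statistic = x$statistic, p = x$p_value)
  }))
}
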