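#' Recover a log-scale estimate from a printed odds ratio and 95% CI
#'
#' `beta = ln(OR)` and `se = (ln(upper) - ln(lower)) / (2 * 1.96)`, using
#' 1.96 exactly (not 1.959964) to match the 1.96-sigma confidence-limit
#' convention used throughout the package, so that two-decimal printed CIs
#' reconstruct consistently.
#'
#' @param orPoint point odds ratio (> 0).
#' @param ciLow,ciHigh 95% confidence limits, `0 < ciLow <= orPoint <=
#'   ciHigh` with `ciLow < ciHigh`.
#' @return list with `beta` and `se`.
#' @examples
#' seFromCI(1.37, 1.07, 1.76)
#' @export
seFromCI <- function(orPoint, ciLow, ciHigh) {
  if (any(!is.finite(c(orPoint, ciLow, ciHigh))) || ciLow <= 0)
    stop("odds ratio and confidence limits must be positive finite", call. = FALSE)
  if (ciLow > orPoint || orPoint > ciHigh)
    stop("require ciLow <= orPoint <= ciHigh", call. = FALSE)
  se <- (log(ciHigh) - log(ciLow)) / (2 * 1.96)
  if (se <= 0) stop("degenerate confidence interval: se must be > 0", call. = FALSE)
  list(beta = log(orPoint), se = se)
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Combines independent estimates of the same (log-scale) effect with
#' weights `1/se^2`: the pooled estimate is the weighted mean, the pooled
#' standard error `1/sqrt(sum w)`, and the p-value two-sided normal. Used
#' to combine discovery- and replication-stage causal estimates; a single
#' input estimate is returned unchanged.
#'
#' @param beta numeric vector of estimates (log-OR or SD scale).
#' @param se numeric vector of their standard errors (> 0).
#' @return an [MREstimate-class] with method `"fixed_effect_meta"`.
#' @export
fixedEffectMeta <- function(beta, se) {
  if (!length(beta)) stop("no estimates to combine", call. = FALSE)
  if (length(beta) != length(se) || any(!is.finite(se) | se <= 0))
    stop("each estimate needs a positive finite se", call. = FALSE)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  newMREstimate("fixed_effect_meta", beta = b, se = s, nSNPs = length(beta))
}

#' Between-group heterogeneity (Cochran's Q on cohort estimates)
#'
#' Q is the inverse-variance-weighted sum of squared deviations of the
#' per-cohort estimates from the fixed-effect pooled estimate, referred to
#' chi-square with `k - 1` degrees of freedom. Used for between-cohort
#' heterogeneity of causal effect estimates.
#'
#' @param beta,se per-cohort estimates and standard errors (k >= 2).
#' @return list with `Q`, `df` and `pval`.
#' @export
betweenGroupQ <- function(beta, se) {
  if (length(beta) < 2L)
    stop("between-group Q requires at least 2 estimates", call. = FALSE)
  if (length(beta) != length(se) || any(!is.finite(se) | se <= 0))
    stop("each estimate needs a positive finite se", call. = FALSE)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b)^2)
  df <- length(beta) - 1L
  list(Q = Q, df = df, pval = stats::pchisq(Q, df = df, lower.tail = FALSE))
}
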