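.extractEffects <- function(data) {
  p <- harmonizedPairs(data)
  if (any(p$beta_exp == 0))
    stop("degenerate instrument (beta_exp == 0): ",
         paste(p$variant_id[p$beta_exp == 0], collapse = ", "), call. = FALSE)
  list(id = p$variant_id, bx = p$beta_exp, sx = p$se_exp,
       by = p$beta_out, sy = p$se_out, k = nrow(p))
}

# per-variant Wald ratios and first-order inverse-variance weights
.ratios <- function(e) list(r = e$by / e$bx, w = (e$bx / e$sy)^2)

#' Wald ratio estimator (single instrument)
#'
#' The causal effect from one instrument is the ratio of the outcome to the
#' exposure association, `beta_out / beta_exp`, with first-order
#' (outcome-noise-only) delta-method standard error `se_out / |beta_exp|`.
#' Invariant under simultaneous re-orientation of both effects.
#'
#' @param data a [HarmonizedData-class] object with exactly one pair.
#' @return an [MREstimate-class] with method `"wald_ratio"`.
#' @export
mrWaldRatio <- function(data) {
  e <- .extractEffects(data)
  if (e$k != 1L)
    stop("wald ratio requires exactly one instrument, got ", e$k, call. = FALSE)
  newMREstimate("wald_ratio", beta = e$by / e$bx, se = e$sy / abs(e$bx),
                nSNPs = 1L)
}

#' Inverse-variance-weighted (IVW) estimator
#'
#' Combines per-instrument Wald ratios `r_j = beta_out,j / beta_exp,j` with
#' weights `w_j = (beta_exp,j / se_out,j)^2` (first-order inverse variance
#' of each ratio), equivalent to weighted regression of the outcome on the
#' exposure effects through the origin. The fixed-effect standard error is
#' `1/sqrt(sum w)`; the multiplicative random-effects variant inflates it by
#' the overdispersion factor `max(1, sqrt(Q/(k-1)))` with Cochran's Q taken
#' about the pooled estimate — the convention of the TwoSampleMR ecosystem.
#' With one instrument the fixed-effect IVW reduces exactly to the Wald
#' ratio.
#'
#' @param data a [HarmonizedData-class] object.
#' @param variant `"fixed"` or `"multiplicative_random"`.
#' @return an [MREstimate-class] with method `"ivw_fe"` or `"ivw_mre"`,
#'   carrying Q and its p-value when k >= 2.
#' @export
mrIVW <- function(data, variant = c("fixed", "multiplicative_random")) {
  variant <- match.arg(variant)
  e <- .extractEffects(data)
  if (e$k < 1L) stop("no instruments", call. = FALSE)
  if (variant == "multiplicative_random" && e$k < 2L)
    stop("multiplicative random-effects IVW requires k >= 2", call. = FALSE)
  if (e$k == 1L)  # exact reduction to the Wald ratio, bit for bit
    return(newMREstimate("ivw_fe", beta = e$by / e$bx,
                         se = e$sy / abs(e$bx), nSNPs = 1L))
  rw <- .ratios(e)
  beta <- sum(rw$w * rw$r) / sum(rw$w)
  se_fe <- 1 / sqrt(sum(rw$w))
  Q <- sum(rw$w * (rw$r - beta)^2)
  df <- e$k - 1L
  qp <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  if (variant == "fixed")
    return(newMREstimate("ivw_fe", beta = beta, se = se_fe, nSNPs = e$k,
                         qStat = Q, qPval = qp))
  phi <- max(1, sqrt(Q / df))
  newMREstimate("ivw_mre", beta = beta, se = se_fe * phi, nSNPs = e$k,
                qStat = Q, qPval = qp, details = list(overdispersion = phi))
}

#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the per-instrument ratio estimates
#' from a given center (typically the pooled IVW estimate), with weights
#' `(beta_exp/se_out)^2`; referred to a chi-square with `k - 1` degrees of
#' freedom. Substantial heterogeneity between instrument-specific causal
#' estimates is indicative of horizontal pleiotropy.
#'
#' @param data a [HarmonizedData-class] object with k >= 2 pairs.
#' @param center value to measure deviations from; defaults to the
#'   fixed-effect IVW estimate.
#' @return list with `Q`, `df` and `pval`.
#' @export
cochransQ <- function(data, center = NULL) {
  e <- .extractEffects(data)
  if (e$k < 2L) stop("Cochran's Q requires at least 2 instruments", call. = FALSE)
  rw <- .ratios(e)
  if (is.null(center)) center <- sum(rw$w * rw$r) / sum(rw$w)
  Q <- sum(rw$w * (rw$r - center)^2)
  df <- e$k - 1L
  list(Q = Q, df = df, pval = stats::pchisq(Q, df = df, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1/se_out^2`, after orienting all exposure
#' effects non-negative. The slope is a causal estimate that remains
#' consistent in the presence of invalid instruments provided the InSIDE
#' assumption (instrument strength independent of direct effects) holds;
#' the intercept estimates the average directional pleiotropic effect.
#' Standard errors come from the WLS covariance with multiplicative
#' overdispersion `max(1, sqrt(RSS_w/(k-2)))`, and p-values use a t
#' reference with `k - 2` degrees of freedom (small-k regression
#' inference).
#'
#' @param data a [HarmonizedData-class] object with k >= 3 pairs.
#' @return list with `slope` and `intercept`, both [MREstimate-class].
#' @export
mrEgger <- function(data) {
  e <- .extractEffects(data)
  if (e$k < 3L) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(e$bx)
  bx <- abs(e$bx); by <- e$by * flip
  if (stats::sd(bx) == 0)
    stop("zero variance in exposure effects: Egger regression is collinear",
         call. = FALSE)
  fit <- stats::lm(by ~ bx, weights = 1 / e$sy^2)
  sm <- summary(fit)
  co <- sm$coefficients
  # lm's se already carries sigma-hat; dividing by min(1, sigma) yields the
  # max(1, sigma) multiplicative-overdispersion convention
  adj <- min(1, sm$sigma)
  se_int <- co["(Intercept)", "Std. Error"] / adj
  se_slo <- co["bx", "Std. Error"] / adj
  df <- e$k - 2L
  list(
    slope = newMREstimate("egger_slope", beta = unname(co["bx", "Estimate"]),
                          se = se_slo, nSNPs = e$k, df = df,
                          details = list(overdispersion = max(1, sm$sigma))),
    intercept = newMREstimate("egger_intercept",
                              beta = unname(co["(Intercept)", "Estimate"]),
                              se = se_int, nSNPs = e$k, df = df,
                              details = list(overdispersion = max(1, sm$sigma))))
}

# weighted-median point estimate on ratio estimates r with weights w
.weightedMedianCore <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(r[1L])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap SE shared by weighted median and mode: perturb both
# betas by their standard errors, recompute the point estimate
.bootstrapSE <- function(e, pointFun, nBoot, seed) {
  if (!is.null(seed)) set.seed(seed)
  ests <- vapply(seq_len(nBoot), function(b) {
    bx <- e$bx + stats::rnorm(e$k, 0, e$sx)
    by <- e$by + stats::rnorm(e$k, 0, e$sy)
    bx[bx == 0] <- .Machine$double.eps
    pointFun(by / bx, (bx / e$sy)^2)
  }, numeric(1))
  stats::sd(ests)
}

#' Weighted median estimator
#'
#' The weighted median of the per-instrument ratio estimates, consistent
#' when instruments carrying more than half of the (inverse-variance)
#' weight are valid, and robust to outlying instruments. Ratios are ordered
#' and the estimate interpolates them linearly at cumulative weight 0.5
#' (with `s_j = sum_{i<=j} w'_i - w'_j/2` for normalized weights). The
#' standard error is the standard deviation of the estimate over `nBoot`
#' parametric-bootstrap resamples in which each pair's betas are perturbed
#' by their standard errors.
#'
#' @param data a [HarmonizedData-class] object with k >= 3 pairs.
#' @param nBoot bootstrap resamples (default 5000).
#' @param seed RNG seed for the bootstrap; supply one for reproducibility.
#' @return an [MREstimate-class] with method `"weighted_median"`.
#' @export
mrWeightedMedian <- function(data, nBoot = 5000, seed = NULL) {
  e <- .extractEffects(data)
  if (e$k < 3L) stop("weighted median requires at least 3 instruments", call. = FALSE)
  rw <- .ratios(e)
  beta <- .weightedMedianCore(rw$r, rw$w)
  se <- .bootstrapSE(e, .weightedMedianCore, nBoot, seed)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  newMREstimate("weighted_median", beta = beta, se = se, nSNPs = e$k,
                details = list(n_boot = nBoot))
}

# weighted kernel-density mode; ties resolve to the smaller mode because the
# evaluation grid ascends and which.max takes the first maximum
.weightedModeCore <- function(bandwidthFactor) {
  function(r, w) {
    if (length(unique(r)) == 1L) return(r[1L])
    h <- bandwidthFactor * 0.9 * stats::mad(r) / length(r)^0.2
    if (h <= 0) h <- bandwidthFactor * 0.9 * stats::sd(r) / length(r)^0.2
    if (h <= 0) return(stats::median(r))
    d <- stats::density(r, weights = w / sum(w), bw = h, n = 1024)
    d$x[which.max(d$y)]
  }
}

#' Weighted mode estimator
#'
#' The mode of a weighted Gaussian kernel density over the per-instrument
#' ratio estimates, consistent when the largest group of instruments
#' sharing the same causal estimate is valid. The bandwidth is
#' `bandwidthFactor` times a robust spread measure
#' (`0.9 * mad(r) / k^(1/5)`); exact symmetric ties resolve
#' deterministically to the smaller mode value. Standard error by
#' parametric bootstrap as in [mrWeightedMedian()].
#'
#' @param data a [HarmonizedData-class] object with k >= 3 pairs.
#' @param bandwidthFactor bandwidth multiplier (default 1); reported in the
#'   estimate's details so sensitivity to it can be assessed.
#' @param nBoot bootstrap resamples (default 5000).
#' @param seed RNG seed for the bootstrap.
#' @return an [MREstimate-class] with method `"weighted_mode"`.
#' @export
mrWeightedMode <- function(data, bandwidthFactor = 1, nBoot = 5000,
                           seed = NULL) {
  e <- .extractEffects(data)
  if (e$k < 3L) stop("weighted mode requires at least 3 instruments", call. = FALSE)
  rw <- .ratios(e)
  core <- .weightedModeCore(bandwidthFactor)
  beta <- core(rw$r, rw$w)
  se <- .bootstrapSE(e, core, nBoot, seed)
  if (!is.finite(se) || se <= 0) se <- .Machine$double.eps
  newMREstimate("weighted_mode", beta = beta, se = se, nSNPs = e$k,
                details = list(n_boot = nBoot,
                               bandwidth_factor = bandwidthFactor))
}

#' Choose the main estimator and sensitivity set from the instrument count
#'
#' One instrument: Wald ratio. Two or three: fixed-effect IVW. Four or
#' more: multiplicative random-effects IVW, with the sensitivity analyses
#' (weighted median and MR-Egger) attached — they require at least four
#' instruments.
#'
#' @param k number of instruments (>= 1).
#' @param outcomeMode `"binary_primary"` or `"continuous_pdff"`; recorded in
#'   the plan so downstream reporting knows whether to exponentiate to an
#'   odds-ratio scale. The selection rules are identical for both.
#' @return list with `main` (`"wald_ratio"` or `"ivw"`), `variant`
#'   (`"fixed"` or `"multiplicative_random"`, NA for Wald), `sensitivity`
#'   (character vector) and `outcomeMode`.
#' @export
selectMainMethod <- function(k, outcomeMode = c("binary_primary",
                                                "continuous_pdff")) {
  outcomeMode <- match.arg(outcomeMode)
  if (k < 1L) stop("no instruments available", call. = FALSE)
  if (k == 1L)
    return(list(main = "wald_ratio", variant = NA_character_,
                sensitivity = character(), outcomeMode = outcomeMode))
  if (k <= 3L)
    return(list(main = "ivw", variant = "fixed", sensitivity = character(),
                outcomeMode = outcomeMode))
  list(main = "ivw", variant = "multiplicative_random",
       sensitivity = c("weighted_median", "mr_egger"),
       outcomeMode = outcomeMode)
}
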