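#' @import methods
NULL

# canonical column set for a summary-statistics table; eaf/n/pval/z optional
.SUMSTAT_COLS <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")

#' SummaryStats: per-variant GWAS summary associations for one trait
#'
#' Container for one trait's GWAS summary statistics, one row per variant.
#' Effects on binary traits are carried on the log odds-ratio scale
#' throughout; odds ratios appear only in reporting output.
#'
#' @slot traitName single character, trait label.
#' @slot traitType `"continuous"` or `"binary"`. Binary implies `beta` is a
#'   log-OR.
#' @slot variants data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` and `n` may be `NA` (outcome GWASs often omit them).
#'
#' @export
setClass("SummaryStats",
  representation(traitName = "character", traitType = "character",
                 variants = "data.frame"))

setValidity("SummaryStats", function(object) {
  msg <- character()
  if (length(object@traitName) != 1L) msg <- c(msg, "traitName must be length 1")
  if (!object@traitType %in% c("continuous", "binary"))
    msg <- c(msg, "traitType must be 'continuous' or 'binary'")
  v <- object@variants
  missing_cols <- setdiff(.SUMSTAT_COLS, names(v))
  if (length(missing_cols))
    return(paste("variants lacks columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(v$variant_id))
    msg <- c(msg, "duplicate variant_id in variants")
  if (nrow(v)) {
    if (any(!is.finite(v$se) | v$se <= 0)) msg <- c(msg, "all se must be > 0")
    bad_eaf <- !is.na(v$eaf) & (v$eaf <= 0 | v$eaf >= 1)
    if (any(bad_eaf)) msg <- c(msg, "eaf must lie in (0,1) when present")
    alleles_ok <- grepl("^[ACGT]$", v$effect_allele) & grepl("^[ACGT]$", v$other_allele)
    if (any(!alleles_ok)) msg <- c(msg, "alleles must be single uppercase A/C/G/T")
    if (any(v$effect_allele == v$other_allele))
      msg <- c(msg, "effect_allele must differ from other_allele")
    bad_p <- !is.na(v$pval) & (v$pval <= 0 | v$pval > 1)
    if (any(bad_p)) msg <- c(msg, "pval must lie in (0,1] when present")
  }
  if (length(msg)) msg else TRUE
})

#' LDTable: pairwise linkage-disequilibrium r-squared with positions
#'
#' Sparse symmetric store of pairwise r² between variants, with per-variant
#' genomic positions so that window semantics (|pos_i - pos_j| <= window on
#' the same chromosome) can be applied. Pairs not stored are taken as r² = 0
#' by consumers (with a logged warning where the pair falls inside a clumping
#' window). An optional `sign` column carries the sign of the underlying
#' dosage correlation, used to orient proxy variants.
#'
#' @slot pairs data.frame with columns `id_a`, `id_b`, `r2` and optionally
#'   `sign`; stored with `id_a < id_b` so each unordered pair appears once.
#' @slot positions data.frame with columns `variant_id`, `chrom`, `pos`.
#'
#' @export
setClass("LDTable",
  representation(pairs = "data.frame", positions = "data.frame"))

setValidity("LDTable", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("id_a", "id_b", "r2") %in% names(p)))
    return("pairs needs columns id_a, id_b, r2")
  if (!all(c("variant_id", "chrom", "pos") %in% names(object@positions)))
    return("positions needs columns variant_id, chrom, pos")
  if (nrow(p)) {
    if (any(p$r2 < 0 | p$r2 > 1, na.rm = TRUE)) msg <- c(msg, "r2 must lie in [0,1]")
    if (any(p$id_a == p$id_b)) msg <- c(msg, "self-pairs must not be stored (r2(v,v)=1 implied)")
    if (any(p$id_a > p$id_b)) msg <- c(msg, "pairs must be stored with id_a < id_b")
    if (anyDuplicated(paste(p$id_a, p$id_b))) msg <- c(msg, "duplicate pair entries")
  }
  if (anyDuplicated(object@positions$variant_id)) msg <- c(msg, "duplicate positions")
  if (length(msg)) msg else TRUE
})

#' InstrumentSet: selected genetic instruments for one exposure
#'
#' @slot exposureName exposure trait label.
#' @slot variants data.frame in `SummaryStats` column layout; every row
#'   passed the significance threshold and survived LD clumping.
#' @slot settings list recording the selection parameters (threshold, clump
#'   r², window) for provenance.
#'
#' @export
setClass("InstrumentSet",
  representation(exposureName = "character", variants = "data.frame",
                 settings = "list"))

#' HarmonizedData: exposure/outcome effects aligned to a common allele
#'
#' Result of merging instrument-exposure and instrument-outcome associations:
#' per retained variant, both betas are expressed per copy of the same
#' effect allele. Variants that could not be harmonized are recorded in
#' `dropped` with a reason; `pairs` and `dropped` partition the instruments
#' attempted.
#'
#' @slot exposureName,outcomeName trait labels.
#' @slot outcomeType `"continuous"` or `"binary"`.
#' @slot pairs data.frame with columns `variant_id`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `proxy_id` (NA unless a proxy supplied
#'   the outcome association), `action_log`.
#' @slot dropped data.frame with columns `variant_id`, `reason`.
#'
#' @export
setClass("HarmonizedData",
  representation(exposureName = "character", outcomeName = "character",
                 outcomeType = "character", pairs = "data.frame",
                 dropped = "data.frame"))

setValidity("HarmonizedData", function(object) {
  msg <- character()
  need <- c("variant_id", "beta_exp", "se_exp", "beta_out", "se_out",
            "eaf_exp", "proxy_id", "action_log")
  if (!all(need %in% names(object@pairs)))
    return(paste("pairs needs columns:", paste(need, collapse = ", ")))
  if (!all(c("variant_id", "reason") %in% names(object@dropped)))
    return("dropped needs columns variant_id, reason")
  p <- object@pairs
  if (nrow(p) && any(p$se_exp <= 0 | p$se_out <= 0))
    msg <- c(msg, "standard errors must be > 0")
  if (!object@outcomeType %in% c("continuous", "binary"))
    msg <- c(msg, "outcomeType must be 'continuous' or 'binary'")
  if (length(msg)) msg else TRUE
})

#' MREstimate: one causal-effect estimate with diagnostics
#'
#' @slot method estimator label: one of `"wald_ratio"`, `"ivw_fe"`,
#'   `"ivw_mre"`, `"egger_slope"`, `"egger_intercept"`, `"weighted_median"`,
#'   `"weighted_mode"`, `"fixed_effect_meta"`.
#' @slot beta point estimate (log-OR per SD of exposure for binary outcomes,
#'   SD per SD for continuous).
#' @slot se standard error.
#' @slot ciLow,ciHigh `beta -/+ 1.96 * se`.
#' @slot pval two-sided p-value (normal reference; t(k-2) for Egger).
#' @slot nSNPs number of instruments used.
#' @slot qStat,qPval Cochran's Q heterogeneity statistic and chi-square
#'   upper-tail p (NA where not applicable).
#' @slot details list of estimator-specific metadata (overdispersion factor,
#'   bootstrap count, bandwidth, ...).
#'
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 nSNPs = "integer", qStat = "numeric", qPval = "numeric",
                 details = "list"))

setValidity("MREstimate", function(object) {
  msg <- character()
  ok_methods <- c("wald_ratio", "ivw_fe", "ivw_mre", "egger_slope",
                  "egger_intercept", "weighted_median", "weighted_mode",
                  "fixed_effect_meta")
  if (!object@method %in% ok_methods)
    msg <- c(msg, paste("unknown method", object@method))
  if (!is.na(object@se) && object@se <= 0) msg <- c(msg, "se must be > 0")
  if (is.finite(object@beta) && is.finite(object@se)) {
    if (abs(object@ciLow - (object@beta - 1.96 * object@se)) > 1e-8 ||
        abs(object@ciHigh - (object@beta + 1.96 * object@se)) > 1e-8)
      msg <- c(msg, "confidence limits must equal beta -/+ 1.96*se")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticStudy: generated two-sample GWAS with known ground truth
#'
#' @slot exposure,outcome `SummaryStats` for the two (non-overlapping)
#'   samples.
#' @slot truth list holding `theta` (true causal effect), `beta_exp_true`,
#'   `alpha` (per-variant direct pleiotropic effects on the outcome),
#'   `valid` (logical: alpha == 0), and the generating `config`.
#' @slot ld `LDTable` (possibly empty when no LD structure was simulated).
#'
#' @export
setClass("SyntheticStudy",
  representation(exposure = "SummaryStats", outcome = "SummaryStats",
                 truth = "list", ld = "LDTable"))
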