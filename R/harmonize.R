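#' Align one outcome association to the exposure's effect allele
#'
#' Expresses the outcome effect per copy of the exposure's effect allele.
#' Matching is attempted as-reported, then with swapped alleles (outcome
#' beta negated, outcome frequency complemented), then after strand
#' complementing the outcome alleles (multi-cohort GWAS sources mix strand
#' conventions), then complement + swap. Palindromic variants (A/T or C/G)
#' cannot be resolved from alleles alone and are handled by policy:
#' `"drop_all"` (default, mirroring the removal of ambiguous palindromes in
#' practice) drops them; `"frequency_inference"` aligns them by comparing
#' allele frequencies, dropping variants whose frequency is inside the
#' ambiguity band (`min(eaf, 1-eaf) > ambiguityBand`) or lacks an outcome
#' frequency. Irreconcilable alleles drop with reason `"allele_mismatch"`.
#'
#' @param exp,out named lists or one-row data.frames with fields
#'   `effect_allele`, `other_allele`, `beta`, `se` and optionally `eaf`.
#' @param palindromePolicy `"drop_all"` or `"frequency_inference"`.
#' @param ambiguityBand frequency band half-width for
#'   `"frequency_inference"` (default 0.42: drop when the minor-allele
#'   frequency exceeds 0.42 on either side).
#' @return list with either `$pair` (fields `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`, `eaf_exp`, `action_log`) or `$drop` (the reason).
#' @export
harmonizePair <- function(exp, out,
                          palindromePolicy = c("drop_all", "frequency_inference"),
                          ambiguityBand = 0.42) {
  palindromePolicy <- match.arg(palindromePolicy)
  e_ea <- toupper(exp$effect_allele); e_oa <- toupper(exp$other_allele)
  o_ea <- toupper(out$effect_allele); o_oa <- toupper(out$other_allele)
  for (a in list(c(e_ea, "exposure effect_allele"), c(e_oa, "exposure other_allele"),
                 c(o_ea, "outcome effect_allele"), c(o_oa, "outcome other_allele")))
    .checkAllele(a[1L], a[2L])

  eaf_exp <- if (!is.null(exp$eaf)) exp$eaf else NA_real_
  eaf_out <- if (!is.null(out$eaf)) out$eaf else NA_real_
  mk <- function(beta_out, log) list(pair = list(
    beta_exp = exp$beta, se_exp = exp$se, beta_out = beta_out,
    se_out = out$se, eaf_exp = eaf_exp, action_log = log))

  if (isPalindromic(e_ea, e_oa)) {
    if (palindromePolicy == "drop_all") return(list(drop = "palindromic"))
    # frequency inference: both frequencies must exist and be unambiguous
    if (is.na(eaf_exp) || is.na(eaf_out))
      return(list(drop = "palindromic_no_eaf"))
    if (min(eaf_exp, 1 - eaf_exp) > ambiguityBand ||
        min(eaf_out, 1 - eaf_out) > ambiguityBand)
      return(list(drop = "palindromic_ambiguous"))
    if (!o_ea %in% c(e_ea, e_oa) || !o_oa %in% c(e_ea, e_oa))
      return(list(drop = "allele_mismatch"))
    same_side <- (eaf_exp < 0.5) == (eaf_out < 0.5)
    if (same_side) return(mk(out$beta, "palindromic_frequency_aligned"))
    return(mk(-out$beta, "palindromic_frequency_flipped"))
  }

  if (o_ea == e_ea && o_oa == e_oa) return(mk(out$beta, "ok"))
  if (o_ea == e_oa && o_oa == e_ea) return(mk(-out$beta, "flipped"))
  c_ea <- complementAllele(o_ea); c_oa <- complementAllele(o_oa)
  if (c_ea == e_ea && c_oa == e_oa) return(mk(out$beta, "strand_complemented"))
  if (c_ea == e_oa && c_oa == e_ea) return(mk(-out$beta, "strand_complemented_flipped"))
  list(drop = "allele_mismatch")
}

#' Harmonize an instrument set against an outcome GWAS
#'
#' Merges instrument-exposure and instrument-outcome associations into a
#' [HarmonizedData-class] object. Instruments absent from the outcome table
#' are, when an LD table is supplied, replaced by their best proxy
#' ([findProxy()]); proxies are oriented to the original instrument's
#' effect allele using the stored dosage-correlation sign when available,
#' otherwise used as-is with an `"proxy_orientation_unverified"` flag in the
#' action log. Instruments that cannot be paired appear in `dropped` with a
#' reason (`"no_proxy"`, `"palindromic"`, `"allele_mismatch"`, ...); pairs
#' and drops partition the instruments attempted, and the whole procedure is
#' deterministic given its inputs.
#'
#' @param instruments an [InstrumentSet-class] object (or a
#'   [SummaryStats-class] whose variants are all instruments).
#' @param outcome a [SummaryStats-class] object.
#' @param ld optional [LDTable-class] for proxy search.
#' @param palindromePolicy,ambiguityBand see [harmonizePair()].
#' @param proxyR2,proxyWindowBp proxy-search parameters for [findProxy()].
#' @return a [HarmonizedData-class] object.
#' @export
harmonizeData <- function(instruments, outcome, ld = NULL,
                          palindromePolicy = "drop_all", ambiguityBand = 0.42,
                          proxyR2 = 0.8, proxyWindowBp = 5e8) {
  iv <- if (is(instruments, "InstrumentSet")) instruments@variants else
    variants(instruments)
  exposureName <- if (is(instruments, "InstrumentSet"))
    instruments@exposureName else traitName(instruments)
  ov <- variants(outcome)
  pairs <- list(); drops <- list()
  for (i in seq_len(nrow(iv))) {
    id <- iv$variant_id[i]
    at <- match(id, ov$variant_id)
    if (!is.na(at)) {
      res <- harmonizePair(iv[i, ], ov[at, ],
                           palindromePolicy = palindromePolicy,
                           ambiguityBand = ambiguityBand)
      if (!is.null(res$drop)) {
        drops[[length(drops) + 1L]] <- data.frame(variant_id = id,
                                                  reason = res$drop)
      } else {
        p <- res$pair
        pairs[[length(pairs) + 1L]] <- data.frame(
          variant_id = id, beta_exp = p$beta_exp, se_exp = p$se_exp,
          beta_out = p$beta_out, se_out = p$se_out, eaf_exp = p$eaf_exp,
          proxy_id = NA_character_, action_log = p$action_log,
          stringsAsFactors = FALSE)
      }
      next
    }
    proxy <- if (is.null(ld)) NULL else
      findProxy(id, outcome, ld, r2Min = proxyR2, windowBp = proxyWindowBp)
    if (is.null(proxy)) {
      drops[[length(drops) + 1L]] <- data.frame(variant_id = id,
                                                reason = "no_proxy")
      next
    }
    prow <- ov[match(proxy, ov$variant_id), ]
    pp <- ldPairs(ld)
    key <- .pairKey(id, proxy)
    sgn <- pp$sign[match(key, paste(pp$id_a, pp$id_b, sep = "|"))]
    if (is.na(sgn)) {
      beta_out <- prow$beta
      log <- sprintf("proxy(%s);proxy_orientation_unverified", proxy)
    } else {
      beta_out <- sgn * prow$beta
      log <- sprintf("proxy(%s);oriented_by_dosage_sign", proxy)
    }
    pairs[[length(pairs) + 1L]] <- data.frame(
      variant_id = id, beta_exp = iv$beta[i], se_exp = iv$se[i],
      beta_out = beta_out, se_out = prow$se, eaf_exp = iv$eaf[i],
      proxy_id = proxy, action_log = log, stringsAsFactors = FALSE)
  }
  empty_pairs <- data.frame(variant_id = character(), beta_exp = numeric(),
                            se_exp = numeric(), beta_out = numeric(),
                            se_out = numeric(), eaf_exp = numeric(),
                            proxy_id = character(), action_log = character(),
                            stringsAsFactors = FALSE)
  empty_drops <- data.frame(variant_id = character(), reason = character(),
                            stringsAsFactors = FALSE)
  new("HarmonizedData",
      exposureName = exposureName, outcomeName = traitName(outcome),
      outcomeType = traitType(outcome),
      pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
      dropped = if (length(drops)) do.call(rbind, drops) else empty_drops)
}

# lightweight constructor from effect vectors, for estimators and simulation
#' Build a HarmonizedData object directly from aligned effect vectors
#'
#' Convenience constructor for already-aligned exposure/outcome effects —
#' the form estimators consume. Used heavily with simulated data where both
#' tables share ids and alleles by construction.
#'
#' @param bx,bxse exposure effects and standard errors.
#' @param by,byse outcome effects and standard errors.
#' @param ids variant ids (defaults to `snp1..snpK`).
#' @param exposureName,outcomeName,outcomeType labels.
#' @return a [HarmonizedData-class] object.
#' @export
mrInput <- function(bx, bxse, by, byse, ids = paste0("snp", seq_along(bx)),
                    exposureName = "exposure", outcomeName = "outcome",
                    outcomeType = "binary") {
  stopifnot(length(bx) == length(by))
  bxse <- rep_len(bxse, length(bx))
  byse <- rep_len(byse, length(bx))
  new("HarmonizedData", exposureName = exposureName,
      outcomeName = outcomeName, outcomeType = outcomeType,
      pairs = data.frame(variant_id = ids, beta_exp = bx, se_exp = bxse,
                         beta_out = by, se_out = byse, eaf_exp = NA_real_,
                         proxy_id = NA_character_, action_log = "ok",
                         stringsAsFactors = FALSE),
      dropped = data.frame(variant_id = character(), reason = character(),
                           stringsAsFactors = FALSE))
}

#' Write / read a harmonized dataset
#'
#' One row per harmonized pair with both betas/SEs and the action log, plus
#' a companion drops file; both tab-separated with `#` metadata headers.
#'
#' @param x a [HarmonizedData-class] object.
#' @param pairsPath,dropsPath output paths.
#' @return the paths, invisibly.
#' @export
writeHarmonizedData <- function(x, pairsPath, dropsPath = NULL) {
  .writeWithHeader(harmonizedPairs(x), pairsPath,
                   settings = list(exposure = x@exposureName,
                                   outcome = x@outcomeName,
                                   outcome_type = x@outcomeType))
  if (!is.null(dropsPath)) .writeWithHeader(droppedVariants(x), dropsPath)
  invisible(c(pairsPath, dropsPath))
}
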