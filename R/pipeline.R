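#' Assemble and validate an analysis configuration
#'
#' Collects everything a full run needs: exposure and outcome summary
#' statistics (as [SummaryStats-class] objects or file paths), an optional
#' LD table, the selection thresholds, the palindrome policy, optional
#' confounder-exclusion and conservative (prioritized-instrument) lists,
#' reverse-direction instrument ids, and the RNG seed required by the
#' bootstrap estimators.
#'
#' @param exposures named list of [SummaryStats-class] objects or file
#'   paths (names are the exposure labels).
#' @param outcomes named list with any of `discovery`, `replication`
#'   (binary outcomes) and `continuous`; each a [SummaryStats-class] or
#'   file path.
#' @param ld an [LDTable-class], or `NULL` when instruments are already
#'   independent and present in all outcome GWASs.
#' @param alphaGW,nTests instrument significance threshold components
#'   (defaults 5e-8 and 102).
#' @param clumpR2,clumpWindowBp LD-clumping parameters (defaults 0.01 and
#'   10 Mb).
#' @param proxyR2,proxyWindowBp proxy-search parameters (defaults 0.8 and
#'   500 Mb).
#' @param palindromePolicy `"drop_all"` or `"frequency_inference"`.
#' @param confounderExclude variant ids associated with confounders, to be
#'   removed in the confounder-exclusion analysis.
#' @param conservative named list (by exposure) of prioritized instrument
#'   id sets; each element is a character vector or a named list of
#'   character vectors (e.g. biologically / genetically prioritized).
#' @param reverseInstruments variant ids instrumenting the disease for
#'   reverse-direction MR.
#' @param nExposuresBonferroni denominator for the interpretation
#'   threshold (defaults to the number of exposures).
#' @param seed RNG seed (mandatory: weighted median/mode bootstrap).
#' @param nBoot bootstrap resamples for weighted median/mode.
#' @return a validated list of class `"analysisConfig"`.
#' @export
analysisConfig <- function(exposures, outcomes, ld = NULL,
                           alphaGW = 5e-8, nTests = 102,
                           clumpR2 = 0.01, clumpWindowBp = 1e7,
                           proxyR2 = 0.8, proxyWindowBp = 5e8,
                           palindromePolicy = "drop_all",
                           confounderExclude = character(),
                           conservative = list(),
                           reverseInstruments = character(),
                           nExposuresBonferroni = length(exposures),
                           seed, nBoot = 5000) {
  if (missing(seed) || !is.finite(seed))
    stop("analysisConfig requires a seed (bootstrap estimators)", call. = FALSE)
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    stop("exposures must be a named list", call. = FALSE)
  for (f in c(exposures, outcomes))
    if (is.character(f) && !file.exists(f))
      stop("referenced file does not exist: ", f, call. = FALSE)
  structure(list(exposures = exposures, outcomes = outcomes, ld = ld,
                 alphaGW = alphaGW, nTests = nTests, clumpR2 = clumpR2,
                 clumpWindowBp = clumpWindowBp, proxyR2 = proxyR2,
                 proxyWindowBp = proxyWindowBp,
                 palindromePolicy = palindromePolicy,
                 confounderExclude = confounderExclude,
                 conservative = conservative,
                 reverseInstruments = reverseInstruments,
                 nExposuresBonferroni = nExposuresBonferroni,
                 seed = as.integer(seed), nBoot = nBoot),
            class = "analysisConfig")
}

#' Read an analysis configuration from a YAML file
#'
#' File paths inside the YAML are resolved relative to the file's
#' directory. Expected keys mirror the [analysisConfig()] arguments;
#' exposures are given as a list of `{name, file, type}` entries, outcomes
#' as `{discovery: {file, type}, ...}`, and the LD table as
#' `{pairs, positions}` file paths.
#'
#' @param path YAML file path.
#' @return an `"analysisConfig"` list.
#' @export
readAnalysisConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(f) if (is.null(f)) NULL else file.path(base, f)
  exposures <- list()
  for (e in y$exposures)
    exposures[[e$name]] <- readSummaryStats(rel(e$file), traitName = e$name,
                                            traitType = e$type %||% "continuous")
  outcomes <- list()
  for (nm in intersect(c("discovery", "replication", "continuous"),
                       names(y$outcomes))) {
    o <- y$outcomes[[nm]]
    outcomes[[nm]] <- readSummaryStats(rel(o$file),
                                       traitName = o$name %||% nm,
                                       traitType = o$type %||%
                                         if (nm == "continuous") "continuous" else "binary")
  }
  ld <- if (!is.null(y$ld))
    readLDTable(rel(y$ld$pairs), rel(y$ld$positions)) else NULL
  analysisConfig(exposures = exposures, outcomes = outcomes, ld = ld,
                 alphaGW = y$alpha_gw %||% 5e-8, nTests = y$n_tests %||% 102,
                 clumpR2 = y$clump_r2 %||% 0.01,
                 clumpWindowBp = y$clump_window_bp %||% 1e7,
                 proxyR2 = y$proxy_r2 %||% 0.8,
                 proxyWindowBp = y$proxy_window_bp %||% 5e8,
                 palindromePolicy = y$palindrome_policy %||% "drop_all",
                 confounderExclude = unlist(y$confounder_exclude) %||% character(),
                 conservative = y$conservative %||% list(),
                 reverseInstruments = unlist(y$reverse_instruments) %||% character(),
                 nExposuresBonferroni = y$n_exposures_bonferroni %||%
                   length(y$exposures),
                 seed = y$seed, nBoot = y$n_boot %||% 5000)
}

.loadSS <- function(x, name = NULL, type = "continuous") {
  if (is(x, "SummaryStats")) return(x)
  readSummaryStats(x, traitName = name %||% basename(x), traitType = type)
}

.interpretationLabel <- function(p, nExposures) {
  thr <- significanceThreshold(0.05, nExposures)
  ifelse(p < thr, "strong", ifelse(p < 0.05, "suggestive", "none"))
}

# one output row per estimate; OR columns only for binary outcomes
.estimateRow <- function(est, exposure, outcome, stage, binary, nExposures) {
  row <- data.frame(exposure = exposure, outcome = outcome, stage = stage,
                    method = mrMethod(est), n_snps = nSNPs(est),
                    beta = mrBeta(est), se = mrSE(est),
                    ci_low = mrCI(est)[1], ci_high = mrCI(est)[2],
                    pval = mrPval(est), q_stat = est@qStat,
                    q_pval = est@qPval, stringsAsFactors = FALSE)
  if (binary) {
    row$or <- exp(row$beta)
    row$or_ci_low <- exp(row$ci_low)
    row$or_ci_high <- exp(row$ci_high)
  }
  row$label <- .interpretationLabel(row$pval, nExposures)
  row
}

# main + (k>=4) sensitivity estimates for one harmonized dataset
.analyzeOne <- function(hd, nBoot, seed, mainOnly = FALSE,
                        forceFixed = FALSE) {
  k <- nrow(harmonizedPairs(hd))
  if (k < 1L) stop("no harmonized instruments", call. = FALSE)
  plan <- selectMainMethod(k, if (hd@outcomeType == "binary")
    "binary_primary" else "continuous_pdff")
  out <- list()
  if (plan$main == "wald_ratio") {
    out$main <- mrWaldRatio(hd)
  } else if (forceFixed || plan$variant == "fixed") {
    out$main <- mrIVW(hd, "fixed")
  } else {
    out$main <- mrIVW(hd, "multiplicative_random")
  }
  if (!mainOnly && length(plan$sensitivity)) {
    out$weighted_median <- mrWeightedMedian(hd, nBoot = nBoot, seed = seed)
    eg <- mrEgger(hd)
    out$egger_slope <- eg$slope
    out$egger_intercept <- eg$intercept
  }
  out
}

# deterministic per-exposure sub-seed, kept within 32-bit integer range
.subSeed <- function(seed, i) (as.integer(seed) + 7919L * i) %% 2147483629L

#' Run the forward MR pipeline: discovery, replication, meta-analysis
#'
#' For each exposure: select instruments (significance threshold + LD
#' clumping), harmonize against each binary outcome GWAS (with proxy
#' substitution for absent variants), estimate the causal effect with the
#' instrument-count-selected method (Wald ratio / fixed IVW / multiplicative
#' random-effects IVW), attach weighted-median and MR-Egger sensitivity
#' analyses when at least four instruments are available, and combine the
#' discovery and replication main estimates by fixed-effect meta-analysis.
#' Estimates are labelled `"strong"` when `p < 0.05/nExposures` and
#' `"suggestive"` when `0.05/nExposures <= p < 0.05`. Per-exposure failures
#' are recorded and the run continues.
#'
#' @param config an [analysisConfig()] object.
#' @param exclude additional variant ids excluded from instrument selection
#'   (used by [runConfounderExclusion()]).
#' @return list with `estimates` (data.frame), `instruments` (per-exposure
#'   counts) and `log` (data.frame of per-exposure events).
#' @export
runForwardMR <- function(config, exclude = character()) {
  stopifnot(inherits(config, "analysisConfig"))
  stages <- intersect(c("discovery", "replication"), names(config$outcomes))
  outcomes <- lapply(stages, function(s)
    .loadSS(config$outcomes[[s]], name = s, type = "binary"))
  names(outcomes) <- stages
  rows <- list(); logs <- list(); counts <- list()
  for (i in seq_along(config$exposures)) {
    exp_name <- names(config$exposures)[i]
    res <- tryCatch({
      expo <- .loadSS(config$exposures[[i]], name = exp_name)
      instr <- selectInstruments(expo, config$ld %||% ldTable(),
                                 alphaGW = config$alphaGW,
                                 nTests = config$nTests,
                                 r2Max = config$clumpR2,
                                 windowBp = config$clumpWindowBp,
                                 exclude = exclude)
      if (nVariants(instr) == 0L) stop("no instruments pass selection")
      stage_rows <- list(); mains <- list()
      for (s in stages) {
        hd <- harmonizeData(instr, outcomes[[s]], ld = config$ld,
                            palindromePolicy = config$palindromePolicy,
                            proxyR2 = config$proxyR2,
                            proxyWindowBp = config$proxyWindowBp)
        for (d in seq_len(nrow(droppedVariants(hd))))
          logs[[length(logs) + 1L]] <- data.frame(
            exposure = exp_name, stage = s,
            event = paste0("dropped:", droppedVariants(hd)$variant_id[d],
                           ":", droppedVariants(hd)$reason[d]),
            stringsAsFactors = FALSE)
        if (nrow(harmonizedPairs(hd)) == 0L)
          stop("no harmonized instruments for stage ", s)
        ests <- .analyzeOne(hd, nBoot = config$nBoot,
                            seed = .subSeed(config$seed, i))
        mains[[s]] <- ests$main
        for (est in ests)
          stage_rows[[length(stage_rows) + 1L]] <-
            .estimateRow(est, exp_name, traitName(outcomes[[s]]), s,
                         binary = TRUE,
                         nExposures = config$nExposuresBonferroni)
      }
      if (length(mains) >= 2L) {
        meta <- fixedEffectMeta(vapply(mains, mrBeta, numeric(1)),
                                vapply(mains, mrSE, numeric(1)))
        stage_rows[[length(stage_rows) + 1L]] <-
          .estimateRow(meta, exp_name, "combined", "meta", binary = TRUE,
                       nExposures = config$nExposuresBonferroni)
      }
      counts[[exp_name]] <- nVariants(instr)
      do.call(rbind, stage_rows)
    }, error = function(e) {
      logs[[length(logs) + 1L]] <<- data.frame(
        exposure = exp_name, stage = "run",
        event = paste0("failed:", conditionMessage(e)),
        stringsAsFactors = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  list(estimates = if (length(rows)) do.call(rbind, rows) else NULL,
       instruments = unlist(counts),
       log = if (length(logs)) do.call(rbind, logs) else
         data.frame(exposure = character(), stage = character(),
                    event = character(), stringsAsFactors = FALSE))
}

#' Forward MR after excluding confounder-associated variants
#'
#' Repeats [runForwardMR()] with the configured confounder-associated
#' variant ids removed before instrument selection, and flags exposures
#' whose instrument count dropped below the thresholds that change the
#' estimation method (4, the sensitivity-analysis minimum, and 2, the IVW
#' minimum).
#'
#' @param config an [analysisConfig()] object.
#' @param exclusionIds variant ids to exclude; defaults to
#'   `config$confounderExclude`.
#' @return as [runForwardMR()], with a `methodChanged` data.frame comparing
#'   instrument counts before and after exclusion.
#' @export
runConfounderExclusion <- function(config, exclusionIds = config$confounderExclude) {
  full <- runForwardMR(config)
  restricted <- runForwardMR(config, exclude = exclusionIds)
  before <- full$instruments; after <- restricted$instruments
  shared <- intersect(names(before), names(after))
  flag <- data.frame(exposure = shared,
                     k_before = unname(before[shared]),
                     k_after = unname(after[shared]), stringsAsFactors = FALSE)
  flag$method_changed <- (flag$k_before >= 4 & flag$k_after < 4) |
    (flag$k_before >= 2 & flag$k_after < 2)
  skipped <- setdiff(names(before), names(after))
  restricted$methodChanged <- flag
  restricted$skipped <- skipped
  restricted
}

#' Conservative MR on prioritized instrument subsets
#'
#' Restricts each exposure's instruments to biologically or genetically
#' prioritized variant ids and re-estimates with the Wald ratio (one
#' instrument) or fixed-effect IVW only. Exposures with no prioritized
#' instruments are reported as not assessable.
#'
#' @param config an [analysisConfig()] object with a `conservative` list.
#' @return list with `estimates` and `notAssessable` (data.frame of
#'   exposure/set combinations with no usable instruments).
#' @export
runConservative <- function(config) {
  stopifnot(inherits(config, "analysisConfig"))
  stages <- intersect(c("discovery", "replication"), names(config$outcomes))
  outcomes <- lapply(stages, function(s)
    .loadSS(config$outcomes[[s]], name = s, type = "binary"))
  names(outcomes) <- stages
  rows <- list(); na_rows <- list()
  for (exp_name in names(config$exposures)) {
    sets <- config$conservative[[exp_name]]
    if (is.null(sets) || !length(unlist(sets))) {
      na_rows[[length(na_rows) + 1L]] <- data.frame(
        exposure = exp_name, set = "any", reason = "no_prioritized_instruments",
        stringsAsFactors = FALSE)
      next
    }
    if (is.character(sets)) sets <- list(prioritized = sets)
    expo <- .loadSS(config$exposures[[exp_name]], name = exp_name)
    instr <- selectInstruments(expo, config$ld %||% ldTable(),
                               alphaGW = config$alphaGW, nTests = config$nTests,
                               r2Max = config$clumpR2,
                               windowBp = config$clumpWindowBp)
    for (set_name in names(sets)) {
      keep <- variants(instr)$variant_id %in% sets[[set_name]]
      if (!any(keep)) {
        na_rows[[length(na_rows) + 1L]] <- data.frame(
          exposure = exp_name, set = set_name,
          reason = "no_prioritized_instruments", stringsAsFactors = FALSE)
        next
      }
      sub <- new("InstrumentSet", exposureName = exp_name,
                 variants = variants(instr)[keep, , drop = FALSE],
                 settings = instr@settings)
      mains <- list()
      for (s in stages) {
        hd <- harmonizeData(sub, outcomes[[s]], ld = config$ld,
                            palindromePolicy = config$palindromePolicy,
                            proxyR2 = config$proxyR2,
                            proxyWindowBp = config$proxyWindowBp)
        if (nrow(harmonizedPairs(hd)) == 0L) next
        est <- .analyzeOne(hd, nBoot = config$nBoot, seed = config$seed,
                           mainOnly = TRUE, forceFixed = TRUE)$main
        mains[[s]] <- est
        row <- .estimateRow(est, exp_name, traitName(outcomes[[s]]), s,
                            binary = TRUE,
                            nExposures = config$nExposuresBonferroni)
        row$set <- set_name
        rows[[length(rows) + 1L]] <- row
      }
      if (length(mains) >= 2L) {
        meta <- fixedEffectMeta(vapply(mains, mrBeta, numeric(1)),
                                vapply(mains, mrSE, numeric(1)))
        row <- .estimateRow(meta, exp_name, "combined", "meta", binary = TRUE,
                            nExposures = config$nExposuresBonferroni)
        row$set <- set_name
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  list(estimates = if (length(rows)) do.call(rbind, rows) else NULL,
       notAssessable = if (length(na_rows)) do.call(rbind, na_rows) else NULL)
}

#' Reverse-direction MR: disease as exposure, traits as outcomes
#'
#' Uses the configured disease instruments (taken from the discovery
#' outcome GWAS) as the exposure and each configured trait GWAS as the
#' outcome, estimating with the fixed-effect IVW plus — where at least
#' three instruments harmonize — the weighted median and weighted mode.
#' Instruments missing from a trait GWAS are dropped with a log record.
#'
#' @param config an [analysisConfig()] object with `reverseInstruments`.
#' @return list with `estimates` and `log`.
#' @export
runReverseMR <- function(config) {
  stopifnot(inherits(config, "analysisConfig"))
  if (!length(config$reverseInstruments))
    stop("config$reverseInstruments is empty", call. = FALSE)
  disease <- .loadSS(config$outcomes$discovery, name = "disease",
                     type = "binary")
  dv <- variants(disease)
  keep <- dv$variant_id %in% config$reverseInstruments
  missing_iv <- setdiff(config$reverseInstruments, dv$variant_id)
  instr <- new("InstrumentSet", exposureName = traitName(disease),
               variants = dv[keep, , drop = FALSE],
               settings = list(instruments = config$reverseInstruments))
  rows <- list()
  logs <- lapply(missing_iv, function(id) data.frame(
    exposure = traitName(disease), stage = "reverse",
    event = paste0("dropped:", id, ":absent_from_exposure_gwas"),
    stringsAsFactors = FALSE))
  for (i in seq_along(config$exposures)) {
    trait_name <- names(config$exposures)[i]
    trait <- .loadSS(config$exposures[[i]], name = trait_name)
    hd <- harmonizeData(instr, trait, ld = config$ld,
                        palindromePolicy = config$palindromePolicy,
                        proxyR2 = config$proxyR2,
                        proxyWindowBp = config$proxyWindowBp)
    for (d in seq_len(nrow(droppedVariants(hd))))
      logs[[length(logs) + 1L]] <- data.frame(
        exposure = trait_name, stage = "reverse",
        event = paste0("dropped:", droppedVariants(hd)$variant_id[d], ":",
                       droppedVariants(hd)$reason[d]), stringsAsFactors = FALSE)
    k <- nrow(harmonizedPairs(hd))
    if (k < 1L) next
    ests <- list(if (k == 1L) mrWaldRatio(hd) else mrIVW(hd, "fixed"))
    if (k >= 3L) {
      sseed <- .subSeed(config$seed, i)
      ests <- c(ests, list(
        mrWeightedMedian(hd, nBoot = config$nBoot, seed = sseed),
        mrWeightedMode(hd, nBoot = config$nBoot, seed = sseed)))
    }
    for (est in ests)
      rows[[length(rows) + 1L]] <-
        .estimateRow(est, traitName(disease), trait_name, "reverse",
                     binary = FALSE,
                     nExposures = config$nExposuresBonferroni)
  }
  list(estimates = if (length(rows)) do.call(rbind, rows) else NULL,
       log = if (length(logs)) do.call(rbind, logs) else NULL)
}

#' Forward MR against a continuous outcome
#'
#' Repeats the forward analysis with a continuous outcome (e.g. an
#' MRI-derived liver-fat fraction validating a binary disease outcome).
#' Method selection is unchanged (Wald ratio / fixed IVW / multiplicative
#' random-effects IVW by instrument count); estimates stay on the
#' SD-per-SD scale and no odds-ratio columns are emitted.
#'
#' @param config an [analysisConfig()] object whose `outcomes$continuous`
#'   is set.
#' @return list with `estimates` and `log`.
#' @export
runContinuousOutcome <- function(config) {
  stopifnot(inherits(config, "analysisConfig"))
  if (is.null(config$outcomes$continuous))
    stop("config$outcomes$continuous is not set", call. = FALSE)
  outcome <- .loadSS(config$outcomes$continuous, name = "continuous",
                     type = "continuous")
  rows <- list(); logs <- list()
  for (i in seq_along(config$exposures)) {
    exp_name <- names(config$exposures)[i]
    res <- tryCatch({
      expo <- .loadSS(config$exposures[[i]], name = exp_name)
      instr <- selectInstruments(expo, config$ld %||% ldTable(),
                                 alphaGW = config$alphaGW,
                                 nTests = config$nTests,
                                 r2Max = config$clumpR2,
                                 windowBp = config$clumpWindowBp)
      if (nVariants(instr) == 0L) stop("no instruments pass selection")
      hd <- harmonizeData(instr, outcome, ld = config$ld,
                          palindromePolicy = config$palindromePolicy,
                          proxyR2 = config$proxyR2,
                          proxyWindowBp = config$proxyWindowBp)
      if (nrow(harmonizedPairs(hd)) == 0L) stop("no harmonized instruments")
      ests <- .analyzeOne(hd, nBoot = config$nBoot,
                          seed = .subSeed(config$seed, i))
      do.call(rbind, lapply(ests, .estimateRow, exposure = exp_name,
                            outcome = traitName(outcome),
                            stage = "continuous", binary = FALSE,
                            nExposures = config$nExposuresBonferroni))
    }, error = function(e) {
      logs[[length(logs) + 1L]] <<- data.frame(
        exposure = exp_name, stage = "continuous",
        event = paste0("failed:", conditionMessage(e)),
        stringsAsFactors = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  list(estimates = if (length(rows)) do.call(rbind, rows) else NULL,
       log = if (length(logs)) do.call(rbind, logs) else NULL)
}

#' Write / read an estimates table
#'
#' Tab-separated with a `#`-prefixed metadata header recording the run
#' settings; numeric values round-trip through [readEstimates()].
#'
#' @param estimates data.frame as produced by the `run*` functions.
#' @param path output path.
#' @param settings named list written into the metadata header.
#' @return `path`, invisibly.
#' @export
writeEstimates <- function(estimates, path, settings = list()) {
  .writeWithHeader(estimates, path, settings = settings)
}

#' @rdname writeEstimates
#' @export
readEstimates <- function(path) .readWithHeader(path)
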