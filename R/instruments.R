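#' Multiplicity-adjusted significance threshold
#'
#' Bonferroni division of a genome-wide significance level by the number of
#' independent tests: `5e-8 / 102` gives the metabolome-adjusted instrument
#' threshold (4.9e-10 at two significant figures) and `0.05 / 20` the
#' 20-exposure interpretation threshold 0.0025.
#'
#' @param alphaGW base significance level, in (0, 1).
#' @param nTests number of tests, >= 1.
#' @return `alphaGW / nTests`.
#' @export
significanceThreshold <- function(alphaGW, nTests) {
  if (!is.finite(alphaGW) || alphaGW <= 0 || alphaGW >= 1)
    stop("alphaGW must lie in (0,1)", call. = FALSE)
  if (!is.finite(nTests) || nTests < 1)
    stop("nTests must be >= 1", call. = FALSE)
  alphaGW / nTests
}

#' Greedy p-value-ordered LD clumping
#'
#' Prunes a set of significant candidate variants so that every retained
#' pair on the same chromosome within `windowBp` has pairwise `r2 < r2Max`.
#' Candidates are visited in ascending p-value order (ties broken by
#' chromosome, position, then id — so the result does not depend on input
#' row order); a variant is accepted iff its r² with every previously
#' accepted same-chromosome variant within the window is below the
#' threshold. This is the PLINK "clump" convention, and the output is the
#' maximal p-ordered independent set. Pairs absent from the LD table are
#' treated as r² = 0 with a warning naming them (real LD tables are sparse).
#'
#' @param candidates a [SummaryStats-class] object or data.frame with
#'   columns `variant_id`, `chrom`, `pos`, `pval`.
#' @param ld an [LDTable-class] object.
#' @param r2Max clumping r² threshold (default 0.01).
#' @param windowBp positional window in base pairs (default 1e7, i.e. 10 Mb).
#' @return character vector of retained variant ids, in acceptance order.
#' @export
ldClump <- function(candidates, ld, r2Max = 0.01, windowBp = 1e7) {
  v <- if (is(candidates, "SummaryStats")) variants(candidates) else
    as.data.frame(candidates, stringsAsFactors = FALSE)
  if (!nrow(v)) return(character())
  ord <- order(v$pval, v$chrom, v$pos, v$variant_id)
  v <- v[ord, , drop = FALSE]
  idx <- .ldIndex(ld)
  kept_id <- character(); kept_chr <- character(); kept_pos <- numeric()
  missing_pairs <- character()
  for (i in seq_len(nrow(v))) {
    id <- v$variant_id[i]; chr <- v$chrom[i]; pos <- v$pos[i]
    near <- which(kept_chr == chr & abs(kept_pos - pos) <= windowBp)
    ok <- TRUE
    if (length(near)) {
      r2 <- unname(idx[.pairKey(id, kept_id[near])])
      if (anyNA(r2)) {
        missing_pairs <- c(missing_pairs,
                           .pairKey(id, kept_id[near])[is.na(r2)])
        r2[is.na(r2)] <- 0
      }
      ok <- all(r2 < r2Max)
    }
    if (ok) {
      kept_id <- c(kept_id, id); kept_chr <- c(kept_chr, chr)
      kept_pos <- c(kept_pos, pos)
    }
  }
  if (length(missing_pairs))
    warning("LD pairs absent from table treated as r2=0: ",
            paste(unique(missing_pairs), collapse = "; "), call. = FALSE)
  kept_id
}

#' Find a proxy variant for an instrument absent from the outcome GWAS
#'
#' Searches the outcome summary table for the variant in highest LD
#' (`r2 > r2Min`) with the missing instrument within `windowBp` on the same
#' chromosome. Ties on r² are broken by smaller positional distance to the
#' missing variant, then lexicographically by id. Returns `NULL` when no
#' proxy qualifies — the instrument is then dropped for that outcome.
#'
#' @param missingId instrument id absent from `outcome`.
#' @param outcome a [SummaryStats-class] object (the outcome GWAS).
#' @param ld an [LDTable-class] object covering the missing variant.
#' @param r2Min minimum acceptable r² (default 0.8).
#' @param windowBp search window in base pairs (default 5e8, the printed
#'   500 Mb; a 500 kb window is accepted the same way).
#' @return the proxy variant id, or `NULL`.
#' @export
findProxy <- function(missingId, outcome, ld, r2Min = 0.8, windowBp = 5e8) {
  pos <- ldPositions(ld)
  at <- match(missingId, pos$variant_id)
  if (is.na(at))
    stop("variant not in LD table positions: ", missingId, call. = FALSE)
  chr <- pos$chrom[at]; bp <- pos$pos[at]
  out_v <- variants(outcome)
  cand <- out_v$variant_id[out_v$variant_id != missingId]
  if (!length(cand)) return(NULL)
  cpos <- pos[match(cand, pos$variant_id), , drop = FALSE]
  keep <- !is.na(cpos$chrom) & cpos$chrom == chr & abs(cpos$pos - bp) <= windowBp
  cand <- cand[keep]; cpos <- cpos[keep, , drop = FALSE]
  if (!length(cand)) return(NULL)
  r2 <- ldR2(ld, rep(missingId, length(cand)), cand)
  r2[is.na(r2)] <- 0
  qual <- r2 > r2Min
  if (!any(qual)) return(NULL)
  cand <- cand[qual]; r2 <- r2[qual]
  dist <- abs(cpos$pos[qual] - bp)
  cand[order(-r2, dist, cand)][1L]
}

#' Select genetic instruments for one exposure
#'
#' Applies the multiplicity-adjusted significance threshold and greedy LD
#' clumping to an exposure GWAS, returning an [InstrumentSet-class].
#'
#' @param exposure a [SummaryStats-class] object.
#' @param ld an [LDTable-class] object.
#' @param alphaGW,nTests threshold parameters for
#'   [significanceThreshold()] (defaults 5e-8 and 102, the metabolome-wide
#'   adjustment).
#' @param r2Max,windowBp clumping parameters for [ldClump()].
#' @param exclude variant ids to remove before selection (e.g. a
#'   confounder-associated exclusion list).
#' @return an [InstrumentSet-class] object.
#' @export
selectInstruments <- function(exposure, ld, alphaGW = 5e-8, nTests = 102,
                              r2Max = 0.01, windowBp = 1e7,
                              exclude = character()) {
  thr <- significanceThreshold(alphaGW, nTests)
  v <- variants(exposure)
  v <- v[!v$variant_id %in% exclude, , drop = FALSE]
  v <- v[!is.na(v$pval) & v$pval < thr, , drop = FALSE]
  kept <- ldClump(v, ld, r2Max = r2Max, windowBp = windowBp)
  v <- v[match(kept, v$variant_id), , drop = FALSE]
  rownames(v) <- NULL
  new("InstrumentSet", exposureName = traitName(exposure), variants = v,
      settings = list(p_threshold = thr, clump_r2 = r2Max,
                      clump_window_bp = windowBp, excluded = exclude))
}
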