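`%||%` <- function(a, b) if (is.null(a)) b else a

.complement <- c(A = "T", T = "A", C = "G", G = "C")

complementAllele <- function(a) unname(.complement[a])

# A/T or C/G pair: strand cannot be resolved from alleles alone
isPalindromic <- function(ea, oa) complementAllele(ea) == oa

.checkAllele <- function(a, what) {
  if (length(a) != 1L || is.na(a) || !grepl("^[ACGT]$", a))
    stop(sprintf("%s must be a single uppercase A/C/G/T, got '%s'", what, a),
         call. = FALSE)
  invisible(a)
}

# two-sided p from a normal or t reference; CIs use 1.96 throughout
.pNormal <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))
.pT <- function(beta, se, df) 2 * stats::pt(-abs(beta / se), df = df)

#' Construct an MREstimate
#'
#' Internal-facing constructor that derives the 1.96-sigma confidence limits
#' and the two-sided p-value from the point estimate and its standard error.
#'
#' @param method estimator label (see [MREstimate-class]).
#' @param beta,se point estimate and standard error.
#' @param nSNPs number of instruments.
#' @param df degrees of freedom for a t reference; `NA` (default) uses the
#'   normal reference.
#' @param qStat,qPval optional Cochran's Q and its p-value.
#' @param details optional list of estimator metadata.
#' @return an [MREstimate-class] object.
#' @export
newMREstimate <- function(method, beta, se, nSNPs, df = NA_real_,
                          qStat = NA_real_, qPval = NA_real_,
                          details = list()) {
  pval <- if (is.na(df)) .pNormal(beta, se) else .pT(beta, se, df)
  new("MREstimate", method = method, beta = beta, se = se,
      ciLow = beta - 1.96 * se, ciHigh = beta + 1.96 * se, pval = pval,
      nSNPs = as.integer(nSNPs), qStat = qStat, qPval = qPval,
      details = details)
}

# write a delimited table with a "#"-prefixed metadata header block
.writeWithHeader <- function(df, path, settings = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# written_by: aminoMR %s",
                     as.character(utils::packageVersion("aminoMR"))), con)
  for (nm in names(settings))
    writeLines(sprintf("# %s: %s", nm, paste(settings[[nm]], collapse = ",")), con)
  # as.character keeps decimal inputs round-trippable
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) {
    s <- as.character(x)
    s[is.na(x)] <- "NA"
    s
  })
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readWithHeader <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}
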