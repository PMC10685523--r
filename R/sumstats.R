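#' Convert a GWAS z-score to a standardized effect size and standard error
#'
#' For a standardized (unit-variance) trait, a variant's per-allele effect
#' and its standard error can be recovered from the association z-score, the
#' minor-allele frequency and the sample size as
#' \deqn{b = z / \sqrt{2p(1-p)(n + z^2)}, \quad
#'       SE = 1 / \sqrt{2p(1-p)(n + z^2)}.}
#' `beta/se` reproduces `z` up to floating rounding, so significance is
#' preserved by the conversion.
#'
#' @param z association z-score (vectorized).
#' @param maf allele frequency in (0, 1).
#' @param n GWAS sample size, >= 1.
#' @return list with numeric components `beta` and `se`.
#' @examples
#' zscoreToBeta(5, maf = 0.5, n = 10000)
#' @export
zscoreToBeta <- function(z, maf, n) {
  if (any(!is.finite(maf) | maf <= 0 | maf >= 1))
    stop("maf must lie strictly in (0,1)", call. = FALSE)
  if (any(!is.finite(n) | n < 1))
    stop("n must be >= 1", call. = FALSE)
  se <- 1 / sqrt(2 * maf * (1 - maf) * (n + z^2))
  list(beta = z * se, se = se)
}

#' Construct a SummaryStats object
#'
#' Normalizes a data.frame of per-variant associations into the canonical
#' [SummaryStats-class] layout: alleles are uppercased, optional columns
#' (`eaf`, `pval`, `n`, `chrom`, `pos`) are filled with `NA` when absent, and
#' rows carrying a z-score but no beta/se are converted with
#' [zscoreToBeta()] (this requires `eaf` and `n`).
#'
#' @param variants data.frame with at least `variant_id`, `effect_allele`,
#'   `other_allele`, and either `beta` + `se` or `z` + `eaf` + `n`.
#' @param traitName trait label.
#' @param traitType `"continuous"` (default) or `"binary"`.
#' @return a [SummaryStats-class] object.
#' @export
summaryStats <- function(variants, traitName, traitType = "continuous") {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  mandatory <- c("variant_id", "effect_allele", "other_allele")
  missing_cols <- setdiff(mandatory, names(v))
  has_beta <- all(c("beta", "se") %in% names(v))
  has_z <- all(c("z", "eaf", "n") %in% names(v))
  if (!has_beta && !has_z)
    missing_cols <- c(missing_cols, "beta+se (or z+eaf+n)")
  if (length(missing_cols))
    stop("summary table lacks mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  v$effect_allele <- toupper(as.character(v$effect_allele))
  v$other_allele <- toupper(as.character(v$other_allele))
  v$variant_id <- as.character(v$variant_id)
  for (col in c("eaf", "pval", "n", "pos", "beta", "se"))
    if (is.null(v[[col]])) v[[col]] <- NA_real_
  if (is.null(v$chrom)) v$chrom <- NA_character_ else v$chrom <- as.character(v$chrom)

  if ("z" %in% names(v)) {
    need <- is.na(v$beta) | is.na(v$se)
    if (any(need)) {
      if (any(is.na(v$eaf[need]) | is.na(v$n[need])))
        stop("rows with z but no beta/se require eaf and n for conversion",
             call. = FALSE)
      conv <- zscoreToBeta(v$z[need], v$eaf[need], v$n[need])
      v$beta[need] <- conv$beta
      v$se[need] <- conv$se
      miss_p <- need & is.na(v$pval)
      v$pval[miss_p] <- pmax(2 * stats::pnorm(-abs(v$z[miss_p])),
                             .Machine$double.xmin)
    }
  }

  # duplicate policy: keep the smallest p-value, warn about the rest
  if (anyDuplicated(v$variant_id)) {
    ord <- order(v$variant_id, v$pval, na.last = TRUE)
    v <- v[ord, , drop = FALSE]
    dup <- duplicated(v$variant_id)
    warning(sprintf("dropping %d duplicated variant_id row(s), keeping smallest p: %s",
                    sum(dup), paste(unique(v$variant_id[dup]), collapse = ", ")),
            call. = FALSE)
    v <- v[!dup, , drop = FALSE]
  }
  v <- v[, union(.SUMSTAT_COLS, intersect("z", names(v))), drop = FALSE]
  rownames(v) <- NULL
  new("SummaryStats", traitName = traitName, traitType = traitType, variants = v)
}

# delimiter auto-detection among tab / comma / whitespace on the header line
.detectSep <- function(path) {
  hdr <- readLines(path, n = 50L)
  hdr <- hdr[!startsWith(hdr, "#")]
  if (!length(hdr)) stop("empty file: ", path, call. = FALSE)
  first <- hdr[[1L]]
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
}

#' Read a GWAS summary-statistics file
#'
#' Reads a delimited text file (tab, comma or whitespace separated; the
#' delimiter is auto-detected from the mandatory header row; lines starting
#' with `#` are ignored) into a [SummaryStats-class] object. Non-canonical
#' column names are handled through `columnMapping`. Rows carrying a z-score
#' but no beta/se are converted via [zscoreToBeta()]; duplicated variant ids
#' keep the smallest p-value with a warning.
#'
#' @param path file path.
#' @param traitName trait label (defaults to the file name).
#' @param traitType `"continuous"` or `"binary"`.
#' @param columnMapping named character vector mapping canonical field names
#'   to file column names, e.g. `c(variant_id = "SNP", pval = "P")`. Columns
#'   already canonically named need no entry.
#' @return a [SummaryStats-class] object.
#' @export
readSummaryStats <- function(path, traitName = basename(path),
                             traitType = "continuous", columnMapping = NULL) {
  sep <- .detectSep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(columnMapping)) {
    for (canon in names(columnMapping)) {
      src <- columnMapping[[canon]]
      if (!src %in% names(raw))
        stop("columnMapping refers to absent file column: ", src, call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  summaryStats(raw, traitName = traitName, traitType = traitType)
}

#' Write a SummaryStats object to delimited text
#'
#' Tab-separated with a `#`-prefixed metadata header block; numeric columns
#' are written so that finite decimal inputs round-trip through
#' [readSummaryStats()] unchanged.
#'
#' @param x a [SummaryStats-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  stopifnot(is(x, "SummaryStats"))
  .writeWithHeader(variants(x), path,
                   settings = list(trait_name = traitName(x),
                                   trait_type = traitType(x)))
}

#' Per-instrument proportion of trait variance explained
#'
#' For a standardized continuous trait the variance explained by one variant
#' is \eqn{2 p (1-p) \beta^2} with `p` the effect-allele frequency; values
#' are clipped to `[0, 1]`. Summing over an instrument set gives the
#' set-level proportion (instruments are approximately independent after LD
#' clumping).
#'
#' @param x a [SummaryStats-class] object (or its `variants` data.frame).
#' @return numeric vector, one value per variant.
#' @export
varianceExplained <- function(x) {
  v <- if (is(x, "SummaryStats")) variants(x) else as.data.frame(x)
  if (any(is.na(v$eaf)))
    stop("eaf is required to compute variance explained", call. = FALSE)
  pmin(1, pmax(0, 2 * v$eaf * (1 - v$eaf) * v$beta^2))
}

#' Single-instrument F-statistic
#'
#' Instrument strength as `(beta/se)^2`, the standard single-variant
#' approximation; values above 10 are conventionally considered strong.
#'
#' @param x a [SummaryStats-class] object (or its `variants` data.frame).
#' @return numeric vector, one value per variant.
#' @export
fStatistic <- function(x) {
  v <- if (is(x, "SummaryStats")) variants(x) else as.data.frame(x)
  if (any(!is.finite(v$se) | v$se <= 0))
    stop("se must be > 0", call. = FALSE)
  (v$beta / v$se)^2
}
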