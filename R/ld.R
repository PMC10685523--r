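#' Construct an LDTable
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `r2` and optionally
#'   `sign` (sign of the underlying dosage correlation). Unordered pairs are
#'   normalized to `id_a < id_b` and de-duplicated (keeping the first entry).
#' @param positions data.frame with columns `variant_id`, `chrom`, `pos`.
#' @return an [LDTable-class] object.
#' @export
ldTable <- function(pairs = data.frame(id_a = character(), id_b = character(),
                                       r2 = numeric()),
                    positions = data.frame(variant_id = character(),
                                           chrom = character(),
                                           pos = numeric())) {
  p <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!"sign" %in% names(p)) p$sign <- rep(NA_real_, nrow(p))
  if (nrow(p)) {
    p$id_a <- as.character(p$id_a)
    p$id_b <- as.character(p$id_b)
    flip <- p$id_a > p$id_b
    tmp <- p$id_a[flip]; p$id_a[flip] <- p$id_b[flip]; p$id_b[flip] <- tmp
    p <- p[p$id_a != p$id_b, , drop = FALSE]
    p <- p[!duplicated(paste(p$id_a, p$id_b)), , drop = FALSE]
  }
  pos <- as.data.frame(positions, stringsAsFactors = FALSE)
  pos$variant_id <- as.character(pos$variant_id)
  pos$chrom <- as.character(pos$chrom)
  rownames(p) <- rownames(pos) <- NULL
  new("LDTable", pairs = p, positions = pos)
}

#' Read / write an LD table
#'
#' Delimited text with columns `id_a`, `id_b`, `r2` (optionally `sign`) for
#' the pairs and `variant_id`, `chrom`, `pos` for positions; the two blocks
#' live in separate files.
#'
#' @param pairsPath,positionsPath file paths.
#' @return an [LDTable-class] object.
#' @export
readLDTable <- function(pairsPath, positionsPath) {
  ldTable(.readWithHeader(pairsPath, sep = .detectSep(pairsPath)),
          .readWithHeader(positionsPath, sep = .detectSep(positionsPath)))
}

#' @rdname readLDTable
#' @param x an [LDTable-class] object.
#' @export
writeLDTable <- function(x, pairsPath, positionsPath) {
  .writeWithHeader(ldPairs(x), pairsPath)
  .writeWithHeader(ldPositions(x), positionsPath)
  invisible(c(pairsPath, positionsPath))
}

# fast lookup environment: "a|b" (a<b) -> r2
.ldIndex <- function(ld) {
  p <- ldPairs(ld)
  r2 <- p$r2
  names(r2) <- paste(p$id_a, p$id_b, sep = "|")
  r2
}

.pairKey <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

#' Look up pairwise r-squared
#'
#' `r2(v, v)` is 1; variants on different chromosomes have `r2 = 0`; a pair
#' not stored in the table returns `NA` (consumers treat this as 0 and log
#' it when the pair falls inside a window of interest).
#'
#' @param ld an [LDTable-class] object.
#' @param a,b variant ids (vectorized).
#' @return numeric vector of r² values.
#' @export
ldR2 <- function(ld, a, b) {
  idx <- .ldIndex(ld)
  out <- unname(idx[.pairKey(a, b)])
  out[a == b] <- 1
  pos <- ldPositions(ld)
  chr <- pos$chrom[match(a, pos$variant_id)]
  chr_b <- pos$chrom[match(b, pos$variant_id)]
  cross <- !is.na(chr) & !is.na(chr_b) & chr != chr_b
  out[cross & is.na(out)] <- 0
  out
}

#' Pairwise r-squared from a genotype-dosage matrix
#'
#' Computes the squared Pearson correlation between all pairs of dosage
#' columns (individuals x variants, values in `[0, 2]`), together with the
#' correlation sign used later for proxy-allele orientation. Positions may
#' be supplied for window semantics.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns
#'   (column names are the variant ids).
#' @param positions optional data.frame `variant_id`, `chrom`, `pos`; by
#'   default all variants are placed consecutively on one chromosome.
#' @return an [LDTable-class] object.
#' @export
r2FromDosages <- function(dosages, positions = NULL) {
  d <- as.matrix(dosages)
  if (nrow(d) < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (is.null(colnames(d))) colnames(d) <- paste0("v", seq_len(ncol(d)))
  sds <- apply(d, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate (constant) dosage column: ",
         paste(colnames(d)[sds == 0], collapse = ", "), call. = FALSE)
  cc <- stats::cor(d)
  ids <- colnames(d)
  if (is.null(positions))
    positions <- data.frame(variant_id = ids, chrom = "1",
                            pos = seq_along(ids), stringsAsFactors = FALSE)
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  pairs <- data.frame(id_a = ids[ut[, 1L]], id_b = ids[ut[, 2L]],
                      r2 = cc[ut]^2, sign = sign(cc[ut]),
                      stringsAsFactors = FALSE)
  ldTable(pairs, positions)
}
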