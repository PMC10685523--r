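# small in-code fixtures shared across test files

makeVariants <- function(ids, beta, se, eaf = 0.3, pval = 1e-12,
                         chrom = "1", pos = seq_along(ids) * 1e6,
                         ea = "A", oa = "G", n = 10000) {
  data.frame(variant_id = ids, chrom = chrom, pos = pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

makeSS <- function(ids, beta, se, ..., traitName = "trait",
                   traitType = "continuous") {
  summaryStats(makeVariants(ids, beta, se, ...), traitName = traitName,
               traitType = traitType)
}

# brute-force oracle for LD clumping: enumerate all independent subsets,
# keep the maximal ones, choose the lexicographically smallest in p-rank
# order (independent of the greedy path under test)
bruteClump <- function(v, ld, r2Max, windowBp) {
  n <- nrow(v)
  if (n == 0L) return(character())
  ord <- order(v$pval, v$chrom, v$pos, v$variant_id)
  v <- v[ord, , drop = FALSE]
  # pairwise compatibility matrix, computed once
  comp <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (v$chrom[i] != v$chrom[j] || abs(v$pos[i] - v$pos[j]) > windowBp) next
    r2 <- ldR2(ld, v$variant_id[i], v$variant_id[j])
    if (is.na(r2)) r2 <- 0
    comp[i, j] <- r2 < r2Max
  }
  subsets <- lapply(seq_len(2^n) - 1L,
                    function(m) which(bitwAnd(m, 2^(seq_len(n) - 1L)) > 0))
  indep <- Filter(function(s) all(comp[s, s]), subsets)
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(seq_len(n), s),
                function(extra) all(comp[extra, s]), logical(1)))
  }, indep)
  # lexicographic order on the sorted p-rank vectors
  key <- vapply(maximal, function(s)
    paste(sprintf("%03d", sort(s)), collapse = ","), character(1))
  best <- maximal[[order(key)[1L]]]
  v$variant_id[sort(best)]
}

randomLDInstance <- function(nCand, seed) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(nCand))
  chrom <- as.character(sample(1:2, nCand, replace = TRUE))
  pos <- sample.int(3e7, nCand)
  v <- makeVariants(ids, beta = 0.1, se = 0.01, chrom = chrom, pos = pos,
                    pval = stats::runif(nCand, 1e-15, 1e-10))
  cmb <- if (nCand >= 2) utils::combn(ids, 2) else matrix(character(), 2, 0)
  keep <- stats::runif(ncol(cmb)) < 0.6  # sparse table
  pairs <- data.frame(id_a = cmb[1, keep], id_b = cmb[2, keep],
                      r2 = stats::runif(sum(keep))^2,
                      stringsAsFactors = FALSE)
  # cross-chromosome pairs must carry r2 = 0
  chr_of <- stats::setNames(chrom, ids)
  cross <- chr_of[pairs$id_a] != chr_of[pairs$id_b]
  pairs$r2[cross] <- 0
  ld <- ldTable(pairs, data.frame(variant_id = ids, chrom = chrom,
                                  pos = pos, stringsAsFactors = FALSE))
  list(v = v, ld = ld)
}
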