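#' Configuration for the synthetic two-sample GWAS generator
#'
#' Bundles and validates the generating parameters. Defaults are sized to
#' echo the study conditions the package targets: an exposure GWAS of
#' ~85,000 participants (a large metabolite meta-analysis), a much smaller
#' outcome GWAS (10,000) so that outcome noise dominates at desk scale,
#' allele frequencies in (0.10, 0.50) and per-allele effect magnitudes in
#' (0.05, 0.30) SD, which give single-instrument F-statistics of roughly
#' 40-4000 — the strong-instrument regime reported for amino-acid GWAS
#' instruments.
#'
#' @param nSnps number of instruments to simulate.
#' @param mafRange allele-frequency range, subset of (0, 1).
#' @param effectRange range of |true exposure effect| in SD units; signs
#'   are random.
#' @param causalTheta true causal effect of exposure on outcome.
#' @param pleiotropy `"none"`, `"balanced"` (direct effects N(0, sd)) or
#'   `"directional"` (N(mean, sd)).
#' @param pleiotropyMean,pleiotropySd parameters of the pleiotropy
#'   distribution.
#' @param propInvalid proportion of instruments carrying pleiotropy
#'   (rounded to a count; 1 means all).
#' @param insideViolation if `TRUE`, pleiotropic effects are scaled by
#'   instrument strength (|b|/mean|b|), violating the InSIDE assumption.
#' @param nExposure,nOutcome GWAS sample sizes for the two samples.
#' @param outcomeType `"continuous"` or `"binary"`. Binary outcomes are
#'   simulated directly on the log-OR scale (observed log-OR = truth +
#'   normal noise); sufficient for estimator algebra and calibration.
#' @param ldBlocks optional list `list(blockSize=, r2Within=,
#'   nIndividuals=)`; when set, instruments come in LD blocks and the study
#'   carries an [LDTable-class] estimated from simulated dosages.
#' @param noiseScale multiplier on both the sampling noise and the reported
#'   standard errors; a near-zero value yields a noise-free study whose
#'   estimators must recover `causalTheta` almost exactly.
#' @param seed mandatory RNG seed.
#' @return a validated list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(nSnps = 10, mafRange = c(0.10, 0.50),
                             effectRange = c(0.05, 0.30), causalTheta = 0,
                             pleiotropy = c("none", "balanced", "directional"),
                             pleiotropyMean = 0, pleiotropySd = 0,
                             propInvalid = if (pleiotropy[1] == "none") 0 else 1,
                             insideViolation = FALSE,
                             nExposure = 85000, nOutcome = 10000,
                             outcomeType = c("binary", "continuous"),
                             ldBlocks = NULL, noiseScale = 1, seed) {
  pleiotropy <- match.arg(pleiotropy)
  outcomeType <- match.arg(outcomeType)
  if (missing(seed) || !is.finite(seed))
    stop("a seed is mandatory for the generator", call. = FALSE)
  stopifnot(nSnps >= 1, length(mafRange) == 2L, mafRange[1] > 0,
            mafRange[2] < 1, mafRange[1] <= mafRange[2],
            length(effectRange) == 2L, effectRange[1] >= 0,
            effectRange[1] <= effectRange[2],
            propInvalid >= 0, propInvalid <= 1,
            nExposure >= 1, nOutcome >= 1, noiseScale >= 0)
  structure(list(nSnps = as.integer(nSnps), mafRange = mafRange,
                 effectRange = effectRange, causalTheta = causalTheta,
                 pleiotropy = pleiotropy, pleiotropyMean = pleiotropyMean,
                 pleiotropySd = pleiotropySd, propInvalid = propInvalid,
                 insideViolation = insideViolation, nExposure = nExposure,
                 nOutcome = nOutcome, outcomeType = outcomeType,
                 ldBlocks = ldBlocks, noiseScale = noiseScale,
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

#' Simulate a two-sample GWAS with known causal ground truth
#'
#' Per variant j: allele frequency `p_j ~ U(mafRange)`; true exposure
#' effect `b_j` with `|b_j| ~ U(effectRange)` and random sign; direct
#' (pleiotropic) outcome effect `alpha_j` per the pleiotropy configuration,
#' defined relative to the exposure-increasing allele (allele coding is
#' arbitrary, so "directional" is only meaningful in that orientation);
#' true outcome effect `theta * b_j + sign(b_j) * alpha_j`. Observed effects add
#' independent Gaussian noise with the standardized-trait standard error
#' `se = noiseScale / sqrt(2 p_j (1-p_j) n)` for the respective sample —
#' the same sampling model that underlies the z-score conversion of
#' [zscoreToBeta()] — so exposure and outcome noise are independent as in a
#' two-sample design. z-scores and p-values are emitted so the
#' significance-selection stage can be exercised on simulated data.
#'
#' @param config a [simulationConfig()] object.
#' @return a [SyntheticStudy-class] object.
#' @export
simulateTwoSample <- function(config) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed)
  k <- config$nSnps
  maf <- stats::runif(k, config$mafRange[1], config$mafRange[2])
  b <- sample(c(-1, 1), k, replace = TRUE) *
    stats::runif(k, config$effectRange[1], config$effectRange[2])

  alpha <- numeric(k)
  n_invalid <- round(config$propInvalid * k)
  invalid <- if (n_invalid > 0) sample.int(k, n_invalid) else integer()
  if (config$pleiotropy != "none" && length(invalid)) {
    mu <- if (config$pleiotropy == "balanced") 0 else config$pleiotropyMean
    a <- stats::rnorm(length(invalid), mu, config$pleiotropySd)
    if (config$insideViolation)
      a <- a * abs(b[invalid]) / mean(abs(b))
    alpha[invalid] <- a
  }
  # pleiotropy is directional with respect to the exposure-increasing
  # allele (the orientation estimators use), so it enters as sign(b)*alpha
  by_true <- config$causalTheta * b + sign(b) * alpha

  se_x <- config$noiseScale / sqrt(2 * maf * (1 - maf) * config$nExposure)
  se_y <- config$noiseScale / sqrt(2 * maf * (1 - maf) * config$nOutcome)
  se_x <- pmax(se_x, .Machine$double.xmin)
  se_y <- pmax(se_y, .Machine$double.xmin)
  bx <- b + stats::rnorm(k, 0, se_x)
  by <- by_true + stats::rnorm(k, 0, se_y)

  ids <- sprintf("rs%06d", seq_len(k))
  if (is.null(config$ldBlocks)) {
    # spread instruments genome-wide so none fall in a clumping window
    chrom <- as.character(rep_len(1:22, k))
    pos <- 1e6 + 1e6 * (seq_len(k) - 1L) %/% 22L
    ld <- ldTable(positions = data.frame(variant_id = ids, chrom = chrom,
                                         pos = pos, stringsAsFactors = FALSE))
  } else {
    lb <- config$ldBlocks
    sim <- simulateLDBlocks(nSnps = k, blockSize = lb$blockSize,
                            r2Within = lb$r2Within,
                            nIndividuals = lb$nIndividuals %||% 1000,
                            ids = ids)
    ld <- sim$ld
    pos <- ldPositions(ld)
    chrom <- pos$chrom[match(ids, pos$variant_id)]
    pos <- pos$pos[match(ids, ldPositions(ld)$variant_id)]
  }

  mk_tab <- function(beta, se, n, name, type) {
    z <- beta / se
    summaryStats(data.frame(variant_id = ids, chrom = chrom, pos = pos,
                            effect_allele = "A", other_allele = "G",
                            eaf = maf, beta = beta, se = se,
                            pval = pmax(2 * stats::pnorm(-abs(z)),
                                        .Machine$double.xmin), n = n,
                            z = z, stringsAsFactors = FALSE),
                 traitName = name, traitType = type)
  }
  new("SyntheticStudy",
      exposure = mk_tab(bx, se_x, config$nExposure, "synthetic_exposure",
                        "continuous"),
      outcome = mk_tab(by, se_y, config$nOutcome, "synthetic_outcome",
                       config$outcomeType),
      truth = list(theta = config$causalTheta, beta_exp_true = b,
                   alpha = alpha, valid = alpha == 0, maf = maf,
                   config = config),
      ld = ld)
}

#' Simulate block-structured genotype dosages and their LD table
#'
#' Generates synthetic dosage values in `[0, 2]` with a specified
#' within-block squared correlation and independence across blocks.
#' Latent Gaussian factors are shared within a block and mapped to `[0, 2]`
#' by the probability-integral transform (`2 * pnorm(x)`); the latent
#' correlation is pre-corrected (`2 sin(pi r / 6)`) so the transformed
#' variables hit the target correlation. Blocks sit on consecutive
#' chromosomes with 100 kb spacing within a block.
#'
#' @param nSnps total number of variants.
#' @param blockSize variants per block (>= 1; the last block may be short).
#' @param r2Within target pairwise r² within a block, in `[0, 1)`.
#' @param nIndividuals rows of the dosage matrix (>= 2).
#' @param ids optional variant ids.
#' @return list with `dosages` (matrix) and `ld` ([LDTable-class]).
#' @export
simulateLDBlocks <- function(nSnps, blockSize, r2Within, nIndividuals = 1000,
                             ids = sprintf("rs%06d", seq_len(nSnps))) {
  stopifnot(blockSize >= 1, nIndividuals >= 2)
  if (r2Within < 0 || r2Within >= 1)
    stop("r2Within must lie in [0, 1)", call. = FALSE)
  r_target <- sqrt(r2Within)
  # invert the Gaussian->uniform correlation attenuation (6/pi asin(rho/2))
  rho <- 2 * sin(pi * r_target / 6)
  block <- rep(seq_len(ceiling(nSnps / blockSize)), each = blockSize)[seq_len(nSnps)]
  d <- matrix(NA_real_, nIndividuals, nSnps)
  for (bk in unique(block)) {
    cols <- which(block == bk)
    g0 <- stats::rnorm(nIndividuals)
    for (j in cols) {
      x <- sqrt(rho) * g0 + sqrt(1 - rho) * stats::rnorm(nIndividuals)
      d[, j] <- 2 * stats::pnorm(x)
    }
  }
  colnames(d) <- ids
  positions <- data.frame(variant_id = ids, chrom = as.character(block),
                          pos = 1e6 + 1e5 * (seq_len(nSnps) -
                                               match(block, block)),
                          stringsAsFactors = FALSE)
  list(dosages = d, ld = r2FromDosages(d, positions))
}

#' Pair a synthetic study's tables into a HarmonizedData object
#'
#' Synthetic exposure and outcome tables share variant ids and alleles by
#' construction, so harmonization is a direct id join; this avoids the full
#' allele-matching machinery in simulation loops.
#'
#' @param study a [SyntheticStudy-class] object.
#' @return a [HarmonizedData-class] object.
#' @export
harmonizeStudy <- function(study) {
  ev <- variants(study@exposure)
  ov <- variants(study@outcome)
  at <- match(ev$variant_id, ov$variant_id)
  mrInput(bx = ev$beta, bxse = ev$se, by = ov$beta[at], byse = ov$se[at],
          ids = ev$variant_id, exposureName = traitName(study@exposure),
          outcomeName = traitName(study@outcome),
          outcomeType = traitType(study@outcome))
}
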