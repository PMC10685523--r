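test_that("Wald ratio is the outcome/exposure quotient with delta-method SE", {
  hd <- mrInput(bx = 0.2, bxse = 0.01, by = 0.1, byse = 0.05)
  est <- mrWaldRatio(hd)
  expect_equal(mrBeta(est), 0.5)
  expect_equal(mrSE(est), 0.25)
  expect_equal(mrCI(est), c(0.5 - 1.96 * 0.25, 0.5 + 1.96 * 0.25))

  expect_equal(mrBeta(mrWaldRatio(mrInput(0.2, 0.01, 0, 0.05))), 0)
  # orientation invariance: negating both effects changes nothing
  neg <- mrWaldRatio(mrInput(-0.2, 0.01, -0.1, 0.05))
  expect_identical(mrBeta(neg), mrBeta(est))
  expect_identical(mrSE(neg), mrSE(est))
  expect_error(mrWaldRatio(mrInput(0, 0.01, 0.1, 0.05)), "degenerate")
})

test_that("IVW matches hand arithmetic, reduces to Wald at k=1, detects homogeneity", {
  # w = (bx/sy)^2: weights 100 and 400 -> beta (100*0.5+400*0.3)/500
  hd <- mrInput(bx = c(1, 2), bxse = 0.01, by = c(0.5, 0.6), byse = 0.1)
  fe <- mrIVW(hd, "fixed")
  expect_equal(mrBeta(fe), 0.34, tolerance = 1e-12)
  expect_equal(mrSE(fe), 1 / sqrt(500), tolerance = 1e-12)
  expect_equal(fe@qStat, 3.2, tolerance = 1e-12)

  # bit-wise k=1 reduction across random inputs
  set.seed(7)
  for (i in 1:50) {
    bx <- stats::rnorm(1); by <- stats::rnorm(1)
    sx <- stats::runif(1, 0.001, 1); sy <- stats::runif(1, 0.001, 1)
    if (bx == 0) next
    one <- mrInput(bx, sx, by, sy)
    expect_identical(mrBeta(mrIVW(one, "fixed")), mrBeta(mrWaldRatio(one)))
    expect_identical(mrSE(mrIVW(one, "fixed")), mrSE(mrWaldRatio(one)))
  }

  # shared ratio: Q = 0 and the multiplicative factor floors at 1
  hom <- mrInput(bx = c(1, 2, 4), bxse = 0.01, by = c(0.3, 0.6, 1.2),
                 byse = 0.1)
  fe2 <- mrIVW(hom, "fixed"); mre <- mrIVW(hom, "multiplicative_random")
  expect_equal(mrBeta(fe2), 0.3)
  expect_equal(fe2@qStat, 0, tolerance = 1e-20)
  expect_equal(mrSE(mre), mrSE(fe2))
  expect_error(mrIVW(mrInput(c(0, 1), 0.01, c(1, 1), 0.1), "fixed"),
               "degenerate")
})

test_that("Cochran's Q matches hand arithmetic and its null distribution", {
  hd <- mrInput(bx = c(1, 2), bxse = 0.01, by = c(0.5, 0.6), byse = 0.1)
  q <- cochransQ(hd, center = 0.34)
  expect_equal(q$Q, 100 * 0.16^2 + 400 * 0.04^2, tolerance = 1e-12)
  expect_equal(q$Q, 3.2, tolerance = 1e-12)
  expect_equal(q$df, 1L)
  hom <- mrInput(bx = c(1, 2), bxse = 0.01, by = c(0.3, 0.6), byse = 0.1)
  qh <- cochransQ(hom)
  expect_equal(qh$Q, 0, tolerance = 1e-20)
  expect_equal(qh$pval, 1)
  expect_error(cochransQ(mrInput(1, 0.01, 1, 0.1)), "at least 2")

  # under the null Q ~ chi-square(k-1): check mean over seeded replicates
  qs <- vapply(1:400, function(i) {
    s <- simulateTwoSample(simulationConfig(nSnps = 10, causalTheta = 0,
                                            seed = 50000 + i))
    cochransQ(harmonizeStudy(s))$Q
  }, numeric(1))
  expect_gt(mean(qs), 9 * 0.88)
  expect_lt(mean(qs), 9 * 1.12)
})

test_that("Egger regression recovers an exact line and flags degeneracy", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  hd <- mrInput(bx, 0.01, 0.02 + 0.5 * bx, c(0.1, 0.2, 0.1, 0.3, 0.15))
  eg <- mrEgger(hd)
  expect_equal(mrBeta(eg$intercept), 0.02, tolerance = 1e-10)
  expect_equal(mrBeta(eg$slope), 0.5, tolerance = 1e-10)
  expect_error(mrEgger(mrInput(c(1, 2), 0.01, c(1, 2), 0.1)), "at least 3")
  expect_error(mrEgger(mrInput(c(1, 1, 1), 0.01, c(1, 2, 3), 0.1)),
               "collinear")
  # negative exposure effects are re-oriented, not mishandled
  eg2 <- mrEgger(mrInput(-bx, 0.01, -(0.02 + 0.5 * bx),
                         c(0.1, 0.2, 0.1, 0.3, 0.15)))
  expect_equal(mrBeta(eg2$slope), 0.5, tolerance = 1e-10)
})

test_that("weighted median interpolates ordered ratios at half weight", {
  hd <- mrInput(bx = c(1, 1, 1), bxse = 1e-6, by = c(0.1, 0.2, 0.3), byse = 1)
  est <- mrWeightedMedian(hd, nBoot = 200, seed = 1)
  expect_equal(mrBeta(est), 0.2)

  # all ratios equal: estimate r, bootstrap SE collapses as noise vanishes
  same <- mrInput(bx = c(1, 2, 4), bxse = 1e-9, by = c(0.3, 0.6, 1.2),
                  byse = 1e-9)
  est2 <- mrWeightedMedian(same, nBoot = 200, seed = 1)
  expect_equal(mrBeta(est2), 0.3, tolerance = 1e-8)
  expect_lt(mrSE(est2), 1e-7)
  expect_error(mrWeightedMedian(mrInput(c(1, 2), 0.01, c(1, 2), 0.1)),
               "at least 3")
})

test_that("weighted median resists a minority of invalid instruments", {
  # 10 valid instruments (theta = 0.3) + 4 pleiotropic ones pushed to 0.8;
  # near-zero noise isolates the estimator algebra
  bx <- rep(0.2, 14)
  by <- c(rep(0.06, 10), rep(0.16, 4))
  hd <- mrInput(bx, 1e-8, by, rep(0.01, 14))
  wm <- mrWeightedMedian(hd, nBoot = 200, seed = 2)
  ivw <- mrIVW(hd, "fixed")
  expect_equal(mrBeta(wm), 0.3, tolerance = 1e-6)
  expect_gt(mrBeta(ivw), 0.4)  # IVW dragged upward by the invalid minority
})

test_that("weighted mode finds the dominant cluster and breaks ties low", {
  same <- mrInput(bx = c(1, 2, 4), bxse = 1e-9, by = c(0.3, 0.6, 1.2),
                  byse = 1e-9)
  expect_equal(mrBeta(mrWeightedMode(same, nBoot = 100, seed = 1)), 0.3)

  # cluster of 7 near 0.3 plus 3 outliers near 1.0
  r <- c(0.28, 0.29, 0.30, 0.30, 0.31, 0.32, 0.30, 0.98, 1.0, 1.02)
  hd <- mrInput(bx = rep(1, 10), bxse = 1e-8, by = r, byse = 0.05)
  est <- mrWeightedMode(hd, nBoot = 100, seed = 1)
  expect_lt(abs(mrBeta(est) - 0.3), 0.05)

  # exact symmetric bimodal tie resolves to the smaller mode
  r2 <- c(0.1, 0.1, 0.5, 0.5)
  tie <- mrInput(bx = rep(1, 4), bxse = 1e-8, by = r2, byse = 0.05)
  expect_lt(mrBeta(mrWeightedMode(tie, nBoot = 100, seed = 1)), 0.3)
})

test_that("estimators are orientation-invariant and scale-equivariant", {
  set.seed(99)
  for (i in 1:5) {
    k <- 8
    bx <- stats::rnorm(k, 0.2, 0.05); sx <- stats::runif(k, 0.005, 0.02)
    by <- 0.4 * bx + stats::rnorm(k, 0, 0.02); sy <- stats::runif(k, 0.01, 0.05)
    hd <- mrInput(bx, sx, by, sy)
    flip <- c(TRUE, rep(FALSE, k - 1))
    sgn <- ifelse(flip, -1, 1)
    hd_f <- mrInput(bx * sgn, sx, by * sgn, sy)
    expect_equal(mrBeta(mrIVW(hd_f, "fixed")), mrBeta(mrIVW(hd, "fixed")))
    expect_equal(mrBeta(mrEgger(hd_f)$slope), mrBeta(mrEgger(hd)$slope))
    expect_equal(mrBeta(mrWeightedMedian(hd_f, nBoot = 50, seed = 3)),
                 mrBeta(mrWeightedMedian(hd, nBoot = 50, seed = 3)))
    # scaling the outcome by c > 0 scales beta and se by c
    cc <- 2.5
    hd_s <- mrInput(bx, sx, cc * by, cc * sy)
    expect_equal(mrBeta(mrIVW(hd_s, "fixed")), cc * mrBeta(mrIVW(hd, "fixed")))
    expect_equal(mrSE(mrIVW(hd_s, "fixed")), cc * mrSE(mrIVW(hd, "fixed")))
  }
})

test_that("method selection follows the instrument-count rules", {
  expect_identical(selectMainMethod(1)$main, "wald_ratio")
  p3 <- selectMainMethod(3)
  expect_identical(p3$main, "ivw")
  expect_identical(p3$variant, "fixed")
  expect_length(p3$sensitivity, 0)
  p20 <- selectMainMethod(20)
  expect_identical(p20$variant, "multiplicative_random")
  expect_setequal(p20$sensitivity, c("weighted_median", "mr_egger"))
  p4 <- selectMainMethod(4, "continuous_pdff")
  expect_identical(p4$outcomeMode, "continuous_pdff")
  expect_setequal(p4$sensitivity, c("weighted_median", "mr_egger"))
  expect_error(selectMainMethod(0), "no instruments")
})
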