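test_that("significance thresholds reproduce the printed corrections", {
  expect_equal(signif(significanceThreshold(5e-8, 102), 2), 4.9e-10)
  expect_identical(significanceThreshold(0.05, 1), 0.05)
  expect_identical(significanceThreshold(0.05, 20), 0.0025)
  expect_error(significanceThreshold(0, 10))
  expect_error(significanceThreshold(0.05, 0))
})

test_that("greedy clumping keeps the best of a correlated pair and ignores cross-chromosome pairs", {
  v <- makeVariants(c("a", "b"), beta = 0.1, se = 0.01,
                    pval = c(1e-12, 1e-11), pos = c(1e6, 2e6))
  ld <- ldTable(data.frame(id_a = "a", id_b = "b", r2 = 0.5),
                data.frame(variant_id = c("a", "b"), chrom = "1",
                           pos = c(1e6, 2e6)))
  expect_identical(ldClump(v, ld, r2Max = 0.01, windowBp = 1e7), "a")

  v2 <- makeVariants(c("a", "b"), beta = 0.1, se = 0.01,
                     pval = c(1e-12, 1e-11), chrom = c("1", "2"),
                     pos = c(1e6, 1e6))
  ld2 <- ldTable(positions = data.frame(variant_id = c("a", "b"),
                                        chrom = c("1", "2"), pos = 1e6))
  expect_setequal(ldClump(v2, ld2, 0.01, 1e7), c("a", "b"))

  # one tight block of 4 plus one independent variant -> exactly 2 retained
  ids <- c("b1", "b2", "b3", "b4", "solo")
  v3 <- makeVariants(ids, beta = 0.1, se = 0.01,
                     pval = c(1e-14, 1e-13, 1e-12, 1e-11, 1e-10),
                     pos = c(1e6, 2e6, 3e6, 4e6, 9e8))
  cmb <- utils::combn(ids[1:4], 2)
  ld3 <- ldTable(data.frame(id_a = cmb[1, ], id_b = cmb[2, ], r2 = 0.9),
                 data.frame(variant_id = ids, chrom = "1",
                            pos = c(1e6, 2e6, 3e6, 4e6, 9e8)))
  kept <- ldClump(v3, ld3, 0.01, 1e7)
  expect_identical(sort(kept), c("b1", "solo"))
  expect_identical(sort(bruteClump(makeVariants(ids, 0.1, 0.01,
                                                pval = c(1e-14, 1e-13, 1e-12, 1e-11, 1e-10),
                                                pos = c(1e6, 2e6, 3e6, 4e6, 9e8)),
                                   ld3, 0.01, 1e7)),
                   sort(kept))
  expect_identical(ldClump(v3[0, ], ld3, 0.01, 1e7), character())
})

test_that("clumping is input-order invariant and respects threshold extremes", {
  inst <- randomLDInstance(7, seed = 101)
  kept <- suppressWarnings(ldClump(inst$v, inst$ld, r2Max = 0.1, windowBp = 1e7))
  shuffled <- inst$v[c(4, 1, 7, 2, 6, 3, 5), ]
  expect_identical(suppressWarnings(ldClump(shuffled, inst$ld, r2Max = 0.1, windowBp = 1e7)), kept)
  # retained same-chromosome pairs within the window satisfy r2 < r2Max
  if (length(kept) >= 2) {
    cmb <- utils::combn(kept, 2)
    pos <- ldPositions(inst$ld)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      ca <- pos$chrom[pos$variant_id == a]; cb <- pos$chrom[pos$variant_id == b]
      if (ca == cb && abs(pos$pos[pos$variant_id == a] -
                          pos$pos[pos$variant_id == b]) <= 1e7) {
        r2 <- ldR2(inst$ld, a, b); if (is.na(r2)) r2 <- 0
        expect_lt(r2, 0.1)
      }
    }
  }
  # r2Max = 1 retains everything (all stored r2 < 1 here)
  expect_setequal(suppressWarnings(ldClump(inst$v, inst$ld, r2Max = 1 + 1e-9, windowBp = 1e7)),
                  inst$v$variant_id)
})

test_that("greedy clumping equals the brute-force maximal p-ordered set", {
  for (seed in 1:40) {
    inst <- randomLDInstance(sample(2:8, 1), seed = 2000 + seed)
    for (r2Max in c(0.01, 0.3)) {
      got <- suppressWarnings(ldClump(inst$v, inst$ld, r2Max, 1e7))
      want <- suppressWarnings(bruteClump(inst$v, inst$ld, r2Max, 1e7))
      expect_setequal(got, want)
    }
  }
})

test_that("proxy search returns the best-r2 candidate with deterministic ties", {
  out <- makeSS(c("p1", "p2", "p3"), beta = 0.01, se = 0.01,
                pos = c(1.1e6, 1.2e6, 1.3e6))
  pos <- data.frame(variant_id = c("miss", "p1", "p2", "p3"), chrom = "1",
                    pos = c(1e6, 1.1e6, 1.2e6, 1.3e6))
  ld <- ldTable(data.frame(id_a = "miss", id_b = "p1", r2 = 0.95), pos)
  expect_identical(findProxy("miss", out, ld), "p1")

  ld2 <- ldTable(data.frame(id_a = c("miss", "miss"), id_b = c("p1", "p2"),
                            r2 = c(0.85, 0.92)), pos)
  expect_identical(findProxy("miss", out, ld2), "p2")

  # exact r2 tie broken by smaller positional distance, then id
  ld3 <- ldTable(data.frame(id_a = c("miss", "miss"), id_b = c("p1", "p3"),
                            r2 = c(0.9, 0.9)), pos)
  expect_identical(findProxy("miss", out, ld3), "p1")

  # nothing above the threshold -> NULL, instrument dropped downstream
  ld4 <- ldTable(data.frame(id_a = "miss", id_b = "p1", r2 = 0.5), pos)
  expect_null(findProxy("miss", out, ld4))
  expect_error(findProxy("unknown", out, ld4), "not in LD table")
})

test_that("dosage r2 equals squared Pearson correlation", {
  d <- cbind(v1 = c(0, 1, 2, 1, 0, 2), v2 = c(0, 1, 2, 1, 0, 2))
  expect_equal(ldPairs(r2FromDosages(d))$r2, 1)

  d2 <- cbind(a = c(0, 2, 0, 2), b = c(0, 2, 2, 0))  # zero correlation
  expect_equal(ldPairs(r2FromDosages(d2))$r2, 0)

  # fixed 6x2 hand-computed matrix: cov 3, sds sqrt(4/5) each -> r = 0.75
  d3 <- cbind(x = c(0, 1, 2, 1, 0, 2), y = c(0, 1, 1, 2, 0, 2))
  expect_equal(ldPairs(r2FromDosages(d3))$r2, 0.5625, tolerance = 1e-12)
  expect_equal(ldPairs(r2FromDosages(d3))$sign, 1)

  expect_error(r2FromDosages(cbind(a = c(1, 1, 1), b = c(0, 1, 2))),
               "constant")
})

test_that("selectInstruments applies threshold, exclusion and clumping together", {
  v <- makeVariants(c("hit1", "hit2", "weak", "conf"), beta = 0.1, se = 0.01,
                    pval = c(1e-12, 1e-11, 1e-6, 1e-13),
                    pos = c(1e6, 5e8, 6e8, 7e8))
  ss <- summaryStats(v, "exp")
  ld <- ldTable(positions = v[, c("variant_id", "chrom", "pos")])
  instr <- selectInstruments(ss, ld, alphaGW = 5e-8, nTests = 102,
                             exclude = "conf")
  expect_setequal(variants(instr)$variant_id, c("hit1", "hit2"))
  expect_equal(instr@settings$p_threshold, 5e-8 / 102)
})
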