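expAssoc <- function(ea = "A", oa = "G", beta = 0.1, se = 0.01, eaf = 0.2)
  list(effect_allele = ea, other_allele = oa, beta = beta, se = se, eaf = eaf)

test_that("allele alignment covers match, swap, strand complement and mismatch", {
  # matching alleles pass through unchanged
  r <- harmonizePair(expAssoc("A", "G"), expAssoc("A", "G", beta = 0.05))
  expect_equal(r$pair$beta_out, 0.05)
  expect_identical(r$pair$action_log, "ok")

  # swapped alleles negate the outcome effect
  r <- harmonizePair(expAssoc("A", "G"), expAssoc("G", "A", beta = 0.05))
  expect_equal(r$pair$beta_out, -0.05)

  # strand complement: T/C on the other strand is A/G
  r <- harmonizePair(expAssoc("A", "G"), expAssoc("T", "C", beta = 0.07))
  expect_equal(r$pair$beta_out, 0.07)
  expect_identical(r$pair$action_log, "strand_complemented")
  r <- harmonizePair(expAssoc("A", "G"), expAssoc("C", "T", beta = 0.07))
  expect_equal(r$pair$beta_out, -0.07)

  # irreconcilable alleles drop
  r <- harmonizePair(expAssoc("A", "G"), expAssoc("A", "C"))
  expect_identical(r$drop, "allele_mismatch")
  expect_error(harmonizePair(expAssoc("A", "X"), expAssoc("A", "G")), "A/C/G/T")
})

test_that("palindromic variants follow the configured policy", {
  # default mirrors unconditional removal of palindromes
  r <- harmonizePair(expAssoc("A", "T"), expAssoc("A", "T"))
  expect_identical(r$drop, "palindromic")
  r <- harmonizePair(expAssoc("C", "G"), expAssoc("C", "G"))
  expect_identical(r$drop, "palindromic")

  # frequency inference aligns unambiguous palindromes ...
  r <- harmonizePair(expAssoc("A", "T", eaf = 0.2),
                     expAssoc("A", "T", beta = 0.03, eaf = 0.25),
                     palindromePolicy = "frequency_inference")
  expect_equal(r$pair$beta_out, 0.03)
  r <- harmonizePair(expAssoc("A", "T", eaf = 0.2),
                     expAssoc("A", "T", beta = 0.03, eaf = 0.8),
                     palindromePolicy = "frequency_inference")
  expect_equal(r$pair$beta_out, -0.03)
  # ... and drops ambiguous or frequency-less ones
  r <- harmonizePair(expAssoc("A", "T", eaf = 0.45),
                     expAssoc("A", "T", eaf = 0.45),
                     palindromePolicy = "frequency_inference")
  expect_identical(r$drop, "palindromic_ambiguous")
  r <- harmonizePair(expAssoc("A", "T", eaf = 0.2),
                     expAssoc("A", "T", eaf = NA),
                     palindromePolicy = "frequency_inference")
  expect_identical(r$drop, "palindromic_no_eaf")
})

test_that("harmonization is idempotent and symmetric under double flip", {
  e <- expAssoc("A", "G", beta = 0.1)
  o <- expAssoc("A", "G", beta = 0.05, eaf = 0.3)
  once <- harmonizePair(e, o)$pair
  again <- harmonizePair(e, list(effect_allele = "A", other_allele = "G",
                                 beta = once$beta_out, se = once$se_out,
                                 eaf = 0.3))$pair
  expect_equal(again, once)
  # swapping outcome alleles and negating its beta gives the same pair
  flipped <- harmonizePair(e, expAssoc("G", "A", beta = -0.05, eaf = 0.7))$pair
  expect_equal(flipped$beta_out, once$beta_out)
  expect_equal(flipped$se_out, once$se_out)
})

test_that("dataset harmonization partitions instruments into pairs and drops", {
  instr <- makeSS(c("rs1", "rs2", "rs3"), beta = c(0.1, 0.2, 0.15),
                  se = 0.01, pos = c(1e6, 2e6, 3e6))
  outcome <- makeSS(c("rs1", "rs2", "rs3"), beta = c(0.02, -0.01, 0.03),
                    se = 0.05, pos = c(1e6, 2e6, 3e6),
                    traitName = "disease", traitType = "binary")
  hd <- harmonizeData(instr, outcome)
  expect_equal(nrow(harmonizedPairs(hd)), 3L)
  expect_equal(nrow(droppedVariants(hd)), 0L)
  expect_identical(hd@outcomeType, "binary")

  # |pairs| + |dropped| always equals instruments attempted
  pal <- makeVariants("rs2", beta = 0.2, se = 0.01, ea = "A", oa = "T",
                      pos = 2e6)
  instr2 <- summaryStats(rbind(makeVariants("rs1", 0.1, 0.01, pos = 1e6),
                               pal), "exp")
  out2 <- summaryStats(rbind(makeVariants("rs1", 0.02, 0.05, pos = 1e6),
                             makeVariants("rs2", 0.01, 0.05, ea = "A",
                                          oa = "T", pos = 2e6)),
                       "disease", "binary")
  hd2 <- harmonizeData(instr2, out2)
  expect_equal(nrow(harmonizedPairs(hd2)) + nrow(droppedVariants(hd2)), 2L)
  expect_identical(droppedVariants(hd2)$reason, "palindromic")
})

test_that("absent instruments use proxies when available, else drop", {
  instr <- makeSS("rs_miss", beta = 0.2, se = 0.01, pos = 1e6)
  outcome <- makeSS("rs_proxy", beta = 0.04, se = 0.05, pos = 1.2e6,
                    traitName = "disease", traitType = "binary")
  pos <- data.frame(variant_id = c("rs_miss", "rs_proxy"), chrom = "1",
                    pos = c(1e6, 1.2e6))
  ld <- ldTable(data.frame(id_a = "rs_miss", id_b = "rs_proxy", r2 = 0.95,
                           sign = -1), pos)
  hd <- harmonizeData(instr, outcome, ld = ld)
  p <- harmonizedPairs(hd)
  expect_equal(nrow(p), 1L)
  expect_identical(p$proxy_id, "rs_proxy")
  expect_equal(p$beta_out, -0.04)  # oriented by the dosage-correlation sign
  expect_match(p$action_log, "proxy\\(rs_proxy\\)")

  # unsigned LD entry: proxy used as-is but flagged for review
  ld2 <- ldTable(data.frame(id_a = "rs_miss", id_b = "rs_proxy", r2 = 0.95), pos)
  hd2 <- harmonizeData(instr, outcome, ld = ld2)
  expect_equal(harmonizedPairs(hd2)$beta_out, 0.04)
  expect_match(harmonizedPairs(hd2)$action_log, "orientation_unverified")

  # no qualifying proxy: instrument dropped with reason
  ld3 <- ldTable(data.frame(id_a = "rs_miss", id_b = "rs_proxy", r2 = 0.5), pos)
  hd3 <- harmonizeData(instr, outcome, ld = ld3)
  expect_equal(nrow(harmonizedPairs(hd3)), 0L)
  expect_identical(droppedVariants(hd3)$reason, "no_proxy")
})
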