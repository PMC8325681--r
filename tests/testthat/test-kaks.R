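# Expected values marked below were computed with the brute-force
# enumeration oracle in helper-oracles.R and frozen.

test_that("per-codon site counts match enumeration and always sum to 3", {
  expect_equal(countSites("GGT"), c(s = 1, n = 2))        # fourfold third pos
  expect_equal(countSites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(countSites("ATG"), c(s = 0, n = 3))        # Met: no synonym
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (cd in sense) {
    got <- countSites(cd)
    expect_equal(unname(sum(got)), 3)
    expect_equal(got, oracleSites(cd))
  }
  expect_error(countSites("TAA"), "stop")
  expect_error(countSites("ANG"), "ambiguous")
})

test_that("difference counts are pathway-averaged, symmetric and sum to the Hamming distance", {
  expect_equal(countDifferences("GGT", "GGC"), c(sd = 1, nd = 0))
  expect_equal(countDifferences("TTT", "TTA"), c(sd = 0, nd = 1))
  # two-difference pair: average over both orderings
  expect_equal(countDifferences("TTT", "GTA"), oracleDiffs("TTT", "GTA"))

  set.seed(42)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (k in 1:40) {
    a <- sample(sense, 1)
    b <- sample(sense, 1)
    ab <- countDifferences(a, b)
    ba <- countDifferences(b, a)
    expect_equal(ab[["sd"]], ba[["sd"]])
    expect_equal(ab[["nd"]], ba[["nd"]])
    ham <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(sum(ab)), ham)
  }
})

test_that("computeKaKs reproduces the worked single-difference case", {
  r0 <- computeKaKs(strrep("GGT", 30), strrep("GGT", 30))
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)

  r <- computeKaKs(strrep("GGT", 9), paste0(strrep("GGT", 8), "GGC"))
  expect_equal(r$s_sites, 9)
  expect_equal(r$n_sites, 18)
  expect_equal(r$s_diffs, 1)
  expect_equal(r$n_diffs, 0)
  expect_equal(r$ks, -0.75 * log(1 - 4 / 27))
  expect_equal(r$ka, 0)
})

test_that("saturated and degenerate inputs are flagged, not dropped silently", {
  # Gly fourfold box: force every third position to differ -> ps = 1 >= 3/4
  a <- strrep("GGT", 20)
  b <- strrep("GGA", 20)
  r <- computeKaKs(a, b)
  expect_true(is.na(r$ks))
  expect_equal(r$status, "saturated")

  # gapped codons dropped pairwise
  r2 <- computeKaKs("GGT---GGC", "GGTAAAGGC")
  expect_equal(r2$codons_used, 2L)

  expect_error(computeKaKs("---", "AAA"), "zero usable codons")
})

test_that("adding one extra synonymous difference never decreases Ks", {
  base <- strrep("GGT", 50)
  for (k in 0:10) {
    b1 <- paste0(strrep("GGC", k), strrep("GGT", 50 - k))
    b2 <- paste0(strrep("GGC", k + 1), strrep("GGT", 50 - k - 1))
    expect_gte(computeKaKs(base, b2)$ks, computeKaKs(base, b1)$ks)
  }
})

test_that("computeKaKs agrees with the brute-force oracle on random pairs", {
  set.seed(7)
  for (i in 1:40) {
    a <- randomCds(50)
    b <- randomCds(50)
    got <- computeKaKs(a, b)
    want <- oracleKaKs(a, b)
    expect_equal(got$s_sites, want$S, tolerance = 1e-9)
    expect_equal(got$s_diffs, want$Sd, tolerance = 1e-9)
    expect_equal(got$n_diffs, want$Nd, tolerance = 1e-9)
    if (is.na(want$ks)) expect_true(is.na(got$ks))
    else expect_equal(got$ks, want$ks, tolerance = 1e-9)
  }
})

test_that("NG86 recovers the simulated divergence of evolved codon pairs", {
  pairs <- evolveCodonPairs(200, 300, targetKs = 0.4, targetKa = 0.05,
                            seed = 7)
  res <- do.call(rbind, lapply(pairs, function(p)
    computeKaKs(p$seq_a, p$seq_b)))
  expect_lt(abs(mean(res$ks) - 0.4) / 0.4, 0.10)
  expect_lt(abs(mean(res$ka) - 0.05) / 0.05, 0.10)
})

test_that("kaksPairs maps ids through a sequence set and flags missing ones", {
  cds <- c(a = strrep("GGT", 9), b = paste0(strrep("GGT", 8), "GGC"))
  out <- kaksPairs(data.frame(id_a = c("a", "a"), id_b = c("b", "zz")), cds)
  expect_equal(out$status, c("ok", "missing_sequence"))
  expect_equal(out$ks[1], -0.75 * log(1 - 4 / 27))
})
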