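test_that("species tags are parsed from tip label prefixes", {
  expect_equal(tipSpecies(c("Cs_g1", "Ac_g2_x", "Vv_y")), c("Cs", "Ac", "Vv"))
  expect_equal(tipSpecies("Cs|g1", delimiter = "|"), "Cs")
})

test_that("outgroup rooting places the outgroup sister to the ingroup", {
  tr <- ape::read.tree(text = "((Cs_1,Ac_1),Vv_1);")
  r <- rootWithOutgroup(tr, "Vv")
  expect_true(ape::is.rooted(r))
  expect_true(ape::is.monophyletic(r, c("Cs_1", "Ac_1")))

  tr2 <- ape::read.tree(text = "((Cs_1,Ac_1),(Vv_1,Vv_2));")
  r2 <- rootWithOutgroup(tr2, "Vv")
  expect_true(ape::is.monophyletic(r2, c("Vv_1", "Vv_2")))

  expect_error(rootWithOutgroup(tr, "Zz"), "no outgroup")
})

test_that("duplication-before-speciation and focal-only topologies are told apart", {
  shared <- ape::read.tree(text = "(((Cs_a,Ac_a),(Cs_b,Ac_b)),Vv_o);")
  expect_equal(classifyWgdTopology(shared, "Cs", c("Ac", "Rs"), "Vv")$call,
               "shared")

  indep <- ape::read.tree(text = "(((Cs_a,Cs_b),Ac_a),Vv_o);")
  expect_equal(classifyWgdTopology(indep, "Cs", c("Ac", "Rs"), "Vv")$call,
               "independent")

  one_focal <- ape::read.tree(text = "((Cs_a,Ac_a),Vv_o);")
  expect_equal(classifyWgdTopology(one_focal, "Cs", "Ac", "Vv")$call, "other")

  no_out <- ape::read.tree(text = "((Cs_a,Ac_a),(Cs_b,Ac_b));")
  expect_equal(classifyWgdTopology(no_out, "Cs", "Ac", "Vv")$call, "other")

  # partner on one side only: undecidable
  mixed <- ape::read.tree(text = "(((Cs_a,Ac_a),Cs_b),Vv_o);")
  expect_equal(classifyWgdTopology(mixed, "Cs", "Ac", "Vv")$call, "other")
})

test_that("any one partner species may witness the shared duplication", {
  t1 <- ape::read.tree(text = "(((Cs_a,Rs_a),(Cs_b,Ac_b)),Vv_o);")
  expect_equal(classifyWgdTopology(t1, "Cs", c("Ac", "Rs"), "Vv")$call,
               "shared")
})

test_that("calls are invariant to tip order and branch lengths", {
  a <- ape::read.tree(text = "(((Cs_a,Ac_a),(Cs_b,Ac_b)),Vv_o);")
  b <- ape::read.tree(text = "(Vv_o,((Ac_b,Cs_b),(Ac_a,Cs_a)));")
  withlen <- ape::read.tree(
    text = "(((Cs_a:0.1,Ac_a:0.9):0.5,(Cs_b:2,Ac_b:0.01):0.2):0.7,Vv_o:3);")
  for (tr in list(a, b, withlen))
    expect_equal(classifyWgdTopology(tr, "Cs", "Ac", "Vv")$call, "shared")
})

test_that("summary percentages follow the counts at full precision", {
  s <- topologySummaryFromCounts(1021L, 471L, 1306L)
  expect_equal(s@nTotal, 2798L)
  expect_equal(round(s@pctShared, 1), 36.5)
  expect_equal(round(s@pctIndependent, 1), 16.8)
  expect_equal(s@sharedRatio, 100 * 1021 / 1492)

  s2 <- topologySummaryFromCounts(67L, 10L, 91L)
  expect_equal(round(s2@pctShared), 40)
  expect_equal(round(s2@pctIndependent), 6)

  z <- summarizeCalls(character(0))
  expect_equal(z@nTotal, 0L)
  expect_equal(z@pctShared, 0)
})

test_that("simulated trees are classified with full accuracy when noise-free", {
  tt <- simulateGeneTrees(10, pShared = 1, seed = 1)
  calls <- classifyTrees(tt$trees, "Cs", c("Ac", "Rs"), "Vv")
  expect_true(all(calls$call == "shared"))

  tt2 <- simulateGeneTrees(400, pShared = 0.7, seed = 2)
  calls2 <- classifyTrees(tt2$trees, "Cs", c("Ac", "Rs"), "Vv")
  expect_equal(mean(calls2$call == tt2$truth), 1)
})

test_that("estimated shared fraction tracks the simulated fraction", {
  tt <- simulateGeneTrees(1000, pShared = 0.7, seed = 3)
  s <- summarizeCalls(classifyTrees(tt$trees, "Cs", c("Ac", "Rs"), "Vv"))
  expect_lt(abs(s@sharedRatio - 70), 3)
})

test_that("label-swap noise degrades trees to non-clean calls", {
  tt <- simulateGeneTrees(200, pShared = 1, seed = 4, epsilon = 1)
  calls <- classifyTrees(tt$trees, "Cs", c("Ac", "Rs"), "Vv")
  # a swap can leave the topology class intact (e.g. swapping the two focal
  # tips); it must never raise accuracy above the noise-free level
  expect_lt(mean(calls$call == "shared"), 1)
})
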