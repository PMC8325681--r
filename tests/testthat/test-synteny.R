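# helpers to build two toy genomes and a pair list from rank coordinates
.twoGenomes <- function(nA = 30L, nB = 30L) {
  list(a = toyGenome(1L, nA, species = "qq"),
       b = toyGenome(1L, nB, species = "tt"))
}

.pairsFromRanks <- function(gs, ra, rb) {
  ta <- geneTable(gs$a)
  tb <- geneTable(gs$b)
  data.frame(id_a = ta$gene_id[match(ra, ta$rank)],
             id_b = tb$gene_id[match(rb, tb$rank)],
             stringsAsFactors = FALSE)
}

test_that("perfectly collinear anchors form a single block; gap outliers are excluded", {
  gs <- .twoGenomes()
  bl <- chainAnchors(.pairsFromRanks(gs, 0:4, 0:4), gs$a, gs$b)
  expect_equal(nrow(blockTable(bl)), 1L)
  expect_equal(blockTable(bl)$n_anchors, 5L)
  expect_equal(blockTable(bl)$orientation, "collinear")

  gs2 <- .twoGenomes(30L, 500L)
  p <- .pairsFromRanks(gs2, c(0:4, 2L), c(0:4, 400L))
  bl2 <- chainAnchors(p, gs2$a, gs2$b)
  expect_equal(nrow(blockTable(bl2)), 1L)
  expect_equal(blockTable(bl2)$n_anchors, 5L)
  expect_false(400L %in% anchorTable(bl2)$rank_b)
})

test_that("inverted collinearity is chained as an anti-diagonal block", {
  gs <- .twoGenomes()
  bl <- chainAnchors(.pairsFromRanks(gs, 0:5, 9:4), gs$a, gs$b)
  expect_equal(blockTable(bl)$orientation, "inverted")
  expect_equal(blockTable(bl)$n_anchors, 6L)
})

test_that("empty input and sub-threshold chains give empty results", {
  gs <- .twoGenomes()
  bl <- chainAnchors(data.frame(id_a = character(), id_b = character()),
                     gs$a, gs$b)
  expect_equal(nrow(blockTable(bl)), 0L)
  bl2 <- chainAnchors(.pairsFromRanks(gs, 0:2, 0:2), gs$a, gs$b,
                      minBlockSize = 5L)
  expect_equal(nrow(blockTable(bl2)), 0L)
})

test_that("chaining equals exhaustive maximum-chain extraction on small instances", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    ra <- sample(0:14, n, replace = TRUE)
    rb <- sample(0:14, n, replace = TRUE)
    keep <- !duplicated(cbind(ra, rb))
    ra <- ra[keep]
    rb <- rb[keep]
    gs <- .twoGenomes(20L, 20L)
    p <- .pairsFromRanks(gs, ra, rb)
    got <- chainAnchors(p, gs$a, gs$b, maxGap = 4L, minBlockSize = 3L)
    want <- oracleChainBlocks(ra, rb, maxGap = 4L, minBlockSize = 3L)
    an <- anchorTable(got)
    got_sets <- unname(lapply(split(seq_len(nrow(an)), an$block_id),
      function(ii) sort(match(paste(an$rank_a[ii], an$rank_b[ii]),
                              paste(ra, rb)))))
    want_sets <- lapply(want, sort)
    expect_equal(got_sets[order(vapply(got_sets, min, 1L))],
                 want_sets[order(vapply(want_sets, min, 1L))],
                 info = sprintf("instance %d", rep))
  }
})

test_that("no anchor is assigned to two blocks and ranks are strictly monotone", {
  sim <- simulateWgdGenome(simulationPlan(seed = 5))
  bl <- selfSynteny(sim$annotation, sim$pairs)
  an <- anchorTable(bl)
  expect_false(any(duplicated(an[, c("gene_a", "gene_b")])))
  expect_true(validObject(bl))
})

test_that("self-synteny finds duplicated chromosomes but not tandem arrays", {
  # two chromosomes that are copies of each other
  rows <- rbind(
    data.frame(gene_id = sprintf("d_a%02d", 1:10), chrom = "chr1",
               start = (0:9) * 1000 + 1, end = (0:9) * 1000 + 900,
               strand = "+"),
    data.frame(gene_id = sprintf("d_b%02d", 1:10), chrom = "chr2",
               start = (0:9) * 1000 + 1, end = (0:9) * 1000 + 900,
               strand = "+"))
  g <- genomeAnnotation(rows, "dd")
  p <- data.frame(id_a = sprintf("d_a%02d", 1:10),
                  id_b = sprintf("d_b%02d", 1:10))
  bl <- selfSynteny(g, p)
  expect_equal(nrow(blockTable(bl)), 1L)
  expect_equal(blockTable(bl)$n_anchors, 10L)

  # a tandem array on one chromosome: suppressed by diagonal filtering
  g2 <- toyGenome(1L, 12L, species = "td")
  ids <- geneTable(g2)$gene_id
  p2 <- data.frame(id_a = ids[1:11], id_b = ids[2:12])
  bl2 <- selfSynteny(g2, p2)
  expect_equal(nrow(blockTable(bl2)), 0L)
})

test_that("depth profiles report the syntenic depth signature of a WGD", {
  # one query chromosome covered twice by a two-chromosome target
  q <- toyGenome(1L, 20L, species = "qq")
  t2 <- toyGenome(2L, 20L, species = "tt")
  tq <- geneTable(q)
  tt <- geneTable(t2)
  p <- rbind(
    data.frame(id_a = tq$gene_id, id_b = tt$gene_id[tt$chrom == "chr1"]),
    data.frame(id_a = tq$gene_id, id_b = tt$gene_id[tt$chrom == "chr2"]))
  bl <- chainAnchors(p, q, t2)
  expect_equal(modalDepth(depthProfile(bl, q)), 2)
  expect_equal(modalDepth(depthProfile(bl, t2)), 1)
  expect_equal(sum(depthHistogram(depthProfile(bl, q))), 20L)
})

test_that("simulated WGD genome vs pre-WGD outgroup shows the 2:1 depth ratio", {
  sim <- simulateWgdGenome(simulationPlan(seed = 2))
  og <- simulateOutgroupGenome(sim, 0.781)
  bl <- chainAnchors(og$orthologs[, c("id_a", "id_b")], sim$annotation,
                     og$annotation)
  expect_equal(modalDepth(depthProfile(bl, og$annotation)), 2)
  expect_equal(modalDepth(depthProfile(bl, sim$annotation)), 1)
  expect_equal(modalDepth(depthProfile(
    selfSynteny(sim$annotation, sim$pairs), sim$annotation)), 1)
})

test_that("dot plot tables carry one row per anchor with block ids", {
  gs <- .twoGenomes()
  bl <- chainAnchors(.pairsFromRanks(gs, 0:4, 0:4), gs$a, gs$b)
  dt <- dotplotTable(bl)
  expect_equal(nrow(dt), 5L)
  expect_equal(length(unique(dt$block_id)), 1L)

  bl2 <- chainAnchors(.pairsFromRanks(gs, c(0:4, 20:24), c(0:4, 20:24)),
                      gs$a, gs$b, maxGap = 5L)
  expect_equal(length(unique(dotplotTable(bl2)$block_id)), 2L)

  empty <- chainAnchors(data.frame(id_a = character(), id_b = character()),
                        gs$a, gs$b)
  expect_equal(nrow(dotplotTable(empty)), 0L)
})
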