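# A toy genome with a planted WGD block, a tandem pair, a proximal pair and
# a dispersed pair; used across the classifier tests.
.dupFixture <- function() {
  rows <- rbind(
    data.frame(gene_id = sprintf("x_a%02d", 1:20), chrom = "chr1",
               start = (0:19) * 1000 + 1, end = (0:19) * 1000 + 900,
               strand = "+"),
    data.frame(gene_id = sprintf("x_b%02d", 1:20), chrom = "chr2",
               start = (0:19) * 1000 + 1, end = (0:19) * 1000 + 900,
               strand = "+"))
  g <- genomeAnnotation(rows, "xx")
  wgd <- data.frame(id_a = sprintf("x_a%02d", 1:8),
                    id_b = sprintf("x_b%02d", 1:8))
  # the dispersed pair is deliberately off-diagonal so it cannot extend the
  # planted collinear block
  extra <- data.frame(
    id_a = c("x_a10", "x_a13", "x_a18"),
    id_b = c("x_a11", "x_a19", "x_b03"))
  pairs <- rbind(wgd, extra)
  blocks <- selfSynteny(g, pairs)
  list(genome = g, pairs = pairs, blocks = blocks)
}

test_that("classification respects the wgd > tandem > proximal > dispersed precedence", {
  fx <- .dupFixture()
  d <- classifyDuplicates(fx$genome, fx$pairs, fx$blocks,
                          tandemMode = "strict")
  mode_of <- function(a, b) d$mode[d$id_a == a & d$id_b == b]
  expect_equal(mode_of("x_a01", "x_b01"), "wgd")       # anchor in a block
  expect_equal(mode_of("x_a10", "x_a11"), "tandem")    # adjacent ranks
  expect_equal(mode_of("x_a13", "x_a19"), "proximal")  # rank distance 6
  expect_equal(mode_of("x_a18", "x_b03"), "dispersed") # different chromosome
})

test_that("every pair receives exactly one mode and the summary sums to the input", {
  fx <- .dupFixture()
  d <- classifyDuplicates(fx$genome, fx$pairs, fx$blocks)
  expect_equal(nrow(d), nrow(fx$pairs))
  expect_true(all(d$mode %in% c("wgd", "tandem", "proximal", "dispersed")))
  ms <- modeSummary(d)
  expect_equal(sum(ms), nrow(d))
  expect_equal(unname(modeSummary(d[0, ])), rep(0L, 4L))
})

test_that("strict-mode classification matches an independent restatement of the rules", {
  fx <- .dupFixture()
  d <- classifyDuplicates(fx$genome, fx$pairs, fx$blocks,
                          tandemMode = "strict")
  want <- oracleDupModes(geneTable(fx$genome), fx$pairs,
                         anchorTable(fx$blocks))
  expect_equal(d$mode, want)

  # and on a randomized pair set over the same genome
  set.seed(3)
  ids <- geneTable(fx$genome)$gene_id
  rp <- normalizePairsForTest(data.frame(
    id_a = sample(ids, 30, replace = TRUE),
    id_b = sample(ids, 30, replace = TRUE)))
  d2 <- classifyDuplicates(fx$genome, rp, fx$blocks, tandemMode = "strict")
  expect_equal(d2$mode, oracleDupModes(geneTable(fx$genome), d2,
                                       anchorTable(fx$blocks)))
})

test_that("array mode promotes pairs separated only by same-family genes", {
  # family f: three consecutive genes g10,g11,g12 all homologous
  g <- toyGenome(1L, 20L, species = "ar")
  ids <- geneTable(g)$gene_id
  pairs <- data.frame(id_a = c(ids[10], ids[11], ids[10]),
                      id_b = c(ids[11], ids[12], ids[12]))
  blocks <- selfSynteny(g, pairs)
  d_strict <- classifyDuplicates(g, pairs, blocks, tandemMode = "strict")
  d_array <- classifyDuplicates(g, pairs, blocks, tandemMode = "array")
  k <- which(d_strict$id_a == ids[10] & d_strict$id_b == ids[12])
  expect_equal(d_strict$mode[k], "proximal")
  expect_equal(d_array$mode[k], "tandem")
})

test_that("planted duplicate modes are recovered on simulated genomes", {
  sim <- simulateWgdGenome(simulationPlan(seed = 4))
  blocks <- selfSynteny(sim$annotation, sim$pairs)
  d <- classifyDuplicates(sim$annotation, sim$pairs, blocks)
  truth <- sim$pairs$true_mode[match(paste(d$id_a, d$id_b),
                                     paste(sim$pairs$id_a, sim$pairs$id_b))]
  # boundary ambiguity is possible where planted pairs happen to be
  # collinear with real block spans or retention gaps break blocks; overall
  # recovery must stay high and wgd inflation must stay marginal
  expect_gt(mean(d$mode == truth), 0.95)
  expect_lt(mean(d$mode == "wgd" & truth != "wgd"), 0.01)
})

test_that("pairs with unknown genes are rejected", {
  fx <- .dupFixture()
  bad <- data.frame(id_a = "x_a01", id_b = "nope")
  expect_error(classifyDuplicates(fx$genome, bad, fx$blocks), "not in this")
})
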