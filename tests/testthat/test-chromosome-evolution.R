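# a genome that is a clean doubling of nine 30-gene chromosomes, plus its
# self-synteny blocks
.cleanDoubled <- function() {
  plan <- simulationPlan(seed = 9, nChromosomes = 9L,
                         genesPerChromosome = 30L, wgdRetention = 1,
                         nFissions = 0L, nFusions = 0L, nInversions = 0L)
  sim <- simulateWgdGenome(plan)
  blocks <- selfSynteny(sim$annotation, sim$pairs)
  list(sim = sim, blocks = blocks)
}

test_that("segment graphs carry one edge per large block and merge overlaps", {
  fx <- .cleanDoubled()
  seg <- buildSegmentGraph(fx$blocks, fx$sim$annotation)
  expect_equal(nrow(seg@segments), 18L)
  expect_equal(nrow(seg@edges), 9L)
  expect_true(all(seg@edges$weight >= 5))

  # overlapping intervals on the same chromosome collapse into one node
  rows <- rbind(
    data.frame(gene_id = sprintf("m_a%02d", 1:20), chrom = "chr1",
               start = (0:19) * 1000 + 1, end = (0:19) * 1000 + 900,
               strand = "+"),
    data.frame(gene_id = sprintf("m_b%02d", 1:20), chrom = "chr2",
               start = (0:19) * 1000 + 1, end = (0:19) * 1000 + 900,
               strand = "+"),
    data.frame(gene_id = sprintf("m_c%02d", 1:20), chrom = "chr3",
               start = (0:19) * 1000 + 1, end = (0:19) * 1000 + 900,
               strand = "+"))
  g <- genomeAnnotation(rows, "mm")
  p <- rbind(data.frame(id_a = sprintf("m_a%02d", 1:20),
                        id_b = sprintf("m_b%02d", 1:20)),
             data.frame(id_a = sprintf("m_a%02d", 3:18),
                        id_b = sprintf("m_c%02d", 3:18)))
  bl <- selfSynteny(g, p)
  sg <- buildSegmentGraph(bl, g)
  expect_equal(sum(sg@segments$chrom == "chr1"), 1L)

  expect_error(buildSegmentGraph(fx$blocks, fx$sim$annotation,
                                 minAnchors = 10000L), "no self-synteny block")
})

test_that("a clean doubled genome yields exactly the ancestral chromosome number", {
  fx <- .cleanDoubled()
  seg <- buildSegmentGraph(fx$blocks, fx$sim$annotation)
  anc <- inferAncestralCount(seg)
  expect_equal(anc$nAncestral, 9L)
  expect_true(all(vapply(anc$groups, length, 1L) == 2L))
})

test_that("the fission/fusion scenario recovers the ancestral count within one", {
  sim <- simulateWgdGenome(simulationPlan(seed = 1))
  blocks <- selfSynteny(sim$annotation, sim$pairs)
  seg <- buildSegmentGraph(blocks, sim$annotation)
  anc <- suppressWarnings(inferAncestralCount(seg))
  expect_lte(abs(anc$nAncestral - 9L), 1L)
})

test_that("light rearrangement still allows exact recovery", {
  plan <- simulationPlan(seed = 6, genesPerChromosome = 100L,
                         wgdRetention = 0.6, nFissions = 1L, nFusions = 1L,
                         nInversions = 1L)
  sim <- simulateWgdGenome(plan)
  blocks <- selfSynteny(sim$annotation, sim$pairs)
  seg <- buildSegmentGraph(blocks, sim$annotation)
  anc <- suppressWarnings(inferAncestralCount(seg))
  expect_equal(anc$nAncestral, 9L)
})

test_that("karyotype bookkeeping accepts exactly the balanced solutions", {
  m <- accountEvents(9, 15, nFissions = 3, nFusions = 6)
  expect_equal(m@nPostWgd, 18L)
  expect_equal(m@nExtant, 15L)

  expect_s4_class(accountEvents(9, 18), "KaryotypeModel")
  expect_error(accountEvents(9, 15), "18")
  expect_error(accountEvents(9, 15), "15")

  set.seed(12)
  for (i in 1:30) {
    na <- sample(1:12, 1)
    fi <- sample(0:5, 1)
    fu <- sample(0:5, 1)
    ne <- sample(1:30, 1)
    balanced <- ne == 2 * na + fi - fu
    if (balanced) expect_s4_class(accountEvents(na, ne, fi, fu),
                                  "KaryotypeModel")
    else expect_error(accountEvents(na, ne, fi, fu), "bookkeeping")
  }
})
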