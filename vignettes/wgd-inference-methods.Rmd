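---
title: "Inferring and dating ancient whole-genome duplications: methods and design"
author: "paleowgd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and dating ancient whole-genome duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleowgd)
```

# The inference chain

An ancient whole-genome duplication (WGD) leaves three independent
signatures in a modern genome, and `paleowgd` implements the standard
evidence chain that reads them:

1. **Synteny.** A WGD doubles every chromosome, so large collinear blocks of
   duplicated gene order survive inside the genome (self-synteny), and the
   genome covers an unduplicated relative twice (a 2:1 syntenic depth
   ratio).
2. **Ks distributions.** Synonymous divergence (Ks) between duplicate pairs
   accumulates roughly clocklike, so the pairs created simultaneously by a
   WGD form a peak in the Ks density, distinguishable from the continuous
   background of small-scale duplication.
3. **Gene-tree topology.** Whether a WGD is shared with a related lineage
   is read from rooted gene trees containing both paralogs: if the
   duplication preceded the speciation, each paralog clade contains
   orthologs from the partner lineage.

A karyotype layer reconciles chromosome numbers across the event (ancestral
count, doubling, then fissions and fusions), and a fully seeded simulator
generates genomes, codon-aligned sequence pairs and gene trees with
recorded ground truth so every stage is testable without genome downloads.

# Gene order, not base pairs

All synteny arithmetic runs in *rank space*: each gene gets a dense 0-based
index along its chromosome, ordered by start coordinate (ties broken by
gene identifier). Dot plots, gap constraints and block spans are all
expressed in ranks because duplication preserves gene order, not intergenic
distance. Coordinates themselves stay 1-based inclusive (GFF3 native) and
are only carried for provenance. Strand is stored but ignored by chaining;
an inversion shows up as an anti-diagonal ("inverted") block, which the
chainer searches for explicitly.

## Anchor chaining

`chainAnchors()` groups homolog pairs by chromosome pair, sorts by rank,
and finds maximum-length chains by dynamic programming under the constraint
that consecutive anchors advance by at most `maxGap = 25` ranks on both
axes, strictly monotonically (increasing/increasing for collinear chains,
increasing/decreasing for inverted ones). Chains are extracted greedily in
descending anchor count; each anchor joins at most one block, and chains
shorter than `minBlockSize = 5` anchors are discarded. The defaults are the
conventional MCScan-family settings; both are exposed as parameters. Ties
are broken deterministically (smallest chromosome/rank tuple, collinear
before inverted, lexicographically smallest anchor sequence), which makes
output byte-reproducible and lets the test suite compare the chainer
against exhaustive search on small instances.

Self-synteny additionally canonicalizes pair orientation, removes
self-matches, and suppresses anchors within `minBlockSize` ranks of the
main diagonal of a single chromosome — otherwise every tandem array would
masquerade as a tiny "duplicated segment".

## Syntenic depth

`depthProfile()` counts, for each query gene, how many block spans cover
its rank, and summarizes the modal nonzero depth. A genome carrying one
WGD relative to its comparator shows modal depth 2 from the comparator's
side and 1 in reverse — the 2:1 signature; self-synteny of a
once-duplicated genome has modal depth 1 (each region has exactly one
partner).

# Duplicate-pair modes

Ks distributions are only informative about a WGD if they are built from
WGD-derived pairs, so pairs are classified with the precedence
`wgd > tandem > proximal > dispersed`: anchors of self-synteny blocks are
`wgd`; same-chromosome pairs at adjacent ranks are `tandem` (in the default
"array" mode, pairs separated only by genes of the same homolog family also
count; a strict-adjacency mode is available); same-chromosome pairs within
`proximalWindow = 10` ranks are `proximal` (the window is the
DupGen_finder-style convention); everything else is `dispersed`. Transposed
duplicates, which require an outgroup to detect, are not modelled and fall
into `dispersed`.

# NG86 Ka/Ks

The estimator is the Nei–Gojobori (1986) counting method under the standard
genetic code, with Jukes–Cantor multiple-hit correction:

- Per codon, each position contributes (number of synonymous
  single-nucleotide changes)/3 to the synonymous site count; changes
  creating stop codons count as nonsynonymous. Site counts are averaged
  over the two sequences.
- Differences between codons differing at $k$ positions are averaged over
  all $k!$ orderings of single changes. Orderings that pass through a stop
  codon are excluded; in the rare case that every ordering does, all are
  kept with stop-producing steps counted as nonsynonymous. This fallback is
  a documented choice — the original method is silent here.
- $K_s = -\tfrac{3}{4}\log(1 - \tfrac{4}{3} p_s)$ with $p_s = S_d/S$, and
  likewise $K_a$. When $p_s \ge 3/4$ the correction is undefined; such
  pairs are returned flagged `saturated`, never silently dropped —
  filtering is the Ks-distribution stage's job.

Codons containing gaps, ambiguity codes or stops in either sequence are
removed pairwise before counting. Pathways are weighted equally (no
transition/transversion weighting — that would be a different model), and
all $64 \times 64$ codon-pair difference counts are precomputed at load so
pair scoring is a vectorized table lookup.

# Ks distributions, peaks and dating

All density machinery operates on $\log K_s$: Ks is positive and strongly
right-skewed, and both kernel and mixture methods behave far better on the
log scale. The default sample filter $(0.01, 3.0)$ removes allelic or
near-zero pairs at the bottom and saturated estimates at the top; dropped
values are counted, and an entirely filtered-out sample is an error rather
than an empty curve.

Two peak estimators are provided:

- **kde** — Gaussian kernel on log Ks with Silverman's bandwidth, mode
  taken as the argmax on a 512-point grid.
- **gmm** — Gaussian mixtures with unequal variances fitted by EM for
  $k = 1..4$ components, selected by BIC; the reported mode is
  $\exp(\text{mean})$ of the heaviest component. Samples under 50 values
  fall back to kde with a warning. The *mode*, not mean or median, is the
  peak statistic, matching the visual reading of Ks histograms.

**Rate correction.** Lineages evolve at different synonymous rates, so Ks
scales must be aligned before cross-species comparison. Two lineages that
split from a common outgroup at the same time must show the same
divergence-peak Ks; the correction coefficient is the ratio of the
reference lineage's split peak to the other lineage's split peak, and the
other lineage's within-genome Ks values are multiplied by it. After
correction the two split peaks agree by construction, which the tests check
as a property.

**Dating.** With a calibration divergence of known age $T$ and split-peak
$K_s^{cal}$, the per-lineage synonymous rate is $r = K_s^{cal} / (2T)$ and
an event peak dates to $t = K_s^{peak}/(2r)$. The calibration used
throughout the examples is the asterid–rosid split (tea versus grape) at
$K_s = 0.781$, $T = 118$ million years, under which the tea WGD peak at
$K_s = 0.425$ dates to $0.425 \times 118 / 0.781 = 64.2$ My — the package
reports the closed-form value at full precision and leaves rounding to
presentation.

# Gene-tree topology classification

Trees are rooted on a designated outgroup (non-monophyletic outgroups make
the tree unclassifiable rather than being forced). With $M$ the most recent
common ancestor of the two focal-species paralogs, the call is:

- **shared** — the two child subtrees of $M$ holding the focal tips each
  contain at least one partner-lineage tip: the duplication preceded the
  focal/partner speciation;
- **independent** — the subtree under $M$ contains only focal-species
  tips: the paralogs coalesce before any partner joins;
- **other** — anything else, including every precondition failure (not
  exactly two focal tips, missing partner or outgroup, ambiguous
  polytomies). Polytomies are handled conservatively: a decisive call
  requires the two focal tips to sit in two distinct child subtrees of
  $M$.

Classification is purely topological — branch lengths are ignored — and
when several partner lineages are supplied, any one of them can witness the
shared duplication. The summary statistic is
$100 \cdot n_{shared} / (n_{shared} + n_{independent})$, computed at full
precision.

# Karyotype reconstruction

Large self-synteny blocks (at least `minAnchors = 5` anchors — "large" has
no published threshold, so the block minimum is reused) define a segment
graph: each block contributes its two rank intervals as nodes and one edge
weighted by anchor count; intervals on the same chromosome merge when they
overlap by more than half of either.

Greedy maximum-weight matching pairs segments into WGD duplicates. The
subtle step is merging matched pairs across chromosome *seams* into
ancestral linkage groups. A seam — two matched segments adjacent on one
chromosome with different partners — is locally the same 1↔2 pattern
whether one post-WGD copy fissioned or two copies fused, so seams cannot be
classified from the graph alone. The package calibrates a typical ancestral
chromosome gene content from chromosomes in clean one-segment duplicate
relationships (falling back to the genome-wide median) and treats seams on
chromosomes holding at least `fusionFactor = 1.5` times that content as
fusion seams (groups kept apart), all others as fission seams (groups
merged). Segments left unmatched are attached to the nearest matched
segment on their chromosome; truly isolated ones become singleton groups
with a warning.

This is deliberately a heuristic, not a full ancestral-genome
reconstruction: its contract is defined by recovery tests — exact recovery
on cleanly doubled genomes and on lightly rearranged ones (about two events
per affected chromosome), and recovery within one chromosome on the default
fission/fusion scenario. Heavily stacked rearrangements (fissions of fusion
products and vice versa) can still confuse seam classification by one or
two groups; the bookkeeping layer (`accountEvents()`) then flags any
inconsistency with the extant count via the balance equation
$n_{extant} = 2\,n_{ancestral} + n_{fissions} - n_{fusions}$.

# What the simulator emulates — and what it does not

`simulateWgdGenome()` replays a WGD history forward: a diploid ancestor
(default 9 chromosomes × 200 genes), duplication of every chromosome,
independent loss of each duplicate copy with probability
$1 - \rho$ (default retention $\rho = 0.5$), then fissions, fusions and
inversions (defaults 3, 6 and 3) applied after the WGD, matching the
narrative order of the modelled history. Retained WGD pairs draw Ks from a
lognormal with mode 0.425 and log-sd 0.2; background tandem, proximal and
dispersed pairs (2%, 1% and 2% of gene count) draw from an exponential with
rate 1 — standard shapes for Ks mixtures. The outgroup generator emits the
unduplicated ancestor with ortholog Ks around the split peak (default
0.781). Gene trees are drawn shared with probability 0.685. Where the
modelled study states a value (chromosome counts, event counts, peak
locations, topology fractions) the default is that value; remaining
defaults (retention, sigmas, background rates) are fixed at values typical
of plant paleopolyploidy data and are not tuned per run.

`evolveCodonPairs()` grounds the Ks scale: random stop-free codon sequences
receive synonymous changes with per-codon probability
$p_s \cdot s_{codon}$, where $p_s = \tfrac{3}{4}(1 - e^{-4K_s/3})$ inverts
the Jukes–Cantor correction, so the NG86 estimate is unbiased in
expectation (and likewise for Ka). At most one change of each kind is
applied per codon, which caps the faithful range at roughly $K_s \lesssim
2$; beyond that the generator refuses rather than produce silently
saturated pairs.

Deliberate non-goals of the simulator: no intergenic sequence, no
transposable elements, no codon-usage bias, no gene-length variation
(300 codons throughout), no gradual rate variation among genes beyond the
Ks spread, and retention is independent per gene (no biased fractionation).
Passing tests therefore demonstrate correctness of the *inference
machinery* under the model's assumptions, not robustness to every
idiosyncrasy of real genomes — in particular, real Ks mixtures are heavier
tailed, real retention is clustered, and real outgroups are not literal
frozen ancestors.

# Numerical and determinism choices

- Every random draw descends from an explicit integer seed; the simulator,
  the mixture fit and the pipeline are byte-reproducible given the seed.
- Problem sizes in examples and tests (9 × 200-gene genomes, 200–300
  sequence pairs of 300 codons, 1000–2000 Ks values, 1000 trees) are chosen
  so each statistic's sampling error is comfortably inside its test
  tolerance while a full run stays interactive.
- Ties anywhere (chain extraction, modal depth, rank assignment) break by
  fixed lexicographic rules, never by hash or insertion order.
- Undefined quantities (saturated Ks, empty depth, zero-call summaries)
  propagate as flagged values or errors, never as silent zeros.

# Worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(seed = 1)
report <- runPipeline(cfg)
report$synteny$modal_depth_outgroup_vs_wgd  # 2   (the 2:1 signature)
report$ks$wgd_peak                          # ~0.425
report$dating$wgd_age_mya                   # ~63
report$karyotype$inferred_ancestral         # 9
writeReport(report, "report.json")
```

# Known limitations

- The karyotype heuristic degrades when rearrangements stack on the same
  chromosome (see above); it reports groups, not gene-level ancestral
  adjacencies.
- NG86 is a counting method: no transition/transversion bias, no codon
  frequencies, no rate variation. It matches the scale of the simulator by
  construction; against maximum-likelihood estimators it is known to run
  slightly low at high divergence.
- The GMM peak reports the heaviest component's mode, which is the right
  statistic for a dominant WGD peak but can track the background when the
  WGD signal is a minority component; inspect `nComponents()` and the
  component table in doubtful cases.
- Tree classification assumes exactly two focal paralogs per tree (the
  anchor-pair design); trees with extra focal duplicates are conservatively
  `other`.
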