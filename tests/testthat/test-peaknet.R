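grWith <- function(chrom, start, end, strand = "+", gene_id = NULL,
                   seqlen = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand)
  if (!is.null(gene_id)) gr$gene_id <- gene_id
  if (!is.null(seqlen))
    GenomeInfoDb::seqlengths(gr) <- setNames(seqlen, unique(chrom))
  gr
}

test_that("region RPKM follows the hand formula and proportionality", {
  region <- grWith("chr1", 1001, 2000)
  reads <- grWith("chr1", seq(1100, 1900, length.out = 10),
                  seq(1100, 1900, length.out = 10))
  expect_equal(regionRpkm(reads, region, librarySize = 1e6), 10)
  expect_equal(regionRpkm(reads, grWith("chr1", 5000, 6000)), 0)
  # doubling region length with the same reads halves the RPKM
  expect_equal(regionRpkm(reads, grWith("chr1", 1001, 3000), 1e6), 5)
  expect_length(regionRpkm(reads, GenomicRanges::GRanges()), 0)
  expect_error(regionRpkm(reads, region, librarySize = 0), "librarySize")
})

test_that("percentile filter keeps exactly the enriched peak on a fixture", {
  # 100 identical 1 kb peaks; input gives each exactly 10 reads; ChIP gives
  # 10 everywhere except 100 reads on peak 7
  peaks <- grWith("chr1", seq(0, 99) * 10000 + 1, seq(0, 99) * 10000 + 1000)
  peaks$name <- sprintf("pk%02d", 1:100)
  mkReads <- function(perPeak) {
    pos <- unlist(lapply(seq_len(100), function(i)
      seq(0, 999, length.out = perPeak[i]) + (i - 1) * 10000 + 1))
    grWith("chr1", round(pos), round(pos))
  }
  input <- mkReads(rep(10, 100))
  chip <- mkReads(c(rep(10, 6), 100, rep(10, 93)))
  filt <- filterPeaks(peaks, chip, input)
  expect_identical(filt$name, "pk07")
  # per-region reading keeps peaks whose ChIP exceeds 0.99x their own input
  filt2 <- filterPeaks(peaks, chip, input, mode = "per-region")
  expect_true("pk07" %in% filt2$name)
  # percentile = 0 keeps everything above the input minimum: equal library
  # sizes, half the peaks at double coverage
  chipHi <- mkReads(rep(c(20, 10), each = 50))
  expect_length(filterPeaks(peaks, chipHi, input, percentile = 0), 50)
  expect_warning(filterPeaks(peaks, input, chipHi), "filtered out")
})

test_that("self-filtering retains about the top percent and is monotone", {
  set.seed(4)
  peaks <- grWith("chr1", seq(0, 199) * 5000 + 1, seq(0, 199) * 5000 + 500)
  pos <- sort(sample(1e6, 20000, replace = TRUE))
  track <- grWith("chr1", pos, pos)
  filt <- filterPeaks(peaks, track, track)
  expect_lte(length(filt), 0.02 * 200)
  # raising the percentile never adds peaks
  kept <- suppressWarnings(vapply(c(0, 50, 90, 99, 100), function(pc)
    length(filterPeaks(peaks, track, track, percentile = pc)), numeric(1)))
  expect_true(all(diff(kept) <= 0))
})

test_that("regulatory domains follow the basal-plus-extension contract", {
  # lone + gene, TSS at BED position 100000 on a 1 Mb chromosome
  g <- grWith("chr1", 100001, 102000, "+", "g1", seqlen = 1e6)
  d <- regulatoryDomains(g)
  expect_equal(unname(d$basalStart), 95001)       # BED 95000
  expect_equal(unname(d$basalEnd), 101000)        # BED half-open end 101000
  expect_equal(GenomicRanges::start(d), 1)        # capped at the chromosome
  expect_equal(GenomicRanges::end(d), 1e6)

  # TSS near the chromosome start: basal clipped, never negative
  g2 <- grWith("chr1", 2001, 4000, "+", "g2", seqlen = 1e6)
  d2 <- regulatoryDomains(g2)
  expect_equal(unname(d2$basalStart), 1)
  expect_equal(unname(d2$basalEnd), 3000)         # BED [0, 3000)

  # two + genes with TSS 100000 and 103000 (BED): gene1's rightward
  # extension stops at gene2's basal start, but never inside its own basal
  gg <- grWith("chr1", c(100001, 103001), c(102000, 105000), "+",
               c("g1", "g2"), seqlen = 1e6)
  dd <- regulatoryDomains(gg)
  expect_equal(GenomicRanges::end(dd)[1], unname(dd$basalEnd[1]))
  expect_equal(GenomicRanges::start(dd)[2], unname(dd$basalStart[2]))
  expect_error(regulatoryDomains(grWith("chr1", 1, 10, "*", "x",
                                        seqlen = 100)), "unstranded")
})

test_that("domains equal the per-bp brute-force reference on random annotations", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(3:7, 1)
    starts <- sort(sample(seq(500, 18000, by = 100), n))
    lens <- sample(200:800, n, replace = TRUE)
    gr <- grWith("chr1", starts, pmin(starts + lens, 19000),
                 sample(c("+", "-"), n, replace = TRUE),
                 sprintf("g%d", 1:n), seqlen = 20000)
    bu <- sample(c(500, 1000, 2000), 1)
    bd <- sample(c(100, 300), 1)
    mx <- sample(c(1500, 3000, 6000), 1)
    d <- regulatoryDomains(gr, bu, bd, mx)
    ref <- bruteDomains(gr, bu, bd, mx)
    expect_equal(GenomicRanges::start(d), ref$start)
    expect_equal(GenomicRanges::end(d), ref$end)
    # invariants: extension never crosses another basal, never exceeds maxExt
    tss <- ifelse(as.character(GenomicRanges::strand(gr)) == "+",
                  GenomicRanges::start(gr), GenomicRanges::end(gr))
    expect_true(all(GenomicRanges::start(d) >= pmin(tss - mx, d$basalStart)))
    expect_true(all(GenomicRanges::end(d) <= pmax(tss + mx - 1, d$basalEnd)))
  }
})

test_that("BED round trip is the identity on coordinates and strand", {
  ann <- generateAnnotation(2, 1e5, 12, seed = 3)
  f <- tempfile(fileext = ".bed")
  writeBed(ann, f)
  rt <- readBed(f)
  expect_equal(GenomicRanges::start(rt), GenomicRanges::start(ann))
  expect_equal(GenomicRanges::end(rt), GenomicRanges::end(ann))
  expect_equal(as.character(GenomicRanges::strand(rt)),
               as.character(GenomicRanges::strand(ann)))
  expect_equal(rt$name, ann$gene_id)
})

test_that("peak assignment matches the brute-force overlap scan", {
  # hand cases: basal-only, shared, and orphan peaks.  With TSS 20 kb apart
  # the basal domains are disjoint and extensions stop at the neighbour's
  # basal edge, so a TSS-proximal peak maps to one gene only
  gg <- grWith("chr1", c(10001, 30001), c(12000, 32000), "+",
               c("gA", "gB"), seqlen = 100000)
  dom <- regulatoryDomains(gg, 5000, 1000, 10000)
  pkIn <- grWith("chr1", 10500, 10600)            # inside gA basal only
  pkOut <- grWith("chr1", 60000, 60100)           # beyond both extensions
  net <- assignPeaks(list(TF1 = pkIn), dom)
  expect_identical(networkEdges(net)$gene, "gA")
  net3 <- assignPeaks(list(TF1 = pkOut), dom)
  expect_equal(nrow(networkEdges(net3)), 0)
  # genes 3 kb apart: their basal domains overlap and a peak in the shared
  # stretch is assigned to both
  gg2 <- grWith("chr1", c(10001, 13001), c(12000, 15000), "+",
                c("gA", "gB"), seqlen = 50000)
  dom2 <- regulatoryDomains(gg2, 5000, 1000, 10000)
  net2 <- assignPeaks(list(TF1 = grWith("chr1", 9500, 9600)), dom2)
  expect_setequal(networkEdges(net2)$gene, c("gA", "gB"))

  # randomized property: implementation == all-pairs scan
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    starts <- sort(sample(seq(1000, 40000, by = 200), n))
    gr <- grWith("chr1", starts, starts + 500,
                 sample(c("+", "-"), n, replace = TRUE),
                 sprintf("g%d", 1:n), seqlen = 50000)
    dom <- regulatoryDomains(gr, 2000, 500, 5000)
    pkList <- lapply(1:2, function(i) {
      s <- sample(49000, 8)
      grWith("chr1", s, s + sample(100:1000, 8, replace = TRUE))
    })
    names(pkList) <- c("TFa", "TFb")
    got <- networkEdges(assignPeaks(pkList, dom))
    want <- bruteAssign(pkList, dom)
    expect_equal(got[order(got$tf, got$gene), ],
                 want[order(want$tf, want$gene), ],
                 ignore_attr = TRUE)
  }
})

test_that("binding combinations and indegree summarize the network faithfully", {
  edges <- data.frame(
    tf = c("A", "B", "A", "B", "A", "C", "C", "C"),
    gene = c("g1", "g1", "g2", "g2", "g3", "g4", "g5", "g6"))
  net <- bindingNetwork(c("A", "B", "C"), edges,
                        genes = sprintf("g%d", 1:8))
  bc <- bindingCombinations(net, sprintf("g%d", 1:8),
                            anyOf = list(AB = c("A", "B")))
  expect_equal(bc$combinations$count[bc$combinations$combo == "A+B"], 2)
  expect_equal(bc$combinations$count[bc$combinations$combo == "A"], 1)
  expect_equal(bc$combinations$count[bc$combinations$combo == ""], 2)
  expect_equal(bc$anyOf$count, 3)
  expect_equal(bc$anyOf$fraction, 3 / 8)

  # empty network: every gene has the empty combination
  net0 <- bindingNetwork("A", data.frame(tf = character(),
                                         gene = character()),
                         genes = c("g1", "g2"))
  bc0 <- bindingCombinations(net0, c("g1", "g2"))
  expect_identical(bc0$combinations$combo, "")
  expect_equal(bc0$combinations$count, 2)

  deg <- indegree(net)
  expect_equal(unname(deg[c("g1", "g3", "g7")]), c(2, 1, 0))
  idg <- indegreeDistribution(net, sprintf("g%d", 1:3), sprintf("g%d", 1:8))
  expect_equal(sum(idg$query), 1)
  expect_equal(sum(idg$background), 1)
  expect_equal(idg$indegree, 0:3)
})

test_that("bound-set enrichment delegates to the hypergeometric machinery", {
  uni <- sprintf("g%03d", 1:200)
  edges <- data.frame(tf = "A", gene = uni[1:20])
  net <- bindingNetwork("A", edges, genes = uni)
  r <- boundSetEnrichment(net, "A", uni[1:10], uni)
  expect_equal(r$k, 10)
  expect_equal(r$p, hypergeomTail(200, 20, 10, 10))
  # disjoint gene set: p = 1
  r0 <- boundSetEnrichment(net, "A", uni[100:120], uni)
  expect_equal(r0$p, 1)
  expect_error(boundSetEnrichment(net, "Z", uni[1:5], uni), "unknown TF")
})

test_that("bound-set enrichment p-values are null-uniform under random binding", {
  set.seed(19)
  uni <- sprintf("g%04d", 1:2000)
  geneSet <- sample(uni, 500)
  ps <- replicate(300, {
    bound <- sample(uni, 500)
    net <- bindingNetwork("A", data.frame(tf = "A", gene = bound),
                          genes = uni)
    boundSetEnrichment(net, "A", geneSet, uni)$p
  })
  # hypergeometric p-values are discrete, so exact ties can occur; the KS
  # statistic itself is still the right uniformity summary here
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("core circuitry finds autoregulation, mutual pairs and triads", {
  tfMap <- c(A = "gA", B = "gB", C = "gC", D = "gD")
  fullEdges <- expand.grid(tf = c("A", "B", "C"),
                           gene = c("gA", "gB", "gC"),
                           stringsAsFactors = FALSE)
  net <- bindingNetwork(c("A", "B", "C"), fullEdges,
                        genes = paste0("g", LETTERS[1:4]))
  circ <- coreCircuitry(net, tfMap[1:3])
  expect_true(all(circ$auto))
  expect_true(all(circ$mutual$mutual))
  expect_identical(circ$triads, "A+B+C")

  # removing one autoregulatory edge breaks the triad
  broken <- fullEdges[!(fullEdges$tf == "B" & fullEdges$gene == "gB"), ]
  circ2 <- coreCircuitry(bindingNetwork(c("A", "B", "C"), broken,
                                        genes = paste0("g", LETTERS[1:4])),
                         tfMap[1:3])
  expect_length(circ2$triads, 0)
  expect_false(circ2$auto[["B"]])

  # two overlapping complete triads among four TFs, vs exhaustive checking
  e4 <- rbind(expand.grid(tf = c("A", "B", "C"), gene = c("gA", "gB", "gC"),
                          stringsAsFactors = FALSE),
              expand.grid(tf = c("B", "C", "D"), gene = c("gB", "gC", "gD"),
                          stringsAsFactors = FALSE))
  net4 <- bindingNetwork(c("A", "B", "C", "D"), e4,
                         genes = paste0("g", LETTERS[1:4]))
  circ4 <- coreCircuitry(net4, tfMap)
  expect_setequal(circ4$triads, c("A+B+C", "B+C+D"))
  # a TF without a mapped gene is excluded with a warning
  expect_warning(coreCircuitry(net4, tfMap[1:3]), "excluded")
})

test_that("triad enumeration equals the exhaustive oracle on random networks", {
  set.seed(6)
  for (rep in 1:25) {
    nTf <- sample(3:6, 1)
    tfs <- sprintf("TF%d", seq_len(nTf))
    tfGenes <- sprintf("gene_%s", tfs)
    names(tfGenes) <- tfs
    pairs <- expand.grid(tf = tfs, gene = tfGenes, stringsAsFactors = FALSE)
    edges <- pairs[runif(nrow(pairs)) < 0.75, , drop = FALSE]
    if (nrow(edges) == 0) next
    net <- bindingNetwork(tfs, edges, genes = tfGenes)
    got <- coreCircuitry(net, tfGenes)$triads
    # oracle: test all C(nTf, 3) triples directly against the edge list
    key <- paste(edges$tf, edges$gene)
    trips <- utils::combn(tfs, 3)
    want <- character()
    for (j in seq_len(ncol(trips))) {
      t3 <- trips[, j]
      all9 <- expand.grid(tf = t3, gene = tfGenes[t3],
                          stringsAsFactors = FALSE)
      if (all(paste(all9$tf, all9$gene) %in% key))
        want <- c(want, paste(t3, collapse = "+"))
    }
    expect_setequal(got, want)
  }
})

test_that("planted edges survive the filter-domain-assign chain", {
  # ~140 planted edges against 5 x 25 decoys: the ~2% rank-based decoy leak
  # through an empirical 99th percentile leaves precision well above target
  ann <- generateAnnotation(2, 1e7, 50, seed = 13)
  ids <- ann$gene_id
  tfSpecs <- list(TF1 = ids[1:30], TF2 = ids[c(1:4, 15:40)],
                  TF3 = ids[c(2, 21:48)], TF4 = ids[c(3, 5:14, 31:48)],
                  TF5 = ids[c(1, 2, 3, 10:35)])
  chip <- generateChipExperiment(ann, tfSpecs, seed = 13)
  dom <- regulatoryDomains(ann)
  filt <- lapply(names(chip$peaks), function(tf)
    filterPeaks(chip$peaks[[tf]], chip$chipReads[[tf]], chip$inputReads))
  names(filt) <- names(chip$peaks)
  net <- assignPeaks(filt, dom)
  planted <- paste(trueEdges(chip$truth)$tf, trueEdges(chip$truth)$gene)
  found <- paste(networkEdges(net)$tf, networkEdges(net)$gene)
  expect_gte(mean(planted %in% found), 0.95)   # recall
  expect_gte(mean(found %in% planted), 0.95)   # precision
})
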