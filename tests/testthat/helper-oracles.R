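# Independent brute-force oracles used to check the fast implementations.
# These deliberately avoid the code paths they verify.

# one-sided signed-rank p by full enumeration of all 2^n sign assignments
bruteSignedRankP <- function(diffs, direction) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(grid, 1, function(s) sum(r[s]))
  if (direction == "greater") mean(Ws >= W) else mean(Ws <= W)
}

# upper-tail hypergeometric p by exhaustive enumeration of all C(N, n) draws
bruteHypergeomP <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)            # items 1..K are the term
  mean(hits >= k)
}

# all-pairs half-open interval overlap scan (coordinates 1-based closed,
# as GRanges) returning a tf->gene edge data.frame
bruteAssign <- function(peaksByTf, domains) {
  dChrom <- as.character(GenomicRanges::seqnames(domains))
  dStart <- GenomicRanges::start(domains)
  dEnd <- GenomicRanges::end(domains)
  rows <- list()
  for (tf in names(peaksByTf)) {
    pk <- peaksByTf[[tf]]
    pChrom <- as.character(GenomicRanges::seqnames(pk))
    genes <- character()
    for (i in seq_along(pk)) {
      for (j in seq_along(domains)) {
        if (pChrom[i] == dChrom[j] &&
            GenomicRanges::start(pk)[i] <= dEnd[j] &&
            GenomicRanges::end(pk)[i] >= dStart[j])
          genes <- c(genes, domains$gene_id[j])
      }
    }
    if (length(genes))
      rows[[tf]] <- data.frame(tf = tf, gene = sort(unique(genes)))
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(tf = character(), gene = character())
}

# per-bp scanning reference for basal-plus-extension domains (small genomes
# only); independent of the vectorized boundary arithmetic
bruteDomains <- function(genes, basalUp, basalDown, maxExt) {
  str <- as.character(GenomicRanges::strand(genes))
  chrom <- as.character(GenomicRanges::seqnames(genes))
  sl <- GenomeInfoDb::seqlengths(genes)
  tss <- ifelse(str == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  bS <- pmax(1, ifelse(str == "+", tss - basalUp, tss - basalDown + 1))
  bE <- pmin(unname(sl[chrom]),
             ifelse(str == "+", tss + basalDown - 1, tss + basalUp))
  n <- length(genes)
  res <- data.frame(start = integer(n), end = integer(n))
  for (i in seq_len(n)) {
    inOtherBasal <- function(pos) {
      any(chrom == chrom[i] & seq_len(n) != i & bS <= pos & bE >= pos)
    }
    s <- bS[i]
    while (s - 1 >= max(1, tss[i] - maxExt) && !inOtherBasal(s - 1)) s <- s - 1
    e <- bE[i]
    lim <- min(unname(sl[chrom[i]]), tss[i] + maxExt - 1)
    while (e + 1 <= lim && !inOtherBasal(e + 1)) e <- e + 1
    res$start[i] <- s
    res$end[i] <- e
  }
  res
}

# adjusted Rand index between two partitions
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  cij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- ai * bj / np
  (cij - expected) / ((ai + bj) / 2 - expected)
}

# random directed binding network over nTfs TFs and a gene universe
randomNetwork <- function(nTfs, genes, pEdge) {
  tfs <- sprintf("TF%d", seq_len(nTfs))
  edges <- expand.grid(tf = tfs, gene = genes, stringsAsFactors = FALSE)
  edges <- edges[runif(nrow(edges)) < pEdge, , drop = FALSE]
  bindingNetwork(tfs, edges, genes = genes)
}
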