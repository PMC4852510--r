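#' RPKM of a read track over regions
#'
#' Reads per kilobase of region per million library reads; a read contributes
#' once to every region its interval overlaps (no fractional assignment).
#'
#' @param reads [GenomicRanges::GRanges] of read intervals.
#' @param regions [GenomicRanges::GRanges] of regions.
#' @param librarySize total mapped reads (default `length(reads)`).
#' @return numeric RPKM per region (empty regions give an empty vector).
#' @examples
#' # 10 reads inside a 1 kb region, library of 1e6 reads -> RPKM 10
#' @export
regionRpkm <- function(reads, regions, librarySize = length(reads)) {
  if (librarySize <= 0) stop("librarySize must be > 0")
  if (length(regions) == 0) return(numeric(0))
  if (any(GenomicRanges::width(regions) <= 0)) stop("zero-width region")
  hits <- GenomicRanges::countOverlaps(regions, reads, ignore.strand = TRUE)
  hits * 1e9 / (librarySize * GenomicRanges::width(regions))
}

#' Filter ChIP peaks against input coverage
#'
#' High-confidence peaks are those whose ChIP RPKM exceeds the input track's
#' RPKM over the same peak regions.  The default reading ("percentile")
#' computes the input-RPKM distribution over all peak regions and keeps peaks
#' whose ChIP RPKM exceeds its `percentile`-th percentile (linear
#' interpolation); the alternative "per-region" reading keeps peaks whose
#' ChIP RPKM exceeds `percentile`/100 times the input RPKM of the same
#' region.
#'
#' @param peaks GRanges of called peaks.
#' @param chipReads,inputReads GRanges read tracks (must be non-empty).
#' @param percentile filter stringency (default 99).
#' @param mode "percentile" (default) or "per-region".
#' @return the retained peaks, with metadata columns `chipRpkm` and
#'   `inputRpkm`; an empty result triggers a warning, not an error.
#' @export
filterPeaks <- function(peaks, chipReads, inputReads, percentile = 99,
                        mode = c("percentile", "per-region")) {
  mode <- match.arg(mode)
  if (length(chipReads) == 0 || length(inputReads) == 0)
    stop("read tracks must be non-empty")
  chipR <- regionRpkm(chipReads, peaks)
  inputR <- regionRpkm(inputReads, peaks)
  keep <- if (mode == "percentile") {
    chipR > quantile(inputR, percentile / 100, names = FALSE)
  } else {
    chipR > (percentile / 100) * inputR
  }
  out <- peaks[keep]
  out$chipRpkm <- chipR[keep]
  out$inputRpkm <- inputR[keep]
  if (length(out) == 0) warning("all peaks filtered out")
  out
}

#' Basal-plus-extension regulatory domains
#'
#' Each gene gets a basal domain from `basalUp` bp upstream to `basalDown` bp
#' downstream of its TSS (in transcription orientation), clipped to the
#' chromosome.  The extended domain grows from the basal domain in both
#' directions up to `maxExt` bp from the TSS, stopping early at the nearest
#' other gene's basal domain; it never retracts inside the gene's own basal
#' domain, and overlapping basal domains are left overlapping.
#'
#' @param genes stranded GRanges with a `gene_id` column and seqlengths set;
#'   strand "*" is an error (a TSS is required).
#' @param basalUp,basalDown basal window, bp (defaults 5000 / 1000).
#' @param maxExt extension cap from the TSS, bp (default 1e6).
#' @return GRanges of extended domains (same order as `genes`) with metadata
#'   `gene_id`, `basalStart`, `basalEnd`.
#' @export
regulatoryDomains <- function(genes, basalUp = 5000, basalDown = 1000,
                              maxExt = 1e6) {
  str <- as.character(GenomicRanges::strand(genes))
  if (any(str == "*")) stop("unstranded gene: TSS undefined")
  sl <- GenomeInfoDb::seqlengths(genes)
  chrom <- as.character(GenomicRanges::seqnames(genes))
  chromLen <- unname(sl[chrom])
  if (any(is.na(chromLen))) stop("seqlengths required on the annotation")
  tss <- ifelse(str == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  bStart <- ifelse(str == "+", tss - basalUp, tss - basalDown + 1)
  bEnd <- ifelse(str == "+", tss + basalDown - 1, tss + basalUp)
  bStart <- pmax(1, bStart)
  bEnd <- pmin(chromLen, bEnd)

  n <- length(genes)
  extStart <- extEnd <- integer(n)
  for (i in seq_len(n)) {
    sameChr <- which(chrom == chrom[i])
    others <- setdiff(sameChr, i)
    left0 <- max(1, tss[i] - maxExt)
    cand <- bEnd[others][bStart[others] < bStart[i]]
    cand <- pmin(cand, bStart[i] - 1) + 1
    extStart[i] <- min(bStart[i], max(c(left0, cand)))
    right0 <- min(chromLen[i], tss[i] + maxExt - 1)
    cand <- bStart[others][bEnd[others] > bEnd[i]]
    cand <- pmax(cand, bEnd[i] + 1) - 1
    extEnd[i] <- max(bEnd[i], min(c(right0, cand)))
  }
  out <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(extStart, extEnd),
                                strand = str,
                                gene_id = genes$gene_id,
                                basalStart = bStart, basalEnd = bEnd)
  GenomeInfoDb::seqlengths(out) <- sl
  out
}

#' Assign filtered peaks to regulatory domains
#'
#' A directed edge tf -> gene is created when any peak of the TF overlaps the
#' gene's extended domain by at least one bp; a single peak may create edges
#' to several genes.
#'
#' @param peaksByTf named list of GRanges (filtered peaks per TF).
#' @param domains GRanges from [regulatoryDomains()].
#' @return a [BindingNetwork-class] over the domain genes.
#' @export
assignPeaks <- function(peaksByTf, domains) {
  if (is.null(names(peaksByTf))) stop("peaksByTf must be named by TF")
  edges <- lapply(names(peaksByTf), function(tf) {
    hits <- GenomicRanges::findOverlaps(peaksByTf[[tf]], domains,
                                        ignore.strand = TRUE)
    genes <- unique(domains$gene_id[S4Vectors::subjectHits(hits)])
    if (length(genes) == 0) return(NULL)
    data.frame(tf = tf, gene = genes, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(tf = character(), gene = character())
  bindingNetwork(names(peaksByTf), edges, genes = domains$gene_id)
}

#' Bound-TF combinations over a gene set
#'
#' @param network a [BindingNetwork-class].
#' @param geneSet character vector of gene ids.
#' @param anyOf optional named list of TF subsets; for each, the count (and
#'   fraction) of `geneSet` genes bound by at least one subset member is
#'   reported.
#' @return list with `combinations` (data.frame `combo` — "+"-joined sorted
#'   TF names, "" for unbound — and `count`, sorted by count) and `anyOf`
#'   (data.frame subset, count, fraction), plus `perGene` (named list of
#'   bound-TF sets restricted to `geneSet`).
#' @export
bindingCombinations <- function(network, geneSet, anyOf = NULL) {
  bt <- boundTfs(network)
  perGene <- lapply(setNames(geneSet, geneSet),
                    function(g) if (g %in% names(bt)) bt[[g]] else character())
  combo <- vapply(perGene, paste, character(1), collapse = "+")
  tab <- sort(table(combo), decreasing = TRUE)
  comb <- data.frame(combo = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  anyDf <- NULL
  if (!is.null(anyOf)) {
    cnt <- vapply(anyOf, function(tfs)
      sum(vapply(perGene, function(b) any(tfs %in% b), logical(1))),
      numeric(1))
    anyDf <- data.frame(subset = names(anyOf), count = as.integer(cnt),
                        fraction = cnt / length(geneSet),
                        stringsAsFactors = FALSE)
  }
  list(combinations = comb, anyOf = anyDf, perGene = perGene)
}

#' Indegree distributions of a gene set and a background set
#'
#' @param network a [BindingNetwork-class].
#' @param geneSet,backgroundSet character vectors of gene ids.
#' @return data.frame with columns `indegree` (0..number of TFs), `query`
#'   and `background` (proportions, each summing to 1).
#' @export
indegreeDistribution <- function(network, geneSet, backgroundSet) {
  deg <- indegree(network)
  lvls <- 0:length(tfNames(network))
  prop <- function(set) {
    d <- deg[intersect(set, names(deg))]
    as.vector(table(factor(d, levels = lvls))) / max(1, length(d))
  }
  data.frame(indegree = lvls, query = prop(geneSet),
             background = prop(backgroundSet))
}

#' Over-representation of a gene set among a TF's bound genes
#'
#' @param network a [BindingNetwork-class].
#' @param tf TF name.
#' @param geneSet query gene ids.
#' @param universe background gene ids.
#' @return one-row data.frame (see [setOverrepresentation()]) with a `tf`
#'   column prepended.
#' @export
boundSetEnrichment <- function(network, tf, geneSet, universe) {
  if (!tf %in% tfNames(network)) stop("unknown TF: ", tf)
  bound <- unique(networkEdges(network)$gene[networkEdges(network)$tf == tf])
  cbind(tf = tf, setOverrepresentation(universe, bound, geneSet),
        stringsAsFactors = FALSE)
}

#' Autoregulation, mutual interactions and fully connected triads
#'
#' Maps each TF to the gene encoding it and reports: whether each TF binds
#' its own gene (autoregulation), which TF pairs bind each other's genes
#' (mutual interaction), and every TF triple whose nine possible edges
#' (three auto + six cross) are all present — the fully connected triads.
#'
#' @param network a [BindingNetwork-class].
#' @param tfGeneMap named character: TF name -> id of the gene encoding it.
#'   TFs without a mapped gene are excluded with a warning.
#' @return list with `auto` (named logical), `mutual` (data.frame tf1, tf2,
#'   mutual), and `triads` (character vector of "+"-joined TF triples).
#' @export
coreCircuitry <- function(network, tfGeneMap) {
  tfs <- intersect(tfNames(network), names(tfGeneMap))
  dropped <- setdiff(tfNames(network), tfs)
  if (length(dropped))
    warning("TF(s) without a mapped gene excluded: ",
            paste(dropped, collapse = ", "))
  ed <- networkEdges(network)
  has <- function(tf, gene) any(ed$tf == tf & ed$gene == gene)
  bind <- outer(tfs, tfs, Vectorize(function(a, b) has(a, tfGeneMap[[b]])))
  dimnames(bind) <- list(tfs, tfs)

  auto <- setNames(diag(bind), tfs)
  mutual <- NULL
  if (length(tfs) >= 2) {
    pairs <- utils::combn(tfs, 2)
    mutual <- data.frame(tf1 = pairs[1, ], tf2 = pairs[2, ],
                         mutual = apply(pairs, 2, function(p)
                           bind[p[1], p[2]] && bind[p[2], p[1]]),
                         stringsAsFactors = FALSE)
  }
  triads <- character()
  if (length(tfs) >= 3) {
    trip <- utils::combn(tfs, 3)
    full <- apply(trip, 2, function(t3) all(bind[t3, t3]))
    triads <- apply(trip[, full, drop = FALSE], 2, paste, collapse = "+")
  }
  list(auto = auto, mutual = mutual, triads = triads)
}
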