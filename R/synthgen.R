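#' Default array sample design
#'
#' Two stages (early blastula "st7", early gastrula "st10.5"), a control, the
#' three single antisense knockdowns and alpha-amanitin at the late stage,
#' with paired replicates throughout.
#'
#' @param nRep replicates per design cell (default 2).
#' @return data.frame with columns `sample`, `stage`, `condition`, `replicate`.
#' @export
defaultDesign <- function(nRep = 2) {
  cells <- rbind(
    data.frame(stage = "st7", condition = "control"),
    expand.grid(stage = "st10.5",
                condition = c("control", "TBP_AS", "TLF_AS", "TBP2_AS",
                              "amanitin"),
                stringsAsFactors = FALSE)
  )
  d <- cells[rep(seq_len(nrow(cells)), each = nRep), ]
  d$replicate <- rep(seq_len(nRep), nrow(cells))
  d$sample <- sprintf("%s_%s_r%d", d$stage, d$condition, d$replicate)
  rownames(d) <- NULL
  d[c("sample", "stage", "condition", "replicate")]
}

#' Default count-experiment design: triple knockdown vs control
#' @param nRep replicates per group (default 2).
#' @return data.frame with columns `sample`, `condition`, `replicate`.
#' @export
countDesign <- function(nRep = 2) {
  d <- expand.grid(replicate = seq_len(nRep),
                   condition = c("control", "TKD"),
                   stringsAsFactors = FALSE)
  d$sample <- sprintf("%s_r%d", d$condition, d$replicate)
  d[c("sample", "condition", "replicate")]
}

.checkDesign <- function(design) {
  need <- c("sample", "stage", "condition", "replicate")
  if (!all(need %in% colnames(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  cells <- rbind(
    data.frame(stage = "st7", condition = "control"),
    data.frame(stage = "st10.5",
               condition = c("control", "TBP_AS", "TLF_AS", "TBP2_AS",
                             "amanitin"))
  )
  for (i in seq_len(nrow(cells))) {
    n <- sum(design$stage == cells$stage[i] &
             design$condition == cells$condition[i])
    if (n < 2)
      stop("design cell missing or unreplicated: ", cells$stage[i], "/",
           cells$condition[i])
  }
  invisible(design)
}

#' Expected log2 expression of one gene class across design cells
#'
#' Encodes the class behaviour the classifier is built to detect: maternal
#' transcripts are flat everywhere; factor-dependent transcripts are induced
#' between stages, shifted by `knockdownLfc` only under their own knockdown,
#' and reduced to `amanitinResidual` of control under alpha-amanitin; TFI
#' transcripts are induced and amanitin-sensitive but untouched by all three
#' knockdowns; silent genes sit at the intensity floor.
#'
#' @param class a label from [GENE_CLASSES].
#' @param baseline maternal/stage-7 log2 level of the gene.
#' @param stage "st7" or "st10.5".
#' @param condition one of control/TBP_AS/TLF_AS/TBP2_AS/amanitin/TKD.
#' @param cfg a [SimConfig-class].
#' @return expected log2 intensity.
#' @export
expectedLog2 <- function(class, baseline, stage, condition, cfg) {
  if (class == "SILENT") return(baseline)
  if (class == "MATERNAL_STABLE") return(baseline)
  # zygotic classes
  x <- baseline
  if (stage == "st10.5") x <- x + cfg@inductionLfc
  if (condition %in% names(.KD_CONDITIONS)) {
    if (.KD_CONDITIONS[[condition]] == class) x <- x + cfg@knockdownLfc
  } else if (condition == "TKD") {
    if (class %in% .KD_CONDITIONS) x <- x + cfg@knockdownLfc
  } else if (condition == "amanitin") {
    x <- x + log2(cfg@amanitinResidual)
  }
  x
}

.drawClasses <- function(cfg) {
  n <- cfg@nGenes
  cnt <- floor(cfg@classProportions * n)
  # distribute remainder to largest fractional parts, deterministically
  rem <- n - sum(cnt)
  if (rem > 0) {
    frac <- cfg@classProportions * n - cnt
    ord <- order(frac, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  sample(rep(names(cnt), cnt))
}

.geneIds <- function(n) sprintf("gene%05d", seq_len(n))

#' Generate a probe-level expression experiment with planted truth
#'
#' Simulates an Affymetrix-style experiment: each transcript is measured by a
#' probe set whose probes share a fixed affinity offset (drawn once, so paired
#' probe-level comparisons cancel it) plus independent log-normal measurement
#' noise.  Class behaviour follows [expectedLog2()].
#'
#' @param cfg a [SimConfig-class].
#' @param design sample design as from [defaultDesign()]; must contain both
#'   stages, the control, all three single knockdowns and amanitin, each with
#'   at least two replicates.
#' @param floor linear intensity floor (default 8); silent genes sit here.
#' @return list with elements `intensities` (linear-scale probe x sample
#'   matrix), `probeMap` (data.frame probe_id, transcript_id), `design`, and
#'   `truth` (a [SyntheticTruth-class]).
#' @examples
#' sim <- generateExpressionExperiment(simConfig(nGenes = 50, seed = 3))
#' dim(sim$intensities)
#' @export
generateExpressionExperiment <- function(cfg, design = defaultDesign(),
                                         floor = 8) {
  .checkDesign(design)
  set.seed(cfg@seed)
  genes <- .geneIds(cfg@nGenes)
  classes <- setNames(.drawClasses(cfg), genes)
  baseline <- setNames(runif(cfg@nGenes, 6, 10), genes)
  baseline[classes == "SILENT"] <- log2(floor)

  npb <- cfg@probesPerTranscript
  probeMap <- data.frame(
    probe_id = sprintf("%s_p%02d", rep(genes, each = npb),
                       rep(seq_len(npb), cfg@nGenes)),
    transcript_id = rep(genes, each = npb),
    stringsAsFactors = FALSE)
  affinity <- rnorm(nrow(probeMap), 0, 0.5)

  mu <- matrix(0, cfg@nGenes, nrow(design),
               dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design)))
    mu[, j] <- mapply(expectedLog2, classes, baseline,
                      MoreArgs = list(stage = design$stage[j],
                                      condition = design$condition[j],
                                      cfg = cfg))
  probeLog2 <- mu[probeMap$transcript_id, , drop = FALSE] + affinity +
    matrix(rnorm(nrow(probeMap) * nrow(design), 0, cfg@probeSd),
           nrow(probeMap), nrow(design))
  intensities <- 2^probeLog2
  rownames(intensities) <- probeMap$probe_id

  truth <- new("SyntheticTruth", classes = classes,
               regulators = setNames(list(), character()), tfs = character())
  list(intensities = intensities, probeMap = probeMap, design = design,
       truth = truth)
}

#' Generate an RNA-seq-like count matrix for knockdown vs control
#'
#' Counts are negative-binomial with a depth-scaled, class-dependent mean.
#' The triple knockdown (TKD) applies the union of the three single-knockdown
#' effects: all three dependent classes drop, TFI and maternal transcripts are
#' unchanged.  `nbDispersion = 0` yields Poisson counts.
#'
#' @param cfg a [SimConfig-class].
#' @param design design as from [countDesign()] with conditions control/TKD.
#' @param truth a [SyntheticTruth-class] from the expression generator; gene
#'   classes are reused so array and count experiments agree.
#' @return integer count matrix, genes x samples.
#' @export
generateCountExperiment <- function(cfg, design = countDesign(),
                                    truth = NULL) {
  if (cfg@seqDepth < 0) stop("negative sequencing depth")
  set.seed(cfg@seed + 1L)
  if (is.null(truth)) {
    genes <- .geneIds(cfg@nGenes)
    classes <- setNames(.drawClasses(cfg), genes)
  } else {
    classes <- geneClasses(truth)
    genes <- names(classes)
  }
  baseline <- setNames(runif(length(genes), 6, 10), genes)
  baseline[classes == "SILENT"] <- 1

  counts <- matrix(0L, length(genes), nrow(design),
                   dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    lg <- mapply(expectedLog2, classes, baseline,
                 MoreArgs = list(stage = "st10.5",
                                 condition = design$condition[j], cfg = cfg))
    rel <- 2^lg
    mu <- cfg@seqDepth * rel / sum(rel)
    counts[, j] <- if (cfg@nbDispersion < 1e-12) rpois(length(mu), mu)
                   else rnbinom(length(mu), mu = mu, size = 1 / cfg@nbDispersion)
  }
  counts
}

#' Generate a random non-overlapping stranded gene annotation
#'
#' Genes (1-3 kb bodies) are packed onto chromosomes with at least 2 kb
#' between neighbours; leftover space is distributed as random gaps.
#'
#' @param nChrom number of chromosomes.
#' @param chromLength length of each chromosome, bp.
#' @param nGenes total gene count.
#' @param seed integer seed.
#' @param minGap minimum intergenic gap, bp (default 2000).
#' @return a stranded [GenomicRanges::GRanges] with metadata `gene_id` and
#'   `score`, plus seqlengths set; deterministic for a seed.
#' @export
generateAnnotation <- function(nChrom, chromLength, nGenes, seed,
                               minGap = 2000) {
  set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(nChrom))
  geneChrom <- sort(rep_len(seq_len(nChrom), nGenes))
  lens <- sample(1000:3000, nGenes, replace = TRUE)
  out <- vector("list", nChrom)
  ids <- .geneIds(nGenes)
  for (ci in seq_len(nChrom)) {
    idx <- which(geneChrom == ci)
    g <- length(idx)
    if (g == 0) next
    slack <- chromLength - sum(lens[idx]) - minGap * (g + 1)
    if (slack < 0)
      stop("cannot pack ", g, " genes into a ", chromLength, " bp chromosome")
    extra <- diff(c(0, sort(runif(g, 0, slack)), slack))
    gaps <- minGap + floor(extra[seq_len(g)])
    starts0 <- cumsum(gaps) + cumsum(c(0, lens[idx][-g]))  # 0-based
    out[[ci]] <- GenomicRanges::GRanges(
      seqnames = chroms[ci],
      ranges = IRanges::IRanges(start = starts0 + 1, width = lens[idx]),
      strand = sample(c("+", "-"), g, replace = TRUE),
      gene_id = ids[idx], score = 0L,
      seqinfo = GenomeInfoDb::Seqinfo(chroms, rep(chromLength, nChrom)))
  }
  sort(do.call(c, out[!vapply(out, is.null, logical(1))]))
}

#' Generate a synthetic ChIP experiment with planted binding edges
#'
#' For each TF, one true peak is placed around the TSS of every planted
#' target gene (inside the gene's future basal regulatory domain) and backed
#' by strongly enriched reads; decoy peaks are placed at the TSS of
#' non-target genes with reads at the background rate, so the input-percentile
#' RPKM filter is what removes them.  Input reads are uniform over the genome.
#'
#' @param annotation stranded gene annotation ([generateAnnotation()]).
#' @param tfSpecs named list: TF name -> character vector of target gene ids
#'   (the planted edges).
#' @param seed integer seed.
#' @param peakWidth peak width in bp (default 300).
#' @param readsPerPeak ChIP reads stacked on each true peak (default 200).
#' @param bgDensity background read density, reads/bp, of the input track
#'   (default 0.02).  ChIP tracks are sequenced to the same total library
#'   size, so the reads stacked on true peaks come out of the ChIP
#'   background — as in a real ChIP library, where the fraction of reads in
#'   peaks depresses background coverage relative to input.
#' @param nDecoys decoy peaks per TF (default 25).
#' @param decoyLevel decoy ChIP coverage relative to input (default 0.7):
#'   in a depth-matched IP library the reads concentrated in bound regions
#'   are missing from unbound ones, so a called-but-unbound region sits
#'   below input coverage.  Setting 1 places decoys exactly at input level,
#'   the boundary case where an empirical 99th-percentile filter passes
#'   roughly the top percent of them by rank.
#' @return list with `peaks` (named list of GRanges per TF), `chipReads`
#'   (named list of GRanges), `inputReads` (GRanges), and `truth`
#'   (a [SyntheticTruth-class] carrying the planted edges).
#' @export
generateChipExperiment <- function(annotation, tfSpecs, seed = 1L,
                                   peakWidth = 300, readsPerPeak = 200,
                                   bgDensity = 0.02, nDecoys = 25,
                                   decoyLevel = 0.7) {
  if (length(tfSpecs) < 1 || is.null(names(tfSpecs)))
    stop("tfSpecs must be a named list of target gene vectors")
  genes <- annotation$gene_id
  unknown <- setdiff(unlist(tfSpecs), genes)
  if (length(unknown))
    stop("tfSpecs reference unknown genes: ", paste(unknown, collapse = ", "))
  set.seed(seed)
  sl <- GenomeInfoDb::seqlengths(annotation)
  genomeBp <- sum(sl)
  tss <- ifelse(as.character(GenomicRanges::strand(annotation)) == "+",
                GenomicRanges::start(annotation),
                GenomicRanges::end(annotation))
  names(tss) <- genes
  chromOf <- setNames(as.character(GenomicRanges::seqnames(annotation)), genes)

  .uniformReads <- function(n) {
    pos <- floor(runif(n, 0, genomeBp)) + 1
    cum <- cumsum(as.numeric(sl))
    ci <- findInterval(pos - 1, c(0, cum), rightmost.closed = TRUE)
    GenomicRanges::sort(GenomicRanges::GRanges(
      names(sl)[ci],
      IRanges::IRanges(start = pos - c(0, cum)[ci], width = 1)))
  }
  .peakAt <- function(gene) {
    ctr <- tss[gene] + sample(-100:100, length(gene), replace = TRUE)
    GenomicRanges::GRanges(chromOf[gene],
      IRanges::IRanges(start = pmax(1, ctr - peakWidth %/% 2),
                       width = peakWidth))
  }

  nBg <- round(genomeBp * bgDensity)
  inputReads <- .uniformReads(nBg)
  peaks <- chipReads <- list()
  for (tf in names(tfSpecs)) {
    targets <- tfSpecs[[tf]]
    truePk <- .peakAt(targets)
    truePk$name <- sprintf("%s_true_%s", tf, targets)
    decoyGenes <- sample(setdiff(genes, targets),
                         min(nDecoys, length(genes) - length(targets)))
    decoyPk <- .peakAt(decoyGenes)
    decoyPk$name <- sprintf("%s_decoy_%s", tf, decoyGenes)
    pk <- c(truePk, decoyPk)
    pk$score <- 0L
    # enriched reads: uniform within each true peak; the ChIP library is
    # sequenced to the input's total size, so enrichment comes out of the
    # ChIP background coverage
    enr <- rep(seq_along(truePk), readsPerPeak)
    rd <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(truePk))[enr],
      IRanges::IRanges(start = GenomicRanges::start(truePk)[enr] +
                         sample.int(peakWidth, length(enr), replace = TRUE) - 1,
                       width = 1))
    nBgChip <- max(0, nBg - length(enr))
    bg <- .uniformReads(nBgChip)
    if (decoyLevel < 1) {
      inDecoy <- IRanges::overlapsAny(bg, decoyPk)
      drop <- inDecoy & runif(length(bg)) > decoyLevel
      bg <- bg[!drop]
    }
    chipReads[[tf]] <- GenomicRanges::sort(c(rd, bg))
    peaks[[tf]] <- GenomicRanges::sort(pk)
  }
  regulators <- split(rep(names(tfSpecs), lengths(tfSpecs)),
                      unlist(tfSpecs, use.names = FALSE))
  classes <- setNames(rep("SILENT", length(genes)), genes)
  truth <- new("SyntheticTruth",
               classes = classes,
               regulators = regulators[intersect(genes, names(regulators))],
               tfs = names(tfSpecs))
  list(peaks = peaks, chipReads = chipReads, inputReads = inputReads,
       truth = truth)
}
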