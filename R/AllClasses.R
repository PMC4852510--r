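#' @import methods
#' @importFrom stats median na.omit p.adjust phyper pnorm quantile rlnorm
#'   rnbinom rnorm rpois runif sd setNames var dnbinom cor kmeans lm coef
#' @importFrom utils head read.delim write.table
NULL

#' Gene classes simulated by the expression generator
#'
#' Every simulated gene carries exactly one label:
#' \describe{
#'   \item{MATERNAL_STABLE}{maternally loaded, equal at both stages, untouched
#'     by every knockdown and by alpha-amanitin.}
#'   \item{TBP_DEP / TLF_DEP / TBP2_DEP}{zygotically induced between stages,
#'     knocked down only when the matching initiation factor is ablated,
#'     amanitin-sensitive.}
#'   \item{TFI}{zygotically induced (or at least actively transcribed),
#'     insensitive to all three single knockdowns, amanitin-sensitive.}
#'   \item{SILENT}{near-floor expression everywhere.}
#' }
#' @export
GENE_CLASSES <- c("MATERNAL_STABLE", "TBP_DEP", "TLF_DEP", "TBP2_DEP",
                  "TFI", "SILENT")

#' Knockdown conditions paired with their dependent gene class
#' @keywords internal
.KD_CONDITIONS <- c(TBP_AS = "TBP_DEP", TLF_AS = "TLF_DEP", TBP2_AS = "TBP2_DEP")

#' Simulation configuration
#'
#' Holds every tunable of the synthetic-data generators.  Defaults encode the
#' experimental design the pipeline assumes: an 11-probe probe set per
#' transcript, a 3 log2-unit developmental induction, a -3 log2-unit
#' knockdown effect, and an alpha-amanitin residual of 5% of control.
#'
#' @slot nGenes number of simulated genes.
#' @slot probesPerTranscript probes per transcript (probe-set size).
#' @slot classProportions named fractions over [GENE_CLASSES]; must sum to 1.
#' @slot inductionLfc log2 induction between the early and late stage.
#' @slot knockdownLfc log2 shift applied in the matching knockdown (negative).
#' @slot amanitinResidual residual fraction of control expression under
#'   alpha-amanitin for zygotically transcribed classes.
#' @slot probeSd log2-scale SD of per-probe measurement noise.
#' @slot nbDispersion negative-binomial dispersion of simulated counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @slot seqDepth expected reads per count-matrix sample.
#' @slot seed integer seed; a fixed seed makes every generator byte-identical.
#' @export
setClass("SimConfig", representation(
  nGenes = "numeric",
  probesPerTranscript = "numeric",
  classProportions = "numeric",
  inductionLfc = "numeric",
  knockdownLfc = "numeric",
  amanitinResidual = "numeric",
  probeSd = "numeric",
  nbDispersion = "numeric",
  seqDepth = "numeric",
  seed = "numeric"
))

setValidity("SimConfig", function(object) {
  p <- object@classProportions
  msg <- character()
  if (!setequal(names(p), GENE_CLASSES))
    msg <- c(msg, "classProportions must be named by GENE_CLASSES")
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-8)
    msg <- c(msg, "classProportions must lie in [0,1] and sum to 1")
  if (object@probeSd < 0) msg <- c(msg, "probeSd must be >= 0")
  if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
  if (object@amanitinResidual <= 0 || object@amanitinResidual > 1)
    msg <- c(msg, "amanitinResidual must be in (0,1]")
  if (object@seqDepth < 0) msg <- c(msg, "seqDepth must be >= 0")
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a [SimConfig-class]
#'
#' @param nGenes number of genes to simulate.
#' @param probesPerTranscript probe-set size (default 11).
#' @param classProportions named fractions over the six gene classes.
#' @param inductionLfc developmental induction, log2 units (default 3).
#' @param knockdownLfc knockdown effect, log2 units (default -3).
#' @param amanitinResidual residual fraction under amanitin (default 0.05).
#' @param probeSd probe noise SD, log2 units (default 0.25).
#' @param nbDispersion NB dispersion of counts (default 0.1).
#' @param seqDepth expected reads per sample (default 1e6).
#' @param seed integer seed (default 1).
#' @return a validated `SimConfig` object.
#' @examples
#' cfg <- simConfig(nGenes = 100, seed = 7)
#' nGenes(cfg)
#' @export
simConfig <- function(nGenes = 1000,
                      probesPerTranscript = 11,
                      classProportions = c(MATERNAL_STABLE = 0.40,
                                           TBP_DEP = 0.12, TLF_DEP = 0.12,
                                           TBP2_DEP = 0.12, TFI = 0.10,
                                           SILENT = 0.14),
                      inductionLfc = 3.0,
                      knockdownLfc = -3.0,
                      amanitinResidual = 0.05,
                      probeSd = 0.25,
                      nbDispersion = 0.1,
                      seqDepth = 1e6,
                      seed = 1L) {
  new("SimConfig", nGenes = nGenes, probesPerTranscript = probesPerTranscript,
      classProportions = classProportions[GENE_CLASSES],
      inductionLfc = inductionLfc, knockdownLfc = knockdownLfc,
      amanitinResidual = amanitinResidual, probeSd = probeSd,
      nbDispersion = nbDispersion, seqDepth = seqDepth, seed = seed)
}

#' @describeIn simConfig number of genes in a configuration
#' @param x a `SimConfig`
#' @export
nGenes <- function(x) x@nGenes

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,",
      object@probesPerTranscript, "probes/transcript\n")
  cat("  induction", object@inductionLfc, "log2; knockdown",
      object@knockdownLfc, "log2; amanitin residual",
      object@amanitinResidual, "\n")
  cat("  probeSd", object@probeSd, "; nbDispersion", object@nbDispersion,
      "; depth", object@seqDepth, "; seed", object@seed, "\n")
  p <- object@classProportions
  cat("  classes:", paste(sprintf("%s=%.2f", names(p), p), collapse = " "), "\n")
})

#' Planted ground truth of a synthetic experiment
#'
#' @slot classes named character: gene id -> gene class label.
#' @slot regulators named list: gene id -> character vector of planted TF
#'   regulators (possibly empty).
#' @slot tfs character vector of TF names.
#' @export
setClass("SyntheticTruth", representation(
  classes = "character",
  regulators = "list",
  tfs = "character"
))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (!all(object@classes %in% GENE_CLASSES))
    msg <- c(msg, "unknown gene class label")
  if (length(object@regulators) &&
      !all(names(object@regulators) %in% names(object@classes)))
    msg <- c(msg, "regulator sets must reference annotated genes")
  if (length(msg)) msg else TRUE
})

#' @describeIn SyntheticTruth-class named gene->class vector
#' @param x,object a `SyntheticTruth`
#' @export
geneClasses <- function(x) x@classes

#' @describeIn SyntheticTruth-class planted TF->gene edges as a data.frame
#'   with columns `tf`, `gene`
#' @export
trueEdges <- function(x) {
  reg <- x@regulators
  n <- lengths(reg)
  data.frame(tf = unlist(reg, use.names = FALSE),
             gene = rep(names(reg), n), stringsAsFactors = FALSE)
}

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@classes), "genes\n")
  print(table(factor(object@classes, levels = GENE_CLASSES)))
  if (length(object@tfs))
    cat("  TFs:", paste(object@tfs, collapse = ", "), "with",
        nrow(trueEdges(object)), "planted edges\n")
})

#' Directed transcription-factor binding network
#'
#' An edge tf -> gene exists iff at least one filtered peak of the TF overlaps
#' the gene's regulatory domain.  A gene's indegree is the number of distinct
#' TFs bound at its domain.
#'
#' @slot tfs character vector of TF names (network inputs).
#' @slot edges data.frame with columns `tf`, `gene`, one row per directed edge.
#' @slot genes character vector: the annotated gene universe.
#' @export
setClass("BindingNetwork", representation(
  tfs = "character",
  edges = "data.frame",
  genes = "character"
))

setValidity("BindingNetwork", function(object) {
  msg <- character()
  if (!all(c("tf", "gene") %in% colnames(object@edges)))
    msg <- c(msg, "edges must have columns tf, gene")
  else {
    if (!all(object@edges$tf %in% object@tfs))
      msg <- c(msg, "edge tf not in TF list")
    if (anyDuplicated(object@edges[c("tf", "gene")]))
      msg <- c(msg, "duplicated edges")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a [BindingNetwork-class]
#' @param tfs TF names.
#' @param edges data.frame with columns `tf`, `gene` (duplicates collapsed).
#' @param genes gene universe; defaults to the genes present in `edges`.
#' @export
bindingNetwork <- function(tfs, edges, genes = unique(edges$gene)) {
  edges <- unique(edges[c("tf", "gene")])
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  new("BindingNetwork", tfs = tfs, edges = edges, genes = as.character(genes))
}

#' @describeIn bindingNetwork directed edge list of a network
#' @param x a `BindingNetwork`
#' @export
networkEdges <- function(x) x@edges

#' @describeIn bindingNetwork TF names of a network
#' @export
tfNames <- function(x) x@tfs

#' @describeIn bindingNetwork bound-TF set per gene (named list over `genes`)
#' @export
boundTfs <- function(x) {
  out <- rep(list(character()), length(x@genes))
  names(out) <- x@genes
  sp <- split(x@edges$tf, x@edges$gene)
  out[names(sp)] <- lapply(sp, sort)
  out
}

#' @describeIn bindingNetwork indegree (number of distinct bound TFs) per gene
#' @export
indegree <- function(x) lengths(boundTfs(x))

setMethod("show", "BindingNetwork", function(object) {
  cat("BindingNetwork:", length(object@tfs), "TFs,",
      length(object@genes), "genes,", nrow(object@edges), "edges\n")
  cat("  TFs:", paste(object@tfs, collapse = ", "), "\n")
})
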