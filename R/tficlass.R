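#' Rules for the compound TFI classification
#'
#' @param devLfc developmental-induction log2 gate (default 1.5).
#' @param kdLfc knockdown-effect log2 gate (default 1.5).
#' @param alpha signed-rank significance level (default 0.05).
#' @param amanitinLfc amanitin-sensitivity log2 gate (default 1.5).
#' @param foldGate if TRUE (default) "affected by a knockdown" requires both
#'   a consistent change call and an absolute mean log2 ratio >= `kdLfc`;
#'   if FALSE the change call alone marks a transcript as affected.
#' @param floor linear intensity floor (default 8).
#' @return validated rule list.
#' @export
classificationRules <- function(devLfc = 1.5, kdLfc = 1.5, alpha = 0.05,
                                amanitinLfc = 1.5, foldGate = TRUE,
                                floor = 8) {
  stopifnot(devLfc > 0, kdLfc > 0, amanitinLfc > 0, alpha > 0, alpha < 1)
  list(devLfc = devLfc, kdLfc = kdLfc, alpha = alpha,
       amanitinLfc = amanitinLfc, foldGate = foldGate, floor = floor)
}

# per-transcript consistent call and mean log2 ratio for one comparison,
# using matched replicate pairs (rep r of cell A vs rep r of cell B)
.comparisonCalls <- function(intensities, probeMap, design,
                             stageA, condA, stageB, condB, rules) {
  th <- changeThresholds(alpha = rules$alpha, floor = rules$floor)
  selA <- design$stage == stageA & design$condition == condA
  selB <- design$stage == stageB & design$condition == condB
  if (!any(selA)) stop("missing design cell: ", stageA, "/", condA)
  if (!any(selB)) stop("missing design cell: ", stageB, "/", condB)
  reps <- intersect(design$replicate[selA], design$replicate[selB])
  if (length(reps) < 2) stop("need >= 2 matched replicates for ",
                             condA, " vs ", condB)
  tx <- probeMap$transcript_id[match(rownames(intensities),
                                     probeMap$probe_id)]
  idx <- split(seq_len(nrow(intensities)), tx)
  calls <- matrix("", length(idx), length(reps))
  ratios <- matrix(0, length(idx), length(reps))
  for (j in seq_along(reps)) {
    sa <- design$sample[selA & design$replicate == reps[j]][1]
    sb <- design$sample[selB & design$replicate == reps[j]][1]
    for (i in seq_along(idx)) {
      cc <- changeCall(intensities[idx[[i]], sa], intensities[idx[[i]], sb],
                       th)
      calls[i, j] <- cc$call
      ratios[i, j] <- cc$log2Ratio
    }
  }
  data.frame(transcript_id = names(idx),
             call = apply(calls, 1, consistentCall),
             meanLog2Ratio = rowMeans(ratios),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Developmentally induced transcripts
#'
#' Consistent Increase call between the early and late stage in every
#' replicate pair, plus a mean log2 ratio above the induction gate.
#'
#' @param intensities probe x sample linear intensity matrix.
#' @param probeMap probe -> transcript map.
#' @param design sample design ([defaultDesign()]).
#' @param rules from [classificationRules()].
#' @return character vector of transcript ids.
#' @export
developmentallyInduced <- function(intensities, probeMap, design,
                                   rules = classificationRules()) {
  cc <- .comparisonCalls(intensities, probeMap, design,
                         "st7", "control", "st10.5", "control", rules)
  cc$transcript_id[cc$call == "I" & cc$meanLog2Ratio > rules$devLfc]
}

#' Transcripts dependent on one initiation factor
#'
#' Consistent Decrease call under the factor's antisense knockdown versus
#' control, plus a mean log2 ratio below minus the knockdown gate.
#'
#' @inheritParams developmentallyInduced
#' @param factor one of "TBP", "TLF", "TBP2".
#' @export
knockdownDependent <- function(intensities, probeMap, design, factor,
                               rules = classificationRules()) {
  cond <- paste0(match.arg(factor, c("TBP", "TLF", "TBP2")), "_AS")
  cc <- .comparisonCalls(intensities, probeMap, design,
                         "st10.5", "control", "st10.5", cond, rules)
  cc$transcript_id[cc$call == "D" & cc$meanLog2Ratio < -rules$kdLfc]
}

#' Transcripts unaffected by all three knockdowns
#'
#' A transcript is "affected" by a knockdown when it has a consistent call in
#' either direction and (with the default fold gate) an absolute mean log2
#' ratio at or above the knockdown gate; unaffected transcripts fail this
#' composite for TBP, TLF and TBP2 alike.
#'
#' @inheritParams developmentallyInduced
#' @export
unaffectedByAll <- function(intensities, probeMap, design,
                            rules = classificationRules()) {
  affected <- NULL
  ids <- NULL
  for (cond in c("TBP_AS", "TLF_AS", "TBP2_AS")) {
    cc <- .comparisonCalls(intensities, probeMap, design,
                           "st10.5", "control", "st10.5", cond, rules)
    if (is.null(ids)) {
      ids <- cc$transcript_id
      affected <- rep(FALSE, length(ids))
    }
    hit <- cc$call != "NC"
    if (rules$foldGate) hit <- hit & abs(cc$meanLog2Ratio) >= rules$kdLfc
    affected <- affected | hit[match(ids, cc$transcript_id)]
  }
  ids[!affected]
}

#' Alpha-amanitin-sensitive transcripts
#'
#' Consistent Decrease under amanitin versus control at the late stage, with
#' a mean log2 ratio at or below minus the amanitin gate -- the operational
#' certificate of active RNAPII transcription.
#'
#' @inheritParams developmentallyInduced
#' @export
amanitinSensitive <- function(intensities, probeMap, design,
                              rules = classificationRules()) {
  cc <- .comparisonCalls(intensities, probeMap, design,
                         "st10.5", "control", "st10.5", "amanitin", rules)
  cc$transcript_id[cc$call == "D" & cc$meanLog2Ratio <= -rules$amanitinLfc]
}

#' The compound TFI classification
#'
#' TFI transcripts are unaffected by knockdown of TBP, TLF and TBP2, and are
#' either developmentally induced or amanitin-sensitive (actively
#' transcribed):
#' `tfi = unaffected_all & (induced | amanitin_sensitive)`.
#'
#' @inheritParams developmentallyInduced
#' @return data.frame with one row per transcript and logical flag columns
#'   `induced`, `tbp_dep`, `tlf_dep`, `tbp2_dep`, `amanitin_sensitive`,
#'   `unaffected_all`, `tfi`.
#' @examples
#' sim <- generateExpressionExperiment(simConfig(nGenes = 40, seed = 2))
#' lab <- tfiSet(sim$intensities, sim$probeMap, sim$design)
#' table(lab$tfi, geneClasses(sim$truth)[lab$transcript_id] == "TFI")
#' @export
tfiSet <- function(intensities, probeMap, design,
                   rules = classificationRules()) {
  ids <- sort(unique(probeMap$transcript_id))
  flag <- function(members) ids %in% members
  lab <- data.frame(
    transcript_id = ids,
    induced = flag(developmentallyInduced(intensities, probeMap, design,
                                          rules)),
    tbp_dep = flag(knockdownDependent(intensities, probeMap, design, "TBP",
                                      rules)),
    tlf_dep = flag(knockdownDependent(intensities, probeMap, design, "TLF",
                                      rules)),
    tbp2_dep = flag(knockdownDependent(intensities, probeMap, design, "TBP2",
                                       rules)),
    amanitin_sensitive = flag(amanitinSensitive(intensities, probeMap,
                                                design, rules)),
    unaffected_all = flag(unaffectedByAll(intensities, probeMap, design,
                                          rules)),
    stringsAsFactors = FALSE)
  lab$tfi <- lab$unaffected_all & (lab$induced | lab$amanitin_sensitive)
  lab
}

#' Replicate expression-ratio matrix for clustering
#'
#' Builds the matrix clustered in the ratio analysis: per transcript, the
#' summarized log2 ratios (knockdowns vs control, late vs early stage,
#' amanitin vs control), one column per replicate comparison.
#'
#' @inheritParams developmentallyInduced
#' @return numeric matrix, transcripts x (5 comparisons * replicates).
#' @export
ratioMatrix <- function(intensities, probeMap, design,
                        rules = classificationRules()) {
  comps <- list(
    TBP_AS  = c("st10.5", "control", "st10.5", "TBP_AS"),
    TLF_AS  = c("st10.5", "control", "st10.5", "TLF_AS"),
    TBP2_AS = c("st10.5", "control", "st10.5", "TBP2_AS"),
    st10_vs_st7 = c("st7", "control", "st10.5", "control"),
    amanitin = c("st10.5", "control", "st10.5", "amanitin"))
  sm <- summarizeProbes(intensities, probeMap, rules$floor)$log2
  cols <- list()
  for (nm in names(comps)) {
    a <- comps[[nm]]
    selA <- design$stage == a[1] & design$condition == a[2]
    selB <- design$stage == a[3] & design$condition == a[4]
    reps <- intersect(design$replicate[selA], design$replicate[selB])
    for (r in reps) {
      sa <- design$sample[selA & design$replicate == r][1]
      sb <- design$sample[selB & design$replicate == r][1]
      cols[[sprintf("%s_r%d", nm, r)]] <- sm[, sb] - sm[, sa]
    }
  }
  do.call(cbind, cols)
}

#' K-means clustering of expression ratios under Pearson distance
#'
#' Lloyd iterations with distance d(x, c) = 1 - Pearson(x, c).  Rows are
#' standardized (zero mean, unit variance) so the correlation distance
#' becomes a scaled squared Euclidean distance; centroids are the
#' standardized means of their members, which makes the objective (sum of
#' 1 - r to the assigned centroid) non-increasing across iterations.  Empty
#' clusters are reseeded from the point farthest from its centroid;
#' zero-variance rows cannot be correlated and are assigned to cluster 1 and
#' flagged.
#'
#' @param ratios transcripts x comparisons numeric matrix.
#' @param k number of clusters (default 8).
#' @param seed integer seed.
#' @param nstart random restarts (default 5); the best objective wins.
#' @param maxIter Lloyd iteration cap (default 100).
#' @return list with `cluster` (named assignment), `centers`, `objective`,
#'   `objectiveTrace` (of the winning start) and `flagged` row names.
#' @export
kmeansRatioClusters <- function(ratios, k = 8, seed = 1L, nstart = 5,
                                maxIter = 100) {
  stopifnot(k >= 1, nrow(ratios) >= k)
  set.seed(seed)
  rsd <- apply(ratios, 1, sd)
  flagged <- rownames(ratios)[rsd == 0 | is.na(rsd)]
  ok <- rsd > 0 & !is.na(rsd)
  z <- t(scale(t(ratios[ok, , drop = FALSE])))
  p <- ncol(z)
  zn <- z / sqrt(rowSums(z^2))            # unit vectors: 1 - r = ||a-b||^2/2

  runOnce <- function() {
    ctr <- zn[sample(nrow(zn), k), , drop = FALSE]
    assign <- rep(1L, nrow(zn))
    trace <- numeric()
    for (it in seq_len(maxIter)) {
      sim <- zn %*% t(ctr)                 # Pearson correlations
      newAssign <- max.col(sim, ties.method = "first")
      obj <- sum(1 - sim[cbind(seq_len(nrow(zn)), newAssign)])
      trace <- c(trace, obj)
      for (cl in seq_len(k)) {
        members <- which(newAssign == cl)
        if (length(members) == 0) {
          worst <- which.min(sim[cbind(seq_len(nrow(zn)), newAssign)])
          newAssign[worst] <- cl
          members <- worst
        }
        m <- colMeans(zn[members, , drop = FALSE])
        m <- m - mean(m)
        if (sum(m^2) > 1e-12) ctr[cl, ] <- m / sqrt(sum(m^2))
      }
      if (it > 1 && identical(assign, newAssign)) { assign <- newAssign; break }
      assign <- newAssign
    }
    list(assign = assign, ctr = ctr, obj = trace[length(trace)],
         trace = trace)
  }
  best <- NULL
  for (s in seq_len(nstart)) {
    res <- runOnce()
    if (is.null(best) || res$obj < best$obj) best <- res
  }
  cluster <- rep(1L, nrow(ratios))
  names(cluster) <- rownames(ratios)
  cluster[rownames(z)] <- best$assign
  list(cluster = cluster, centers = best$ctr, objective = best$obj,
       objectiveTrace = best$trace, flagged = flagged)
}
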