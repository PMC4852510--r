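#' Default run configuration (synthetic mode)
#'
#' A single nested list drives the whole pipeline; it is serialized verbatim
#' (YAML) into every run directory for auditability.
#'
#' @param seed master seed for the run.
#' @return config list with components `mode`, `seed`, `sim`, `thresholds`,
#'   `rules`, `cluster`, `network`.
#' @export
defaultRunConfig <- function(seed = 42L) {
  list(
    mode = "synthetic",
    seed = as.integer(seed),
    sim = list(nGenes = 1000, probesPerTranscript = 11, inductionLfc = 3.0,
               knockdownLfc = -3.0, amanitinResidual = 0.05, probeSd = 0.25,
               nbDispersion = 0.1, seqDepth = 1e6),
    thresholds = list(alpha = 0.05, lfc = 1.5, deFdr = 0.10, floor = 8),
    rules = list(devLfc = 1.5, kdLfc = 1.5, alpha = 0.05, amanitinLfc = 1.5,
                 foldGate = TRUE),
    cluster = list(k = 8, nstart = 5),
    network = list(nChrom = 2, chromLength = 5e7, nTfs = 4,
                   targetsPerTf = 15, percentile = 99,
                   basalUp = 5000, basalDown = 1000, maxExt = 1e6)
  )
}

#' Validate a run configuration
#'
#' Schema and cross-field checks; an empty issue list means the config is
#' runnable.
#'
#' @param config config list (see [defaultRunConfig()]).
#' @return character vector of issues (empty when valid).
#' @export
validateConfig <- function(config) {
  issues <- character()
  addIf <- function(cond, msg) if (isTRUE(cond)) c(issues, msg) else issues
  mode <- config$mode
  issues <- addIf(is.null(mode) || !mode %in% c("synthetic", "real"),
                  "mode must be 'synthetic' or 'real'")
  issues <- addIf(is.null(config$seed), "seed is required")
  hasPaths <- !is.null(config$inputs)
  issues <- addIf(identical(mode, "synthetic") && hasPaths,
                  "synthetic mode must not carry real-input paths")
  issues <- addIf(identical(mode, "real") && !hasPaths,
                  "real mode requires an 'inputs' block")
  if (identical(mode, "real") && hasPaths) {
    for (f in c("expression", "probeMap", "design"))
      issues <- addIf(is.null(config$inputs[[f]]),
                      paste0("inputs$", f, " path missing"))
    if (!is.null(config$inputs$peaks))
      issues <- addIf(is.null(config$inputs$annotation),
                      "network stage needs inputs$annotation")
  }
  a <- config$rules$alpha
  issues <- addIf(!is.null(a) && (a <= 0 || a >= 1),
                  "rules$alpha must be in (0,1)")
  k <- config$cluster$k
  issues <- addIf(!is.null(k) && k < 1, "cluster$k must be >= 1")
  pc <- config$network$percentile
  issues <- addIf(!is.null(pc) && (pc < 0 || pc > 100),
                  "network$percentile must be in [0,100]")
  issues
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' simulate (or load) -> classify -> cluster -> differential expression ->
#' enrichment -> binding network, writing every intermediate table, a
#' network JSON and a markdown report into `outdir`.  With a fixed seed the
#' run directory is reproduced bit-identically.
#'
#' @param config config list; must pass [validateConfig()].
#' @param outdir output directory (created; existing files overwritten).
#' @return `outdir`, invisibly.  Files written: `config.yaml`, `run.log`,
#'   `labeling.tsv`, `clusters.tsv`, `de.tsv`, `enrichment.tsv`,
#'   `network.json`, `edges.tsv`, `report.md` (plus `truth_classes.tsv` and
#'   `truth_edges.tsv` in synthetic mode).
#' @export
runAll <- function(config = defaultRunConfig(), outdir) {
  issues <- validateConfig(config)
  if (length(issues))
    stop("invalid config:\n  - ", paste(issues, collapse = "\n  - "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  th <- do.call(changeThresholds, config$thresholds)
  rules <- do.call(classificationRules, config$rules)
  rpt <- character()
  note <- function(...) rpt <<- c(rpt, paste0(...))
  note("# Pipeline run report", "")

  if (config$mode == "synthetic") {
    cfg <- do.call(simConfig, c(config$sim, list(seed = config$seed)))
    sim <- .stage("simulate", generateExpressionExperiment(cfg))
    truthClass <- geneClasses(sim$truth)
    writeTsv(data.frame(gene_id = names(truthClass), class = truthClass),
             file.path(outdir, "truth_classes.tsv"), rowLabel = NULL)
  } else {
    sim <- .stage("load", list(
      intensities = as.matrix(readTsv(config$inputs$expression)),
      probeMap = readTsv(config$inputs$probeMap, rowLabel = NULL),
      design = readTsv(config$inputs$design, rowLabel = NULL)))
    truthClass <- NULL
  }

  lab <- .stage("classify",
                tfiSet(sim$intensities, sim$probeMap, sim$design, rules))
  writeTsv(lab, file.path(outdir, "labeling.tsv"), rowLabel = NULL)
  tfiGenes <- lab$transcript_id[lab$tfi]
  note("", sprintf("- TFI transcripts: %d of %d", length(tfiGenes),
                   nrow(lab)))
  if (!is.null(truthClass)) {
    truthTfi <- names(truthClass)[truthClass == "TFI"]
    sens <- mean(truthTfi %in% tfiGenes)
    spec <- mean(!setdiff(lab$transcript_id, truthTfi) %in% tfiGenes)
    note(sprintf("- TFI recovery vs planted truth: sensitivity %.3f, specificity %.3f",
                 sens, spec))
  }

  active <- lab$transcript_id[lab$induced | lab$amanitin_sensitive]
  km <- NULL
  if (length(active) >= config$cluster$k) {
    rm <- .stage("cluster", {
      m <- ratioMatrix(sim$intensities, sim$probeMap, sim$design, rules)
      kmeansRatioClusters(m[active, , drop = FALSE], k = config$cluster$k,
                          seed = config$seed, nstart = config$cluster$nstart)
    })
    km <- rm
    writeTsv(data.frame(transcript_id = names(rm$cluster),
                        cluster = rm$cluster),
             file.path(outdir, "clusters.tsv"), rowLabel = NULL)
    note(sprintf("- clustered %d developmentally active transcripts into %d clusters (objective %.3f)",
                 length(active), config$cluster$k, rm$objective))
  }

  if (config$mode == "synthetic") {
    counts <- .stage("counts", generateCountExperiment(cfg, countDesign(),
                                                       sim$truth))
    de <- .stage("de", nbDeTest(counts, factor(countDesign()$condition,
                                               c("control", "TKD")), th))
    writeTsv(de, file.path(outdir, "de.tsv"), rowLabel = NULL)
    dec <- sum(de$direction == "decreased" & de$gene_id %in% tfiGenes)
    shift <- groupShiftTest(de$log2_fc[de$gene_id %in% tfiGenes])
    note(sprintf("- triple-knockdown DE: %d TFI transcripts decreased at FDR %.2f; TFI set shift p = %.3g",
                 dec, th$deFdr, shift$p))

    gmt <- split(names(truthClass), truthClass)
    enr <- .stage("enrich", termEnrichment(gmt, tfiGenes,
                                           lab$transcript_id))
    writeTsv(enr, file.path(outdir, "enrichment.tsv"), rowLabel = NULL)
    note(sprintf("- class-term enrichment: %d term(s) pass size/FDR/fold filters",
                 nrow(enr)))

    np <- config$network
    net <- .stage("network", {
      ann <- generateAnnotation(np$nChrom, np$chromLength, cfg@nGenes,
                                seed = config$seed + 2L)
      tfiAnn <- intersect(ann$gene_id, names(truthClass)[truthClass == "TFI"])
      set.seed(config$seed + 3L)
      tfGenes <- sample(tfiAnn, np$nTfs)
      tfs <- setNames(tfGenes, sprintf("TF%d", seq_len(np$nTfs)))
      tfSpecs <- lapply(seq_len(np$nTfs), function(i) {
        targets <- unique(c(tfGenes[1:min(3, np$nTfs)],
                            sample(tfiAnn, np$targetsPerTf)))
        targets
      })
      names(tfSpecs) <- names(tfs)
      chip <- generateChipExperiment(ann, tfSpecs, seed = config$seed + 4L)
      dom <- regulatoryDomains(ann, np$basalUp, np$basalDown, np$maxExt)
      filt <- lapply(names(chip$peaks), function(tf)
        filterPeaks(chip$peaks[[tf]], chip$chipReads[[tf]],
                    chip$inputReads, np$percentile))
      names(filt) <- names(chip$peaks)
      list(network = assignPeaks(filt, dom), chip = chip, tfMap = tfs)
    })
    writeNetworkJson(net$network, file.path(outdir, "network.json"))
    writeTsv(networkEdges(net$network), file.path(outdir, "edges.tsv"),
             rowLabel = NULL)
    tEdges <- trueEdges(net$chip$truth)
    writeTsv(tEdges, file.path(outdir, "truth_edges.tsv"), rowLabel = NULL)
    key <- function(d) paste(d$tf, d$gene)
    found <- key(networkEdges(net$network)); planted <- key(tEdges)
    prec <- mean(found %in% planted); rec <- mean(planted %in% found)
    note(sprintf("- network: %d edges; planted-edge precision %.3f, recall %.3f",
                 length(found), prec, rec))
    tfiNet <- intersect(net$network@genes,
                        names(truthClass)[truthClass == "TFI"])
    comb <- bindingCombinations(net$network, tfiNet,
                                anyOf = list(all = tfNames(net$network)))
    note(sprintf("- %.0f%% of TFI genes bound by >= 1 TF; top combination '%s' (%d genes)",
                 100 * comb$anyOf$fraction[1], comb$combinations$combo[1],
                 comb$combinations$count[1]))
    idg <- indegreeDistribution(net$network, tfiNet, net$network@genes)
    writeTsv(idg, file.path(outdir, "indegree.tsv"), rowLabel = NULL)
    circ <- coreCircuitry(net$network, net$tfMap)
    note(sprintf("- fully connected triads: %s",
                 if (length(circ$triads)) paste(circ$triads, collapse = "; ")
                 else "none"))
  }

  writeLines(c(sprintf("tfinet %s", as.character(utils::packageVersion("tfinet"))),
               sprintf("seed: %d", config$seed),
               sprintf("mode: %s", config$mode),
               sprintf("alpha: %g, lfc gate: %g, DE FDR: %g",
                       rules$alpha, rules$kdLfc, th$deFdr)),
             file.path(outdir, "run.log"))
  writeLines(rpt, file.path(outdir, "report.md"))
  invisible(outdir)
}
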