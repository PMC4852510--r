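#' Default thresholds for change calls and differential expression
#'
#' @param alpha one-sided signed-rank significance level (default 0.05).
#' @param lfc log2 fold-change gate (default 1.5, i.e. 2.8-fold).
#' @param deFdr FDR level for the count-based DE test (default 0.10).
#' @param floor linear intensity floor applied before log2 (default 8),
#'   standard microarray practice to avoid unstable ratios.
#' @return validated list of thresholds.
#' @export
changeThresholds <- function(alpha = 0.05, lfc = 1.5, deFdr = 0.10,
                             floor = 8) {
  stopifnot(alpha > 0, alpha < 1, lfc > 0, deFdr > 0, deFdr < 1, floor > 0)
  list(alpha = alpha, lfc = lfc, deFdr = deFdr, floor = floor)
}

.floorLog2 <- function(x, floor = 8) log2(pmax(x, floor))

#' Summarize probe-level intensities to transcript log2 expression
#'
#' Per transcript and sample, the mean of floored log2 probe intensities.
#' Transcripts measured by fewer than 3 probes are flagged but not dropped.
#'
#' @param intensities linear-scale probe x sample matrix.
#' @param probeMap data.frame with columns `probe_id`, `transcript_id`;
#'   every probe row must be mapped.
#' @param floor linear intensity floor (default 8).
#' @return list with `log2` (transcript x sample matrix), `nProbes`,
#'   and logical `flagged` (< 3 probes).
#' @export
summarizeProbes <- function(intensities, probeMap, floor = 8) {
  if (!all(rownames(intensities) %in% probeMap$probe_id))
    stop("unmapped probes: ",
         paste(head(setdiff(rownames(intensities), probeMap$probe_id)),
               collapse = ", "))
  tx <- probeMap$transcript_id[match(rownames(intensities),
                                     probeMap$probe_id)]
  lg <- .floorLog2(intensities, floor)
  cnt <- table(tx)
  out <- rowsum(lg, tx)
  nP <- setNames(as.integer(cnt[rownames(out)]), rownames(out))
  out <- out / nP
  list(log2 = out, nProbes = nP, flagged = nP < 3)
}

#' One-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are discarded; absolute values are midranked.  For
#' n <= 12 usable pairs the null distribution of the rank sum is enumerated
#' exactly over all 2^n sign assignments (by generating-function convolution,
#' which handles ties exactly); above that a normal approximation with tie
#' and continuity corrections is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param direction "greater" tests for a positive shift, "less" for a
#'   negative one.
#' @param exactMax largest n handled by exact enumeration (default 12).
#' @return list with `statistic` (signed-rank sum W of positive differences),
#'   `p` (one-sided), `n` (usable pairs) and `exact`.  If every difference is
#'   zero, the no-change sentinel `list(statistic = NA, p = NA, n = 0)` is
#'   returned.
#' @examples
#' signedRankTest(c(1, 2, 3, 4, 5), "greater")$p  # 1/32
#' @export
signedRankTest <- function(diffs, direction = c("greater", "less"),
                           exactMax = 12) {
  direction <- match.arg(direction)
  d <- diffs[diffs != 0 & !is.na(diffs)]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p = NA_real_, n = 0L, exact = NA))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    # distribution of 2*W under sign randomization; midranks*2 are integers
    r2 <- as.integer(round(2 * r))
    pmf <- c(1, rep(0, sum(r2)))          # pmf[w+1] = #assignments with 2W=w
    for (ri in r2) {
      shifted <- c(rep(0, ri), pmf[seq_len(length(pmf) - ri)])
      pmf <- pmf + shifted
    }
    pmf <- pmf / 2^n
    w2 <- round(2 * W)
    p <- if (direction == "greater") sum(pmf[(w2 + 1):length(pmf)])
         else sum(pmf[1:(w2 + 1)])
    list(statistic = W, p = min(p, 1), n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (direction == "greater") (W - mu - 0.5) / sqrt(sig2)
         else (W - mu + 0.5) / sqrt(sig2)
    p <- if (direction == "greater") pnorm(z, lower.tail = FALSE)
         else pnorm(z)
    list(statistic = W, p = p, n = n, exact = FALSE)
  }
}

#' Probe-level change call between two samples
#'
#' MAS5-comparison style: a one-sided signed-rank test on paired probe log2
#' differences in each direction.  Increase if p(greater) < alpha, Decrease
#' if p(less) < alpha, otherwise NoChange.  The reported log2 ratio is the
#' difference of the summarized (mean floored log2) values.
#'
#' @param probesA,probesB linear probe intensities of the same probe set in
#'   the reference (A) and test (B) sample.
#' @param thresholds from [changeThresholds()].
#' @return list with `call` ("I"/"D"/"NC"), `p` (smaller one-sided p, NA when
#'   no usable pairs), `log2Ratio`, and `flagged` (< 3 usable probe pairs).
#' @export
changeCall <- function(probesA, probesB, thresholds = changeThresholds()) {
  if (length(probesA) != length(probesB))
    stop("probe sets differ in length")
  la <- .floorLog2(probesA, thresholds$floor)
  lb <- .floorLog2(probesB, thresholds$floor)
  d <- lb - la
  lr <- mean(lb) - mean(la)
  usable <- sum(d != 0, na.rm = TRUE)
  if (usable < 3)
    return(list(call = "NC", p = NA_real_, log2Ratio = lr, flagged = TRUE))
  tg <- signedRankTest(d, "greater")
  tl <- signedRankTest(d, "less")
  call <- if (tg$p < thresholds$alpha) "I"
          else if (tl$p < thresholds$alpha) "D" else "NC"
  list(call = call, p = min(tg$p, tl$p), log2Ratio = lr, flagged = FALSE)
}

#' Collapse replicate change calls into one consistent call
#'
#' Increase (or Decrease) only if every replicate comparison agrees; any
#' disagreement or NoChange yields NoChange.
#'
#' @param calls character vector of per-replicate calls ("I"/"D"/"NC").
#' @return "I", "D" or "NC".
#' @export
consistentCall <- function(calls) {
  if (length(calls) == 0) stop("no change calls supplied")
  if (all(calls == "I")) "I" else if (all(calls == "D")) "D" else "NC"
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; NA p-values propagate as NA and are excluded from
#' the number of tests.
#'
#' @param pvals numeric p-values in [0,1] (NA allowed).
#' @return adjusted p-values in input order.
#' @export
bhFdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  p.adjust(pvals, method = "BH")
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over all-nonzero genes of the ratio of the count to
#' the gene's geometric mean across samples.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of size factors.
#' @export
sizeFactorsMor <- function(counts) {
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop("no gene has nonzero counts in all samples; ",
         "consider a pseudo-reference sample")
  lg <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2, function(x) exp(median(x - ref)))
}

# conditioned NB exact test for one gene: probability of splits of the total
# as or less likely than the observed one, given group means and dispersion
.nbExactP <- function(kA, kB, muA, muB, sizeA, sizeB) {
  S <- kA + kB
  if (S == 0) return(1)
  a <- 0:S
  lpa <- if (is.finite(sizeA)) dnbinom(a, mu = muA, size = sizeA, log = TRUE)
         else dpois(a, muA, log = TRUE)
  lpb <- if (is.finite(sizeB)) dnbinom(S - a, mu = muB, size = sizeB,
                                       log = TRUE)
         else dpois(S - a, muB, log = TRUE)
  lj <- lpa + lpb
  m <- max(lj)
  pj <- exp(lj - m)
  obs <- pj[kA + 1]
  sum(pj[pj <= obs * (1 + 1e-8)]) / sum(pj)
}

#' Negative-binomial exact test for differential expression
#'
#' A compact reimplementation of the classical count-based DE test:
#' median-of-ratios normalization, per-gene method-of-moments dispersion
#' raised to a log-linear mean-dispersion trend (dispersion used =
#' max(gene estimate, trend value)), and a two-sided conditioned NB exact
#' test on the split of the per-group count totals.
#'
#' @param counts genes x samples integer matrix.
#' @param groups character/factor of length ncol(counts) with exactly two
#'   levels; the first level is the reference (control).
#' @param thresholds from [changeThresholds()]; `deFdr` sets the reported
#'   direction calls.
#' @return data.frame with columns gene_id, base_mean, log2_fc, p, padj,
#'   direction ("decreased"/"increased"/"ns"); log2_fc is treated minus
#'   control on normalized means with a 0.5 pseudocount.
#' @export
nbDeTest <- function(counts, groups, thresholds = changeThresholds()) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("groups must have exactly two levels")
  if (any(table(groups) < 2)) stop("need >= 2 replicates per group")
  sf <- sizeFactorsMor(counts)
  norm <- sweep(counts, 2, sf, "/")
  baseMean <- rowMeans(norm)
  gA <- groups == levels(groups)[1]

  # method-of-moments dispersion: pooled within-group variance minus the
  # normalization-scaled shot-noise term
  xi <- mean(1 / sf)
  dfs <- table(groups) - 1
  w <- (apply(norm[, gA, drop = FALSE], 1, var) * dfs[1] +
        apply(norm[, !gA, drop = FALSE], 1, var) * dfs[2]) / sum(dfs)
  dispRaw <- (w - baseMean * xi) / baseMean^2   # may be negative
  dispMoM <- pmax(dispRaw, 1e-8)
  dispUse <- dispMoM
  # log-linear trend fit on bin-aggregated raw-scale dispersion means:
  # per-gene MoM estimates from few replicates are noisy and right-skewed,
  # so least squares on their logs underestimates the typical dispersion
  fitIdx <- which(baseMean > 0)
  if (length(fitIdx) >= 50) {
    lm0 <- log(baseMean[fitIdx])
    bins <- cut(lm0, breaks = 20)
    bMean <- tapply(baseMean[fitIdx], bins, mean)
    bDisp <- pmax(tapply(dispRaw[fitIdx], bins, mean), 1e-8)
    okb <- !is.na(bMean) & tapply(lm0, bins, length) >= 10
    if (sum(okb, na.rm = TRUE) >= 3) {
      fit <- lm(log(bDisp[okb]) ~ log(bMean[okb]))
      trend <- exp(coef(fit)[1] + coef(fit)[2] * log(pmax(baseMean, 1e-8)))
      dispUse <- pmax(dispMoM, trend)
    }
  }

  sA <- sum(sf[gA]); sB <- sum(sf[!gA])
  ssqA <- sum(sf[gA]^2); ssqB <- sum(sf[!gA]^2)
  kA <- rowSums(counts[, gA, drop = FALSE])
  kB <- rowSums(counts[, !gA, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(i) {
    q <- baseMean[i]
    if (q == 0) return(1)
    d <- dispUse[i]
    szA <- if (d < 1e-10) Inf else sA^2 / (d * ssqA)
    szB <- if (d < 1e-10) Inf else sB^2 / (d * ssqB)
    .nbExactP(kA[i], kB[i], q * sA, q * sB, szA, szB)
  }, numeric(1))
  padj <- bhFdr(p)
  mA <- kA / sA; mB <- kB / sB
  log2fc <- log2((mB + 0.5) / (mA + 0.5))
  direction <- ifelse(padj <= thresholds$deFdr & log2fc < 0, "decreased",
               ifelse(padj <= thresholds$deFdr & log2fc > 0, "increased",
                      "ns"))
  data.frame(gene_id = rownames(counts), base_mean = baseMean,
             log2_fc = log2fc, p = p, padj = padj, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided signed-rank test of a gene set's log2 fold changes against zero
#'
#' Used to ask whether a whole set of transcripts shifts coherently under a
#' treatment (e.g. whether TFI transcripts move under triple knockdown).
#'
#' @param ratios per-gene log2 fold changes of the set.
#' @return list with `statistic`, `p` (two-sided), `n`.  Sets smaller than 5
#'   carry a power floor (minimum attainable two-sided p of 2/2^n) and are
#'   flagged with a warning.
#' @export
groupShiftTest <- function(ratios) {
  if (length(ratios) == 0) stop("empty gene set")
  if (length(ratios) < 5)
    warning("set size < 5: minimum attainable two-sided p is ",
            signif(2 / 2^length(ratios), 3))
  tg <- signedRankTest(ratios, "greater")
  tl <- signedRankTest(ratios, "less")
  if (is.na(tg$p))
    return(list(statistic = NA_real_, p = NA_real_, n = 0L))
  list(statistic = tg$statistic, p = min(1, 2 * min(tg$p, tl$p)), n = tg$n)
}
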