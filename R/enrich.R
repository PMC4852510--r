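#' Upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' k members of a K-sized term when sampling n items from a universe of N
#' without replacement.  Computed in log space via [stats::phyper].
#'
#' @param N universe size.
#' @param K term (annotated set) size.
#' @param n query (drawn set) size.
#' @param k observed overlap.
#' @return p-value in (0, 1]; k <= 0 gives exactly 1.
#' @examples
#' hypergeomTail(10, 5, 5, 5)  # 1 / choose(10, 5)
#' @export
hypergeomTail <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, K <= N, n <= N)
  if (k > min(K, n)) stop("overlap k exceeds min(K, n)")
  if (k <= 0) return(1)
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Fold enrichment (observed over expected overlap)
#'
#' @inheritParams hypergeomTail
#' @return k * N / (n * K); 0 when k = 0.
#' @examples
#' round(foldEnrichment(15491, 205, 466, 12), 1)  # 1.9
#' @export
foldEnrichment <- function(N, K, n, k) {
  stopifnot(N > 0, K > 0, n > 0, k >= 0)
  k * N / (n * K)
}

#' Spatially localized transcript sets from dissection expression ratios
#'
#' Animal/vegetal and dorsal/ventral log2 ratios are thresholded strictly
#' above the localization gate in each direction.
#'
#' @param expr data.frame or matrix with per-transcript log2 expression
#'   columns `animal`, `vegetal`, `dorsal`, `ventral`; rownames (or a
#'   `transcript_id` column) identify transcripts.
#' @param lfc localization gate, log2 units (default 1.5); membership
#'   requires a ratio strictly greater than the gate.
#' @return named list of four character vectors: `animal`, `vegetal`,
#'   `dorsal`, `ventral`.
#' @export
localizedSets <- function(expr, lfc = 1.5) {
  stopifnot(lfc > 0)
  if (is.data.frame(expr) && "transcript_id" %in% colnames(expr)) {
    rownames(expr) <- expr$transcript_id
  }
  need <- c("animal", "vegetal", "dorsal", "ventral")
  miss <- setdiff(need, colnames(expr))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  ids <- rownames(expr)
  av <- expr[, "animal"] - expr[, "vegetal"]
  dv <- expr[, "dorsal"] - expr[, "ventral"]
  list(animal = ids[av > lfc], vegetal = ids[-av > lfc],
       dorsal = ids[dv > lfc], ventral = ids[-dv > lfc])
}

#' Over-representation of a query set in an annotated term set
#'
#' Both sets are restricted to the universe before sizing; fold and p-value
#' depend only on (N, K, n, k).
#'
#' @param universe character vector: the measured background.
#' @param termSet character vector: the annotated set (e.g. genes bound by a
#'   TF, or a GO term's genes).
#' @param querySet character vector: the set under test.
#' @return one-row data.frame with N, K, n, k, fold, p.
#' @export
setOverrepresentation <- function(universe, termSet, querySet) {
  if (length(universe) == 0) stop("empty universe")
  term <- intersect(termSet, universe)
  query <- intersect(querySet, universe)
  N <- length(unique(universe)); K <- length(unique(term))
  n <- length(unique(query)); k <- length(intersect(term, query))
  fold <- if (K == 0 || n == 0) NA_real_ else foldEnrichment(N, K, n, k)
  p <- if (K == 0 || n == 0) 1 else hypergeomTail(N, K, n, k)
  data.frame(N = N, K = K, n = n, k = k, fold = fold, p = p)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: term id, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors with a `description` attribute.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  out <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(out) <- vapply(parts, `[`, character(1), 1)
  attr(out, "description") <- vapply(parts, `[`, character(1), 2)
  out
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description per-term descriptions (default the term names).
#' @export
writeGmt <- function(sets, path, description = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Term over-representation with size, FDR and fold filters
#'
#' Every term is intersected with the universe, tested by the upper-tail
#' hypergeometric, and BH-adjusted across all tested terms; only terms with
#' at least `minTerm` universe members, adjusted p at most `maxFdr` and fold
#' enrichment at least `minFold` are reported, sorted by p.
#'
#' @param gene2term named list term -> member genes (e.g. from [readGmt()]).
#' @param query character vector under test.
#' @param universe character vector background (must be non-empty).
#' @param minTerm minimum in-universe term size (default 10).
#' @param maxFdr BH FDR cap (default 0.05).
#' @param minFold minimum fold enrichment (default 4).
#' @return data.frame with term_id, N, K, n, k, fold, p, padj for passing
#'   terms, ordered by p.
#' @export
termEnrichment <- function(gene2term, query, universe, minTerm = 10,
                           maxFdr = 0.05, minFold = 4) {
  if (length(universe) == 0) stop("empty universe")
  rows <- lapply(names(gene2term), function(tid) {
    r <- setOverrepresentation(universe, gene2term[[tid]], query)
    cbind(term_id = tid, r, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- bhFdr(res$p)
  keep <- res$K >= minTerm & res$padj <= maxFdr &
    !is.na(res$fold) & res$fold >= minFold
  res <- res[keep, , drop = FALSE]
  res[order(res$p), , drop = FALSE]
}
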