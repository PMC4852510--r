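#' Write genomic intervals as 6-column BED
#'
#' 0-based half-open on disk; GRanges coordinates (1-based closed) are
#' converted by \pkg{rtracklayer}.
#'
#' @param gr GRanges; a `name` or `gene_id` metadata column supplies BED
#'   names, `score` the score column.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  if (is.null(gr$name)) {
    gr$name <- if (!is.null(gr$gene_id)) gr$gene_id
               else sprintf("iv%06d", seq_along(gr))
  }
  if (is.null(gr$score)) gr$score <- 0L
  rtracklayer::export(gr[, c("name", "score")], path, format = "BED")
}

#' Read a BED file into GRanges (1-based closed in memory)
#' @param path BED path.
#' @return GRanges with `name`/`score` metadata when present.
#' @export
readBed <- function(path) rtracklayer::import(path, format = "BED")

#' Write a matrix or data.frame as TSV with a header row
#' @param x matrix/data.frame.
#' @param path output path.
#' @param rowLabel when `x` has rownames, the header of the leading id
#'   column (default "id"); NULL drops rownames.
#' @export
writeTsv <- function(x, path, rowLabel = "id") {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.null(rowLabel) && !is.null(rownames(x)) &&
      !identical(rownames(x), as.character(seq_len(nrow(df))))) {
    df <- cbind(setNames(data.frame(rownames(x), stringsAsFactors = FALSE),
                         rowLabel), df)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV written by [writeTsv()]
#' @param path TSV path.
#' @param rowLabel id column to move into rownames (NULL to keep as column).
#' @return data.frame.
#' @export
readTsv <- function(path, rowLabel = "id") {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(rowLabel) && rowLabel %in% colnames(df)) {
    rownames(df) <- df[[rowLabel]]
    df[[rowLabel]] <- NULL
  }
  df
}

#' Export a binding network as JSON
#'
#' Nodes, directed edges and per-gene bound-TF combinations, written with
#' stable ordering so a fixed seed reproduces identical bytes.
#'
#' @param network a [BindingNetwork-class].
#' @param path output path.
#' @export
writeNetworkJson <- function(network, path) {
  bt <- boundTfs(network)
  obj <- list(
    tfs = tfNames(network),
    genes = network@genes,
    edges = networkEdges(network),
    combinations = vapply(bt, paste, character(1), collapse = "+"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
}
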