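#' Read and write pipeline TSV files
#'
#' Plain tab-separated formats used throughout the pipeline. Protein
#' matrices are written with proteins as rows, a header row of column ids,
#' and the processing stage recorded in a leading comment line
#' (\code{# stage: ...}); fragment tables and metadata use the long-format
#' headers produced by [generate_cohort()].
#'
#' @param matrix a [protein_matrix()].
#' @param path file path.
#' @return the written path (writers, invisibly) or the parsed object
#'   (readers).
#' @name swathdia-io
NULL

#' @rdname swathdia-io
#' @export
write_protein_matrix <- function(matrix, path) {
  if (!inherits(matrix, "protein_matrix"))
    stop("'matrix' must be a protein_matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s", matrix$stage), con)
  d <- data.frame(protein_id = rownames(matrix$values),
                  matrix$values, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname swathdia-io
#' @export
read_protein_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  stage <- sub("^#\\s*stage:\\s*", "", first)
  if (identical(stage, first))
    stop("missing '# stage:' header line in ", path)
  d <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  values <- as.matrix(d[, -1L, drop = FALSE])
  rownames(values) <- d[[1L]]
  protein_matrix(values, stage = stage)
}

#' @rdname swathdia-io
#' @export
read_fragment_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "peptide_id", "fragment_id", "run_id",
            "intensity")
  if (!all(need %in% names(d)))
    stop("fragment table must have columns ", paste(need, collapse = ", "))
  d
}

#' @rdname swathdia-io
#' @export
read_metadata <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
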