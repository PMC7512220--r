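#' Protein intensity matrix
#'
#' Container for a protein x run (or protein x sample) intensity matrix
#' together with its processing stage. Stages move strictly forward:
#' \code{raw} (one column per run, straight from fragment rollup) ->
#' \code{normalized} (total-sum normalized runs) -> \code{averaged}
#' (technical replicates collapsed, one column per sample).
#'
#' @param values numeric matrix, proteins as rows (rownames = protein ids),
#'   runs or samples as columns (colnames = run/sample ids). All values must
#'   be non-negative and finite.
#' @param stage one of \code{"raw"}, \code{"normalized"}, \code{"averaged"}.
#'
#' @return an object of class \code{protein_matrix}: a list with elements
#'   \code{values} and \code{stage}.
#' @export
protein_matrix <- function(values, stage = c("raw", "normalized", "averaged")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein rownames and run/sample colnames")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' must be finite and non-missing")
  if (any(values < 0))
    stop("protein intensities must be non-negative")
  structure(list(values = values, stage = stage), class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix [%s]: %d proteins x %d %s\n",
              x$stage, nrow(x$values), ncol(x$values),
              if (x$stage == "averaged") "samples" else "runs"))
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

.assert_stage <- function(m, stage, arg = "matrix") {
  if (!inherits(m, "protein_matrix"))
    stop(sprintf("'%s' must be a protein_matrix", arg))
  if (!identical(m$stage, stage))
    stop(sprintf("'%s' must have stage '%s' (got '%s')", arg, stage, m$stage))
  invisible(m)
}
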