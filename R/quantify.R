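#' Roll fragment-ion intensities up to protein intensities
#'
#' Implements the extraction-style quantification rule: for each protein,
#' the strongest peptides are selected (default 10), and within each selected
#' peptide the strongest fragment ions (default 6); the protein intensity in
#' a run is the sum of the selected fragments' peak intensities in that run.
#'
#' "Strongest" is defined on the cross-run summed intensity, computed once
#' per protein, so the identical feature set quantifies every run and the
#' resulting columns are comparable. Ties in strength are broken by
#' lexicographic feature identifier for determinism. Fragments missing from
#' a run contribute zero (absence of a peak is zero measured intensity); a
#' protein with no observed selected fragment in some run gets value 0 and a
#' summary warning is raised.
#'
#' @param fragments data.frame with columns \code{protein_id},
#'   \code{peptide_id}, \code{fragment_id}, \code{run_id}, \code{intensity}.
#' @param runs data.frame with columns \code{run_id}, \code{sample_id},
#'   \code{replicate_index}; every \code{run_id} in \code{fragments} must
#'   appear here.
#' @param top_peptides,top_fragments selection depths.
#' @return a [protein_matrix()] with stage \code{"raw"}, one column per run.
#' @export
rollup_protein_intensity <- function(fragments, runs, top_peptides = 10L,
                                     top_fragments = 6L) {
  need <- c("protein_id", "peptide_id", "fragment_id", "run_id", "intensity")
  if (!all(need %in% names(fragments)))
    stop("'fragments' must have columns ",
         paste(need, collapse = ", "))
  if (nrow(fragments) == 0L) stop("'fragments' is empty")
  if (top_peptides < 1L || top_fragments < 1L)
    stop("'top_peptides' and 'top_fragments' must be >= 1")
  bad <- setdiff(unique(fragments$run_id), runs$run_id)
  if (length(bad) > 0L)
    stop("fragment table references unknown run_id(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (any(fragments$intensity < 0))
    stop("fragment intensities must be non-negative")

  dt <- data.table::as.data.table(fragments)
  ## cross-run strength per fragment, then per peptide (sum of all its
  ## fragments across all runs)
  fstr <- dt[, list(frag_strength = sum(intensity)),
             by = c("protein_id", "peptide_id", "fragment_id")]
  pstr <- fstr[, list(pep_strength = sum(frag_strength)),
               by = c("protein_id", "peptide_id")]
  ## rank peptides within protein: strength desc, id asc for ties
  data.table::setorderv(pstr, c("protein_id", "pep_strength", "peptide_id"),
                        order = c(1L, -1L, 1L))
  pstr[, pep_rank := seq_len(.N), by = "protein_id"]
  keep_pep <- pstr[pep_rank <= top_peptides,
                   c("protein_id", "peptide_id"), with = FALSE]
  fsel <- fstr[keep_pep, on = c("protein_id", "peptide_id")]
  data.table::setorderv(fsel,
                        c("protein_id", "peptide_id", "frag_strength",
                          "fragment_id"),
                        order = c(1L, 1L, -1L, 1L))
  fsel[, frag_rank := seq_len(.N), by = c("protein_id", "peptide_id")]
  fsel <- fsel[frag_rank <= top_fragments]

  sel <- dt[fsel[, c("protein_id", "peptide_id", "fragment_id"),
                 with = FALSE],
            on = c("protein_id", "peptide_id", "fragment_id")]
  agg <- sel[, list(intensity = sum(intensity)),
             by = c("protein_id", "run_id")]

  prot_ids <- sort(unique(dt$protein_id))
  run_ids <- runs$run_id
  values <- matrix(0, nrow = length(prot_ids), ncol = length(run_ids),
                   dimnames = list(prot_ids, run_ids))
  values[cbind(match(agg$protein_id, prot_ids),
               match(agg$run_id, run_ids))] <- agg$intensity
  n_zero <- sum(values == 0)
  if (n_zero > 0L)
    warning(sprintf(
      "%d protein x run cell(s) had no observed selected fragment; set to 0",
      n_zero), call. = FALSE)
  protein_matrix(values, stage = "raw")
}

#' Total-sum normalize a raw protein matrix
#'
#' Global normalization on the total sum of peak intensities: every run
#' (column) is rescaled so all column totals are equal. The common target is
#' the mean of the original column totals, which keeps values on the
#' original intensity scale; within-column ratios are preserved exactly.
#'
#' @param matrix a [protein_matrix()] with stage \code{"raw"}.
#' @return a [protein_matrix()] with stage \code{"normalized"}.
#' @export
total_sum_normalize <- function(matrix) {
  .assert_stage(matrix, "raw")
  totals <- colSums(matrix$values)
  zero <- totals <= 0
  if (any(zero))
    stop("degenerate run(s) with zero total intensity: ",
         paste(colnames(matrix$values)[zero], collapse = ", "))
  target <- mean(totals)
  scaled <- sweep(matrix$values, 2L, target / totals, `*`)
  protein_matrix(scaled, stage = "normalized")
}

#' Average technical replicates into per-sample intensities
#'
#' Collapses replicate runs of each sample by the arithmetic mean, producing
#' one column per sample. Run from the normalized matrix, this is the input
#' to the statistical stages.
#'
#' @param matrix a [protein_matrix()] with stage \code{"normalized"}.
#' @param runs run metadata mapping \code{run_id} to \code{sample_id}.
#' @return a [protein_matrix()] with stage \code{"averaged"}, columns in
#'   first-appearance order of samples in \code{runs}.
#' @export
average_replicates <- function(matrix, runs) {
  .assert_stage(matrix, "normalized")
  run_ids <- colnames(matrix$values)
  missing_runs <- setdiff(run_ids, runs$run_id)
  if (length(missing_runs) > 0L)
    stop("matrix columns missing from run metadata: ",
         paste(missing_runs, collapse = ", "))
  sample_of <- runs$sample_id[match(run_ids, runs$run_id)]
  sample_ids <- unique(runs$sample_id)
  lost <- setdiff(sample_ids, sample_of)
  if (length(lost) > 0L)
    stop("sample(s) with zero runs in the matrix: ",
         paste(lost, collapse = ", "))
  values <- vapply(sample_ids, function(s)
    rowMeans(matrix$values[, sample_of == s, drop = FALSE]),
    numeric(nrow(matrix$values)))
  dimnames(values) <- list(rownames(matrix$values), sample_ids)
  protein_matrix(values, stage = "averaged")
}

#' Quantify a fragment table end to end
#'
#' Convenience composition of [rollup_protein_intensity()],
#' [total_sum_normalize()] and [average_replicates()].
#'
#' @inheritParams rollup_protein_intensity
#' @return a list with the \code{raw}, \code{normalized} and \code{averaged}
#'   [protein_matrix()] objects.
#' @export
quantify_cohort <- function(fragments, runs, top_peptides = 10L,
                            top_fragments = 6L) {
  raw <- rollup_protein_intensity(fragments, runs, top_peptides,
                                  top_fragments)
  normalized <- total_sum_normalize(raw)
  averaged <- average_replicates(normalized, runs)
  list(raw = raw, normalized = normalized, averaged = averaged)
}
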