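#' Size-matched random-panel specificity test of an annotated protein set
#'
#' Asks whether a designated protein panel (for example, all
#' mitochondrion-annotated proteins among the quantified set) predicts
#' case/control membership better than random panels of the same size. The
#' panel's LOOCV error count under the principal-component logistic
#' classifier is compared to the errors of \code{n_draws} panels of equal
#' size sampled uniformly without replacement from the remaining
#' (non-flagged) proteins; drawing from all proteins instead is available
#' behind \code{draw_from = "all"} for sensitivity.
#'
#' The comparison statistic is the LOOCV error count (the classifier's
#' reported performance measure); the mean held-out log-loss is reported
#' alongside as a tie-aware secondary statistic. The one-sided empirical p
#' is the add-one-smoothed fraction of random panels doing as well or
#' better: \code{(1 + #\{random_error <= subset_error\}) / (n_draws + 1)}.
#'
#' @param matrix a [protein_matrix()] with stage \code{"averaged"}.
#' @param samples sample metadata (\code{sample_id}, \code{group}).
#' @param annotations data.frame with column \code{protein_id} and one or
#'   more 0/1 (or logical) flag columns; protein ids must be a subset of
#'   the matrix's proteins.
#' @param flag_name name of the flag column defining the panel.
#' @param k_components,pca_policy,lambda classifier settings, as in
#'   [pc_logistic_loocv()].
#' @param n_draws number of random panels (default 500).
#' @param seed integer seed driving the draws.
#' @param draw_from \code{"nonflagged"} (default; "other" proteins only) or
#'   \code{"all"}.
#' @return object of class \code{subset_test_result}: list with
#'   \code{subset_size}, \code{subset_error}, \code{subset_logloss},
#'   \code{random_errors}, \code{random_logloss}, \code{n_draws},
#'   \code{empirical_p}, \code{seed}.
#' @export
run_subset_test <- function(matrix, samples, annotations, flag_name,
                            k_components = 3L,
                            pca_policy = c("refit_per_fold", "global"),
                            lambda = 1e-3, n_draws = 500L, seed = 1L,
                            draw_from = c("nonflagged", "all")) {
  .assert_stage(matrix, "averaged")
  pca_policy <- match.arg(pca_policy)
  draw_from <- match.arg(draw_from)
  if (n_draws < 1L) stop("'n_draws' must be >= 1")
  if (!flag_name %in% names(annotations))
    stop(sprintf("annotation flag '%s' not found", flag_name))
  prot <- rownames(matrix$values)
  unknown <- setdiff(annotations$protein_id, prot)
  if (length(unknown) > 0L)
    stop("annotation table references unquantified protein(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  flag <- as.logical(annotations[[flag_name]])
  flagged <- annotations$protein_id[flag]
  if (length(flagged) == 0L)
    stop(sprintf("flagged set '%s' is empty", flag_name))
  if (length(flagged) >= length(prot))
    stop("flagged set must be smaller than the quantified protein set")
  pool <- if (draw_from == "nonflagged") setdiff(prot, flagged) else prot
  m <- length(flagged)
  if (m > length(pool))
    stop(sprintf(
      "subset size %d exceeds the %d protein(s) available to draw from",
      m, length(pool)))

  grp <- samples$group[match(colnames(matrix$values), samples$sample_id)]
  y <- as.integer(grp == "case")
  run_panel <- function(ids) {
    vals <- matrix$values[ids, , drop = FALSE]
    cache <- .loocv_precompute(vals, k_components, pca_policy)
    fit <- .loocv_from_cache(cache, y, lambda = lambda)
    eps <- 1e-12
    ll <- -mean(y * log(pmax(fit$probs, eps)) +
                (1 - y) * log(pmax(1 - fit$probs, eps)))
    c(error = fit$error_count, logloss = ll)
  }
  subset_fit <- run_panel(flagged)
  draws <- .with_seed(seed, lapply(seq_len(n_draws), function(b)
    sample(pool, m)))
  random_fits <- vapply(draws, run_panel, numeric(2L))
  empirical_p <- (1 + sum(random_fits["error", ] <= subset_fit["error"])) /
    (n_draws + 1)
  structure(list(
    subset_size = m, subset_error = unname(subset_fit["error"]),
    subset_logloss = unname(subset_fit["logloss"]),
    random_errors = unname(random_fits["error", ]),
    random_logloss = unname(random_fits["logloss", ]),
    n_draws = as.integer(n_draws), empirical_p = empirical_p,
    seed = as.integer(seed)), class = "subset_test_result")
}

#' @export
print.subset_test_result <- function(x, ...) {
  cat(sprintf(
    "subset_test_result: panel of %d proteins, LOOCV error %d vs random mean %.2f (n_draws = %d), empirical p = %.4g\n",
    x$subset_size, x$subset_error, mean(x$random_errors), x$n_draws,
    x$empirical_p))
  invisible(x)
}
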