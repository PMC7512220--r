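#' Per-protein two-sample Student t-test
#'
#' Two-sided pooled-variance Student t-test of case versus control for every
#' protein of a replicate-averaged matrix. By default the test statistic is
#' computed on log10-transformed intensities (MS intensities are
#' approximately log-normal and the companion fold-change is defined in
#' log10 units); the untransformed-scale variant is available via
#' \code{log_transform = FALSE}, and Welch's unequal-variance form via
#' \code{var_equal = FALSE}, for sensitivity checks.
#'
#' The reported \code{log10_fc} is always \code{log10(mean_case /
#' mean_control)} of the (linear-scale) averaged intensities, regardless of
#' the test scale. Benjamini-Hochberg q-values are attached as an
#' informational column; the primary filtering path uses raw p-values.
#'
#' @param matrix a [protein_matrix()] with stage \code{"averaged"}.
#' @param samples data.frame with columns \code{sample_id} and \code{group}
#'   (\code{"case"} / \code{"control"}); at least 2 samples per group.
#' @param log_transform test on log10 intensities (default TRUE).
#' @param var_equal pooled-variance Student t (default TRUE) or Welch.
#' @return data.frame with columns \code{protein_id}, \code{p_value},
#'   \code{log10_fc}, \code{fold_change}, \code{direction} (all
#'   \code{"unchanged"} until a filter is applied) and \code{q_value}.
#' @export
t_test_protein <- function(matrix, samples, log_transform = TRUE,
                           var_equal = TRUE) {
  .assert_stage(matrix, "averaged")
  cols <- colnames(matrix$values)
  grp <- samples$group[match(cols, samples$sample_id)]
  if (anyNA(grp))
    stop("sample metadata missing for column(s): ",
         paste(cols[is.na(grp)], collapse = ", "))
  if (!all(grp %in% c("case", "control")))
    stop("'group' must be 'case' or 'control'")
  n1 <- sum(grp == "case"); n2 <- sum(grp == "control")
  if (n1 < 2L || n2 < 2L)
    stop("need at least 2 samples per group for a t-test")

  vals <- matrix$values
  mean_case <- rowMeans(vals[, grp == "case", drop = FALSE])
  mean_ctrl <- rowMeans(vals[, grp == "control", drop = FALSE])
  if (any(mean_case <= 0) || any(mean_ctrl <= 0))
    stop("undefined fold-change: non-positive group mean for protein(s): ",
         paste(utils::head(
           rownames(vals)[mean_case <= 0 | mean_ctrl <= 0], 5L),
           collapse = ", "))
  lfc <- log10(mean_case / mean_ctrl)

  x <- if (log_transform) {
    if (any(vals <= 0))
      stop("log-scale test requires strictly positive intensities")
    log10(vals)
  } else vals
  x1 <- x[, grp == "case", drop = FALSE]
  x2 <- x[, grp == "control", drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2L, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  ## degenerate: no variance in either group and equal means
  flat <- se == 0
  p[flat & (m1 == m2)] <- 1
  lfc[flat & (m1 == m2)] <- 0
  if (any(flat & (m1 != m2)))
    p[flat & (m1 != m2)] <- 0  # infinite t: means differ with zero variance

  data.frame(protein_id = rownames(vals), p_value = p, log10_fc = lfc,
             fold_change = 10^lfc,
             direction = rep("unchanged", length(p)),
             q_value = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential-abundance filter specification
#'
#' The threshold grammar used for reporting differential proteins. Exactly
#' one of the two effect gates is active: either a symmetric log10
#' fold-change gate (\code{lfc_min_abs}; retain when \code{log10_fc >
#' lfc_min_abs} or \code{< -lfc_min_abs}) or explicit fold-change bounds
#' (\code{fc_bounds = c(upper_gate, lower_gate)}; retain when
#' \code{fold_change > upper_gate} or \code{< lower_gate}). All inequalities
#' are strict.
#'
#' [primary_filter()] is the stringent default (p < 0.01, |log10FC| > 0.2);
#' [relaxed_filter()] is the wider panel filter (p < 0.05, FC > 1.3 or
#' < 0.75).
#'
#' @param p_max p-value gate (retain p < p_max).
#' @param lfc_min_abs symmetric |log10 fold-change| gate, or NULL.
#' @param fc_bounds length-2 \code{c(upper_gate, lower_gate)}, or NULL.
#' @return an object of class \code{filter_spec}.
#' @export
filter_spec <- function(p_max, lfc_min_abs = NULL, fc_bounds = NULL) {
  if (is.null(lfc_min_abs) == is.null(fc_bounds))
    stop("exactly one of 'lfc_min_abs' and 'fc_bounds' must be given")
  if (length(p_max) != 1L || p_max <= 0 || p_max > 1)
    stop("'p_max' must be a probability in (0, 1]")
  if (!is.null(lfc_min_abs) &&
      (length(lfc_min_abs) != 1L || lfc_min_abs < 0))
    stop("'lfc_min_abs' must be a single non-negative number")
  if (!is.null(fc_bounds) &&
      (length(fc_bounds) != 2L || fc_bounds[1L] <= fc_bounds[2L]))
    stop("'fc_bounds' must be c(upper_gate, lower_gate) with upper > lower")
  structure(list(p_max = p_max, lfc_min_abs = lfc_min_abs,
                 fc_bounds = fc_bounds), class = "filter_spec")
}

#' @rdname filter_spec
#' @export
primary_filter <- function() filter_spec(p_max = 0.01, lfc_min_abs = 0.2)

#' @rdname filter_spec
#' @export
relaxed_filter <- function() filter_spec(p_max = 0.05,
                                         fc_bounds = c(1.3, 0.75))

#' Apply a differential-abundance filter
#'
#' Retains the records passing a [filter_spec()] and sets their
#' \code{direction} to \code{"increased"} or \code{"decreased"} by the sign
#' of the effect. The filter is idempotent.
#'
#' Published tables print effect sizes rounded (typically to 2 decimals), so
#' a value printed exactly at a gate may have passed it before rounding.
#' When filtering such transcriptions, set \code{rounding} to the printed
#' quantum (e.g. 0.01): each strict comparison then receives half-quantum
#' slack on the effect columns. Computed (unrounded) values use the default
#' \code{rounding = 0}, i.e. the strict grammar.
#'
#' @param records data.frame as returned by [t_test_protein()] (columns
#'   \code{p_value} and \code{log10_fc} and/or \code{fold_change}).
#' @param spec a [filter_spec()].
#' @param rounding printed quantum of the effect columns (default 0).
#' @return the retained rows with \code{direction} set.
#' @export
apply_filter <- function(records, spec, rounding = 0) {
  if (!inherits(spec, "filter_spec"))
    stop("'spec' must be a filter_spec")
  if (!all(is.finite(records$p_value)))
    stop("records must have finite p-values")
  eps <- rounding / 2
  pass_p <- records$p_value < spec$p_max
  if (!is.null(spec$lfc_min_abs)) {
    eff <- records$log10_fc
    up <- eff > spec$lfc_min_abs - eps
    down <- eff < -spec$lfc_min_abs + eps
  } else {
    eff <- records$fold_change
    up <- eff > spec$fc_bounds[1L] - eps
    down <- eff < spec$fc_bounds[2L] + eps
  }
  keep <- pass_p & (up | down)
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(up[keep], "increased", "decreased")
  rownames(out) <- NULL
  out
}

#' Round a differential table for reporting
#'
#' Formats a differential result the way published tables print it:
#' p-values to 2 significant figures, log10 fold-changes and fold-changes to
#' 2 decimals.
#'
#' @param records data.frame from [t_test_protein()] / [apply_filter()].
#' @return the data.frame with rounded numeric columns.
#' @export
format_differential <- function(records) {
  records$p_value <- signif(records$p_value, 2L)
  records$log10_fc <- round(records$log10_fc, 2L)
  records$fold_change <- round(records$fold_change, 2L)
  if ("q_value" %in% names(records))
    records$q_value <- signif(records$q_value, 2L)
  records
}
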