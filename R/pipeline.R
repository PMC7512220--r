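#' Pipeline configuration
#'
#' Central configuration for [run_pipeline()]. Every consumed parameter
#' defaults to the pipeline's canonical analysis value: primary filter
#' p < 0.01 with |log10FC| > 0.2, relaxed panel filter p < 0.05 with FC
#' > 1.3 or < 0.75, k = 3 principal components for the classifier,
#' technical triplicates in the simulated cohort. Unknown keys are
#' rejected by name. The effective configuration is echoed into the run
#' manifest.
#'
#' @param ... named overrides of the defaults; see Details.
#'
#' @details Recognized keys: \code{cohort} (list of [cohort_config()]
#'   overrides for the simulated input), \code{input_dir} (read
#'   \code{fragments.tsv}, \code{runs.tsv}, \code{samples.tsv} from a
#'   directory instead of simulating), \code{top_peptides},
#'   \code{top_fragments}, \code{primary_p_max}, \code{primary_lfc_min},
#'   \code{relaxed_p_max}, \code{relaxed_fc_bounds}, \code{k_components},
#'   \code{pca_policy}, \code{lambda}, \code{subgroup_components},
#'   \code{run_permutation}, \code{n_permutations},
#'   \code{permutation_seed}, \code{run_subset_test}, \code{annotations}
#'   (data.frame; or \code{"planted"} to flag the generator's planted
#'   proteins), \code{annotation_flag}, \code{n_draws}, \code{subset_seed}.
#' @return a validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    cohort = list(), input_dir = NULL,
    top_peptides = 10L, top_fragments = 6L,
    primary_p_max = 0.01, primary_lfc_min = 0.2,
    relaxed_p_max = 0.05, relaxed_fc_bounds = c(1.3, 0.75),
    k_components = 3L, pca_policy = "refit_per_fold", lambda = 1e-3,
    subgroup_components = c(1L, 2L),
    run_permutation = TRUE, n_permutations = 2000L, permutation_seed = 1L,
    run_subset_test = FALSE, annotations = NULL,
    annotation_flag = "flagged", n_draws = 500L, subset_seed = 1L)
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1L]]))
    overrides <- overrides[[1L]]
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown pipeline configuration key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

## small stable hash (FNV-1a, 32-bit) of the deparsed configuration,
## recorded in the manifest so reruns are comparable
.config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages on a synthetic cohort (or user-supplied fragment
#' tables): quantification (rollup, total-sum normalization, replicate
#' averaging), differential abundance under the primary and relaxed
#' filters, square-root/Pareto PCA with subgroup selection, a
#' subgroup-restricted differential comparison (core cases versus
#' controls), the principal-component LOOCV classifier, an optional
#' label-permutation test and an optional panel specificity test. All stage
#' outputs are written as TSV files to \code{out_dir} together with a
#' plain-text run manifest (versions, seeds, configuration echo and hash).
#' A failure in any stage aborts with an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (\code{cohort}, \code{matrices}, \code{differential},
#'   \code{differential_primary}, \code{differential_relaxed},
#'   \code{pca}, \code{subgroup}, \code{differential_subgroup},
#'   \code{classifier}, \code{permutation}, \code{subset}).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  wr <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  t0 <- Sys.time()
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  ## --- input ------------------------------------------------------------
  cohort <- stage("input", {
    if (!is.null(config$input_dir)) {
      list(fragments = read_fragment_table(
             file.path(config$input_dir, "fragments.tsv")),
           runs = read_metadata(file.path(config$input_dir, "runs.tsv")),
           samples = read_metadata(
             file.path(config$input_dir, "samples.tsv")),
           truth = NULL, config = NULL)
    } else {
      generate_cohort(do.call(cohort_config, config$cohort))
    }
  })
  note("input: %d fragment rows, %d runs, %d samples",
       nrow(cohort$fragments), nrow(cohort$runs), nrow(cohort$samples))

  ## --- quantify ---------------------------------------------------------
  mats <- stage("quantify", suppressWarnings(
    quantify_cohort(cohort$fragments, cohort$runs,
                    config$top_peptides, config$top_fragments)))
  write_protein_matrix(mats$normalized,
                       file.path(out_dir, "matrix_normalized.tsv"))
  write_protein_matrix(mats$averaged,
                       file.path(out_dir, "matrix_averaged.tsv"))
  note("quantify: %d proteins x %d samples", nrow(mats$averaged$values),
       ncol(mats$averaged$values))

  ## --- differential (all cases) ----------------------------------------
  primary <- filter_spec(config$primary_p_max,
                         lfc_min_abs = config$primary_lfc_min)
  relaxed <- filter_spec(config$relaxed_p_max,
                         fc_bounds = config$relaxed_fc_bounds)
  de <- stage("differential", t_test_protein(mats$averaged,
                                             cohort$samples))
  de_primary <- apply_filter(de, primary)
  de_relaxed <- apply_filter(de, relaxed)
  wr(format_differential(de), "differential_all.tsv")
  wr(format_differential(de_primary), "differential_primary.tsv")
  wr(format_differential(de_relaxed), "differential_relaxed.tsv")
  note("differential: %d primary, %d relaxed of %d proteins",
       nrow(de_primary), nrow(de_relaxed), nrow(de))

  ## --- stratify ---------------------------------------------------------
  pca <- stage("stratify", suppressWarnings(
    sqrt_pareto_pca(mats$averaged)))
  sg <- stage("stratify", select_subgroup(pca, cohort$samples,
                                          config$subgroup_components))
  wr(data.frame(sample_id = rownames(pca$scores), pca$scores),
     "pca_scores.tsv")
  wr(data.frame(protein_id = rownames(pca$loadings),
                pca$loadings[, config$subgroup_components, drop = FALSE]),
     "pca_loadings.tsv")
  wr(data.frame(component = paste0("PC", seq_along(pca$explained_pct)),
                explained_pct = pca$explained_pct), "pca_explained.tsv")
  wr(data.frame(
    sample_id = names(sg$cluster),
    status = ifelse(names(sg$cluster) %in% sg$excluded_case_ids,
                    "excluded_case",
                    ifelse(names(sg$cluster) %in% sg$core_case_ids,
                           "core_case", "control"))),
     "subgroup_assignment.tsv")
  note("stratify: %d core / %d excluded case(s), silhouette %.3f%s",
       length(sg$core_case_ids), length(sg$excluded_case_ids),
       sg$silhouette, if (sg$stable) "" else " (unstable)")

  ## --- subgroup-restricted differential ---------------------------------
  de_sub <- stage("differential_subgroup", {
    keep <- !colnames(mats$averaged$values) %in% sg$excluded_case_ids
    sub_m <- protein_matrix(
      mats$averaged$values[, keep, drop = FALSE], stage = "averaged")
    apply_filter(t_test_protein(sub_m, cohort$samples), primary)
  })
  wr(format_differential(de_sub), "differential_subgroup_primary.tsv")
  note("differential_subgroup: %d proteins pass the primary filter",
       nrow(de_sub))

  ## --- classify ---------------------------------------------------------
  clf <- stage("classify", pc_logistic_loocv(
    mats$averaged, cohort$samples, config$k_components,
    config$pca_policy, config$lambda))
  wr(clf$per_sample, "loocv_predictions.tsv")
  note("classify: %d/%d LOOCV errors", clf$error_count,
       nrow(clf$per_sample))

  perm <- NULL
  if (isTRUE(config$run_permutation)) {
    perm <- stage("permtest", permutation_test(
      mats$averaged, cohort$samples, config$k_components, clf,
      config$n_permutations, config$permutation_seed,
      config$pca_policy, config$lambda))
    wr(data.frame(null_error = perm$null_errors), "permutation_null.tsv")
    note("permtest: p = %.4g (%s, %d permutations)", perm$p_value,
         perm$method, perm$n_permutations)
  }

  ## --- subset specificity -----------------------------------------------
  subset_res <- NULL
  if (isTRUE(config$run_subset_test)) {
    subset_res <- stage("subsettest", {
      ann <- config$annotations
      if (identical(ann, "planted")) {
        if (is.null(cohort$truth))
          stop("'planted' annotations need a simulated cohort")
        ann <- data.frame(protein_id = cohort$truth$protein_id,
                          stringsAsFactors = FALSE)
        ann[[config$annotation_flag]] <-
          as.integer(cohort$truth$is_de)
        ann <- ann[ann$protein_id %in%
                     rownames(mats$averaged$values), ]
      }
      run_subset_test(mats$averaged, cohort$samples, ann,
                      config$annotation_flag, config$k_components,
                      config$pca_policy, config$lambda,
                      n_draws = config$n_draws,
                      seed = config$subset_seed)
    })
    wr(data.frame(random_error = subset_res$random_errors),
       "subset_null_errors.tsv")
    wr(data.frame(statistic = c("subset_size", "subset_error",
                                "subset_logloss", "empirical_p"),
                  value = c(subset_res$subset_size,
                            subset_res$subset_error,
                            subset_res$subset_logloss,
                            subset_res$empirical_p)),
       "subset_summary.tsv")
    note("subsettest: panel error %d, empirical p = %.4g",
         subset_res$subset_error, subset_res$empirical_p)
  }

  ## --- manifest ---------------------------------------------------------
  flat_cfg <- vapply(unclass(config), function(v) {
    if (is.null(v)) "NULL"
    else if (is.data.frame(v)) sprintf("<data.frame %d rows>", nrow(v))
    else paste(unlist(v), collapse = ",")
  }, character(1L))
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("swathdia"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("config_hash: %s", .config_hash(config)),
    sprintf("elapsed_s: %.1f",
            as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    sprintf("config.%s: %s", names(flat_cfg), unname(flat_cfg)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))

  invisible(list(cohort = cohort, matrices = mats, differential = de,
                 differential_primary = de_primary,
                 differential_relaxed = de_relaxed, pca = pca,
                 subgroup = sg, differential_subgroup = de_sub,
                 classifier = clf, permutation = perm,
                 subset = subset_res))
}

#' Check the packaged published-table fixtures for internal consistency
#'
#' The package ships transcriptions of the published differential tables
#' (\code{tables2_3.tsv}: the 60 primary-filter proteins; \code{table4.tsv}:
#' the mitochondria-related panel under the relaxed filter). This check
#' verifies that (a) every row satisfies its table's filter and (b) where a
#' table prints both a log10 fold-change and a fold-change, they agree
#' (\code{10^log10_fc} vs \code{fold_change} within a relative tolerance,
#' default 2\%, since the two columns were rounded independently for
#' printing). Threshold comparisons receive half-quantum slack for the
#' printed rounding (see [apply_filter()]). Violations are reported, not
#' raised.
#'
#' @param dir directory holding the fixture files; defaults to the
#'   installed package data.
#' @param roundtrip_rel_tol relative tolerance for the fold-change
#'   round-trip (default 0.02).
#' @return data.frame report with one row per check performed, columns
#'   \code{fixture}, \code{check}, \code{n}, \code{n_violations},
#'   \code{violations} (comma-separated ids, possibly empty).
#' @export
verify_fixtures <- function(dir = system.file("extdata",
                                              package = "swathdia"),
                            roundtrip_rel_tol = 0.02) {
  f23 <- file.path(dir, "tables2_3.tsv")
  f4 <- file.path(dir, "table4.tsv")
  if (!file.exists(f23) || !file.exists(f4))
    stop("fixture file(s) missing under ", dir)
  t23 <- utils::read.delim(f23, stringsAsFactors = FALSE)
  t4 <- utils::read.delim(f4, stringsAsFactors = FALSE)

  report <- list()
  add <- function(fixture, check, ids_all, bad) {
    report[[length(report) + 1L]] <<- data.frame(
      fixture = fixture, check = check, n = length(ids_all),
      n_violations = sum(bad),
      violations = paste(ids_all[bad], collapse = ","),
      stringsAsFactors = FALSE)
  }

  t23$row_id <- seq_len(nrow(t23))
  t4$row_id <- seq_len(nrow(t4))

  ## tables 2+3: every row must pass the primary filter (printed rounding
  ## quantum 0.01 on the effect)
  kept <- apply_filter(t23, primary_filter(), rounding = 0.01)
  add("tables2_3", "passes_primary_filter", t23$gene_name,
      !t23$row_id %in% kept$row_id)
  ## directions consistent with the table of origin
  dir_ok <- (t23$log10_fc > 0) == (t23$table == 2L)
  add("tables2_3", "direction_matches_table", t23$gene_name, !dir_ok)
  ## fold-change round-trip
  rt <- abs(10^t23$log10_fc - t23$fold_change) / t23$fold_change
  add("tables2_3", "fold_change_roundtrip", t23$gene_name,
      rt > roundtrip_rel_tol)

  ## table 4: every row must pass the relaxed filter (quantum 0.01 on FC)
  kept4 <- apply_filter(t4, relaxed_filter(), rounding = 0.01)
  add("table4", "passes_relaxed_filter", t4$protein_name,
      !t4$row_id %in% kept4$row_id)
  dir4 <- ifelse(t4$fold_change > 1, "increased", "decreased")
  add("table4", "direction_matches_table", t4$protein_name,
      dir4 != t4$direction)

  do.call(rbind, report)
}
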