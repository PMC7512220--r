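#' Synthetic SWATH-like cohort configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. The
#' defaults emulate the study design this pipeline targets: 11 cases and 9
#' controls measured in technical triplicate, with the disease signal carried
#' by a 9-of-11 case subgroup (the remaining two cases are generated from the
#' control distribution, so stratification has something real to find),
#' thousands of proteins of which a set carries planted case/control effects
#' of 0.2-0.5 log10 units.
#'
#' Intensities are drawn on a log10 scale and exponentiated, so fragment
#' intensities are long-tailed (log-normal) as in MS data, and the "top
#' peptides / top fragments" rollup selection is non-trivial. Coefficients of
#' variation are specified on the linear scale and converted internally to
#' log-normal sigma via \code{sqrt(log(1 + cv^2))}.
#'
#' @param n_cases,n_controls number of case / control samples.
#' @param n_subgroup_cases number of cases that actually carry the planted
#'   disease signal; the remaining cases are signal-free.
#' @param n_proteins number of proteins in the library.
#' @param peptides_per_protein,fragments_per_peptide list with element
#'   \code{mean}: counts are drawn as \code{1 + rpois(mean - 1)} so every
#'   protein has at least one peptide and every peptide one fragment.
#' @param n_replicates technical replicates (runs) per sample.
#' @param n_de_proteins number of planted differential proteins (may be 0).
#' @param effect_log10fc length-2 range of planted |log10 fold-change|;
#'   a single value is treated as a degenerate range.
#' @param frac_up fraction of planted effects that are increases in cases.
#' @param noise_cv fragment-level biological coefficient of variation
#'   (sample-to-sample, linear scale).
#' @param replicate_cv technical replicate coefficient of variation.
#' @param run_depth_factor_sd sd (log10 units) of the per-run global depth
#'   factor; this is exactly what total-sum normalization must remove.
#' @param missing_rate probability that a fragment is unobserved in a run;
#'   missing observations are absent rows, not zeros.
#' @param seed integer seed; identical configs give byte-identical cohorts.
#'
#' @return a validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_cases = 11L, n_controls = 9L,
                          n_subgroup_cases = 9L, n_proteins = 2970L,
                          peptides_per_protein = list(mean = 8),
                          fragments_per_peptide = list(mean = 8),
                          n_replicates = 3L, n_de_proteins = 99L,
                          effect_log10fc = c(0.2, 0.5), frac_up = 0.5,
                          noise_cv = 0.2, replicate_cv = 0.1,
                          run_depth_factor_sd = 0.1, missing_rate = 0.05,
                          seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_subgroup_cases = as.integer(n_subgroup_cases),
              n_proteins = as.integer(n_proteins),
              peptides_per_protein = peptides_per_protein,
              fragments_per_peptide = fragments_per_peptide,
              n_replicates = as.integer(n_replicates),
              n_de_proteins = as.integer(n_de_proteins),
              effect_log10fc = as.numeric(effect_log10fc),
              frac_up = as.numeric(frac_up), noise_cv = as.numeric(noise_cv),
              replicate_cv = as.numeric(replicate_cv),
              run_depth_factor_sd = as.numeric(run_depth_factor_sd),
              missing_rate = as.numeric(missing_rate), seed = as.integer(seed))

  chk_count <- function(x, nm, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min)
      stop(sprintf("invalid cohort configuration: '%s' must be a count >= %d",
                   nm, min), call. = FALSE)
  }
  chk_count(cfg$n_cases, "n_cases"); chk_count(cfg$n_controls, "n_controls")
  chk_count(cfg$n_subgroup_cases, "n_subgroup_cases", 0L)
  chk_count(cfg$n_proteins, "n_proteins")
  chk_count(cfg$n_replicates, "n_replicates")
  chk_count(cfg$n_de_proteins, "n_de_proteins", 0L)
  if (cfg$n_subgroup_cases > cfg$n_cases)
    stop("invalid cohort configuration: 'n_subgroup_cases' must be <= n_cases",
         call. = FALSE)
  if (cfg$n_de_proteins > cfg$n_proteins)
    stop("invalid cohort configuration: 'n_de_proteins' must be <= n_proteins",
         call. = FALSE)
  for (nm in c("peptides_per_protein", "fragments_per_peptide")) {
    m <- cfg[[nm]]$mean
    if (is.null(m) || length(m) != 1L || is.na(m) || m < 1)
      stop(sprintf("invalid cohort configuration: '%s' needs a mean >= 1", nm),
           call. = FALSE)
  }
  if (length(cfg$effect_log10fc) == 1L)
    cfg$effect_log10fc <- rep(cfg$effect_log10fc, 2L)
  if (length(cfg$effect_log10fc) != 2L || any(cfg$effect_log10fc < 0) ||
      diff(cfg$effect_log10fc) < 0)
    stop("invalid cohort configuration: 'effect_log10fc' must be a non-negative non-decreasing range",
         call. = FALSE)
  if (is.na(cfg$frac_up) || cfg$frac_up < 0 || cfg$frac_up > 1)
    stop("invalid cohort configuration: 'frac_up' must lie in [0, 1]",
         call. = FALSE)
  for (nm in c("noise_cv", "replicate_cv", "run_depth_factor_sd")) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0)
      stop(sprintf("invalid cohort configuration: '%s' must be >= 0", nm),
           call. = FALSE)
  }
  if (is.na(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid cohort configuration: 'missing_rate' must lie in [0, 1)",
         call. = FALSE)
  if (is.na(cfg$seed))
    stop("invalid cohort configuration: 'seed' must be an integer",
         call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# linear-scale CV -> sigma of the log10-normal
.cv_to_sd_log10 <- function(cv) sqrt(log(1 + cv^2)) / log(10)

# run generator stages on an isolated RNG stream, restoring global state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic fragment-level SWATH-like cohort
#'
#' Simulates a case/control DIA cohort at fragment-ion resolution with known
#' ground truth. Per fragment, the expected log10 intensity is the sum of a
#' protein baseline, a peptide ionization term and a fragment share (all
#' normal on the log10 scale), plus the planted effect for differential
#' proteins in signal-carrying case samples, plus fragment x sample
#' biological noise. Replicate runs of one sample share that sample-level
#' expectation and add technical noise and a per-run global depth factor.
#' Fragments failing the detection draw are absent rows.
#'
#' @param config a [cohort_config()].
#' @return a list with elements \code{fragments} (data.frame: protein_id,
#'   peptide_id, fragment_id, run_id, intensity), \code{runs} (run_id,
#'   sample_id, replicate_index), \code{samples} (sample_id, group),
#'   \code{truth} (protein_id, is_de, true_log10fc; the signal-carrying case
#'   ids are in \code{attr(truth, "subgroup_members")}) and \code{config}.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  cfg <- config
  .with_seed(cfg$seed, {
    stage_seed <- sample.int(.Machine$integer.max - 1L, 6L)

    ## --- design: feature tree and sample frame --------------------------
    set.seed(stage_seed[1L])
    sample_ids <- c(sprintf("P%d", seq_len(cfg$n_cases)),
                    sprintf("C%d", seq_len(cfg$n_controls)))
    samples <- data.frame(
      sample_id = sample_ids,
      group = rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls)),
      stringsAsFactors = FALSE)
    runs <- data.frame(
      run_id = paste0(rep(sample_ids, each = cfg$n_replicates), "_R",
                      rep(seq_len(cfg$n_replicates), length(sample_ids))),
      sample_id = rep(sample_ids, each = cfg$n_replicates),
      replicate_index = rep(seq_len(cfg$n_replicates), length(sample_ids)),
      stringsAsFactors = FALSE)

    prot_ids <- sprintf("PROT%05d", seq_len(cfg$n_proteins))
    n_pep <- 1L + stats::rpois(cfg$n_proteins,
                               max(cfg$peptides_per_protein$mean - 1, 0))
    pep_prot <- rep.int(seq_len(cfg$n_proteins), n_pep)
    pep_within <- sequence(n_pep)
    n_pep_total <- length(pep_prot)
    n_frag <- 1L + stats::rpois(n_pep_total,
                                max(cfg$fragments_per_peptide$mean - 1, 0))
    frag_pep <- rep.int(seq_len(n_pep_total), n_frag)
    frag_within <- sequence(n_frag)
    n_frag_total <- length(frag_pep)
    frag_prot <- pep_prot[frag_pep]

    pep_ids <- sprintf("%s_PEP%02d", prot_ids[pep_prot], pep_within)
    frag_ids <- sprintf("%s_F%02d", pep_ids[frag_pep], frag_within)

    ## --- truth: planted effects and subgroup ----------------------------
    set.seed(stage_seed[2L])
    true_lfc <- numeric(cfg$n_proteins)
    if (cfg$n_de_proteins > 0L) {
      de_idx <- sort(sample.int(cfg$n_proteins, cfg$n_de_proteins))
      mag <- stats::runif(cfg$n_de_proteins,
                          cfg$effect_log10fc[1L], cfg$effect_log10fc[2L])
      n_up <- round(cfg$frac_up * cfg$n_de_proteins)
      sgn <- rep(-1, cfg$n_de_proteins)
      if (n_up > 0L) sgn[sample.int(cfg$n_de_proteins, n_up)] <- 1
      true_lfc[de_idx] <- sgn * mag
    }
    case_ids <- samples$sample_id[samples$group == "case"]
    subgroup <- sort(sample(case_ids, cfg$n_subgroup_cases))
    truth <- data.frame(protein_id = prot_ids, is_de = true_lfc != 0,
                        true_log10fc = true_lfc, stringsAsFactors = FALSE)
    attr(truth, "subgroup_members") <- subgroup

    ## --- baselines: long-tailed fragment abundances ---------------------
    set.seed(stage_seed[3L])
    base_prot <- stats::rnorm(cfg$n_proteins, mean = 5, sd = 1)
    eff_pep <- stats::rnorm(n_pep_total, sd = 0.5)
    eff_frag <- stats::rnorm(n_frag_total, sd = 0.4)
    frag_mu <- base_prot[frag_prot] + eff_pep[frag_pep] + eff_frag

    ## --- sample-level expectations (shared by replicates) ---------------
    set.seed(stage_seed[4L])
    n_samp <- nrow(samples)
    sd_bio <- .cv_to_sd_log10(cfg$noise_cv)
    mu <- matrix(frag_mu, nrow = n_frag_total, ncol = n_samp) +
      matrix(stats::rnorm(n_frag_total * n_samp) * sd_bio,
             nrow = n_frag_total)
    signal_cols <- which(samples$sample_id %in% subgroup)
    if (length(signal_cols) > 0L && any(true_lfc != 0))
      mu[, signal_cols] <- mu[, signal_cols] + true_lfc[frag_prot]

    ## --- runs: technical noise, depth factor, missingness ---------------
    set.seed(stage_seed[5L])
    depth <- stats::rnorm(nrow(runs)) * cfg$run_depth_factor_sd
    sd_tech <- .cv_to_sd_log10(cfg$replicate_cv)
    samp_col <- match(runs$sample_id, samples$sample_id)
    pieces <- vector("list", nrow(runs))
    for (r in seq_len(nrow(runs))) {
      lg <- mu[, samp_col[r]] +
        stats::rnorm(n_frag_total) * sd_tech + depth[r]
      keep <- if (cfg$missing_rate > 0)
        stats::runif(n_frag_total) >= cfg$missing_rate
      else rep(TRUE, n_frag_total)
      pieces[[r]] <- data.table::data.table(
        protein_id = prot_ids[frag_prot[keep]],
        peptide_id = pep_ids[frag_pep[keep]],
        fragment_id = frag_ids[keep],
        run_id = runs$run_id[r],
        intensity = 10^lg[keep])
    }
    fragments <- as.data.frame(data.table::rbindlist(pieces))

    list(fragments = fragments, runs = runs, samples = samples,
         truth = truth, config = cfg)
  })
}

#' Write a synthetic cohort to TSV files
#'
#' Writes the fragment table, run map, sample table and truth table of a
#' generated cohort into a directory as plain tab-separated files
#' (\code{fragments.tsv}, \code{runs.tsv}, \code{samples.tsv},
#' \code{truth.tsv}) plus the configuration as a flat \code{key\tvalue} file
#' (\code{config.tsv}).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(cohort$fragments, "fragments.tsv")
  wr(cohort$runs, "runs.tsv")
  wr(cohort$samples, "samples.tsv")
  tr <- cohort$truth
  tr$in_subgroup <- paste(attr(cohort$truth, "subgroup_members"),
                          collapse = ",")
  wr(tr, "truth.tsv")
  cfg <- cohort$config
  flat <- vapply(cfg, function(v)
    paste(unlist(v), collapse = ","), character(1L))
  utils::write.table(
    data.frame(key = names(flat), value = unname(flat)),
    file.path(dir, "config.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
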